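# Shared fixtures: tiny genomes, random interval sets, and brute-force
# oracles used to cross-check the interval engine and the classifier.

tiny_genome <- function() define_genome(c(chrA = 1e6, chrB = 8e5))

random_intervals <- function(n, genome, max_len = 5000, label = "rand",
                             strand = ".") {
  chrom <- sample(names(genome), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n, 0, unname(genome[chrom]) - len))
  interval_set(chrom, start, start + len, strand = strand, label = label,
               genome = genome)
}

# O(n*m) all-pairs overlap oracle, independent of the IRanges path.
brute_membership <- function(sites, regions) {
  vapply(seq_len(nrow(sites)), function(i) {
    any(vapply(seq_len(nrow(regions)), function(j)
      sites$chrom[i] == regions$chrom[j] &&
        sites$start[i] < regions$end[j] &&
        regions$start[j] < sites$end[i], logical(1)))
  }, logical(1))
}

# Independent per-site re-derivation of the classification rule.
brute_classify <- function(sites, a, b, d) {
  vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, , drop = FALSE]
    in_a <- brute_membership(s, a)
    in_b <- brute_membership(s, b)
    in_d <- brute_membership(s, d)
    if (!(in_a || in_d)) "in_vitro_only"
    else if (in_a && in_b && !in_d) "ambiguous"
    else "in_vivo"
  }, character(1))
}

# Exact two-sided Mann-Whitney p by enumerating all rank assignments
# (tie-free inputs only).
brute_ranksum_p <- function(a, b) {
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  mu <- length(a) * length(b) / 2
  combos <- utils::combn(n, length(a))
  us <- apply(combos, 2, function(i) sum(i) - length(a) * (length(a) + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

small_synth <- function(seed = 1, ...) {
  simulate_dataset(synth_config(genome = c(chr1 = 2e6, chr2 = 2e6),
                                n_sites = 400, seed = seed, ...))
}
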