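test_that("composite profiles reproduce delta, flat and oriented coverage", {
  gen <- define_genome(c(chr1 = 1e5))
  sites <- interval_set("chr1", c(10000, 30000, 60000),
                        c(10400, 30400, 60400),
                        strand = c("+", "+", "+"), label = "s")
  cen <- interval_center(sites)
  delta <- bedgraph("chr1", cen, cen + 1, 1)
  pr <- composite_profile(delta, sites, gen, half_width = 50)
  expect_equal(pr$value[pr$offset == 0], 1)
  expect_equal(sum(pr$value), 1)

  flat <- bedgraph("chr1", 0, 1e5, 3.5)
  pf <- composite_profile(flat, sites, gen, half_width = 100)
  expect_true(all(pf$value == 3.5))

  # a one-sided signal flips for minus-strand sites
  right <- bedgraph("chr1", cen, cen + 30, 1)  # signal right of center
  plus <- composite_profile(right, sites, gen, half_width = 50)
  minus_sites <- sites; minus_sites$strand <- "-"
  minus <- composite_profile(right, minus_sites, gen, half_width = 50)
  expect_equal(minus$value, rev(plus$value))

  # truncated sites are excluded and counted
  edge <- interval_set("chr1", c(10, 30000), c(410, 30400), label = "s")
  pe <- composite_profile(flat, edge, gen, half_width = 1000)
  expect_equal(attr(pe, "n_excluded"), 1)
  expect_equal(pe$n[1], 1)

  expect_error(composite_profile(flat, sites[0, ], gen), "empty")
})

test_that("composite profile of simulated coverage is a 2L - m trapezoid", {
  gen <- define_genome(c(chr1 = 1e5))
  L <- 100; m <- 34
  s <- interval_set("chr1", 50000 - (L - m) - 16, 50000 + L - 16,
                    strand = "+", label = "s",
                    extra = data.frame(motif_start = 50000 - 16,
                                       motif_end = 50000 - 16 + m))
  set.seed(8)
  cov <- simulate_affinity_coverage(s, L, depth = 5000)
  pr <- composite_profile(cov, s, gen, half_width = 120)
  support <- pr$offset[pr$value > 0]
  expect_equal(max(support) - min(support) + 1, 2 * L - m)
  # plateau over the motif (positions covered by every admissible
  # fragment), monotone shoulders
  peak <- max(pr$value)
  cen <- interval_center(s)
  motif_offsets <- pr$offset >= (s$motif_start - cen) &
    pr$offset <= (s$motif_end - 1 - cen)
  expect_true(all(pr$value[motif_offsets] > 0.97 * peak))
  left <- pr$value[pr$offset < (s$motif_start - cen) & pr$value > 0]
  expect_true(all(diff(left) >= -0.05 * peak))
})

test_that("nucleotide profiles align, orient and normalise per position", {
  seqs <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 250)))
  # two sites sharing one plus-strand sequence
  sites <- interval_set("chr1", c(100, 500), c(120, 520), strand = "+",
                        label = "s",
                        extra = data.frame(motif_start = c(104, 504),
                                           motif_end = c(112, 512)))
  pr <- nucleotide_frequency_profile(seqs, sites, flank = 4)
  freqs <- as.matrix(stats::xtabs(value ~ offset + channel,
                                  as.data.frame(pr)))
  expect_true(all(abs(rowSums(freqs) - 1) < 1e-9))
  expect_true(all(apply(freqs, 1, max) == 1))  # identical sequences

  # orientation equivariance: reverse-complement the genome, flip strands
  rc <- Biostrings::reverseComplement(seqs)
  names(rc) <- names(seqs)
  len <- Biostrings::width(seqs)[1]
  flipped <- sites
  flipped$strand <- "-"
  flipped$motif_start <- len - sites$motif_end
  flipped$motif_end <- len - sites$motif_start
  tmp <- as.data.frame(flipped)
  tmp$start <- len - sites$end; tmp$end <- len - sites$start
  flipped <- as_interval_set(tmp, label = "s")
  pr2 <- nucleotide_frequency_profile(rc, flipped, flank = 4)
  expect_equal(as.data.frame(pr)[order(pr$offset, pr$channel), ],
               as.data.frame(pr2)[order(pr2$offset, pr2$channel), ],
               ignore_attr = TRUE)

  # sites beyond the contig are skipped with a count
  far <- interval_set("chr1", 990, 999, strand = "+", label = "s",
                      extra = data.frame(motif_start = 992,
                                         motif_end = 1000))
  both <- as_interval_set(rbind(as.data.frame(sites)[1, ],
                                as.data.frame(far)), label = "s")
  pr3 <- nucleotide_frequency_profile(seqs, both, flank = 4)
  expect_equal(attr(pr3, "n_skipped"), 1)
})

test_that("implanted motif weights are recovered from the toy genome", {
  tr <- small_synth(seed = 131)
  seqs <- simulate_genome_sequence(tr)
  pr <- nucleotide_frequency_profile(seqs, tr$sites, flank = 10)
  mod <- tr$motif
  for (p in mod$invariant) {
    v <- pr$value[pr$offset == p - 1 & pr$channel == mod$major[p]]
    expect_gt(v, 0.8)  # 0.9 true weight, ~400 sites
  }
  flank_vals <- pr$value[pr$offset < 0]
  expect_lt(max(abs(flank_vals - 0.25)), 0.12)
})

test_that("SNP ratio profiles normalise to mean 1 and flag empty windows", {
  gen <- define_genome(c(chr1 = 1e6))
  set.seed(19)
  sites <- random_intervals(500, gen, max_len = 300, strand = "+")
  snp_pos <- sort(sample.int(1e6, 50000)) - 1
  snps <- interval_set("chr1", snp_pos, snp_pos + 1, label = "snp")
  pr <- snp_density_profile(snps, sites, window = 2000)
  expect_equal(mean(pr$value), 1, tolerance = 1e-12)
  expect_lt(max(abs(pr$value - 1)), 1)     # uniform SNPs: ratio near 1

  none <- interval_set("chr1", 0, 1, label = "snp")
  far_sites <- interval_set("chr1", 5e5, 5e5 + 100, label = "s")
  expect_error(snp_density_profile(none, far_sites), "undefined")

  smoothed <- snp_density_profile(snps, sites, window = 2000, smooth = 51)
  expect_equal(mean(smoothed$value), 1, tolerance = 1e-9)
  expect_error(snp_density_profile(snps, sites, smooth = 4), "odd")
})

test_that("binned log2 enrichment is scaled, guarded and localised", {
  gen <- define_genome(c(chr1 = 2e4))
  track <- bedgraph("chr1", 0, 2e4, 10)
  same <- binned_log2_enrichment(track, track, gen, bin = 2000)
  expect_true(all(same$value == 0))
  expect_equal(nrow(same), 10)

  # doubled on half the genome, absent on the other half; totals equal
  sample_tr <- bedgraph("chr1", 0, 1e4, 20)
  enr <- binned_log2_enrichment(sample_tr, track, gen, bin = 2000,
                                pseudocount = 1)
  expect_equal(enr$value[enr$start < 1e4], rep(1, 5), tolerance = 0.01)
  expect_lt(max(enr$value[enr$start >= 1e4]), -10)

  # zero-count bins give 0, never infinities
  empty <- bedgraph("chr1", 0, 1, 0)
  z <- binned_log2_enrichment(empty, empty, gen, bin = 2000)
  expect_true(all(is.finite(z$value)))
  expect_true(all(z$value == 0))

  bad <- bedgraph("chrX", 0, 100, 1)
  expect_error(binned_log2_enrichment(bad, track, gen), "not in genome")
})
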