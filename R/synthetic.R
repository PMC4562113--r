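# Synthetic-data generator: a toy genome carrying a binding-site catalog with
# log-normal affinities, chromatin-domain mosaics, a logistic
# affinity-vs-chromatin-barrier activation model, in-vivo mark peaks, SNPs
# enriched at active sites, and (separately) fragment-coverage tracks. It
# provides ground truth so every downstream estimator is testable without
# sequencing data.

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe a toy study: 2 chromosomes x 10 Mb and 2,000 binding
#' sites, with activation parameters calibrated so roughly half of the sites
#' activate. A site's peak interval spans `2 * fragment_length - motif_length`
#' bp centered on its motif (the aggregate footprint of fragments that fully
#' contain the motif).
#'
#' @param genome Named numeric vector of chromosome lengths (bp).
#' @param n_sites Total number of binding sites (>= 2 per chromosome).
#' @param affinity_meanlog,affinity_sdlog Parameters of the log-normal
#'   affinity distribution (log of ppm).
#' @param motif_length Informative motif span in bp (default 31).
#' @param fragment_length Mean sheared-fragment length in bp (default 177,
#'   giving a 323-bp site footprint).
#' @param domain_specs Per domain type, a list with `fraction` (target genome
#'   fraction in `[0, 1]`) and `mean_length` (mean segment length, bp).
#'   Types `H3K9me2`, `H3K9me3`, `cLAD` act as chromatin barriers; `gene`
#'   defines gene bodies.
#' @param activation List with `baseline_logodds`, `affinity_coeff`,
#'   `barrier_penalty` (named vector over barrier domain types) and
#'   `expression_coeff`. A site activates with probability
#'   `plogis(baseline + affinity_coeff * log(affinity) -
#'   sum(barrier_penalty[d] * in_domain_d) + expression_coeff * log1p(FPKM))`.
#' @param expression_meanlog,expression_sdlog Log-normal FPKM parameters for
#'   gene expression.
#' @param ambiguous_fraction Fraction of sites given promoter-like H3K4me3
#'   peaks in both strains with no DMC1 (the ambiguous class).
#' @param snp List with `background_rate` (SNPs per bp) and `enrichment`
#'   (rate multiplier, >= 1, within the central `motif_length` bp of
#'   historically active sites).
#' @param gaps Optional data frame `chrom, start, end` of implanted site-free
#'   spans.
#' @param peak_width Named list of peak widths (bp) for `h3k4me3`, `dmc1`,
#'   `prdm9_chip`.
#' @param min_site_spacing Minimum distance between site centers (bp).
#' @param seed Integer seed; the whole dataset is deterministic given it.
#'
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(genome = c(chr1 = 1e7, chr2 = 1e7),
                         n_sites = 2000,
                         affinity_meanlog = 1.5,
                         affinity_sdlog = 1,
                         motif_length = 31,
                         fragment_length = 177,
                         domain_specs = list(
                           H3K9me2 = list(fraction = 0.35, mean_length = 3e5),
                           H3K9me3 = list(fraction = 0.15, mean_length = 2e5),
                           cLAD = list(fraction = 0.30, mean_length = 5e5),
                           gene = list(fraction = 0.35, mean_length = 3e4)),
                         activation = list(
                           baseline_logodds = -0.95,
                           affinity_coeff = 1.0,
                           barrier_penalty = c(H3K9me2 = 1.5, H3K9me3 = 2.0,
                                               cLAD = 1.0),
                           expression_coeff = 0.4),
                         expression_meanlog = 1.0,
                         expression_sdlog = 1.5,
                         ambiguous_fraction = 0.04,
                         snp = list(background_rate = 0.005, enrichment = 3),
                         gaps = NULL,
                         peak_width = list(h3k4me3 = 1000, dmc1 = 1400,
                                           prdm9_chip = 300),
                         min_site_spacing = 200,
                         seed = 1L) {
  cfg <- list(genome = define_genome(genome), n_sites = as.integer(n_sites),
              affinity_meanlog = affinity_meanlog,
              affinity_sdlog = affinity_sdlog,
              motif_length = as.integer(motif_length),
              fragment_length = as.integer(fragment_length),
              domain_specs = domain_specs, activation = activation,
              expression_meanlog = expression_meanlog,
              expression_sdlog = expression_sdlog,
              ambiguous_fraction = ambiguous_fraction, snp = snp,
              gaps = gaps, peak_width = peak_width,
              min_site_spacing = min_site_spacing, seed = as.integer(seed))
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$motif_length >= cfg$fragment_length)
    stop("motif_length must be smaller than fragment_length")
  if (cfg$n_sites < 2 * length(cfg$genome))
    stop("need at least 2 sites per chromosome")
  fr <- vapply(cfg$domain_specs, function(d) d$fraction, numeric(1))
  if (any(fr < 0 | fr > 1)) stop("domain fractions must be in [0, 1]")
  if (cfg$snp$enrichment < 1) stop("snp enrichment must be >= 1")
  if (cfg$ambiguous_fraction < 0 || cfg$ambiguous_fraction > 1)
    stop("ambiguous_fraction must be in [0, 1]")
  if (!is.null(cfg$gaps)) {
    g <- cfg$gaps
    if (!all(c("chrom", "start", "end") %in% names(g)))
      stop("gaps must have columns chrom, start, end")
    if (!all(g$chrom %in% names(cfg$genome)))
      stop("gap chromosome not in genome")
    if (any(g$start < 0) || any(g$end > unname(cfg$genome[g$chrom])) ||
        any(g$start >= g$end))
      stop("infeasible gap: must lie within its chromosome")
  }
  invisible(cfg)
}

# Allowed placement segments on one chromosome: [margin, len - margin] minus
# gap intervals expanded by `margin`.
.allowed_segments <- function(len, gaps, margin) {
  segs <- data.frame(start = margin, end = len - margin)
  if (is.null(gaps) || nrow(gaps) == 0) return(segs)
  g <- gaps[order(gaps$start), , drop = FALSE]
  starts <- c(segs$start, g$end + margin)
  ends <- c(g$start - margin, segs$end)
  out <- data.frame(start = starts, end = ends)
  out[out$end > out$start, , drop = FALSE]
}

# Place n centers uniformly over segments with minimum spacing, via the
# collapsed-coordinate trick; returns sorted positions.
.place_centers <- function(segs, n, spacing) {
  lens <- segs$end - segs$start
  total <- sum(lens)
  slack <- total - (n - 1) * spacing
  if (slack <= 0) stop("infeasible config: not enough room for ", n, " sites")
  u <- sort(stats::runif(n, 0, slack))
  coll <- u + (seq_len(n) - 1) * spacing
  cum <- cumsum(lens)
  seg_idx <- findInterval(coll, c(0, cum[-length(cum)] + 1e-9)) # 1..k
  seg_idx <- pmin(pmax(seg_idx, 1L), nrow(segs))
  offset <- coll - c(0, cum)[seg_idx]
  floor(segs$start[seg_idx] + offset)
}

# Alternating-segment mosaic for one chromosome: exponential in-domain
# lengths with mean `mean_len`, out-of-domain mean `mean_len * (1 - f) / f`.
.mosaic_chrom <- function(len, fraction, mean_len) {
  if (fraction <= 0) return(data.frame(start = numeric(0), end = numeric(0)))
  if (fraction >= 1) return(data.frame(start = 0, end = len))
  out_mean <- mean_len * (1 - fraction) / fraction
  n_guess <- 2 * (ceiling(len / (mean_len + out_mean) * 2) + 10)
  starts <- numeric(0); ends <- numeric(0)
  pos <- 0
  in_domain <- stats::runif(1) < fraction
  repeat {
    state <- rep(c(in_domain, !in_domain), length.out = n_guess)
    seg <- ifelse(state, stats::rexp(n_guess, 1 / mean_len),
                  stats::rexp(n_guess, 1 / out_mean))
    s <- pos + c(0, cumsum(seg[-n_guess]))
    e <- pos + cumsum(seg)
    keep <- s < len
    ks <- s[keep]; ke <- pmin(e[keep], len); kstate <- state[keep]
    starts <- c(starts, ks[kstate]); ends <- c(ends, ke[kstate])
    pos <- pos + sum(seg)
    if (pos >= len) break
    # n_guess is even, so the state entering the next batch is unchanged
  }
  df <- data.frame(start = floor(starts), end = ceiling(ends))
  df[df$end > df$start, , drop = FALSE]
}

.simulate_domains <- function(genome, spec) {
  rows <- lapply(names(genome), function(ch) {
    d <- .mosaic_chrom(unname(genome[ch]), spec$fraction, spec$mean_length)
    if (nrow(d)) cbind(chrom = ch, d) else NULL
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    return(interval_set(character(0), numeric(0), numeric(0)))
  df <- df[df$end > df$start, , drop = FALSE]
  interval_set(df$chrom, df$start, df$end)
}

#' Position weight model for the implanted binding motif
#'
#' Major bases cycle A,C,G,T along the motif except at the invariant
#' positions 8, 11, 13, 15, 16 which carry G, G, T, C, T at weight 0.9; all
#' other positions carry their major base at weight 0.55 (remaining mass
#' uniform over the other three bases).
#'
#' @param m Motif length (bp).
#' @return List with `major` (character vector), `weight` (numeric vector)
#'   and `invariant` (positions with weight 0.9).
#' @export
motif_model <- function(m) {
  major <- c("A", "C", "G", "T")[((seq_len(m) - 1) %% 4) + 1]
  weight <- rep(0.55, m)
  inv_pos <- c(8, 11, 13, 15, 16)
  inv_base <- c("G", "G", "T", "C", "T")
  keep <- inv_pos <= m
  major[inv_pos[keep]] <- inv_base[keep]
  weight[inv_pos[keep]] <- 0.9
  list(major = major, weight = weight, invariant = inv_pos[keep])
}

#' Simulate a complete synthetic dataset
#'
#' Generates binding sites (uniform outside any implanted gaps, exact total
#' count), log-normal affinities, chromatin-domain mosaics, genes with
#' expression, logistic activation, in-vivo mark peaks (H3K4me3 in two
#' "strains", DMC1, PRDM9 ChIP at the top affinity decile of activated
#' sites), promoter-like ambiguous peaks, and SNPs enriched at the motifs of
#' historically active sites. Deterministic given `config$seed`.
#'
#' @param config A [synth_config()].
#' @param dir Optional output directory; when given, all tracks are written
#'   as BED/TSV plus a config echo (YAML) and the ground-truth table.
#'
#' @return A list of class `"synth_truth"`: `config`, `genome`, `sites`
#'   (interval set with `affinity_ppm`, `motif_start`, `motif_end`,
#'   activation probability, `activated` and `ambiguous` flags), `domains`,
#'   `genes`, `peaks` (list of interval sets), `snps`, and `motif`.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  genome <- config$genome
  L <- config$fragment_length; m <- config$motif_length
  site_w <- 2 * L - m
  margin <- L + 1

  ## --- site placement -------------------------------------------------
  segs_by_chrom <- lapply(names(genome), function(ch) {
    g <- config$gaps
    g <- if (is.null(g)) NULL else g[g$chrom == ch, , drop = FALSE]
    .allowed_segments(unname(genome[ch]), g, margin)
  })
  names(segs_by_chrom) <- names(genome)
  allow_len <- vapply(segs_by_chrom, function(s) sum(s$end - s$start),
                      numeric(1))
  n_chr <- stats::setNames(
    pmax(2L, floor(config$n_sites * allow_len / sum(allow_len))),
    names(genome))
  while (sum(n_chr) != config$n_sites) {
    i <- if (sum(n_chr) < config$n_sites) which.max(allow_len / n_chr)
         else which.max(n_chr)
    n_chr[i] <- n_chr[i] + sign(config$n_sites - sum(n_chr))
  }
  centers <- lapply(names(genome), function(ch)
    .place_centers(segs_by_chrom[[ch]], n_chr[[ch]], config$min_site_spacing))
  site_chrom <- rep(names(genome), n_chr)
  site_center <- unlist(centers, use.names = FALSE)

  n <- config$n_sites
  affinity <- stats::rlnorm(n, config$affinity_meanlog, config$affinity_sdlog)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  motif_start <- site_center - floor((m - 1) / 2)
  motif_end <- motif_start + m
  start <- motif_start - (L - m)
  end <- motif_start + L
  ids <- sprintf("site_%05d", seq_len(n))

  ## --- domains, genes -------------------------------------------------
  domains <- lapply(config$domain_specs[setdiff(names(config$domain_specs),
                                                "gene")],
                    function(sp) .simulate_domains(genome, sp))
  genes <- .simulate_domains(genome, config$domain_specs$gene)
  n_gene <- nrow(genes)
  if (n_gene < 4) stop("gene mosaic produced fewer than 4 genes")
  expr <- stats::rlnorm(n_gene, config$expression_meanlog,
                        config$expression_sdlog)
  genes$score <- expr
  genes$id <- sprintf("gene_%05d", seq_len(n_gene))

  sites_df <- data.frame(chrom = site_chrom, start = start, end = end,
                         strand = strand, score = affinity, id = ids,
                         affinity_ppm = affinity, motif_start = motif_start,
                         motif_end = motif_end)

  ## --- activation model ------------------------------------------------
  pen <- config$activation$barrier_penalty
  barrier <- numeric(n)
  in_dom <- list()
  for (d in names(domains)) {
    flag <- overlap_membership(sites_df, domains[[d]])
    in_dom[[d]] <- flag
    if (d %in% names(pen)) barrier <- barrier + pen[[d]] * flag
  }
  pr <- overlap_pairs(sites_df, genes)
  x_expr <- numeric(n)
  if (nrow(pr)) {
    best <- tapply(genes$score[pr$subject], pr$query, max)
    x_expr[as.integer(names(best))] <- log1p(best)
  }
  lp <- config$activation$baseline_logodds +
    config$activation$affinity_coeff * log(affinity) - barrier +
    config$activation$expression_coeff * x_expr
  p_act <- stats::plogis(lp)
  activated <- stats::runif(n) < p_act

  ## --- ambiguous promoter-like peaks ----------------------------------
  n_amb <- round(config$ambiguous_fraction * n)
  inactive_idx <- which(!activated)
  amb_idx <- if (n_amb > 0 && length(inactive_idx))
    sort(sample(inactive_idx, min(n_amb, length(inactive_idx)))) else integer(0)
  ambiguous <- seq_len(n) %in% amb_idx

  ## --- in vivo mark peaks ----------------------------------------------
  mk_peaks <- function(idx, width, jitter, label, prefix) {
    if (!length(idx))
      return(interval_set(character(0), numeric(0), numeric(0), label = label))
    cen <- site_center[idx] + round(stats::runif(length(idx), -jitter, jitter))
    lens <- unname(genome[site_chrom[idx]])
    interval_set(site_chrom[idx],
                 pmax(0, cen - floor(width / 2)),
                 pmin(lens, cen + ceiling(width / 2)),
                 id = sprintf("%s_%05d", prefix, seq_along(idx)),
                 label = label)
  }
  act_idx <- which(activated)
  w <- config$peak_width
  h3k4me3_a <- mk_peaks(sort(c(act_idx, amb_idx)), w$h3k4me3, 50,
                        "H3K4me3_strainA", "k4a")
  h3k4me3_b <- mk_peaks(sort(c(act_idx, amb_idx)), w$h3k4me3, 50,
                        "H3K4me3_strainB", "k4b")
  dmc1 <- mk_peaks(act_idx, w$dmc1, 100, "DMC1", "dmc1")
  n_top <- ceiling(0.1 * length(act_idx))
  top_idx <- act_idx[order(affinity[act_idx], decreasing = TRUE)][seq_len(n_top)]
  prdm9_chip <- mk_peaks(sort(top_idx), w$prdm9_chip, 20, "PRDM9_ChIP", "p9")

  ## --- SNPs -------------------------------------------------------------
  b <- config$snp$background_rate; e <- config$snp$enrichment
  snp_pos <- lapply(names(genome), function(ch) {
    len <- unname(genome[ch])
    bg <- floor(stats::runif(stats::rpois(1, len * b), 0, len))
    i <- which(site_chrom == ch & activated)
    extra <- if (length(i) && e > 1) {
      k <- stats::rpois(length(i), (e - 1) * b * m)
      unlist(lapply(seq_along(i), function(j)
        if (k[j] > 0) floor(stats::runif(k[j], motif_start[i[j]],
                                         motif_end[i[j]])) else numeric(0)))
    } else numeric(0)
    sort(unique(c(bg, extra)))
  })
  names(snp_pos) <- names(genome)
  snp_df <- data.frame(
    chrom = rep(names(genome), lengths(snp_pos)),
    start = unlist(snp_pos, use.names = FALSE))
  snps <- interval_set(snp_df$chrom, snp_df$start, snp_df$start + 1,
                       label = "SNPs")

  sites <- as_interval_set(cbind(sites_df,
                                 activation_prob = p_act,
                                 activated = activated,
                                 ambiguous = ambiguous),
                           label = "binding_sites", genome = genome)

  truth <- structure(list(config = config, genome = genome, sites = sites,
                          domains = domains,
                          genes = as_interval_set(genes, label = "genes"),
                          peaks = list(h3k4me3_a = h3k4me3_a,
                                       h3k4me3_b = h3k4me3_b,
                                       dmc1 = dmc1, prdm9_chip = prdm9_chip),
                          snps = snps, motif = motif_model(m)),
                     class = "synth_truth")
  if (!is.null(dir)) write_dataset(truth, dir)
  truth
}

#' @export
print.synth_truth <- function(x, ...) {
  cat(sprintf(paste0("synthetic dataset: %d sites on %d chromosome(s), ",
                     "%d activated (%.1f%%), %d ambiguous, %d SNPs\n"),
              nrow(x$sites), length(x$genome), sum(x$sites$activated),
              100 * mean(x$sites$activated), sum(x$sites$ambiguous),
              nrow(x$snps)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' @param truth A `synth_truth` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of written file paths.
#' @export
write_dataset <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  files <- character(0)
  add <- function(path) files <<- c(files, path)

  add(write_chrom_sizes(truth$genome, p("genome.sizes")))
  add(write_bed(truth$sites, p("sites.bed")))
  for (nm in names(truth$peaks))
    add(write_bed(truth$peaks[[nm]], p(paste0(nm, ".bed"))))
  for (nm in names(truth$domains))
    add(write_bed(truth$domains[[nm]], p(paste0("domain_", nm, ".bed"))))
  add(write_bed(truth$genes, p("genes.bed")))
  add(write_bed(truth$snps, p("snps.bed")))
  tr <- as.data.frame(truth$sites)[, c("id", "chrom", "start", "end", "strand",
                                       "affinity_ppm", "motif_start",
                                       "motif_end", "activation_prob",
                                       "activated", "ambiguous")]
  add(write_tsv(tr, p("truth.tsv")))
  cfg <- truth$config
  cfg_list <- list(genome = as.list(unclass(cfg$genome)),
                   n_sites = cfg$n_sites, seed = cfg$seed,
                   affinity_meanlog = cfg$affinity_meanlog,
                   affinity_sdlog = cfg$affinity_sdlog,
                   motif_length = cfg$motif_length,
                   fragment_length = cfg$fragment_length,
                   ambiguous_fraction = cfg$ambiguous_fraction,
                   snp = cfg$snp,
                   activation = lapply(cfg$activation, function(x)
                     if (is.null(names(x))) x else as.list(x)))
  yaml::write_yaml(cfg_list, p("config.yaml"))
  add(p("config.yaml"))
  invisible(files)
}

#' Simulate fragment coverage over binding sites
#'
#' Every retained fragment (length `fragment_length`) fully contains a site's
#' motif (length `m`), so its start is uniform over the `L - m + 1` admissible
#' offsets and the aggregate per-site coverage is a trapezoid spanning exactly
#' `2L - m` bp, maximal over the motif. The coverage integral equals
#' `n_fragments x L` exactly.
#'
#' @param sites Interval set carrying `motif_start`/`motif_end` columns.
#' @param fragment_length Fragment length L (bp); must exceed the motif
#'   length.
#' @param depth Fragments sampled per site.
#' @param motif_length Optional override of the motif length; by default it
#'   is taken from the sites' motif columns (must be constant).
#' @return A [bedgraph()] coverage track (zero-coverage runs omitted).
#' @export
simulate_affinity_coverage <- function(sites, fragment_length, depth = 200,
                                       motif_length = NULL) {
  L <- fragment_length
  if (is.null(motif_length)) {
    ml <- unique(sites$motif_end - sites$motif_start)
    if (length(ml) != 1) stop("sites have non-constant motif length")
    m <- ml
  } else m <- motif_length
  if (L <= m) stop("fragment_length must exceed the motif length")
  n <- nrow(sites)
  if (n == 0) stop("no sites supplied")
  ms <- if (is.null(motif_length)) sites$motif_start
        else interval_center(sites) - floor((m - 1) / 2)
  offsets <- sample.int(L - m + 1, n * depth, replace = TRUE) - 1L
  frag_start <- rep(ms - (L - m), each = depth) + offsets
  frag_chrom <- rep(sites$chrom, each = depth)
  rows <- lapply(split(frag_start, frag_chrom), function(fs) {
    ev_pos <- c(fs, fs + L)
    ev_val <- rep(c(1, -1), each = length(fs))
    o <- order(ev_pos)
    pos <- ev_pos[o]
    cum <- cumsum(ev_val[o])
    last <- !duplicated(pos, fromLast = TRUE)
    brk <- pos[last]; val <- cum[last]
    k <- length(brk)
    data.frame(start = brk[-k], end = brk[-1], value = val[-k])
  })
  df <- do.call(rbind, Map(cbind, chrom = names(rows), rows))
  df <- df[df$value > 0, , drop = FALSE]
  bedgraph(df$chrom, df$start, df$end, df$value, label = "affinity_coverage")
}

#' Simulate the toy genome sequence with implanted motifs
#'
#' Background bases are uniform over A/C/G/T; each site receives a motif
#' instance sampled from [motif_model()] (reverse-complemented for
#' minus-strand sites) at its motif interval. Deterministic given the
#' config seed.
#'
#' @param truth A `synth_truth` object.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
simulate_genome_sequence <- function(truth) {
  cfg <- truth$config
  set.seed(cfg$seed + 104729L)  # independent stream from simulate_dataset
  bases <- c("A", "C", "G", "T")
  mod <- truth$motif
  m <- cfg$motif_length
  chroms <- names(truth$genome)
  seqs <- lapply(chroms, function(ch) {
    len <- unname(truth$genome[ch])
    paste(sample(bases, len, replace = TRUE), collapse = "")
  })
  names(seqs) <- chroms
  dna <- Biostrings::DNAStringSet(unlist(seqs))

  s <- truth$sites
  n <- nrow(s)
  inst <- matrix("", nrow = n, ncol = m)
  for (p in seq_len(m)) {
    hit <- stats::runif(n) < mod$weight[p]
    other <- setdiff(bases, mod$major[p])
    inst[, p] <- ifelse(hit, mod$major[p],
                        other[sample.int(3, n, replace = TRUE)])
  }
  inst_str <- apply(inst, 1, paste, collapse = "")
  minus <- s$strand == "-"
  if (any(minus))
    inst_str[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(inst_str[minus])))
  for (ch in chroms) {
    i <- which(s$chrom == ch)
    if (!length(i)) next
    dna[[ch]] <- Biostrings::replaceAt(
      dna[[ch]],
      IRanges::IRanges(s$motif_start[i] + 1, s$motif_end[i]),
      inst_str[i])
  }
  dna
}
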