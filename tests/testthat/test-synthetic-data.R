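test_that("same seed gives byte-identical output files", {
  cfg <- synth_config(genome = c(chr1 = 2e6), n_sites = 200, seed = 9)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, dir = d1)
  simulate_dataset(cfg, dir = d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
})

test_that("implanted gaps are site-free and the site count is exact", {
  cfg <- synth_config(genome = c(chr1 = 1e7), n_sites = 2000,
                      gaps = data.frame(chrom = "chr1", start = 4e6,
                                        end = 4.3e6), seed = 13)
  d <- withr::local_tempdir()
  simulate_dataset(cfg, dir = d)
  sites <- read_bed(file.path(d, "sites.bed"))
  expect_equal(nrow(sites), 2000)
  cen <- interval_center(sites)
  expect_equal(sum(cen >= 4e6 & cen < 4.3e6), 0)
})

test_that("infeasible configs are rejected", {
  expect_error(synth_config(gaps = data.frame(chrom = "chr1", start = 0,
                                              end = 2e7)),
               "infeasible gap")
  expect_error(synth_config(domain_specs = list(
    H3K9me2 = list(fraction = 1.2, mean_length = 1e5),
    gene = list(fraction = 0.3, mean_length = 3e4))), "fraction")
  expect_error(synth_config(motif_length = 200, fragment_length = 100),
               "motif_length")
  expect_error(synth_config(snp = list(background_rate = 0.005,
                                       enrichment = 0.5)), "enrichment")
})

test_that("realized domain fractions track their targets", {
  # SD of the realized covered fraction of an alternating exponential mosaic
  # of cycle length c = mean_in / f over genome length G is approximately
  # sqrt(2 f^2 (1-f)^2 c / G); check each domain within 3 of these SDs.
  cfg <- synth_config(seed = 21)
  tr <- simulate_dataset(cfg)
  G <- sum(tr$genome)
  for (d in names(tr$domains)) {
    f <- cfg$domain_specs[[d]]$fraction
    cyc <- cfg$domain_specs[[d]]$mean_length / f
    sd_f <- sqrt(2 * f^2 * (1 - f)^2 * cyc / G)
    realized <- covered_bp(tr$domains[[d]]) / G
    expect_lt(abs(realized - f), 3 * sd_f + 0.02)
  }
})

test_that("empirical activation rates match the logistic model", {
  tr <- simulate_dataset(synth_config(seed = 31, n_sites = 2000))
  p <- tr$sites$activation_prob
  act <- tr$sites$activated
  bins <- cut(p, breaks = quantile(p, seq(0, 1, 0.2)), include.lowest = TRUE)
  for (b in levels(bins)) {
    i <- bins == b
    se <- sqrt(mean(p[i]) * (1 - mean(p[i])) / sum(i))
    expect_lt(abs(mean(act[i]) - mean(p[i])), 4 * se + 0.01)
  }
})

test_that("null generator settings produce null structure downstream", {
  # no barriers, no expression effect: activation probability identical
  # inside and outside domains
  tr <- small_synth(seed = 41, activation = list(
    baseline_logodds = -0.95, affinity_coeff = 1.0,
    barrier_penalty = c(H3K9me2 = 0, H3K9me3 = 0, cLAD = 0),
    expression_coeff = 0))
  in_k9 <- overlap_membership(tr$sites, tr$domains$H3K9me3)
  aff <- log(tr$sites$affinity_ppm)
  # probabilities depend only on affinity: identical fitted relation
  expect_equal(tr$sites$activation_prob,
               plogis(-0.95 + aff), tolerance = 1e-12)
  expect_false(any(is.na(in_k9)))
})

test_that("PRDM9 ChIP peaks mark the top affinity decile of activated sites", {
  tr <- simulate_dataset(synth_config(seed = 51))
  act <- tr$sites[tr$sites$activated, ]
  n_top <- ceiling(0.1 * nrow(act))
  expect_equal(nrow(tr$peaks$prdm9_chip), n_top)
  mm <- match_chip_peaks(tr$peaks$prdm9_chip, tr$sites)
  expect_equal(mm$percent_matched, 100)
  thresh <- sort(act$affinity_ppm, decreasing = TRUE)[n_top]
  matched_aff <- overlap_membership(tr$sites, tr$peaks$prdm9_chip)
  expect_true(all(sort(tr$sites$affinity_ppm[matched_aff],
                       decreasing = TRUE)[seq_len(n_top)] >= thresh))
})

test_that("fragment coverage is trapezoidal with exact span and integral", {
  s <- interval_set("chr1", 5000, 5000 + 2 * 100 - 34, strand = "+",
                    label = "s")
  set.seed(2)
  cov <- simulate_affinity_coverage(s, 100, depth = 5000, motif_length = 34)
  expect_equal(max(cov$end) - min(cov$start), 166)   # 2L - m
  expect_equal(sum((cov$end - cov$start) * cov$value), 5000 * 100)

  # boundary: L = m + 1 gives span m + 2
  s2 <- interval_set("chr1", 5000, 5000 + 2 * 35 - 34, strand = "+")
  cov2 <- simulate_affinity_coverage(s2, 35, depth = 2000, motif_length = 34)
  expect_equal(max(cov2$end) - min(cov2$start), 36)

  expect_error(simulate_affinity_coverage(s, 34, motif_length = 34),
               "exceed")
})

test_that("SNP enrichment is confined to active-site motifs", {
  tr <- simulate_dataset(synth_config(seed = 61))
  s <- tr$sites
  motif_act <- interval_set(s$chrom[s$activated],
                            s$motif_start[s$activated],
                            s$motif_end[s$activated])
  motif_inact <- interval_set(s$chrom[!s$activated],
                              s$motif_start[!s$activated],
                              s$motif_end[!s$activated])
  rate_act <- sum(overlap_membership(tr$snps, motif_act)) /
    covered_bp(motif_act)
  rate_inact <- sum(overlap_membership(tr$snps, motif_inact)) /
    covered_bp(motif_inact)
  b <- tr$config$snp$background_rate
  expect_gt(rate_act, 2 * rate_inact)
  expect_lt(abs(rate_inact - b) / b, 0.25)
})
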