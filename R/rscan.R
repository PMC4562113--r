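# r-scan detection of hotspot-deficient regions. The r-scan length of order r
# at hotspot i is the span covering r consecutive inter-hotspot distances,
# R_i^(r) = pos_{i+r} - pos_i (Karlin-Macken). Extreme (long) spans indicate
# dispersion; significance is assessed against an empirical null built from
# randomly drawn hotspot sets, with Benjamini-Hochberg control across the
# (r, k) family of retained extreme spans.

#' Configuration for r-scan deficiency detection
#'
#' @param r_max Largest scan order r (spans cover up to `r_max` consecutive
#'   inter-hotspot distances; default 24).
#' @param k_max Number of top-ranked spans retained per order (default 10).
#' @param n_null Number of random hotspot sets for the empirical null
#'   (default 10,000; >= 100).
#' @param alpha Significance level on BH-adjusted p-values (default 0.05).
#' @param seed Integer seed for the null draws.
#' @param null_source `"background_set"` draws null hotspots without
#'   replacement from a supplied background catalog; `"uniform"` draws
#'   uniform integer positions along each chromosome.
#' @param bh_family `"joint"` adjusts across all r x k statistics together
#'   (default); `"per_r"` adjusts within each scan order.
#' @param extent `"minimal"` (default) builds deficient regions from
#'   significant spans that contain no shorter significant span, localising
#'   each anomaly; `"all"` merges every significant span.
#' @param keep_null Keep the full null distributions in the result.
#' @return A list of class `"rscan_config"`.
#' @export
rscan_config <- function(r_max = 24, k_max = 10, n_null = 10000,
                         alpha = 0.05, seed = 1L,
                         null_source = c("background_set", "uniform"),
                         bh_family = c("joint", "per_r"),
                         extent = c("minimal", "all"),
                         keep_null = FALSE) {
  stopifnot(r_max >= 1, k_max >= 1, n_null >= 100, alpha > 0, alpha < 1)
  structure(list(r_max = as.integer(r_max), k_max = as.integer(k_max),
                 n_null = as.integer(n_null), alpha = alpha,
                 seed = as.integer(seed),
                 null_source = match.arg(null_source),
                 bh_family = match.arg(bh_family),
                 extent = match.arg(extent),
                 keep_null = keep_null),
            class = "rscan_config")
}

# Coerce test/background input to a named list of sorted position vectors.
positions_by_chrom <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    return(lapply(x, function(p) sort(as.numeric(p))))
  }
  if (is.data.frame(x)) {
    pos <- if (!is.null(x$end)) interval_center(x) else x$pos
    return(lapply(split(as.numeric(pos), x$chrom), sort))
  }
  stop("cannot interpret positions: supply an interval set, a data frame, ",
       "or a named list of position vectors")
}

#' Inter-hotspot distances on one chromosome
#'
#' For `n` positions there are `n - 1` consecutive distances
#' `U_i = pos_{i+1} - pos_i`. Unsorted input is sorted first.
#'
#' @param positions Numeric vector of hotspot positions (bp); length >= 2.
#' @return Numeric vector of `n - 1` non-negative distances whose sum is
#'   `max(positions) - min(positions)`.
#' @export
interhotspot_distances <- function(positions) {
  if (length(positions) < 2)
    stop("need at least 2 positions to form inter-hotspot distances")
  diff(sort(as.numeric(positions)))
}

#' r-scan lengths from inter-hotspot distances
#'
#' `R_i^(r) = sum of U_i .. U_{i+r-1}`, i.e. the span covering r consecutive
#' inter-hotspot distances; there are `length(U) - r + 1` values.
#'
#' @param U Inter-hotspot distances ([interhotspot_distances()]).
#' @param r Scan order, `>= 1`; `r > length(U)` yields an empty result.
#' @return Numeric vector of spans.
#' @export
rscan_lengths <- function(U, r) {
  stopifnot(r >= 1)
  nU <- length(U)
  if (r > nU) return(numeric(0))
  cs <- c(0, cumsum(U))
  cs[(r + 1):(nU + 1)] - cs[1:(nU - r + 1)]
}

# All spans of order r across chromosomes, with genomic locations.
rscan_spans <- function(pos_by_chrom, r) {
  rows <- lapply(names(pos_by_chrom), function(ch) {
    p <- pos_by_chrom[[ch]]
    n <- length(p)
    if (n < r + 1) return(NULL)
    data.frame(chrom = ch, start = p[1:(n - r)], end = p[(1 + r):n])
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), length = numeric(0)))
  df$length <- df$end - df$start
  df
}

#' Top-ranked r-scan spans
#'
#' Ranks pooled spans in descending length; ties broken by (chrom, start).
#' The k-th entry is the k-th largest span `m_k^(r)`.
#'
#' @param spans Data frame from pooled spans (`chrom, start, end, length`).
#' @param k_max Number of ranks retained; fewer spans than `k_max` returns
#'   all, ranked.
#' @return The top spans with a rank column `k`.
#' @export
extreme_spans <- function(spans, k_max) {
  if (nrow(spans) == 0) return(cbind(spans, k = integer(0)))
  o <- order(-spans$length, spans$chrom, spans$start)
  top <- spans[o[seq_len(min(k_max, nrow(spans)))], , drop = FALSE]
  top$k <- seq_len(nrow(top))
  rownames(top) <- NULL
  top
}

# Top-k span lengths for every r from one set of positions; returns an
# r_max x k_max matrix (NA where fewer spans exist).
.mk_matrix <- function(pos_by_chrom, r_max, k_max) {
  m <- matrix(NA_real_, r_max, k_max)
  lens <- vector("list", r_max)
  for (p in pos_by_chrom) {
    n <- length(p)
    if (n < 2) next
    for (r in seq_len(min(r_max, n - 1))) {
      lens[[r]] <- c(lens[[r]], p[(1 + r):n] - p[1:(n - r)])
    }
  }
  for (r in seq_len(r_max)) {
    v <- lens[[r]]
    if (is.null(v)) next
    k <- min(k_max, length(v))
    m[r, seq_len(k)] <- -sort(-v, partial = seq_len(k))[seq_len(k)]
  }
  m
}

#' Empirical null distributions of extreme r-scan spans
#'
#' Draws `n_null` random hotspot sets matching the per-chromosome counts of
#' the test set -- without replacement from a background catalog
#' (`null_source = "background_set"`) or as uniform integer positions along
#' each chromosome (`"uniform"`) -- and records `m_k^(r)` for every
#' `r <= r_max`, `k <= k_max`. Deterministic given `config$seed`.
#'
#' @param counts Named integer vector: test-set hotspot count per chromosome.
#' @param config An [rscan_config()].
#' @param background Named list of background positions per chromosome
#'   (required for `"background_set"`).
#' @param genome A `genome` object (required for `"uniform"`).
#' @return Array `[n_null, r_max, k_max]` of null extreme span lengths.
#' @export
rscan_null <- function(counts, config, background = NULL, genome = NULL) {
  chroms <- names(counts)
  if (config$null_source == "background_set") {
    if (is.null(background)) stop("background positions required")
    short <- chroms[vapply(chroms, function(ch)
      length(background[[ch]]) < counts[[ch]], logical(1))]
    if (length(short))
      stop("background smaller than test count on: ",
           paste(short, collapse = ", "))
  } else {
    if (is.null(genome)) stop("genome required for uniform null")
  }
  set.seed(config$seed)
  out <- array(NA_real_, c(config$n_null, config$r_max, config$k_max))
  for (b in seq_len(config$n_null)) {
    draw <- lapply(chroms, function(ch) {
      k <- counts[[ch]]
      if (config$null_source == "background_set")
        sort(sample(background[[ch]], k))
      else {
        n_pos <- unname(genome[ch])
        uh <- k < n_pos / 2   # hashed rejection sampling needs k < n/2
        sort(sample.int(n_pos, k, useHash = uh)) - 1
      }
    })
    out[b, , ] <- .mk_matrix(draw, config$r_max, config$k_max)
  }
  out
}

#' Detect hotspot-deficient regions with r-scan statistics
#'
#' The full procedure: per-chromosome inter-hotspot distances; spans of every
#' order `r <= r_max`; the `k_max` largest spans per order across the genome;
#' empirical p-values `p = (1 + #\{null >= observed\}) / (n_null + 1)` against
#' the permutation null; BH adjustment across the retained family; spans with
#' adjusted p below `alpha` marked dispersed; deficient regions built from
#' the significant spans (minimal spans by default, see [rscan_config()]),
#' merged with gap 0; regions overlapping supplied assembly-gap annotations
#' removed.
#'
#' @param test Test hotspot set: an interval set (centers are used), a data
#'   frame with `chrom`/`pos`, or a named list of position vectors.
#' @param genome A `genome` object.
#' @param background Background catalog for the null (same forms as `test`);
#'   required when `config$null_source == "background_set"`.
#' @param gaps Optional interval set of assembly gaps / low-mappability
#'   regions; deficient regions overlapping any are dropped.
#' @param config An [rscan_config()].
#' @return An object of class `"rscan_result"`: `spans` (retained extreme
#'   spans with `r`, `k`, `length`, `p_raw`, `p_adj`, `significant`,
#'   `minimal`), `regions` (merged deficient regions, score =
#'   -log10 adjusted p), `n_removed_by_gaps`, `counts`, `config`.
#' @export
rscan <- function(test, genome, background = NULL, gaps = NULL,
                  config = rscan_config()) {
  stopifnot(inherits(config, "rscan_config"))
  pos <- positions_by_chrom(test)
  small <- names(pos)[lengths(pos) < 2]
  if (length(small)) {
    warning("chromosome(s) skipped (fewer than 2 hotspots): ",
            paste(small, collapse = ", "))
    pos <- pos[lengths(pos) >= 2]
  }
  empty_result <- function() {
    structure(list(spans = data.frame(), regions = interval_set(
      character(0), numeric(0), numeric(0), label = "deficient_regions"),
      n_removed_by_gaps = 0L, counts = integer(0), config = config),
      class = "rscan_result")
  }
  if (!length(pos)) {
    warning("empty test set: no chromosome has 2 or more hotspots")
    return(empty_result())
  }
  bg <- if (!is.null(background)) positions_by_chrom(background) else NULL

  ## observed extreme spans per order
  obs_list <- lapply(seq_len(config$r_max), function(r) {
    sp <- rscan_spans(pos, r)
    sp <- extreme_spans(sp, config$k_max)
    if (nrow(sp)) sp$r <- r
    sp
  })
  obs <- do.call(rbind, obs_list[vapply(obs_list, nrow, integer(1)) > 0])
  if (is.null(obs) || nrow(obs) == 0) {
    warning("no r-scan spans could be formed")
    return(empty_result())
  }

  ## empirical null and p-values
  counts <- vapply(pos, length, integer(1))
  null_m <- rscan_null(counts, config, background = bg, genome = genome)
  obs$p_raw <- vapply(seq_len(nrow(obs)), function(i) {
    nulls <- null_m[, obs$r[i], obs$k[i]]
    (1 + sum(nulls >= obs$length[i], na.rm = TRUE)) / (config$n_null + 1)
  }, numeric(1))
  if (config$bh_family == "joint") {
    obs$p_adj <- stats::p.adjust(obs$p_raw, method = "BH")
  } else {
    obs$p_adj <- NA_real_
    for (r in unique(obs$r)) {
      i <- obs$r == r
      obs$p_adj[i] <- stats::p.adjust(obs$p_raw[i], method = "BH")
    }
  }
  obs$significant <- obs$p_adj < config$alpha

  ## localisation: a significant span is minimal when no other significant
  ## span is properly contained in it
  sig <- which(obs$significant)
  obs$minimal <- obs$significant
  if (length(sig) > 1) {
    for (i in sig) {
      contained <- sig[obs$chrom[sig] == obs$chrom[i] &
                         obs$start[sig] >= obs$start[i] &
                         obs$end[sig] <= obs$end[i] &
                         obs$length[sig] < obs$length[i]]
      if (length(contained)) obs$minimal[i] <- FALSE
    }
  }

  use <- if (config$extent == "minimal") obs$minimal else obs$significant
  n_removed <- 0L
  if (any(use)) {
    sel <- obs[use, , drop = FALSE]
    regions <- merge_intervals(
      interval_set(sel$chrom, sel$start, sel$end, label = "deficient_regions"),
      gap = 0)
    ## score each region with -log10 of the best adjusted p among its spans
    pr <- overlap_pairs(regions, sel)
    sc <- tapply(sel$p_adj[pr$subject], pr$query, min)
    regions$score[as.integer(names(sc))] <- -log10(pmax(sc, 1e-300))
    if (!is.null(gaps) && nrow(gaps) > 0) {
      hit <- overlap_membership(regions, gaps)
      n_removed <- sum(hit)
      regions <- regions[!hit, , drop = FALSE]
      attr(regions, "label") <- "deficient_regions"
      class(regions) <- c("interval_set", "data.frame")
    }
  } else {
    regions <- interval_set(character(0), numeric(0), numeric(0),
                            label = "deficient_regions")
  }
  rownames(obs) <- NULL
  res <- list(spans = obs, regions = regions, n_removed_by_gaps = n_removed,
              counts = counts, config = config)
  if (config$keep_null) res$null_m <- null_m
  structure(res, class = "rscan_result")
}

#' @export
print.rscan_result <- function(x, ...) {
  cat(sprintf(paste0("r-scan dispersion scan: %d hotspots on %d chromosome(s)\n",
                     "  retained extreme spans: %d (r <= %d, k <= %d)\n",
                     "  significant spans:      %d (BH-adjusted p < %g)\n",
                     "  deficient regions:      %d (%d removed over gaps)\n"),
              sum(x$counts), length(x$counts), nrow(x$spans),
              x$config$r_max, x$config$k_max,
              if (nrow(x$spans)) sum(x$spans$significant) else 0L,
              x$config$alpha, nrow(x$regions), x$n_removed_by_gaps))
  invisible(x)
}

#' @export
summary.rscan_result <- function(object, ...) {
  print(object)
  if (nrow(object$regions)) {
    cat("deficient regions:\n")
    print.data.frame(as.data.frame(object$regions)[,
      c("chrom", "start", "end", "score")])
  }
  invisible(object)
}

#' Cross-reference deficient regions against binding-site density
#'
#' A called region is "truly deficient" in in vivo usage (rather than a
#' region where binding itself is impossible or reads are unmappable) when
#' its in vitro binding-site density is at least `threshold_fraction` of the
#' genome-wide average.
#'
#' @param regions Disjoint interval set of deficient regions.
#' @param sites Binding-site interval set (the in vitro catalog).
#' @param genome A `genome` object.
#' @param threshold_fraction Density threshold as a fraction of the
#'   genome-wide average (default 0.5).
#' @return List with `regions` (data frame adding `n_sites`,
#'   `density_per_mb`, `truly_deficient`), `genome_density_per_mb`, and
#'   `fraction_truly_deficient`.
#' @export
cross_reference_deficiency <- function(regions, sites, genome,
                                       threshold_fraction = 0.5) {
  if (nrow(regions) && any(regions$end <= regions$start))
    stop("zero-length region")
  genome_density <- nrow(sites) / (sum(genome) / 1e6)
  df <- as.data.frame(regions)[, c("chrom", "start", "end")]
  if (nrow(df)) {
    pr <- overlap_pairs(regions, sites)
    cnt <- integer(nrow(df))
    if (nrow(pr)) {
      tb <- table(pr$query)
      cnt[as.integer(names(tb))] <- as.integer(tb)
    }
    df$n_sites <- cnt
    df$density_per_mb <- cnt / ((df$end - df$start) / 1e6)
    df$truly_deficient <- df$density_per_mb >=
      threshold_fraction * genome_density
  } else {
    df$n_sites <- integer(0); df$density_per_mb <- numeric(0)
    df$truly_deficient <- logical(0)
  }
  list(regions = df, genome_density_per_mb = genome_density,
       fraction_truly_deficient = if (nrow(df)) mean(df$truly_deficient)
                                  else NA_real_)
}
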