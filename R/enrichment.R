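# Usage quantification: fractions of in vivo used sites by genomic category
# (with Poisson errors), affinity quintiles in closed vs open chromatin,
# rank-sum comparisons, and the small density/rate metrics.

#' Usage fraction with Poisson standard error, from counts
#'
#' `fraction = n_used / n_total`; the standard error treats the numerator
#' count as Poisson: `se = sqrt(n_used) / n_total`. A binomial alternative
#' `se_binomial = sqrt(f (1 - f) / n_total)` is also reported.
#'
#' @param n_used Count of in vivo used sites in the category.
#' @param n_total Total (non-ambiguous) sites in the category; must be > 0.
#' @param label Category label.
#' @return One-row data frame: `label`, `n_total`, `n_used`, `fraction`,
#'   `se`, `se_binomial`.
#' @examples
#' category_usage(15244, 31770) # fraction 0.480
#' @export
category_usage <- function(n_used, n_total, label = "all") {
  if (n_total <= 0) stop("usage fraction undefined: n_total must be > 0")
  if (n_used < 0 || n_used > n_total) stop("n_used must be in [0, n_total]")
  f <- n_used / n_total
  data.frame(label = label, n_total = n_total, n_used = n_used, fraction = f,
             se = sqrt(n_used) / n_total,
             se_binomial = sqrt(f * (1 - f) / n_total))
}

#' Usage fraction of classified sites within a genomic category
#'
#' Membership is any-overlap (>= 1 bp) of the site interval with the
#' category's intervals; ambiguous sites are excluded from numerator and
#' denominator. With `category = NULL` the genome-wide fraction is returned.
#'
#' @param classified A [classify_sites()] result.
#' @param category Interval set defining the category, or `NULL`.
#' @param label Category label (defaults to the category's set label).
#' @param complement Use the sites *not* overlapping the category instead.
#' @return One-row data frame as in [category_usage()].
#' @export
usage_fraction <- function(classified, category = NULL, label = NULL,
                           complement = FALSE) {
  s <- classified$sites
  keep <- s$status != "ambiguous"
  s <- s[keep, , drop = FALSE]
  if (is.null(category)) {
    member <- rep(TRUE, nrow(s))
    if (is.null(label)) label <- "all"
  } else {
    member <- overlap_membership(s, category)
    if (complement) member <- !member
    if (is.null(label))
      label <- paste0(set_label(category), if (complement) "-" else "+")
  }
  category_usage(sum(member & s$status == "in_vivo"), sum(member), label)
}

#' Split genes into expression quartiles
#'
#' Equal-count bins by expression value, quartile 1 lowest to quartile 4
#' highest; ties are broken by stable input order, so zero-expression genes
#' fall into the bottom bin. Bin sizes differ by at most one.
#'
#' @param genes Interval set of genes.
#' @param expression Numeric vector of non-negative expression values, one
#'   per gene; defaults to the genes' `score` column.
#' @return List of 4 interval sets (`q1` .. `q4`), each labelled.
#' @export
expression_quartiles <- function(genes, expression = genes$score) {
  n <- nrow(genes)
  if (n < 4) stop("need at least 4 genes to form quartiles")
  if (any(is.na(expression)) || any(expression < 0))
    stop("expression values must be non-negative and non-missing")
  o <- order(expression)              # stable for ties
  sizes <- diff(floor(n * (0:4) / 4))
  bin <- integer(n)
  bin[o] <- rep(1:4, sizes)
  lapply(stats::setNames(1:4, paste0("q", 1:4)), function(q) {
    g <- genes[bin == q, , drop = FALSE]
    attr(g, "label") <- paste0("expression_q", q)
    class(g) <- c("interval_set", "data.frame")
    g
  })
}

#' Usage ratio in closed vs open chromatin by affinity quintile
#'
#' Sites are ranked by affinity genome-wide and split into five equal-count
#' quintiles (quintile 1 lowest affinity). Within each quintile the in vivo
#' usage fraction is computed separately for sites in closed chromatin
#' (overlapping `closed`) and open chromatin (the rest), and their ratio
#' `(used/total)_closed / (used/total)_open` is reported: 1 means no
#' heterochromatin effect. Ambiguous sites are excluded throughout.
#'
#' @param classified A [classify_sites()] result; sites must carry
#'   affinities (`affinity_ppm` or `score`).
#' @param closed Interval set of closed chromatin (e.g. the union of
#'   H3K9me2 and H3K9me3 domains).
#' @return Data frame with one row per quintile: affinity range, closed and
#'   open counts, fractions, `ratio` and its delta-method `se`. A quintile
#'   with no closed or no open sites gets `NA` ratio.
#' @export
affinity_quintile_ratio <- function(classified, closed) {
  s <- classified$sites
  s <- s[s$status != "ambiguous", , drop = FALSE]
  aff <- if (!is.null(s$affinity_ppm)) s$affinity_ppm else s$score
  if (any(is.na(aff))) stop("sites must carry affinity scores")
  n <- nrow(s)
  if (nrow(closed) == 0) stop("closed chromatin set is empty")
  o <- order(aff)
  sizes <- diff(floor(n * (0:5) / 5))
  bin <- integer(n)
  bin[o] <- rep(1:5, sizes)
  in_closed <- overlap_membership(s, closed)
  used <- s$status == "in_vivo"
  out <- lapply(1:5, function(q) {
    i <- bin == q
    tc <- sum(i & in_closed); uc <- sum(i & in_closed & used)
    to <- sum(i & !in_closed); uo <- sum(i & !in_closed & used)
    fc <- if (tc > 0) uc / tc else NA_real_
    fo <- if (to > 0) uo / to else NA_real_
    ratio <- if (tc > 0 && to > 0 && fo > 0) fc / fo else NA_real_
    se <- if (!is.na(ratio) && uc > 0 && uo > 0)
      ratio * sqrt(1 / uc - 1 / tc + 1 / uo - 1 / to) else NA_real_
    data.frame(quintile = q, affinity_min = min(aff[i]),
               affinity_max = max(aff[i]),
               n_closed = tc, used_closed = uc,
               n_open = to, used_open = uo,
               fraction_closed = fc, fraction_open = fo,
               ratio = ratio, se = se)
  })
  if (any(vapply(out, function(d) is.na(d$ratio), logical(1))))
    warning("ratio undefined for at least one quintile ",
            "(no closed or no open sites)")
  do.call(rbind, out)
}

#' Two-sample Mann-Whitney (rank-sum) comparison
#'
#' Exact enumeration when `n_a * n_b <= 400` and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction.
#'
#' @param values_a,values_b Numeric vectors, each non-empty.
#' @return List with `U` (Mann-Whitney U for the first sample), `p`
#'   (two-sided), and `method`.
#' @export
rank_sum_compare <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b))
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- (length(values_a) * length(values_b) <= 400) && !ties
  wt <- stats::wilcox.test(values_a, values_b, exact = exact,
                           correct = !exact)
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Normalize read counts to parts per million
#'
#' @param read_counts Non-negative counts.
#' @param library_size Total reads in the library (> 0).
#' @return `read_counts * 1e6 / library_size`.
#' @examples
#' ppm_normalize(50, 1e7) # 5
#' @export
ppm_normalize <- function(read_counts, library_size) {
  if (library_size <= 0) stop("library_size must be > 0")
  if (any(read_counts < 0)) stop("read counts must be non-negative")
  read_counts * 1e6 / library_size
}

#' Binding-site density in sites per Mb
#'
#' @param n_sites Site count.
#' @param span_mb Region span in Mb (> 0).
#' @return Density rounded to 2 decimals.
#' @examples
#' site_density(122, 13) # 9.38
#' @export
site_density <- function(n_sites, span_mb) {
  if (span_mb <= 0) stop("span must be > 0")
  round(n_sites / span_mb, 2)
}

#' Recombination rate in cM/Mb
#'
#' `100 * (n_recombinants / n_progeny) / interval_mb`.
#'
#' @param n_recombinants Recombinant count (<= `n_progeny`).
#' @param n_progeny Progeny count (> 0).
#' @param interval_mb Interval size in Mb (> 0).
#' @return Rate rounded to 3 decimals.
#' @examples
#' recombination_rate(5, 1092, 15.96) # 0.029
#' @export
recombination_rate <- function(n_recombinants, n_progeny, interval_mb) {
  if (n_progeny <= 0 || interval_mb <= 0)
    stop("n_progeny and interval_mb must be > 0")
  if (n_recombinants > n_progeny)
    stop("recombinants cannot exceed progeny")
  round(100 * (n_recombinants / n_progeny) / interval_mb, 3)
}
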