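# Site classification: partition the in vitro binding-site catalog into
# in_vivo / in_vitro_only / ambiguous classes from overlap with in vivo mark
# peak sets, and match ChIP peaks back to sites.

#' Classify binding sites by in vivo evidence
#'
#' A site overlapping (>= 1 bp) the first strain's H3K4me3 set or the DMC1
#' set is a candidate in vivo hotspot. Among candidates, a site overlapping
#' the H3K4me3 peaks of *both* strains but no DMC1 peak is promoter-like and
#' classified `ambiguous`; remaining candidates are `in_vivo`; non-candidates
#' are `in_vitro_only`. The partition is exhaustive and mutually exclusive.
#'
#' @param sites Sorted interval set of binding sites.
#' @param h3k4me3_a,h3k4me3_b Sorted H3K4me3 peak sets from the two strains
#'   (the first is the strain whose binding-site catalog is being used).
#' @param dmc1 Sorted DMC1 (DSB) peak set.
#'
#' @return A list of class `"classified_sites"` with `status` (factor with
#'   levels `in_vivo`, `in_vitro_only`, `ambiguous`, one per site, in site
#'   order), `sites` (the input with a `status` column), and `counts`
#'   (`n_total`, `n_overlapping`, `n_ambiguous`, `n_in_vivo`,
#'   `n_in_vitro_only`).
#' @export
classify_sites <- function(sites, h3k4me3_a, h3k4me3_b, dmc1) {
  check_sorted(sites, "sites")
  check_sorted(h3k4me3_a, "h3k4me3_a")
  check_sorted(h3k4me3_b, "h3k4me3_b")
  check_sorted(dmc1, "dmc1")

  in_a <- overlap_membership(sites, h3k4me3_a)
  in_b <- overlap_membership(sites, h3k4me3_b)
  in_dmc1 <- overlap_membership(sites, dmc1)

  candidate <- in_a | in_dmc1
  ambiguous <- candidate & in_a & in_b & !in_dmc1
  status <- factor(ifelse(!candidate, "in_vitro_only",
                          ifelse(ambiguous, "ambiguous", "in_vivo")),
                   levels = c("in_vivo", "in_vitro_only", "ambiguous"))

  counts <- list(n_total = length(status),
                 n_overlapping = sum(candidate),
                 n_ambiguous = sum(status == "ambiguous"),
                 n_in_vivo = sum(status == "in_vivo"),
                 n_in_vitro_only = sum(status == "in_vitro_only"))
  stopifnot(counts$n_in_vivo + counts$n_ambiguous == counts$n_overlapping,
            counts$n_in_vivo + counts$n_in_vitro_only + counts$n_ambiguous ==
              counts$n_total)

  out <- sites
  out$status <- status
  structure(list(status = status, sites = out, counts = counts),
            class = "classified_sites")
}

#' @export
print.classified_sites <- function(x, ...) {
  ct <- x$counts
  cat(sprintf(paste0("classified binding sites: %d total\n",
                     "  in vivo:        %6d (%.1f%%)\n",
                     "  in vitro only:  %6d\n",
                     "  ambiguous:      %6d (removed from usage)\n"),
              ct$n_total, ct$n_in_vivo, 100 * ct$n_in_vivo / ct$n_total,
              ct$n_in_vitro_only, ct$n_ambiguous))
  invisible(x)
}

#' Write classification results
#'
#' Per-site TSV (id, status, affinity) plus a JSON summary of the five
#' counts.
#'
#' @param classified A `classified_sites` object.
#' @param tsv_path,json_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_classification <- function(classified, tsv_path, json_path) {
  s <- classified$sites
  aff <- if (!is.null(s$affinity_ppm)) s$affinity_ppm else s$score
  write_tsv(data.frame(id = s$id, chrom = s$chrom, start = s$start,
                       end = s$end, status = as.character(s$status),
                       affinity_ppm = aff), tsv_path)
  jsonlite::write_json(classified$counts, json_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(tsv_path, json_path))
}

#' Match ChIP peaks to binding sites
#'
#' Counts ChIP peaks overlapping (>= 1 bp) at least one site and reports the
#' signed center offsets (peak center minus site center) for all overlapping
#' peak-site pairs.
#'
#' @param chip_peaks Sorted interval set of ChIP peaks.
#' @param sites Sorted interval set of binding sites.
#' @return List with `n_peaks`, `n_matched`, `percent_matched`
#'   (`round(100 * n_matched / n_peaks)`), and `center_offsets`.
#' @export
match_chip_peaks <- function(chip_peaks, sites) {
  check_sorted(chip_peaks, "chip_peaks")
  check_sorted(sites, "sites")
  if (nrow(chip_peaks) == 0)
    stop("percentage undefined: no ChIP peaks supplied")
  matched <- overlap_membership(chip_peaks, sites)
  pr <- overlap_pairs(chip_peaks, sites)
  offs <- interval_center(chip_peaks[pr$query, , drop = FALSE]) -
    interval_center(sites[pr$subject, , drop = FALSE])
  list(n_peaks = nrow(chip_peaks), n_matched = sum(matched),
       percent_matched = percent_of(sum(matched), nrow(chip_peaks)),
       center_offsets = as.numeric(offs))
}

#' Integer percentage of a count over a total
#' @param n Numerator count.
#' @param total Denominator count (> 0).
#' @return `round(100 * n / total)`.
#' @examples
#' percent_of(1578, 1709) # 92
#' @export
percent_of <- function(n, total) {
  if (total <= 0) stop("percentage undefined for total <= 0")
  round(100 * n / total)
}
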