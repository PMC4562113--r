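# Positional aggregation around binding sites: composite coverage metaplots,
# nucleotide-frequency matrices along oriented motifs, SNP-density ratio
# profiles, and binned log2 enrichment tracks. Long-format output:
# (offset, channel, value, n).

profile_frame <- function(offset, channel, value, n_sites) {
  df <- data.frame(offset = offset, channel = channel, value = value,
                   n = n_sites)
  class(df) <- c("profile_matrix", "data.frame")
  df
}

# Per-bp step-function lookup into a bedGraph, per chromosome; positions
# outside any segment get 0.
.coverage_at <- function(bg, chrom, pos) {
  out <- numeric(length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    seg <- bg[bg$chrom == ch, , drop = FALSE]
    if (!nrow(seg)) next
    idx <- findInterval(pos[i], seg$start)
    ok <- idx >= 1 & idx <= nrow(seg)
    ok[ok] <- pos[i][ok] < seg$end[idx[ok]]
    v <- numeric(length(i))
    v[ok] <- seg$value[idx[ok]]
    out[i] <- v
  }
  out
}

#' Composite coverage profile around sites
#'
#' Mean coverage at each offset relative to the site anchor, aggregated
#' across sites; minus-strand sites are reversed before aggregation. Sites
#' whose window would extend past a chromosome end are excluded.
#'
#' @param coverage A [bedgraph()] track (non-negative values).
#' @param sites Oriented interval set of sites.
#' @param genome A `genome` object (for end truncation).
#' @param half_width Window half-width; offsets run `-half_width ..
#'   +half_width` (odd window).
#' @param anchor `"center"` (interval center, default) or `"motif_start"`.
#' @return A long profile data frame (channel `"coverage"`); attribute
#'   `n_excluded` counts truncated sites.
#' @export
composite_profile <- function(coverage, sites, genome, half_width = 500,
                              anchor = c("center", "motif_start")) {
  anchor <- match.arg(anchor)
  if (nrow(sites) == 0) stop("empty site set")
  a <- if (anchor == "center") interval_center(sites) else sites$motif_start
  lo <- a - half_width
  hi <- a + half_width
  keep <- lo >= 0 & hi < unname(genome[sites$chrom])
  n_excl <- sum(!keep)
  if (!any(keep)) stop("all site windows exceed chromosome bounds")
  a <- a[keep]
  chrom <- sites$chrom[keep]
  strand <- sites$strand[keep]
  offs <- -half_width:half_width
  w <- length(offs)
  pos <- rep(a, each = w) + rep(offs, length(a))
  vals <- .coverage_at(coverage, rep(chrom, each = w), pos)
  m <- matrix(vals, nrow = w)      # offsets x sites
  rev_i <- which(strand == "-")
  if (length(rev_i)) m[, rev_i] <- m[w:1, rev_i]
  out <- profile_frame(offs, "coverage", rowMeans(m), length(a))
  attr(out, "n_excluded") <- n_excl
  out
}

#' Nucleotide-frequency profile along oriented sites
#'
#' Sites are aligned on the motif start and minus-strand windows are
#' reverse-complemented, so offset 0 is the first motif base in motif
#' orientation; `flank` positions are added on both sides. Per-offset base
#' frequencies sum to 1. Sites whose window exceeds the contig are skipped
#' and counted.
#'
#' @param genome_seq A [Biostrings::DNAStringSet] (or named character
#'   vector) keyed by chromosome.
#' @param sites Interval set carrying `motif_start`, `motif_end` and strand.
#' @param flank Flanking bp included on each side of the motif.
#' @return Long profile data frame with channels `"A","C","G","T"`;
#'   attribute `n_skipped`.
#' @export
nucleotide_frequency_profile <- function(genome_seq, sites, flank = 10) {
  if (nrow(sites) == 0) stop("empty site set")
  if (!methods::is(genome_seq, "DNAStringSet"))
    genome_seq <- Biostrings::DNAStringSet(genome_seq)
  m <- unique(sites$motif_end - sites$motif_start)
  if (length(m) != 1) stop("sites have non-constant motif length")
  lens <- stats::setNames(Biostrings::width(genome_seq), names(genome_seq))
  lo <- sites$motif_start - flank
  hi <- sites$motif_end + flank
  keep <- lo >= 0 & hi <= unname(lens[sites$chrom])
  n_skip <- sum(!keep)
  s <- sites[keep, , drop = FALSE]
  if (nrow(s) == 0) stop("all site windows exceed their contigs")
  win <- vapply(seq_len(nrow(s)), function(i)
    as.character(Biostrings::subseq(genome_seq[[s$chrom[i]]],
                                    s$motif_start[i] - flank + 1,
                                    s$motif_end[i] + flank)),
    character(1))
  minus <- s$strand == "-"
  if (any(minus))
    win[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(win[minus])))
  mat <- do.call(rbind, strsplit(win, ""))
  offs <- (-flank):(m + flank - 1)
  freq <- vapply(c("A", "C", "G", "T"), function(b) colMeans(mat == b),
                 numeric(ncol(mat)))
  out <- profile_frame(rep(offs, 4),
                       rep(c("A", "C", "G", "T"), each = length(offs)),
                       as.numeric(freq), nrow(s))
  attr(out, "n_skipped") <- n_skip
  out
}

#' SNP-density ratio profile around sites
#'
#' Windows of `window` bp (`[-window/2, window/2)`) are centered and
#' oriented on the sites; the per-offset SNP frequency across sites is
#' divided by its mean over the whole window (the regional average), so the
#' profile mean is exactly 1. An enrichment of mutations at the motif of
#' historically used sites appears as a central peak.
#'
#' @param snps Interval set of SNP positions (1-bp intervals).
#' @param sites Oriented interval set of sites.
#' @param window Window width in bp (default 2000).
#' @param smooth Odd moving-average window in offsets (0 = off, default).
#' @return Long profile data frame (channel `"snp_ratio"`).
#' @export
snp_density_profile <- function(snps, sites, window = 2000, smooth = 0) {
  if (nrow(sites) == 0) stop("empty site set")
  hw <- floor(window / 2)
  cen <- interval_center(sites)
  counts <- numeric(2 * hw)
  offs <- (-hw):(hw - 1)
  for (ch in unique(sites$chrom)) {
    i <- which(sites$chrom == ch)
    sp <- sort(snps$start[snps$chrom == ch])
    if (!length(sp)) next
    lo <- findInterval(cen[i] - hw - 0.5, sp) + 1   # first SNP >= cen - hw
    hi <- findInterval(cen[i] + hw - 0.5, sp)       # last SNP <= cen + hw - 1
    for (jj in seq_along(i)) {
      if (hi[jj] < lo[jj]) next
      d <- sp[lo[jj]:hi[jj]] - cen[i[jj]]
      if (sites$strand[i[jj]] == "-") d <- -d - 1
      counts <- counts + tabulate(d + hw + 1, nbins = 2 * hw)
    }
  }
  if (sum(counts) == 0)
    stop("ratio undefined: no SNPs fall in any site window")
  freq <- counts / nrow(sites)
  ratio <- freq / mean(freq)
  if (smooth > 0) {
    if (smooth %% 2 == 0) stop("smoothing window must be odd")
    ratio <- stats::filter(ratio, rep(1 / smooth, smooth), sides = 2,
                           circular = TRUE)
    ratio <- as.numeric(ratio)
  }
  profile_frame(offs, "snp_ratio", ratio, nrow(sites))
}

#' Binned log2 enrichment of a sample track over a control track
#'
#' Both tracks are binned (`bin` bp), scaled to equal totals, and compared
#' as `log2((sample + pseudocount) / (control + pseudocount))` per bin.
#' Empty bins give 0, never infinities.
#'
#' @param sample_coverage,control_coverage [bedgraph()] tracks on the same
#'   genome.
#' @param genome A `genome` object.
#' @param bin Bin width in bp (default 2000).
#' @param pseudocount Positive pseudocount (default 1).
#' @return A [bedgraph()] track of per-bin log2 ratios.
#' @export
binned_log2_enrichment <- function(sample_coverage, control_coverage, genome,
                                   bin = 2000, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  for (tr in list(sample_coverage, control_coverage)) {
    unknown <- setdiff(unique(tr$chrom), names(genome))
    if (length(unknown))
      stop("track chromosome(s) not in genome: ",
           paste(unknown, collapse = ", "))
  }
  bin_track <- function(tr) {
    out <- list()
    for (ch in names(genome)) {
      nb <- ceiling(unname(genome[ch]) / bin)
      tot <- numeric(nb)
      seg <- tr[tr$chrom == ch, , drop = FALSE]
      if (nrow(seg)) {
        bins <- IRanges::IRanges(start = (seq_len(nb) - 1) * bin + 1,
                                 end = pmin(seq_len(nb) * bin,
                                            unname(genome[ch])))
        hits <- IRanges::findOverlaps(.as_iranges(seg$start, seg$end), bins)
        ov <- IRanges::width(IRanges::pintersect(
          .as_iranges(seg$start, seg$end)[S4Vectors::queryHits(hits)],
          bins[S4Vectors::subjectHits(hits)]))
        contrib <- ov * seg$value[S4Vectors::queryHits(hits)]
        agg <- tapply(contrib, S4Vectors::subjectHits(hits), sum)
        tot[as.integer(names(agg))] <- agg
      }
      out[[ch]] <- tot
    }
    out
  }
  s <- bin_track(sample_coverage)
  c0 <- bin_track(control_coverage)
  ts <- sum(unlist(s)); tc <- sum(unlist(c0))
  if (tc > 0 && ts > 0) c0 <- lapply(c0, function(x) x * ts / tc)
  rows <- lapply(names(genome), function(ch) {
    nb <- length(s[[ch]])
    data.frame(chrom = ch, start = (seq_len(nb) - 1) * bin,
               end = pmin(seq_len(nb) * bin, unname(genome[ch])),
               value = log2((s[[ch]] + pseudocount) /
                              (c0[[ch]] + pseudocount)))
  })
  df <- do.call(rbind, rows)
  bedgraph(df$chrom, df$start, df$end, df$value, label = "log2_enrichment")
}
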