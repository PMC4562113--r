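# Core interval data model. All coordinates are 0-based half-open [start, end),
# the BED convention; any 1-based dialect must be converted at the reader
# boundary. "Overlap" throughout the package means >= 1 shared bp.

#' Define a genome as an ordered set of chromosome lengths
#'
#' @param lengths Named numeric vector of chromosome lengths in bp. Names are
#'   chromosome names and must be unique; lengths must be positive.
#'
#' @return A named numeric vector with class `"genome"`.
#' @examples
#' gen <- define_genome(c(chr1 = 1e7, chr2 = 8e6))
#' @export
define_genome <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("genome lengths must be named by chromosome")
  if (anyDuplicated(names(lengths)))
    stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive and finite")
  structure(stats::setNames(as.numeric(lengths), names(lengths)),
            class = "genome")
}

#' Read a two-column chromosome-sizes file
#'
#' @param path Path to a TSV with columns chromosome name and length (bp).
#' @return A [define_genome()] object.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  define_genome(stats::setNames(df$length, df$chrom))
}

#' Write a chromosome-sizes file
#' @param genome A `genome` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(data.frame(chrom = names(genome), length = genome),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a sorted interval set
#'
#' An interval set is a data frame of genomic intervals (0-based half-open)
#' with columns `chrom`, `start`, `end`, `strand`, `score`, `id`, carrying a
#' `label` attribute naming the assay or category. Intervals are sorted by
#' (chrom, start, end); validation enforces `0 <= start < end` and, when a
#' genome is supplied, `end <= chromosome length`.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors, 0-based half-open coordinates.
#' @param strand Strand, one of `"+", "-", "."` (default `"."`).
#' @param score Optional numeric score (`NA` when absent).
#' @param id Optional label per interval.
#' @param label Set label (assay/category name); must be non-empty.
#' @param genome Optional `genome` object for bounds checking.
#' @param extra Optional data frame of additional per-interval columns.
#'
#' @return A data frame of class `c("interval_set", "data.frame")`.
#' @examples
#' interval_set("chr1", c(10, 100), c(50, 200), label = "peaks")
#' @export
interval_set <- function(chrom, start, end, strand = ".", score = NA_real_,
                         id = NA_character_, label = "intervals",
                         genome = NULL, extra = NULL) {
  if (!nzchar(label)) stop("label must be non-empty")
  n <- max(length(chrom), length(start), length(end))
  if (length(start) == 0 || length(end) == 0 || length(chrom) == 0) n <- 0
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = rep_len(as.numeric(start), n),
                   end = rep_len(as.numeric(end), n),
                   strand = rep_len(as.character(strand), n),
                   score = rep_len(as.numeric(score), n),
                   id = rep_len(as.character(id), n),
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    stopifnot(nrow(extra) == n || n == 0)
    df <- cbind(df, extra)
  }
  validate_intervals(df, genome)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "label") <- label
  class(df) <- c("interval_set", "data.frame")
  df
}

validate_intervals <- function(df, genome = NULL) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(!is.finite(df$start)) || any(!is.finite(df$end)))
    stop("interval coordinates must be finite")
  if (any(df$start < 0)) stop("interval start must be >= 0")
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("invalid interval (start >= end) at row ", bad[1], ": ",
         df$chrom[bad[1]], ":", df$start[bad[1]], "-", df$end[bad[1]])
  if (any(!df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  if (!is.null(genome)) {
    unknown <- setdiff(unique(df$chrom), names(genome))
    if (length(unknown))
      stop("chromosome(s) not in genome: ", paste(unknown, collapse = ", "))
    over <- which(df$end > unname(genome[df$chrom]))
    if (length(over))
      stop("interval exceeds chromosome length at row ", over[1])
  }
  invisible(df)
}

set_label <- function(x) {
  lab <- attr(x, "label")
  if (is.null(lab)) "intervals" else lab
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("interval_set '%s': %d intervals on %d chromosome(s)\n",
              set_label(x), nrow(x), length(unique(x$chrom))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

as_interval_set <- function(df, label = "intervals", genome = NULL) {
  for (col in c("strand", "score", "id")) {
    if (is.null(df[[col]]))
      df[[col]] <- switch(col, strand = ".", score = NA_real_,
                          id = NA_character_)
  }
  interval_set(df$chrom, df$start, df$end, df$strand, df$score, df$id,
               label = label, genome = genome,
               extra = df[setdiff(names(df),
                                  c("chrom", "start", "end", "strand",
                                    "score", "id"))])
}

is_sorted_intervals <- function(df) {
  if (nrow(df) < 2) return(TRUE)
  o <- order(df$chrom, df$start, df$end)
  all(o == seq_len(nrow(df)))
}

check_sorted <- function(df, what = "interval set") {
  if (!is_sorted_intervals(df))
    stop(what, " must be sorted by (chrom, start); use interval_set()")
  invisible(df)
}

# IRanges bridge: 0-based half-open -> 1-based closed.
.as_iranges <- function(start, end) IRanges::IRanges(start = start + 1, end = end)

#' Do two intervals share at least one base pair?
#'
#' Half-open overlap: true iff both intervals are on the same chromosome and
#' `a$start < b$end && b$start < a$end`. Abutting intervals do not overlap.
#'
#' @param a,b Single intervals: one-row data frames or lists with `chrom`,
#'   `start`, `end`.
#' @return Logical scalar.
#' @examples
#' any_overlap(list(chrom = "chr1", start = 10, end = 50),
#'             list(chrom = "chr1", start = 49, end = 60))
#' @export
any_overlap <- function(a, b) {
  identical(as.character(a$chrom[1]), as.character(b$chrom[1])) &&
    a$start[1] < b$end[1] && b$start[1] < a$end[1]
}

#' Flag sites overlapping any region
#'
#' For each site, reports whether it overlaps (>= 1 bp) at least one interval
#' of `regions`. Uses an interval-tree query, so runtime is subquadratic.
#'
#' @param sites,regions Interval sets (or data frames with `chrom`, `start`,
#'   `end`).
#' @return Logical vector, one flag per row of `sites`, in the input order of
#'   `sites`.
#' @export
overlap_membership <- function(sites, regions) {
  n <- nrow(sites)
  out <- logical(n)
  if (n == 0 || nrow(regions) == 0) return(out)
  for (ch in unique(sites$chrom)) {
    i <- which(sites$chrom == ch)
    j <- which(regions$chrom == ch)
    if (!length(j)) next
    out[i] <- IRanges::overlapsAny(
      .as_iranges(sites$start[i], sites$end[i]),
      .as_iranges(regions$start[j], regions$end[j]))
  }
  out
}

# All overlapping (site, region) pairs; returns a two-column index data frame.
overlap_pairs <- function(query, subject) {
  qi <- integer(0); si <- integer(0)
  for (ch in unique(query$chrom)) {
    i <- which(query$chrom == ch)
    j <- which(subject$chrom == ch)
    if (!length(j) || !length(i)) next
    hits <- IRanges::findOverlaps(
      .as_iranges(query$start[i], query$end[i]),
      .as_iranges(subject$start[j], subject$end[j]))
    qi <- c(qi, i[S4Vectors::queryHits(hits)])
    si <- c(si, j[S4Vectors::subjectHits(hits)])
  }
  data.frame(query = qi, subject = si)
}

#' Merge overlapping or near-adjacent intervals
#'
#' Fuses intervals on the same chromosome that overlap or whose gap is at most
#' `gap` bp. The result is sorted, pairwise disjoint and the operation is
#' idempotent. Strand, score and id are dropped.
#'
#' @param set An interval set.
#' @param gap Non-negative maximum gap (bp) across which intervals are fused;
#'   `gap = 0` fuses overlapping and abutting intervals.
#' @return A merged `interval_set`.
#' @export
merge_intervals <- function(set, gap = 0) {
  stopifnot(gap >= 0)
  if (nrow(set) == 0)
    return(interval_set(character(0), numeric(0), numeric(0),
                        label = set_label(set)))
  pieces <- lapply(split(seq_len(nrow(set)), set$chrom), function(i) {
    red <- IRanges::reduce(.as_iranges(set$start[i], set$end[i]),
                           min.gapwidth = gap + 1)
    data.frame(chrom = set$chrom[i[1]],
               start = BiocGenerics::start(red) - 1,
               end = BiocGenerics::end(red))
  })
  out <- do.call(rbind, pieces)
  interval_set(out$chrom, out$start, out$end, label = set_label(set))
}

#' Interval center
#'
#' `floor((start + end) / 2)`; always lies within `[start, end)`.
#'
#' @param a Interval(s): data frame or list with `start` and `end`.
#' @return Numeric vector of center positions (bp).
#' @export
interval_center <- function(a) floor((a$start + a$end) / 2)

#' Total basepairs covered by an interval set (no double counting)
#' @param set An interval set.
#' @return Numeric scalar, bp covered by the union of the intervals.
#' @export
covered_bp <- function(set) {
  m <- merge_intervals(set, gap = 0)
  sum(m$end - m$start)
}
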