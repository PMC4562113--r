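# Readers/writers for the BED-family text formats the pipeline consumes.
# BED is 0-based half-open, which is also the package's internal convention,
# so no coordinate shifting happens here.

#' Read a BED file (3-6 columns)
#'
#' Accepts BED3 (chrom, start, end), BED4 (+name), BED5 (+score) and BED6
#' (+strand). Score and strand are parsed when present. Lines are validated;
#' a malformed line or inverted coordinates raise an error naming the line.
#'
#' @param path Path to a tab-separated BED file.
#' @param label Label for the resulting set (defaults to the file name).
#' @return A sorted [interval_set()].
#' @export
read_bed <- function(path, label = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(interval_set(character(0), numeric(0), numeric(0), label = label))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(ncols < 3 | ncols > 6)
  if (length(bad))
    stop("malformed BED line ", bad[1], " in ", path, ": expected 3-6 fields, got ",
         ncols[bad[1]])
  nc <- ncols[1]
  if (any(ncols != nc))
    stop("malformed BED line ", which(ncols != nc)[1], " in ", path,
         ": inconsistent field count")
  m <- matrix(unlist(fields), ncol = nc, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", bad[1], " in ", path, ": non-numeric coordinates")
  bad <- which(start >= end)
  if (length(bad))
    stop("invalid BED line ", bad[1], " in ", path, ": start >= end (",
         m[bad[1], 2], " >= ", m[bad[1], 3], ")")
  id <- if (nc >= 4) m[, 4] else NA_character_
  score <- if (nc >= 5) suppressWarnings(as.numeric(m[, 5])) else NA_real_
  strand <- if (nc >= 6) m[, 6] else "."
  interval_set(m[, 1], start, end, strand = strand, score = score, id = id,
               label = label)
}

#' Write an interval set as BED
#'
#' Column count is the smallest that loses nothing: BED3 when no id, score or
#' strand is set; BED5 when scores are present; BED6 when strands are present.
#' Round-trips with [read_bed()] reproduce the set exactly.
#'
#' @param set An interval set.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(set, path) {
  has_strand <- nrow(set) > 0 && any(set$strand != ".")
  has_score <- nrow(set) > 0 && any(!is.na(set$score))
  has_id <- nrow(set) > 0 && any(!is.na(set$id))
  fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE)
  cols <- list(set$chrom, fmt_num(set$start), fmt_num(set$end))
  if (has_strand || has_score || has_id)
    cols <- c(cols, list(ifelse(is.na(set$id), ".", set$id)))
  if (has_strand || has_score)
    cols <- c(cols, list(ifelse(is.na(set$score), "0",
                                fmt_num(set$score))))
  if (has_strand) cols <- c(cols, list(set$strand))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path Path to a 4-column bedGraph (chrom, start, end, value),
#'   0-based half-open.
#' @param label Track label.
#' @return A data frame `chrom, start, end, value` of class
#'   `c("bedgraph", "data.frame")`, sorted by (chrom, start).
#' @export
read_bedgraph <- function(path, label = basename(path)) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  bedgraph(df$chrom, df$start, df$end, df$value, label = label)
}

#' Construct a bedGraph track
#' @param chrom,start,end,value Track columns (0-based half-open).
#' @param label Track label.
#' @return A sorted data frame of class `c("bedgraph", "data.frame")`.
#' @export
bedgraph <- function(chrom, start, end, value, label = "coverage") {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), value = as.numeric(value))
  if (nrow(df) && any(df$start >= df$end))
    stop("bedGraph intervals must have start < end")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "label") <- label
  class(df) <- c("bedgraph", "data.frame")
  df
}

#' Write a bedGraph track
#' @param bg A bedGraph data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(bg, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  writeLines(paste(bg$chrom, fmt(bg$start), fmt(bg$end), fmt(bg$value),
                   sep = "\t"), path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
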