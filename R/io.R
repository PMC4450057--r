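## Plain-text table interfaces. All genomic interval files (CNV segments,
## peaks, coverage) use the BED dialect: 0-based half-open coordinates,
## tab-separated, no header, columns chrom/start/end/value.

#' Read a BED-like interval track
#'
#' Reads a 4-column tab-separated track (chrom, start, end, value; 0-based
#' half-open, no header). Used for copy-number segments (value = log2 ratio),
#' CTCF peaks (value = score) and coverage (bedGraph; value = depth).
#'
#' @param path input file.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{value}.
#' @export
read_track <- function(path) {
  if (!file.exists(path)) stop("track file not found: ", path)
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 3) stop("track must have at least 3 columns: ", path)
  if (ncol(d) == 3) d$V4 <- NA_real_
  d <- d[, 1:4]
  names(d) <- c("chrom", "start", "end", "value")
  d$start <- as.integer(d$start); d$end <- as.integer(d$end)
  d$value <- as.numeric(d$value)
  if (any(d$start >= d$end)) stop("track interval with start >= end in ", path)
  d
}

#' Write a BED-like interval track
#' @param track data.frame with chrom/start/end/value.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_track <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

## mean value of a track over [start, end), treating bases without any
## interval as value 0; returns NA if the track has no interval overlapping
## the query at all
.track_mean <- function(track, chrom, start, end) {
  t <- track[track$chrom == chrom & track$start < end & track$end > start, ,
             drop = FALSE]
  if (nrow(t) == 0) return(NA_real_)
  w <- pmin(t$end, end) - pmax(t$start, start)
  sum(w * t$value) / (end - start)
}

## intervals of a track overlapping [start, end) by >= min_overlap bp
.track_overlaps <- function(track, chrom, start, end, min_overlap = 1L) {
  t <- track[track$chrom == chrom, , drop = FALSE]
  ov <- pmin(t$end, end) - pmax(t$start, start)
  t[ov >= min_overlap, , drop = FALSE]
}

#' Read a fusion-call table
#'
#' Reads a SOAPfuse-like tab-separated table with header columns
#' \code{sample_id}, \code{gene5}, \code{chrom5}, \code{pos5},
#' \code{strand5}, \code{gene3}, \code{chrom3}, \code{pos3}, \code{strand3},
#' \code{junction_reads}, \code{spanning_reads}. Positions in the file are
#' 1-based junction bases (the last transcribed base of the 5' segment, the
#' first of the 3' segment) and are converted to internal 0-based exon
#' boundary coordinates.
#'
#' @param path input file.
#' @return data.frame of fusion calls with internal boundary coordinates and
#'   an empty \code{fusion_class} column.
#' @export
read_fusion_calls <- function(path) {
  if (!file.exists(path)) stop("fusion table not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene5", "chrom5", "pos5", "strand5",
            "gene3", "chrom3", "pos3", "strand3",
            "junction_reads", "spanning_reads")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("fusion table missing column(s): ",
                         paste(miss, collapse = ", "))
  d$bp5 <- ifelse(d$strand5 == "+", d$pos5, d$pos5 - 1L)
  d$bp3 <- ifelse(d$strand3 == "+", d$pos3 - 1L, d$pos3)
  if (is.null(d$fusion_class)) d$fusion_class <- NA_character_
  d
}

#' Write a fusion-call table
#'
#' Mirrors [read_fusion_calls()], converting internal boundary coordinates
#' back to 1-based junction bases and appending the \code{fusion_class}
#' column when present.
#'
#' @param calls data.frame of fusion calls.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_fusion_calls <- function(calls, path) {
  d <- calls
  if (!is.null(d$bp5)) d$pos5 <- ifelse(d$strand5 == "+", d$bp5, d$bp5 + 1L)
  if (!is.null(d$bp3)) d$pos3 <- ifelse(d$strand3 == "+", d$bp3 + 1L, d$bp3)
  cols <- c("sample_id", "gene5", "chrom5", "pos5", "strand5",
            "gene3", "chrom3", "pos3", "strand3",
            "junction_reads", "spanning_reads")
  if (!is.null(d$fusion_class)) cols <- c(cols, "fusion_class")
  utils::write.table(d[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an expression table
#'
#' Tab-separated with header; columns \code{feature_id}, \code{condition}
#' (\code{si_neg} or \code{siCTCF}), \code{value} (relative units or FPKM,
#' non-negative).
#'
#' @param path input file.
#' @return data.frame.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("feature_id", "condition", "value")
  if (!all(need %in% names(d)))
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  if (any(d$value < 0)) stop("negative expression value in ", path)
  d
}

#' @rdname read_expression
#' @param expr expression data.frame.
#' @export
write_expression <- function(expr, path) {
  utils::write.table(expr[, c("feature_id", "condition", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a criteria matrix
#'
#' The criteria matrix is a tab-separated table with header \code{pair_id},
#' \code{sanger_confirmed}, \code{immediate_neighbor},
#' \code{interstitial_deletion}, \code{ctcf_binding}, \code{sictcf_induced},
#' \code{intergenic_transcript}; cell values are \code{Y}, \code{N} or empty
#' (empty = not evaluated, read as \code{NA}).
#'
#' @param path file path.
#' @return data.frame of tri-state criteria flags.
#' @export
read_criteria_matrix <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  need <- c("pair_id", criteria_stages())
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("criteria matrix missing column(s): ",
                         paste(miss, collapse = ", "))
  for (s in criteria_stages()) {
    bad <- !is.na(d[[s]]) & !(d[[s]] %in% c("Y", "N"))
    if (any(bad)) stop("criteria values must be Y, N or empty (column ", s,
                       ")")
  }
  d[, need, drop = FALSE]
}

#' @rdname read_criteria_matrix
#' @param records criteria data.frame.
#' @export
write_criteria_matrix <- function(records, path) {
  cols <- c("pair_id", criteria_stages())
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
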