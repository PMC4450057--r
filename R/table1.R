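#' Published 48-pair criteria matrix
#'
#' The tri-state criteria matrix for the 48 candidate same-strand zero-gap
#' fusion pairs of the LNCaP CTCF-knockdown screen, shipped with the
#' package as a plain-text fixture. Blank cells (stages never reached after
#' an earlier elimination) are read as \code{NA}. The 16 pairs that
#' satisfied all six criteria are marked in the \code{starred} column; they
#' are the expected final set of [apply_criteria()] on these records.
#'
#' @return data.frame with \code{pair_id}, the six tri-state stage columns
#'   (see [criteria_stages()]) and logical \code{starred}.
#' @examples
#' t1 <- table1_fixture()
#' rep <- apply_criteria(t1)
#' rep$stage_counts
#' setdiff(rep$final_pairs, t1$pair_id[t1$starred])  # character(0)
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_criteria.tsv", package = "cissage",
                      mustWork = TRUE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  d$starred <- as.logical(d$starred)
  stopifnot(nrow(d) == 48, sum(d$starred) == 16)
  d
}
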