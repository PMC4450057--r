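#' Candidate enumeration configuration
#'
#' The four rules distilled from validated cis-SAGe events: (1) same-strand
#' immediate neighbors, (2) intergenic distance strictly under
#' \code{max_distance}, (3) the 5' gene actively transcribed
#' (FPKM > \code{min_fpkm}), and (4) a predicted junction joining the
#' second-to-last exon of the 5' gene to the second exon of the 3' gene.
#'
#' @param max_distance intergenic distance cutoff in bp, strict (default
#'   30000).
#' @param min_fpkm expression threshold on the 5' gene, strict (default 1.0).
#' @param require_multi_exon drop pairs where either gene's canonical
#'   transcript has fewer than 2 exons, so the 2-to-2 junction exists
#'   (default TRUE); disable to reproduce the bare 3-rule pair count.
#' @param require_3prime_expression also require FPKM(gene3) > min_fpkm
#'   (default FALSE, matching the rule set).
#' @return List of class \code{RuleConfig}.
#' @export
rule_config <- function(max_distance = 30000L, min_fpkm = 1.0,
                        require_multi_exon = TRUE,
                        require_3prime_expression = FALSE) {
  if (max_distance <= 0) stop("max_distance must be positive")
  structure(list(max_distance = as.integer(max_distance),
                 min_fpkm = min_fpkm,
                 require_multi_exon = require_multi_exon,
                 require_3prime_expression = require_3prime_expression),
            class = "RuleConfig")
}

#' Enumerate genome-wide cis-SAGe candidate pairs
#'
#' Applies the four candidate rules to every same-strand immediate neighbor
#' pair of the annotation and emits the surviving pairs together with their
#' predicted donor/acceptor exons and junction.
#'
#' @param ann a \code{GenomeAnnotation}.
#' @param fpkm named numeric vector, gene_id -> FPKM. Genes missing from the
#'   table are treated as unexpressed (FPKM 0) with a message.
#' @param cfg a [rule_config()].
#' @return data.frame with one row per candidate: \code{pair_id},
#'   \code{gene5}, \code{gene3}, \code{chrom}, \code{strand},
#'   \code{intergenic_distance}, \code{fpkm5}, donor/acceptor exon
#'   coordinates and the predicted junction boundaries.
#' @export
enumerate_candidates <- function(ann, fpkm, cfg = rule_config()) {
  np <- neighbor_pairs(ann, same_strand_only = TRUE)
  if (nrow(np) == 0) return(.empty_candidates())
  np <- np[np$intergenic_distance < cfg$max_distance, , drop = FALSE]
  missing <- setdiff(unique(c(np$gene5, np$gene3)), names(fpkm))
  if (length(missing) > 0)
    message(length(missing),
            " gene(s) absent from the expression table treated as FPKM 0")
  f5 <- ifelse(np$gene5 %in% names(fpkm), fpkm[np$gene5], 0)
  keep <- f5 > cfg$min_fpkm
  if (cfg$require_3prime_expression) {
    f3 <- ifelse(np$gene3 %in% names(fpkm), fpkm[np$gene3], 0)
    keep <- keep & f3 > cfg$min_fpkm
  }
  np <- np[keep, , drop = FALSE]
  f5 <- f5[keep]
  if (nrow(np) == 0) return(.empty_candidates())
  rows <- list()
  for (i in seq_len(nrow(np))) {
    n5 <- canonical_transcript(ann, np$gene5[i])$n_exons
    n3 <- canonical_transcript(ann, np$gene3[i])$n_exons
    if (cfg$require_multi_exon && (n5 < 2 || n3 < 2)) next
    pj <- tryCatch(predicted_junction(ann, np$gene5[i], np$gene3[i]),
                   error = function(e) NULL)
    if (is.null(pj)) {
      if (cfg$require_multi_exon) next
      ## single-exon member with the multi-exon rule disabled: keep the
      ## pair, but there is no predictable 2-to-2 junction
      pj <- list(donor_start = NA_integer_, donor_end = NA_integer_,
                 acceptor_start = NA_integer_, acceptor_end = NA_integer_,
                 junction_donor = NA_integer_,
                 junction_acceptor = NA_integer_)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      pair_id = paste0(np$gene5[i], "-", np$gene3[i]),
      gene5 = np$gene5[i], gene3 = np$gene3[i],
      chrom = np$chrom[i], strand = np$strand5[i],
      intergenic_distance = np$intergenic_distance[i],
      fpkm5 = unname(f5[i]),
      donor_start = pj$donor_start, donor_end = pj$donor_end,
      acceptor_start = pj$acceptor_start, acceptor_end = pj$acceptor_end,
      junction_donor = pj$junction_donor,
      junction_acceptor = pj$junction_acceptor,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(.empty_candidates())
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

.empty_candidates <- function()
  data.frame(pair_id = character(0), gene5 = character(0),
             gene3 = character(0), chrom = character(0),
             strand = character(0), intergenic_distance = integer(0),
             fpkm5 = numeric(0), donor_start = integer(0),
             donor_end = integer(0), acceptor_start = integer(0),
             acceptor_end = integer(0), junction_donor = integer(0),
             junction_acceptor = integer(0))

#' Predicted cis-SAGe junction for a gene pair
#'
#' The predicted chimera joins the second-to-last exon (backward rank 2) of
#' the 5' gene's canonical transcript to the second exon (forward rank 2) of
#' the 3' gene's. The junction is strand-aware: the donor point is the 3'
#' edge of the donor exon in transcription direction, the acceptor point the
#' 5' edge of the acceptor exon. The two exon spans double as amplicon
#' target intervals for junction-spanning primers.
#'
#' @param ann a \code{GenomeAnnotation}.
#' @param gene5_id,gene3_id parental gene ids; both canonical transcripts
#'   need at least 2 exons.
#' @return List with \code{donor_start}/\code{donor_end},
#'   \code{acceptor_start}/\code{acceptor_end} (0-based half-open exon
#'   spans) and \code{junction_donor}/\code{junction_acceptor} boundary
#'   coordinates.
#' @export
predicted_junction <- function(ann, gene5_id, gene3_id) {
  t5 <- canonical_transcript(ann, gene5_id)
  t3 <- canonical_transcript(ann, gene3_id)
  if (t5$n_exons < 2)
    stop("5' gene ", gene5_id, " is single-exon: no prediction")
  if (t3$n_exons < 2)
    stop("3' gene ", gene3_id, " is single-exon: no prediction")
  ex5 <- transcript_exons(ann, t5$transcript_id)
  ex3 <- transcript_exons(ann, t3$transcript_id)
  s5 <- ex5$strand[1]; s3 <- ex3$strand[1]
  ## donor: backward rank 2 = forward rank n-1, in genomic order:
  donor_gi <- if (s5 == "+") nrow(ex5) - 1L else 2L
  accep_gi <- if (s3 == "+") 2L else nrow(ex3) - 1L
  donor <- ex5[donor_gi, ]; accep <- ex3[accep_gi, ]
  list(donor_start = donor$start, donor_end = donor$end,
       acceptor_start = accep$start, acceptor_end = accep$end,
       junction_donor = if (s5 == "+") donor$end else donor$start,
       junction_acceptor = if (s3 == "+") accep$start else accep$end)
}

#' Random subset of candidate pairs
#'
#' @param candidates candidate data.frame from [enumerate_candidates()].
#' @param n subset size (must not exceed the candidate count).
#' @param seed RNG seed; the same seed always yields the same subset.
#' @return \code{candidates} rows for the sampled pairs.
#' @export
sample_candidates <- function(candidates, n, seed = 1L) {
  if (n > nrow(candidates))
    stop("cannot sample ", n, " of ", nrow(candidates), " candidates")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  idx <- sample.int(nrow(candidates), n)
  out <- candidates[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a candidate table
#' @param candidates candidate data.frame.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
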