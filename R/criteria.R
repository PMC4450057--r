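#' Names of the six filtering stages, in cascade order
#'
#' The cascade mirrors the experimental flow used to separate true cis-SAGe
#' events from look-alikes: Sanger confirmation of the junction, immediate
#' neighborhood of the parental genes, absence of an interstitial deletion
#' between the fused exons, presence of intergenic CTCF binding, induction of
#' the chimera under CTCF knockdown, and detection of an intergenic
#' (read-through precursor) transcript.
#'
#' @return Character vector of the six stage names.
#' @export
criteria_stages <- function()
  c("sanger_confirmed", "immediate_neighbor", "interstitial_deletion",
    "ctcf_binding", "sictcf_induced", "intergenic_transcript")

#' Filtering cascade configuration
#'
#' @param fc_threshold fold-change threshold for calling a fusion induced (or
#'   down-regulated) under CTCF knockdown; must be > 1 (default 1.5).
#' @param deletion_log2_cutoff copy-number log2 ratio at or below which a
#'   segment counts as a deletion (default -0.3, a common single-copy-loss
#'   heuristic).
#' @param min_peak_overlap_bp minimum overlap in bp between a peak/segment
#'   and the queried interval (default 1).
#' @param min_intergenic_mean_coverage minimum mean read coverage over the
#'   intergenic gap to call an intergenic transcript present (default 1.0).
#' @param pseudocount added to both expression values before the fold change
#'   so zero expression stays defined (default 0.01).
#' @param read_length,min_anchor sequencing read length and minimum junction
#'   anchor, used for the default fusion effective length in FPKM conversion
#'   (defaults 101 and 8).
#' @return List of class \code{FilterConfig}.
#' @export
filter_config <- function(fc_threshold = 1.5, deletion_log2_cutoff = -0.3,
                          min_peak_overlap_bp = 1L,
                          min_intergenic_mean_coverage = 1.0,
                          pseudocount = 0.01,
                          read_length = 101L, min_anchor = 8L) {
  if (fc_threshold <= 1) stop("fc_threshold must be > 1")
  structure(list(fc_threshold = fc_threshold,
                 deletion_log2_cutoff = deletion_log2_cutoff,
                 min_peak_overlap_bp = as.integer(min_peak_overlap_bp),
                 min_intergenic_mean_coverage = min_intergenic_mean_coverage,
                 pseudocount = pseudocount,
                 read_length = as.integer(read_length),
                 min_anchor = as.integer(min_anchor)),
            class = "FilterConfig")
}

#' Immediate-neighbor criterion
#'
#' \code{"Y"} iff no other gene (either strand) overlaps the intergenic gap
#' between the two parental genes.
#'
#' @param ann a \code{GenomeAnnotation}.
#' @param gene5_id,gene3_id parental gene ids.
#' @return \code{"Y"}, \code{"N"}, or \code{NA} (with a warning) when a gene
#'   is absent from the annotation.
#' @export
check_immediate_neighbor <- function(ann, gene5_id, gene3_id) {
  g <- ann$genes$gene_id
  if (!(gene5_id %in% g) || !(gene3_id %in% g)) {
    warning("gene(s) absent from annotation: ",
            paste(setdiff(c(gene5_id, gene3_id), g), collapse = ", "))
    return(NA_character_)
  }
  if (length(intervening_genes(ann, gene5_id, gene3_id)) == 0) "Y" else "N"
}

#' Interstitial-deletion criterion
#'
#' \code{"Y"} (deletion present; the pair FAILS this stage) iff any
#' copy-number segment with log2 ratio at or below the cutoff overlaps the
#' interval between the fused exons by at least \code{min_peak_overlap_bp};
#' \code{"N"} is the passing value. \code{NA} when no segment covers the
#' region at all.
#'
#' @param chrom chromosome.
#' @param fused_exon5_end,fused_exon3_start 0-based boundary coordinates of
#'   the fused exons (end of the 5' fused exon, start of the 3' fused exon in
#'   genomic order; \code{fused_exon5_end < fused_exon3_start}).
#' @param cnv segment track data.frame (see [read_track()]; value = log2
#'   ratio).
#' @param cfg a [filter_config()].
#' @return \code{"Y"}, \code{"N"} or \code{NA}.
#' @export
check_interstitial_deletion <- function(chrom, fused_exon5_end,
                                        fused_exon3_start, cnv,
                                        cfg = filter_config()) {
  if (fused_exon5_end >= fused_exon3_start)
    stop("fused_exon5_end must be < fused_exon3_start")
  cover <- .track_overlaps(cnv, chrom, fused_exon5_end, fused_exon3_start,
                           cfg$min_peak_overlap_bp)
  if (nrow(cover) == 0) return(NA_character_)
  if (any(cover$value <= cfg$deletion_log2_cutoff)) "Y" else "N"
}

#' Intergenic CTCF-binding criterion
#'
#' \code{"Y"} iff at least one peak overlaps the intergenic interval (end of
#' the 5' gene to start of the 3' gene) by at least
#' \code{min_peak_overlap_bp}.
#'
#' @param chrom chromosome.
#' @param gap_start,gap_end 0-based half-open intergenic interval.
#' @param peaks peak track data.frame (see [read_track()]).
#' @param cfg a [filter_config()].
#' @return \code{"Y"}, \code{"N"}, or \code{NA} (with a warning) for an
#'   empty peak track.
#' @export
check_ctcf_binding <- function(chrom, gap_start, gap_end, peaks,
                               cfg = filter_config()) {
  if (is.null(peaks) || nrow(peaks) == 0) {
    warning("empty CTCF peak track: criterion not evaluable")
    return(NA_character_)
  }
  if (gap_start >= gap_end) return("N")
  hit <- .track_overlaps(peaks, chrom, gap_start, gap_end,
                         cfg$min_peak_overlap_bp)
  if (nrow(hit) > 0) "Y" else "N"
}

#' Classify response to CTCF knockdown
#'
#' Fold change is computed as (knockdown + pseudocount) / (control +
#' pseudocount). \code{induced} iff FC >= threshold, \code{down} iff
#' FC <= 1/threshold, else \code{unchanged}.
#'
#' @param value_neg expression in the negative-control condition.
#' @param value_kd expression in the CTCF-knockdown condition.
#' @param cfg a [filter_config()].
#' @return One of \code{"induced"}, \code{"down"}, \code{"unchanged"}, with
#'   the fold change in attribute \code{"fold_change"}.
#' @export
classify_induction <- function(value_neg, value_kd, cfg = filter_config()) {
  if (value_neg < 0 || value_kd < 0)
    stop("expression values must be non-negative")
  fc <- (value_kd + cfg$pseudocount) / (value_neg + cfg$pseudocount)
  out <- if (fc >= cfg$fc_threshold) "induced"
         else if (fc <= 1 / cfg$fc_threshold) "down"
         else "unchanged"
  attr(out, "fold_change") <- fc
  out
}

#' Intergenic-transcript criterion
#'
#' Evidence for a read-through precursor transcript between the parental
#' genes. An experimental flag (e.g. from intergenic RT-PCR) takes precedence
#' over the coverage track; with only a track, \code{"Y"} iff mean coverage
#' over the gap reaches \code{min_intergenic_mean_coverage}.
#'
#' @param chrom chromosome.
#' @param gap_start,gap_end 0-based half-open intergenic interval.
#' @param coverage coverage track data.frame or NULL.
#' @param flag experimental evidence flag \code{"Y"}/\code{"N"} or NA/NULL.
#' @param cfg a [filter_config()].
#' @return \code{"Y"}, \code{"N"} or \code{NA} when neither source is
#'   available.
#' @export
check_intergenic_transcript <- function(chrom, gap_start, gap_end,
                                        coverage = NULL, flag = NULL,
                                        cfg = filter_config()) {
  if (!is.null(flag) && !is.na(flag)) {
    if (!flag %in% c("Y", "N")) stop("flag must be 'Y' or 'N'")
    return(flag)
  }
  if (is.null(coverage) || nrow(coverage) == 0) return(NA_character_)
  m <- .track_mean(coverage, chrom, gap_start, gap_end)
  if (is.na(m)) return(NA_character_)
  if (m >= cfg$min_intergenic_mean_coverage) "Y" else "N"
}

#' Apply the six-criteria cascade
#'
#' Runs candidate pairs through the six stages in cascade order. A pair
#' survives a stage iff its flag is the passing value (\code{"Y"} everywhere
#' except the deletion stage, where \code{"N"} = no deletion passes).
#' \code{NA} at a stage a pair is still active in eliminates it with a
#' warning. \code{eliminated_at} records the first failing stage.
#'
#' @param records data.frame with \code{pair_id} plus the six tri-state
#'   columns named as in [criteria_stages()].
#' @return List of class \code{FilterReport}: \code{records} (input plus
#'   \code{eliminated_at}), \code{stage_counts} (named integer vector of
#'   survivor counts after each stage), \code{final_pairs} (ids passing all
#'   six), \code{n_input}.
#' @export
apply_criteria <- function(records) {
  stages <- criteria_stages()
  miss <- setdiff(c("pair_id", stages), names(records))
  if (length(miss)) stop("records missing column(s): ",
                         paste(miss, collapse = ", "))
  pass_value <- c(sanger_confirmed = "Y", immediate_neighbor = "Y",
                  interstitial_deletion = "N", ctcf_binding = "Y",
                  sictcf_induced = "Y", intergenic_transcript = "Y")
  eliminated_at <- rep(NA_character_, nrow(records))
  alive <- rep(TRUE, nrow(records))
  stage_counts <- integer(length(stages))
  names(stage_counts) <- stages
  for (s in stages) {
    flag <- records[[s]]
    na_active <- alive & is.na(flag)
    if (any(na_active)) {
      warning(sum(na_active), " pair(s) with unevaluated '", s,
              "' while still active: treated as failing")
    }
    fail <- alive & (is.na(flag) | flag != pass_value[[s]])
    eliminated_at[fail] <- s
    alive <- alive & !fail
    stage_counts[[s]] <- sum(alive)
  }
  out <- records
  out$eliminated_at <- eliminated_at
  structure(list(records = out, stage_counts = stage_counts,
                 final_pairs = records$pair_id[alive],
                 n_input = nrow(records)),
            class = "FilterReport")
}

#' @export
print.FilterReport <- function(x, ...) {
  cat("cis-SAGe criteria cascade:", x$n_input, "candidate pair(s)\n")
  for (s in names(x$stage_counts))
    cat(sprintf("  after %-22s %d\n", s, x$stage_counts[[s]]))
  cat("final set (", length(x$final_pairs), "): ",
      paste(x$final_pairs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Convert junction read counts to FPKM
#'
#' @param junction_reads number of fragments spanning the fusion junction.
#' @param effective_length_kb effective junction length in kb; the default
#'   used elsewhere is \code{2 * (read_length - min_anchor) / 1000}.
#' @param total_fragments_millions library size in millions of fragments.
#' @return FPKM value(s); vectorized.
#' @export
fkpm_from_junction_reads <- function(junction_reads, effective_length_kb,
                                     total_fragments_millions) {
  if (any(effective_length_kb <= 0) || any(total_fragments_millions <= 0))
    stop("effective length and library size must be positive")
  junction_reads / (effective_length_kb * total_fragments_millions)
}

#' Fusion-to-parental expression ratios
#'
#' @param fusion_fkpm,parental_fkpm numeric vectors (recycled) of fusion and
#'   parental-gene FPKM.
#' @param ids optional identifiers.
#' @param significant_fraction ratio at or above which the fusion counts as a
#'   significant portion of the parental gene's expression (default 0.10).
#' @return data.frame sorted by descending ratio with columns \code{id},
#'   \code{fusion_fkpm}, \code{parental_fkpm}, \code{ratio},
#'   \code{significant}. A zero parental FPKM gives ratio \code{NA} with
#'   a warning.
#' @export
fusion_parental_ratio <- function(fusion_fkpm, parental_fkpm, ids = NULL,
                                  significant_fraction = 0.10) {
  n <- max(length(fusion_fkpm), length(parental_fkpm))
  fusion_fkpm <- rep_len(fusion_fkpm, n)
  parental_fkpm <- rep_len(parental_fkpm, n)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ratio <- ifelse(parental_fkpm > 0, fusion_fkpm / parental_fkpm, NA_real_)
  if (any(parental_fkpm == 0))
    warning("parental FPKM of 0: ratio undefined for ",
            sum(parental_fkpm == 0), " entr(y/ies)")
  d <- data.frame(id = ids, fusion_fkpm = fusion_fkpm,
                  parental_fkpm = parental_fkpm, ratio = ratio,
                  significant = !is.na(ratio) & ratio >= significant_fraction,
                  stringsAsFactors = FALSE)
  d <- d[order(-d$ratio, d$id, na.last = TRUE), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Build criteria records from pipeline evidence
#'
#' Assembles a Table-1-style tri-state matrix for candidate pairs from the
#' annotation and evidence tracks, ready for [apply_criteria()].
#'
#' @param pairs data.frame with \code{pair_id}, \code{gene5}, \code{gene3}
#'   and fused-exon boundary columns \code{fused_exon5_end},
#'   \code{fused_exon3_start} (0-based genomic boundaries, genomic order).
#' @param ann a \code{GenomeAnnotation}.
#' @param cnv,peaks,coverage evidence tracks (see [read_track()]); any may be
#'   NULL.
#' @param expr expression table with fusion-level rows per condition (see
#'   [read_expression()]); feature_id must equal \code{pair_id}.
#' @param sanger named character vector of \code{"Y"}/\code{"N"} Sanger
#'   flags per pair_id, or NULL (then NA).
#' @param intergenic_flags optional named vector of experimental intergenic
#'   transcript flags overriding the coverage track.
#' @param cfg a [filter_config()].
#' @return data.frame of criteria records.
#' @export
build_criteria_records <- function(pairs, ann, cnv = NULL, peaks = NULL,
                                   coverage = NULL, expr = NULL,
                                   sanger = NULL, intergenic_flags = NULL,
                                   cfg = filter_config()) {
  g <- ann$genes
  n <- nrow(pairs)
  rec <- data.frame(pair_id = pairs$pair_id, stringsAsFactors = FALSE)
  for (s in criteria_stages()) rec[[s]] <- NA_character_
  for (i in seq_len(n)) {
    g5 <- g[g$gene_id == pairs$gene5[i], , drop = FALSE]
    g3 <- g[g$gene_id == pairs$gene3[i], , drop = FALSE]
    chrom <- g5$chrom
    gap_s <- min(g5$end, g3$end); gap_e <- max(g5$start, g3$start)
    if (gap_s > gap_e) { gap_s <- 0L; gap_e <- 0L }
    rec$sanger_confirmed[i] <-
      if (!is.null(sanger)) unname(sanger[pairs$pair_id[i]])
      else NA_character_
    rec$immediate_neighbor[i] <-
      check_immediate_neighbor(ann, pairs$gene5[i], pairs$gene3[i])
    if (!is.null(cnv))
      rec$interstitial_deletion[i] <- check_interstitial_deletion(
        chrom, pairs$fused_exon5_end[i], pairs$fused_exon3_start[i], cnv, cfg)
    if (!is.null(peaks))
      rec$ctcf_binding[i] <- check_ctcf_binding(chrom, gap_s, gap_e, peaks,
                                                cfg)
    if (!is.null(expr)) {
      e <- expr[expr$feature_id == pairs$pair_id[i], , drop = FALSE]
      vn <- e$value[e$condition == "si_neg"]
      vk <- e$value[e$condition == "siCTCF"]
      if (length(vn) == 1 && length(vk) == 1) {
        ind <- classify_induction(vn, vk, cfg)
        rec$sictcf_induced[i] <- if (ind == "induced") "Y" else "N"
      }
    }
    fl <- if (!is.null(intergenic_flags))
      unname(intergenic_flags[pairs$pair_id[i]]) else NULL
    rec$intergenic_transcript[i] <- check_intergenic_transcript(
      chrom, gap_s, gap_e, coverage, fl, cfg)
  }
  rec
}
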