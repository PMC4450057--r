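#' Fusion taxonomy classes
#'
#' The three mutually exclusive chimeric-RNA categories used throughout:
#' \code{INTERCHR} (parental genes on different chromosomes),
#' \code{INTRACHR_SS_0GAP} (same chromosome, same strand, no gene in between,
#' 5' gene transcriptionally upstream — the cis-SAGe candidate class) and
#' \code{INTRACHR_OTHER} (all remaining same-chromosome fusions).
#'
#' @return Character vector of the three class names.
#' @export
fusion_classes <- function() c("INTRACHR_SS_0GAP", "INTRACHR_OTHER", "INTERCHR")

#' Classify one fusion call
#'
#' @param gene5_id,gene3_id parental gene ids (5' and 3' side of the chimeric
#'   RNA as reported by the caller).
#' @param ann a \code{GenomeAnnotation}.
#' @return A single class name (see [fusion_classes()]), with attribute
#'   \code{"reason"} when the call is same-chromosome but not SS-0GAP.
#'   Self-fusions (\code{gene5_id == gene3_id}) are rejected with an error.
#' @details A same-strand adjacent pair reported with the transcriptionally
#'   downstream gene as gene5 is classed \code{INTRACHR_OTHER} with reason
#'   \code{"reversed-order"}: read-through transcription cannot produce it.
#'   Overlapping same-strand neighbors (distance 0) still qualify as SS-0GAP.
#' @export
classify_fusion <- function(gene5_id, gene3_id, ann) {
  if (identical(gene5_id, gene3_id))
    stop("self-fusion rejected: ", gene5_id)
  g <- ann$genes
  a <- g[g$gene_id == gene5_id, , drop = FALSE]
  b <- g[g$gene_id == gene3_id, , drop = FALSE]
  if (nrow(a) == 0) stop("unknown gene_id: ", gene5_id)
  if (nrow(b) == 0) stop("unknown gene_id: ", gene3_id)
  if (a$chrom != b$chrom) return("INTERCHR")
  if (a$strand != b$strand) {
    r <- "INTRACHR_OTHER"; attr(r, "reason") <- "different-strand"
    return(r)
  }
  if (length(intervening_genes(ann, gene5_id, gene3_id)) > 0) {
    r <- "INTRACHR_OTHER"; attr(r, "reason") <- "intervening-gene"
    return(r)
  }
  upstream_ok <- if (a$strand == "+") a$start <= b$start else a$start >= b$start
  if (!upstream_ok) {
    r <- "INTRACHR_OTHER"; attr(r, "reason") <- "reversed-order"
    return(r)
  }
  "INTRACHR_SS_0GAP"
}

#' Classify a table of fusion calls
#'
#' Vectorized wrapper around [classify_fusion()]; fills the
#' \code{fusion_class} column.
#'
#' @param calls data.frame from [read_fusion_calls()] (needs \code{gene5},
#'   \code{gene3}).
#' @param ann a \code{GenomeAnnotation}.
#' @return \code{calls} with \code{fusion_class} set for every row.
#' @export
classify_fusions <- function(calls, ann) {
  calls$fusion_class <- vapply(seq_len(nrow(calls)), function(i)
    as.character(classify_fusion(calls$gene5[i], calls$gene3[i], ann)),
    character(1))
  calls
}

#' Per-sample fusion category fractions
#'
#' @param calls classified fusion calls (column \code{fusion_class} set).
#' @param by_sample split by \code{sample_id} (default TRUE); otherwise one
#'   pooled row with sample_id \code{"all"}.
#' @param unique_pairs count each ordered parental gene pair once per sample
#'   instead of each junction isoform (default FALSE).
#' @return data.frame with one row per sample: \code{sample_id},
#'   \code{total_calls}, and a fraction column per class. Fractions sum to 1
#'   for samples with calls; a sample with no calls would be dropped.
#' @export
category_fractions <- function(calls, by_sample = TRUE, unique_pairs = FALSE) {
  if (nrow(calls) == 0) stop("no fusion calls: fractions undefined")
  if (any(is.na(calls$fusion_class)))
    stop("all calls must be classified first (see classify_fusions)")
  d <- calls
  if (!by_sample) d$sample_id <- "all"
  if (unique_pairs) {
    key <- paste(d$sample_id, d$gene5, d$gene3, sep = "\r")
    d <- d[!duplicated(key), , drop = FALSE]
  }
  cls <- fusion_classes()
  out <- lapply(split(d, d$sample_id), function(s) {
    counts <- vapply(cls, function(k) sum(s$fusion_class == k), numeric(1))
    row <- data.frame(sample_id = s$sample_id[1], total_calls = nrow(s),
                      stringsAsFactors = FALSE)
    for (k in cls) row[[k]] <- counts[[k]] / nrow(s)
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pearson correlation of matched category fractions
#'
#' Correlates the SS-0GAP (or any) fraction between matched sample pairs,
#' e.g. tumors and their adjacent normals.
#'
#' @param tumor,normal equal-length numeric vectors of matched fractions
#'   (length >= 3).
#' @return Pearson product-moment correlation coefficient.
#' @export
paired_fraction_correlation <- function(tumor, normal) {
  if (length(tumor) != length(normal))
    stop("matched vectors must have equal length")
  if (length(tumor) < 3) stop("need at least 3 matched pairs")
  if (stats::sd(tumor) == 0 || stats::sd(normal) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(tumor, normal, method = "pearson")
}

#' Collapse fusion calls to unique parental gene pairs
#'
#' One record per ordered (gene5, gene3) pair, with junction-read support
#' summed over calls and the number of distinct junction isoforms (distinct
#' breakpoint pairs) counted. A pair and its reverse are distinct.
#'
#' @param calls classified fusion calls.
#' @return data.frame with \code{pair_id} (\code{"GENE5-GENE3"} built from
#'   gene symbols/ids), \code{gene5}, \code{gene3}, \code{fusion_class},
#'   \code{n_calls}, \code{isoform_count}, \code{junction_reads}.
#' @export
collapse_unique_pairs <- function(calls) {
  key <- paste(calls$gene5, calls$gene3, sep = "\r")
  out <- lapply(split(calls, key), function(s) {
    iso <- if (!is.null(s$bp5)) nrow(unique(s[, c("bp5", "bp3")]))
           else nrow(s)
    data.frame(pair_id = paste0(s$gene5[1], "-", s$gene3[1]),
               gene5 = s$gene5[1], gene3 = s$gene3[1],
               fusion_class = s$fusion_class[1],
               n_calls = nrow(s), isoform_count = iso,
               junction_reads = sum(s$junction_reads),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$pair_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
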