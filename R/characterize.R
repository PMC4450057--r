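#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes the KS statistic D as the maximum vertical distance between the
#' two empirical CDFs, evaluated over the pooled sample points, and the
#' asymptotic two-sample Smirnov p-value
#' \deqn{p = 2 \sum_{k \ge 1} (-1)^{k-1} e^{-2 k^2 n_e D^2}}
#' with effective size \eqn{n_e = n_1 n_2 / (n_1 + n_2)}. At the sample
#' sizes typical of a fusion cohort (16-32) the p-value is approximate.
#'
#' @param sample,background non-empty numeric vectors.
#' @return List of class \code{KSResult}: \code{D}, \code{p_value},
#'   \code{n_sample}, \code{n_background}.
#' @export
ks_two_sample <- function(sample, background) {
  x <- as.numeric(sample); y <- as.numeric(background)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty")
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  D <- max(abs(Fx - Fy))
  ne <- length(x) * length(y) / (length(x) + length(y))
  k <- seq_len(100)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * ne * D^2))
  p <- min(1, max(0, p))
  structure(list(D = D, p_value = p, n_sample = length(x),
                 n_background = length(y)),
            class = "KSResult")
}

#' @export
print.KSResult <- function(x, ...) {
  cat(sprintf("Two-sample KS: D = %.4f, p = %.4g (n = %d vs %d)\n",
              x$D, x$p_value, x$n_sample, x$n_background))
  invisible(x)
}

#' Exon ranks flanking fusion junctions
#'
#' For each classified call, ranks the exon immediately upstream of the
#' junction in the 5' gene and the exon immediately downstream in the 3'
#' gene, against the canonical transcripts. The 5' exon is matched on its 3'
#' (donor) boundary, the 3' exon on its 5' (acceptor) boundary.
#'
#' @param ann a \code{GenomeAnnotation}.
#' @param calls fusion calls with internal boundary columns \code{bp5},
#'   \code{bp3} (as produced by [read_fusion_calls()]).
#' @param tol boundary matching tolerance in bp (default 5).
#' @return \code{calls} with columns \code{rank5_fwd}, \code{rank5_bwd},
#'   \code{rank3_fwd}, \code{rank3_bwd} (NA when a junction maps to no exon).
#' @export
junction_exon_ranks <- function(ann, calls, tol = 5L) {
  n <- nrow(calls)
  r5f <- r5b <- r3f <- r3b <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    t5 <- canonical_transcript(ann, calls$gene5[i])$transcript_id
    t3 <- canonical_transcript(ann, calls$gene3[i])$transcript_id
    r5f[i] <- exon_rank(ann, t5, position = calls$bp5[i],
                        direction = "forward", tol = tol)
    r5b[i] <- exon_rank(ann, t5, position = calls$bp5[i],
                        direction = "backward", tol = tol)
    r3f[i] <- exon_rank(ann, t3, position = calls$bp3[i],
                        direction = "forward", tol = tol)
    r3b[i] <- exon_rank(ann, t3, position = calls$bp3[i],
                        direction = "backward", tol = tol)
  }
  calls$rank5_fwd <- r5f; calls$rank5_bwd <- r5b
  calls$rank3_fwd <- r3f; calls$rank3_bwd <- r3b
  calls
}

#' Histogram of junction exon positions
#'
#' Tabulates the rank of the exon flanking the fusion junction, per side and
#' counting direction (for the 5' gene the backward count, from the 3' end,
#' is the biologically informative one: the favored donor is the
#' second-to-last exon).
#'
#' @param ranked calls with rank columns from [junction_exon_ranks()].
#' @param side \code{"5prime"} or \code{"3prime"}.
#' @param direction \code{"forward"} or \code{"backward"}.
#' @return List: \code{counts} (named integer vector, rank -> count),
#'   \code{n_ranked}, \code{n_unranked}. Unranked junctions are excluded
#'   with a warning.
#' @export
exon_position_histogram <- function(ranked,
                                    side = c("5prime", "3prime"),
                                    direction = c("forward", "backward")) {
  side <- match.arg(side); direction <- match.arg(direction)
  col <- paste0("rank", if (side == "5prime") "5" else "3",
                if (direction == "forward") "_fwd" else "_bwd")
  if (is.null(ranked[[col]]))
    stop("missing rank column ", col, "; run junction_exon_ranks first")
  r <- ranked[[col]]
  n_un <- sum(is.na(r))
  if (n_un > 0)
    warning(n_un, " junction(s) without an exon rank excluded")
  r <- r[!is.na(r)]
  counts <- table(factor(r, levels = sort(unique(r))))
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       n_ranked = length(r), n_unranked = n_un)
}

#' Joint (5' backward, 3' forward) junction configuration counts
#'
#' Counts combinations of the 5'-gene backward rank and the 3'-gene forward
#' rank; the "2-2" combination (second-to-last exon of the 5' gene spliced to
#' the second exon of the 3' gene) is the hallmark cis-SAGe configuration.
#'
#' @param ranked calls with rank columns from [junction_exon_ranks()].
#' @return data.frame with \code{rank5_bwd}, \code{rank3_fwd}, \code{count},
#'   sorted by descending count.
#' @export
junction_configuration_counts <- function(ranked) {
  ok <- !is.na(ranked$rank5_bwd) & !is.na(ranked$rank3_fwd)
  d <- ranked[ok, c("rank5_bwd", "rank3_fwd"), drop = FALSE]
  if (nrow(d) == 0)
    return(data.frame(rank5_bwd = integer(0), rank3_fwd = integer(0),
                      count = integer(0)))
  key <- paste(d$rank5_bwd, d$rank3_fwd)
  tab <- table(key)
  parts <- strsplit(names(tab), " ", fixed = TRUE)
  out <- data.frame(
    rank5_bwd = as.integer(vapply(parts, `[`, character(1), 1)),
    rank3_fwd = as.integer(vapply(parts, `[`, character(1), 2)),
    count = as.integer(tab))
  out <- out[order(-out$count, out$rank5_bwd, out$rank3_fwd), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulated tail probability for target-exon usage
#'
#' The null model draws, for each 3' parental gene, one fused exon uniformly
#' from its \code{1..E_i} exons, and counts how many genes hit the target
#' rank. The reported p is the fraction of replicates with a count at least
#' as large as observed.
#'
#' @param exon_totals integer vector \code{E_i}, exons per 3' parental gene
#'   (all >= 1).
#' @param observed_k observed number of genes fused at the target rank.
#' @param target_rank exon rank tested (default 2).
#' @param n_sim number of replicates (default 10000).
#' @param seed RNG seed for reproducibility (default 1).
#' @param acceptor_only if TRUE, restrict the null to acceptor-bearing exons
#'   \code{2..E_i} (single-exon genes then never hit any rank >= 2); default
#'   FALSE, i.e. uniform over all exons.
#' @return List of class \code{ExonUsageTest}: inputs plus \code{p_sim} and
#'   \code{p_exact} (the matching Poisson-binomial tail).
#' @export
exon2_usage_simulation <- function(exon_totals, observed_k, target_rank = 2L,
                                   n_sim = 10000L, seed = 1L,
                                   acceptor_only = FALSE) {
  E <- as.integer(exon_totals)
  if (any(E < 1)) stop("every gene must have at least one exon")
  if (observed_k > length(E))
    stop("observed_k cannot exceed the number of genes")
  if (n_sim < 1) stop("n_sim must be >= 1")
  p_i <- .target_rank_probs(E, target_rank, acceptor_only)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  hits <- matrix(stats::runif(n_sim * length(E)) < rep(p_i, each = n_sim),
                 nrow = n_sim)
  counts <- rowSums(hits)
  p_sim <- mean(counts >= observed_k)
  structure(list(exon_totals = E, observed_k = observed_k,
                 target_rank = as.integer(target_rank),
                 n_sim = as.integer(n_sim), seed = seed,
                 p_sim = p_sim,
                 p_exact = exon2_usage_exact(E, observed_k, target_rank,
                                             acceptor_only),
                 counts = counts),
            class = "ExonUsageTest")
}

#' @export
print.ExonUsageTest <- function(x, ...) {
  cat(sprintf(
    "Exon-%d usage: %d/%d genes at target rank; p_sim = %.3g (n_sim = %d), p_exact = %.3g\n",
    x$target_rank, x$observed_k, length(x$exon_totals), x$p_sim, x$n_sim,
    x$p_exact))
  invisible(x)
}

## per-gene probability of drawing the target rank under the null
.target_rank_probs <- function(E, target_rank, acceptor_only = FALSE) {
  if (acceptor_only) {
    ifelse(E >= target_rank & E >= 2, 1 / (E - 1), 0)
  } else {
    ifelse(E >= target_rank, 1 / E, 0)
  }
}

#' Exact tail probability for target-exon usage
#'
#' The count of genes hitting the target rank is Poisson-binomial with
#' per-gene success probability \code{1/E_i} (0 when the gene has fewer than
#' \code{target_rank} exons). The tail \code{Pr(K >= observed_k)} is computed
#' by exact convolution of the per-gene distributions.
#'
#' @inheritParams exon2_usage_simulation
#' @return Tail probability.
#' @export
exon2_usage_exact <- function(exon_totals, observed_k, target_rank = 2L,
                              acceptor_only = FALSE) {
  E <- as.integer(exon_totals)
  if (any(E < 1)) stop("every gene must have at least one exon")
  p_i <- .target_rank_probs(E, target_rank, acceptor_only)
  pmf <- 1
  for (p in p_i) pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  k <- observed_k
  if (k <= 0) return(1)
  if (k > length(E)) return(0)
  sum(pmf[(k + 1):length(pmf)])
}

## save/restore the global RNG state so seeded helpers do not perturb the
## caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Classify the coding impact of a fusion junction
#'
#' Determines whether a fusion at annotated exon boundaries leaves the
#' protein-coding sequence untouched (\code{NR}: a junction point in the
#' UTR on either side), preserves the 3' gene's reading frame
#' (\code{in_frame}) or disrupts it (\code{out_of_frame}). Frames are
#' computed on the canonical transcripts: the cumulative coding length from
#' the 5' CDS start to the donor point modulo 3 is compared with the 3'
#' junction's offset into its own CDS modulo 3. A transcript without an
#' annotated CDS yields \code{NR} with a warning.
#'
#' @param ann a \code{GenomeAnnotation}.
#' @param gene5_id,gene3_id parental gene ids.
#' @param bp5 donor boundary: 0-based genomic coordinate of the 3' edge of
#'   the last retained 5'-gene exon.
#' @param bp3 acceptor boundary: 0-based genomic coordinate of the 5' edge
#'   of the first retained 3'-gene exon.
#' @return \code{"NR"}, \code{"in_frame"} or \code{"out_of_frame"}. A
#'   junction point strictly inside a CDS but not on an exon boundary is
#'   refused with an error (non-canonical junction).
#' @export
classify_coding_impact <- function(ann, gene5_id, gene3_id, bp5, bp3) {
  t5 <- canonical_transcript(ann, gene5_id)
  t3 <- canonical_transcript(ann, gene3_id)
  .check_on_boundary <- function(tid, pos, which_edge) {
    ex <- transcript_exons(ann, tid)
    if (!any(ex$start == pos | ex$end == pos))
      stop("junction position ", pos, " is not an annotated exon boundary ",
           "of transcript ", tid, " (non-canonical junction)")
  }
  .check_on_boundary(t5$transcript_id, bp5)
  .check_on_boundary(t3$transcript_id, bp3)
  if (is.na(t5$cds_start) || is.na(t3$cds_start)) {
    warning("missing CDS annotation: classified NR by convention")
    return("NR")
  }
  tc <- function(tx, gpos) genomic_to_transcript(ann, tx$transcript_id, gpos)
  strand5 <- ann$genes$strand[ann$genes$gene_id == gene5_id]
  strand3 <- ann$genes$strand[ann$genes$gene_id == gene3_id]
  ## transcript-coordinate offsets of junction and CDS edges
  j5 <- tc(t5, bp5)
  cds5_s <- tc(t5, if (strand5 == "+") t5$cds_start else t5$cds_end)
  cds5_e <- tc(t5, if (strand5 == "+") t5$cds_end else t5$cds_start)
  j3 <- tc(t3, bp3)
  cds3_s <- tc(t3, if (strand3 == "+") t3$cds_start else t3$cds_end)
  cds3_e <- tc(t3, if (strand3 == "+") t3$cds_end else t3$cds_start)
  if (j5 <= cds5_s || j5 >= cds5_e) return("NR")
  if (j3 <= cds3_s || j3 >= cds3_e) return("NR")
  coding5 <- j5 - cds5_s            # coding bases retained from the 5' gene
  offset3 <- j3 - cds3_s            # bases into the 3' CDS at the junction
  if ((coding5 - offset3) %% 3 == 0) "in_frame" else "out_of_frame"
}

#' Cross-tabulate coding impact against nuclear enrichment
#'
#' A fusion is nuclear-enriched iff nuclear/cytoplasmic ratio is strictly
#' greater than 1. Records with zero cytoplasmic level are flagged and get an
#' infinite ratio (enriched).
#'
#' @param records data.frame with \code{fusion_id}, \code{nuclear_level},
#'   \code{cytoplasmic_level} (both >= 0).
#' @param impacts named character vector fusion_id -> coding impact
#'   (\code{NR}/\code{in_frame}/\code{out_of_frame}).
#' @return List: \code{records} (with \code{ratio}, \code{enriched},
#'   \code{impact}), \code{crosstab} (impact x enrichment counts).
#' @export
summarize_fractionation <- function(records, impacts) {
  if (any(records$nuclear_level < 0 | records$cytoplasmic_level < 0))
    stop("fractionation levels must be non-negative")
  ratio <- ifelse(records$cytoplasmic_level > 0,
                  records$nuclear_level / records$cytoplasmic_level, Inf)
  if (any(records$cytoplasmic_level == 0))
    warning("zero cytoplasmic level: ratio infinite for ",
            sum(records$cytoplasmic_level == 0), " record(s)")
  records$ratio <- ratio
  records$enriched <- ratio > 1
  records$impact <- unname(impacts[records$fusion_id])
  tab <- table(
    impact = factor(records$impact, levels = c("NR", "out_of_frame",
                                               "in_frame")),
    nuclear_enriched = factor(records$enriched, levels = c(TRUE, FALSE)))
  list(records = records, crosstab = tab)
}
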