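#' Simulation configuration
#'
#' Parameters of the synthetic genome and cohort generator. Defaults imitate
#' the qualitative shape of a mammalian annotation: ~12% single-exon genes
#' with a secondary mode near 5 exons per gene, exon lengths around 150 bp,
#' intron lengths around 1.5 kb, and a median same-strand intergenic
#' distance of about 54 kb, so that planted cis-SAGe pairs (all under 30 kb)
#' stand out against the background the way real ones do.
#'
#' @param n_chromosomes number of chromosomes (default 4).
#' @param genes_per_chromosome genes per chromosome (default 500).
#' @param single_exon_prob point mass of single-exon genes (default 0.12).
#' @param exon_count_lambda Poisson rate of the multi-exon component; the
#'   exon count of a multi-exon gene is 2 + Poisson(lambda) (default 3.5,
#'   putting the mode near 5).
#' @param exon_length_meanlog,exon_length_sdlog log-normal exon length
#'   parameters (defaults log(150), 0.6).
#' @param intron_length_meanlog,intron_length_sdlog log-normal intron length
#'   parameters (defaults log(1500), 1.0).
#' @param intergenic_meanlog,intergenic_sdlog log-normal intergenic distance
#'   parameters (defaults log(54000), 1.2 — median 54 kb).
#' @param minus_strand_prob probability a gene lies on the minus strand
#'   (default 0.5).
#' @param seed RNG seed fixing the whole genome (default 1).
#' @return List of class \code{SimConfig}.
#' @export
sim_config <- function(n_chromosomes = 4L, genes_per_chromosome = 500L,
                       single_exon_prob = 0.12, exon_count_lambda = 3.5,
                       exon_length_meanlog = log(150),
                       exon_length_sdlog = 0.6,
                       intron_length_meanlog = log(1500),
                       intron_length_sdlog = 1.0,
                       intergenic_meanlog = log(54000),
                       intergenic_sdlog = 1.2,
                       minus_strand_prob = 0.5, seed = 1L) {
  if (single_exon_prob < 0 || single_exon_prob > 1)
    stop("single_exon_prob must be in [0, 1]")
  if (n_chromosomes < 1 || genes_per_chromosome < 1)
    stop("need at least one chromosome and one gene")
  structure(as.list(environment()), class = "SimConfig")
}

#' Simulate a genome annotation
#'
#' Lays out non-overlapping genes chromosome by chromosome with structures
#' sampled from the configured distributions; one transcript per gene, with
#' a CDS trimmed in from both transcript ends so coding-impact arithmetic is
#' exercised. Deterministic under the config seed, and reloadable through
#' [load_annotation()] after [write_annotation()].
#'
#' @param cfg a [sim_config()].
#' @return A \code{GenomeAnnotation}.
#' @export
simulate_annotation <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  genes <- list(); exons <- list(); cds <- list()
  for (ci in seq_len(cfg$n_chromosomes)) {
    chrom <- paste0("chr", ci)
    pos <- 10000L
    for (gi in seq_len(cfg$genes_per_chromosome)) {
      gid <- sprintf("%s.g%04d", chrom, gi)
      gap <- as.integer(round(stats::rlnorm(1, cfg$intergenic_meanlog,
                                            cfg$intergenic_sdlog)))
      pos <- pos + max(200L, gap)
      n_ex <- if (stats::runif(1) < cfg$single_exon_prob) 1L
              else 2L + stats::rpois(1, cfg$exon_count_lambda)
      ex_len <- pmax(30L, as.integer(round(stats::rlnorm(
        n_ex, cfg$exon_length_meanlog, cfg$exon_length_sdlog))))
      in_len <- if (n_ex > 1) pmax(60L, as.integer(round(stats::rlnorm(
        n_ex - 1, cfg$intron_length_meanlog, cfg$intron_length_sdlog))))
        else integer(0)
      starts <- pos + cumsum(c(0L, ex_len[-n_ex] + in_len))
      ends <- starts + ex_len
      strand <- if (stats::runif(1) < cfg$minus_strand_prob) "-" else "+"
      tid <- paste0(gid, ".t1")
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid, symbol = gid, chrom = chrom, strand = strand,
        start = starts[1], end = ends[n_ex], stringsAsFactors = FALSE)
      exons[[length(exons) + 1L]] <- data.frame(
        transcript_id = tid, gene_id = gid, start = starts, end = ends,
        stringsAsFactors = FALSE)
      trim5 <- min(30L, ex_len[1] %/% 3L)
      trim3 <- min(30L, ex_len[n_ex] %/% 3L)
      cds[[length(cds) + 1L]] <- data.frame(
        transcript_id = tid, cds_start = starts[1] + trim5,
        cds_end = ends[n_ex] - trim3, stringsAsFactors = FALSE)
      pos <- ends[n_ex]
    }
  }
  genome_annotation(do.call(rbind, genes), do.call(rbind, exons),
                    do.call(rbind, cds))
}

#' Plant fusion events with known ground truth
#'
#' Places synthetic fusion calls of four kinds on the simulated genome:
#' \describe{
#'   \item{cis_sage}{true read-through events on same-strand immediate pairs
#'     under 30 kb apart with both genes multi-exonic; a fraction
#'     \code{exon_bias} get the canonical "2-2" junction (second-to-last
#'     exon of the 5' gene to second exon of the 3' gene), the rest a random
#'     valid exon pair.}
#'   \item{deletion_driven}{decoys on immediate same-strand pairs whose
#'     fused-exon interval will carry a copy-number loss.}
#'   \item{trans_like}{decoys on immediate same-strand pairs that will be
#'     down-regulated rather than induced under CTCF knockdown.}
#'   \item{interchr}{fusions joining genes on different chromosomes.}
#' }
#'
#' @param ann a \code{GenomeAnnotation} (from [simulate_annotation()]).
#' @param n_per_type named integer vector with entries \code{cis_sage},
#'   \code{deletion_driven}, \code{trans_like}, \code{interchr} (default
#'   16, 5, 13, 5 — the validated-event and decoy counts the package's
#'   default cohort emulates).
#' @param exon_bias fraction of cis-SAGe events with the 2-2 junction
#'   configuration (default 11/16). The biased count is
#'   \code{round(exon_bias * n)} and is planted deterministically.
#' @param min_exons_cis minimum exon count for both genes of a cis-SAGe pair
#'   (default 4).
#' @param max_distance_cis intergenic distance bound for cis-SAGe pairs,
#'   strict (default 30000).
#' @param seed RNG seed (default 1).
#' @return List: \code{calls} (fusion-call data.frame, unclassified) and
#'   \code{truth} (one row per planted event: \code{pair_id}, \code{gene5},
#'   \code{gene3}, \code{event_type}, planted junction ranks,
#'   \code{expected_class}, \code{expected_fate}, and the fused-exon
#'   interval \code{del_start}/\code{del_end} for same-chromosome events).
#' @export
plant_events <- function(ann,
                         n_per_type = c(cis_sage = 16L, deletion_driven = 5L,
                                        trans_like = 13L, interchr = 5L),
                         exon_bias = 11 / 16, min_exons_cis = 4L,
                         max_distance_cis = 30000L, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  np <- neighbor_pairs(ann, same_strand_only = TRUE)
  tx <- ann$transcripts[ann$transcripts$canonical, ]
  nex <- stats::setNames(tx$n_exons, tx$gene_id)
  ## planted pairs need room in the gap for peaks/coverage evidence
  np <- np[np$intergenic_distance >= 1000, , drop = FALSE]
  multi2 <- nex[np$gene5] >= 2 & nex[np$gene3] >= 2
  elig_cis <- which(np$intergenic_distance < max_distance_cis &
                      nex[np$gene5] >= min_exons_cis &
                      nex[np$gene3] >= min_exons_cis)
  elig_other <- which(multi2)
  n_cis <- n_per_type[["cis_sage"]]
  n_del <- n_per_type[["deletion_driven"]]
  n_trn <- n_per_type[["trans_like"]]
  n_int <- n_per_type[["interchr"]]
  ## pairs are selected gene-disjoint so that no two planted events share a
  ## parental gene (keeps evidence intervals of different events disjoint)
  used_genes <- character(0)
  pick_disjoint <- function(pool, n, label) {
    pool <- sample(pool)
    out <- integer(0)
    for (i in pool) {
      if (length(out) == n) break
      if (np$gene5[i] %in% used_genes || np$gene3[i] %in% used_genes) next
      out <- c(out, i)
      used_genes <<- c(used_genes, np$gene5[i], np$gene3[i])
    }
    if (length(out) < n)
      stop("only ", length(out), " eligible gene-disjoint ", label,
           " pairs for ", n, " requested")
    out
  }
  cis_idx <- pick_disjoint(elig_cis, n_cis, "cis-SAGe")
  pool <- setdiff(elig_other, cis_idx)
  del_idx <- pick_disjoint(pool, n_del, "deletion decoy")
  trn_idx <- pick_disjoint(setdiff(pool, del_idx), n_trn, "trans-like decoy")

  g <- ann$genes
  make_event <- function(i, type, force_22) {
    g5 <- np$gene5[i]; g3 <- np$gene3[i]
    t5 <- canonical_transcript(ann, g5); t3 <- canonical_transcript(ann, g3)
    n5 <- t5$n_exons; n3 <- t3$n_exons
    if (force_22) { r5b <- 2L; r3f <- 2L }
    else { r5b <- sample.int(n5, 1); r3f <- sample.int(n3, 1) }
    ex5 <- transcript_exons(ann, t5$transcript_id)
    ex3 <- transcript_exons(ann, t3$transcript_id)
    s <- np$strand5[i]
    donor <- ex5[if (s == "+") n5 - r5b + 1L else r5b, ]
    accep <- ex3[if (s == "+") r3f else n3 - r3f + 1L, ]
    bp5 <- if (s == "+") donor$end else donor$start
    bp3 <- if (s == "+") accep$start else accep$end
    data.frame(pair_id = paste0(g5, "-", g3), gene5 = g5, gene3 = g3,
               event_type = type, rank5_bwd = r5b, rank3_fwd = r3f,
               chrom5 = np$chrom[i], chrom3 = np$chrom[i],
               strand5 = s, strand3 = s, bp5 = bp5, bp3 = bp3,
               del_start = min(bp5, bp3), del_end = max(bp5, bp3),
               expected_class = "INTRACHR_SS_0GAP",
               expected_fate = switch(type, cis_sage = "pass",
                                      deletion_driven = "interstitial_deletion",
                                      trans_like = "sictcf_induced"),
               stringsAsFactors = FALSE)
  }
  n_biased <- round(exon_bias * n_cis)
  truth <- do.call(rbind, c(
    lapply(seq_along(cis_idx), function(k)
      make_event(cis_idx[k], "cis_sage", force_22 = k <= n_biased)),
    lapply(del_idx, make_event, type = "deletion_driven", force_22 = FALSE),
    lapply(trn_idx, make_event, type = "trans_like", force_22 = FALSE)))

  ## interchromosomal decoys: random multi-exon genes on different chromosomes
  used <- c(truth$gene5, truth$gene3)
  free <- g[!(g$gene_id %in% used) & nex[g$gene_id] >= 2, , drop = FALSE]
  inter <- list()
  while (length(inter) < n_int) {
    cand <- free[sample.int(nrow(free), 2), ]
    if (cand$chrom[1] == cand$chrom[2]) next
    jr <- function(gid) {
      t <- canonical_transcript(ann, gid)
      ex <- transcript_exons(ann, t$transcript_id)
      i <- sample.int(nrow(ex), 1)
      ex[i, ]
    }
    d <- jr(cand$gene_id[1]); a <- jr(cand$gene_id[2])
    inter[[length(inter) + 1L]] <- data.frame(
      pair_id = paste0(cand$gene_id[1], "-", cand$gene_id[2]),
      gene5 = cand$gene_id[1], gene3 = cand$gene_id[2],
      event_type = "interchr", rank5_bwd = NA_integer_,
      rank3_fwd = NA_integer_,
      chrom5 = cand$chrom[1], chrom3 = cand$chrom[2],
      strand5 = cand$strand[1], strand3 = cand$strand[2],
      bp5 = if (cand$strand[1] == "+") d$end else d$start,
      bp3 = if (cand$strand[2] == "+") a$start else a$end,
      del_start = NA_integer_, del_end = NA_integer_,
      expected_class = "INTERCHR", expected_fate = "classified_out",
      stringsAsFactors = FALSE)
  }
  truth <- rbind(truth, do.call(rbind, inter))
  rownames(truth) <- NULL

  calls <- data.frame(
    sample_id = "sim", gene5 = truth$gene5, gene3 = truth$gene3,
    chrom5 = truth$chrom5, strand5 = truth$strand5,
    chrom3 = truth$chrom3, strand3 = truth$strand3,
    bp5 = truth$bp5, bp3 = truth$bp3,
    junction_reads = 1L + stats::rpois(nrow(truth), 20),
    spanning_reads = stats::rpois(nrow(truth), 10),
    fusion_class = NA_character_, stringsAsFactors = FALSE)
  list(calls = calls, truth = truth)
}

#' Simulate evidence tracks and expression tables for a planted cohort
#'
#' Builds the inputs the filtering cascade consumes, consistent with the
#' planted ground truth: a copy-number track that is neutral everywhere
#' except for single-copy losses (log2 = -1) under the fused-exon intervals
#' of deletion-driven decoys; CTCF peaks in the intergenic gaps of cis-SAGe
#' and trans-like pairs; intergenic read coverage above threshold only for
#' cis-SAGe pairs; per-fusion expression induced (FC 2.5) for cis-SAGe,
#' repressed (FC 0.4) for trans-like and flat for deletion-driven pairs
#' under CTCF knockdown; a gene FPKM table in which the 5' gene of every
#' cis-SAGe pair is actively transcribed; and all-confirmed Sanger flags for
#' the same-chromosome pairs.
#'
#' @param ann a \code{GenomeAnnotation}.
#' @param truth truth table from [plant_events()].
#' @param seed RNG seed for the nuisance values (default 1).
#' @return List with \code{cnv}, \code{peaks}, \code{coverage} (track
#'   data.frames), \code{fusion_expr} (expression data.frame),
#'   \code{gene_fpkm} (named vector), \code{sanger} (named flag vector).
#' @export
simulate_tracks_and_expression <- function(ann, truth, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  g <- ann$genes
  ss <- truth[truth$event_type != "interchr", , drop = FALSE]
  gap_of <- function(i) {
    g5 <- g[g$gene_id == ss$gene5[i], ]; g3 <- g[g$gene_id == ss$gene3[i], ]
    c(start = min(g5$end, g3$end), end = max(g5$start, g3$start))
  }
  ## CNV: per-chromosome neutral coverage with losses carved out
  chrom_end <- vapply(split(g$end, g$chrom), max, integer(1))
  del <- ss[ss$event_type == "deletion_driven", , drop = FALSE]
  cnv <- list()
  for (chrom in names(chrom_end)) {
    cuts <- c(0L, chrom_end[[chrom]] + 10000L)
    dc <- del[del$chrom5 == chrom, , drop = FALSE]
    bounds <- sort(unique(c(cuts, dc$del_start, dc$del_end)))
    for (j in seq_len(length(bounds) - 1)) {
      s <- bounds[j]; e <- bounds[j + 1]
      lost <- any(dc$del_start <= s & dc$del_end >= e)
      cnv[[length(cnv) + 1L]] <- data.frame(
        chrom = chrom, start = s, end = e,
        value = if (lost) -1.0 else round(stats::rnorm(1, 0, 0.03), 3),
        stringsAsFactors = FALSE)
    }
  }
  cnv <- do.call(rbind, cnv)

  peaks <- list(); coverage <- list()
  for (i in seq_len(nrow(ss))) {
    gap <- gap_of(i)
    mid <- (gap[["start"]] + gap[["end"]]) %/% 2L
    if (ss$event_type[i] %in% c("cis_sage", "trans_like"))
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = ss$chrom5[i], start = mid - 100L, end = mid + 100L,
        value = round(stats::runif(1, 5, 50), 1), stringsAsFactors = FALSE)
    coverage[[length(coverage) + 1L]] <- data.frame(
      chrom = ss$chrom5[i], start = gap[["start"]], end = gap[["end"]],
      value = if (ss$event_type[i] == "cis_sage")
        round(stats::runif(1, 3, 10), 1) else 0,
      stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, peaks)
  coverage <- do.call(rbind, coverage)

  base <- stats::runif(nrow(ss), 5, 15)
  fc <- ifelse(ss$event_type == "cis_sage", 2.5,
               ifelse(ss$event_type == "trans_like", 0.4, 1.0))
  fusion_expr <- rbind(
    data.frame(feature_id = ss$pair_id, condition = "si_neg",
               value = round(base, 3), stringsAsFactors = FALSE),
    data.frame(feature_id = ss$pair_id, condition = "siCTCF",
               value = round(base * fc, 3), stringsAsFactors = FALSE))

  gene_fpkm <- stats::setNames(
    round(stats::rlnorm(nrow(g), log(5), 1.5), 3), g$gene_id)
  cis5 <- ss$gene5[ss$event_type == "cis_sage"]
  gene_fpkm[cis5] <- pmax(gene_fpkm[cis5], 2)

  sanger <- stats::setNames(rep("Y", nrow(ss)), ss$pair_id)
  list(cnv = cnv, peaks = peaks, coverage = coverage,
       fusion_expr = fusion_expr, gene_fpkm = gene_fpkm, sanger = sanger)
}
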