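# Shared in-code fixtures and independent oracles.

# three adjacent plus-strand genes on chr1, two exons each
toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("G1", "G2", "G3"), symbol = c("G1", "G2", "G3"),
    chrom = "chr1", strand = "+",
    start = c(100L, 2000L, 5000L), end = c(1000L, 3000L, 6000L))
  exons <- data.frame(
    transcript_id = rep(c("G1.t1", "G2.t1", "G3.t1"), each = 2),
    gene_id = rep(c("G1", "G2", "G3"), each = 2),
    start = c(100L, 600L, 2000L, 2600L, 5000L, 5600L),
    end = c(300L, 1000L, 2200L, 3000L, 5200L, 6000L))
  genome_annotation(genes, exons)
}

# random annotation of n genes over a few chromosomes, for property tests;
# gene structures are simple but strands and gaps vary
random_annotation <- function(n, seed) {
  set.seed(seed)
  chroms <- paste0("chr", sample(1:3, n, replace = TRUE))
  genes <- exons <- list()
  for (chrom in unique(chroms)) {
    k <- sum(chroms == chrom)
    pos <- 0L
    for (i in seq_len(k)) {
      gid <- sprintf("%s.g%02d", chrom, i)
      pos <- pos + sample(50:5000, 1)
      n_ex <- sample(1:4, 1)
      width <- sample(50:200, n_ex, replace = TRUE)
      gaps <- if (n_ex > 1) sample(50:500, n_ex - 1, replace = TRUE)
              else integer(0)
      starts <- pos + cumsum(c(0L, width[-n_ex] + gaps))
      ends <- starts + width
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid, symbol = gid, chrom = chrom,
        strand = sample(c("+", "-"), 1),
        start = starts[1], end = ends[n_ex])
      exons[[length(exons) + 1L]] <- data.frame(
        transcript_id = paste0(gid, ".t1"), gene_id = gid,
        start = starts, end = ends)
      pos <- ends[n_ex]
    }
  }
  genome_annotation(do.call(rbind, genes), do.call(rbind, exons))
}

# O(n^2) adjacency oracle: same-strand immediate pairs by definition --
# consecutive in start order among same-strand genes on a chromosome, with
# no gene of any strand overlapping the open gap
brute_same_strand_pairs <- function(ann) {
  g <- ann$genes
  out <- list()
  for (i in seq_len(nrow(g))) for (j in seq_len(nrow(g))) {
    if (i == j) next
    a <- g[i, ]; b <- g[j, ]
    if (a$chrom != b$chrom || a$strand != b$strand) next
    if (!(a$start < b$start || (a$start == b$start && a$gene_id < b$gene_id)))
      next
    # no same-strand gene strictly between them in start order
    between <- g$chrom == a$chrom & g$strand == a$strand &
      !(g$gene_id %in% c(a$gene_id, b$gene_id)) &
      (g$start > a$start | (g$start == a$start & g$gene_id > a$gene_id)) &
      (g$start < b$start | (g$start == b$start & g$gene_id < b$gene_id))
    if (any(between)) next
    # no gene of any strand intruding into the open gap
    if (a$end < b$start) {
      gap <- g$chrom == a$chrom & !(g$gene_id %in% c(a$gene_id, b$gene_id)) &
        g$start < b$start & g$end > a$end
      if (any(gap)) next
    }
    g5 <- if (a$strand == "+") a else b
    g3 <- if (a$strand == "+") b else a
    out[[length(out) + 1L]] <- data.frame(
      gene5 = g5$gene_id, gene3 = g3$gene_id,
      intergenic_distance = max(0L, b$start - a$end))
  }
  if (!length(out))
    return(data.frame(gene5 = character(0), gene3 = character(0),
                      intergenic_distance = integer(0)))
  do.call(rbind, out)
}

# brute-force KS statistic: maximize the ECDF gap over pooled points
brute_ks_D <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# exact exon-2 tail by exhaustive enumeration over all outcome vectors
enum_exon2_tail <- function(E, k, target_rank = 2) {
  grids <- lapply(E, seq_len)
  outcomes <- expand.grid(grids)
  probs <- apply(outcomes, 1, function(row) prod(1 / E))
  hits <- apply(outcomes, 1, function(row) sum(row == target_rank))
  sum(probs[hits >= k])
}

# one default-scale simulated cohort, built once and shared across tests
.cohort_cache <- new.env(parent = emptyenv())
sim_cohort_fixture <- function(seed = 11L) {
  key <- paste0("s", seed)
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  ann <- simulate_annotation(sim_config(seed = seed))
  pe <- plant_events(ann, seed = seed)
  tr <- simulate_tracks_and_expression(ann, pe$truth, seed = seed)
  .cohort_cache[[key]] <- list(ann = ann, calls = pe$calls,
                               truth = pe$truth, tracks = tr)
  .cohort_cache[[key]]
}
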