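test_that("construction sorts genes and exons and validates structure", {
  ann <- toy_annotation()
  expect_equal(ann$genes$gene_id, c("G1", "G2", "G3"))
  expect_true(all(diff(ann$genes$start) > 0))

  # exons supplied in descending order come back ascending
  genes <- data.frame(gene_id = "G1", symbol = "G1", chrom = "chr1",
                      strand = "+", start = 0L, end = 1000L)
  exons <- data.frame(transcript_id = "t1", gene_id = "G1",
                      start = c(600L, 0L), end = c(900L, 300L))
  ann2 <- genome_annotation(genes, exons)
  expect_equal(ann2$exons$start, c(0L, 600L))

  # structural violations are rejected
  expect_error(genome_annotation(genes, transform(exons, end = c(900, 700))),
               "overlapping")
  expect_error(
    genome_annotation(genes,
                      data.frame(transcript_id = "t1", gene_id = "G1",
                                 start = 500L, end = 1200L)),
    "outside declared gene span")
})

test_that("GTF round trip is lossless", {
  ann <- random_annotation(20, seed = 42)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_annotation(ann, path)
  ann2 <- load_annotation(path)
  expect_equal(ann2$genes, ann$genes)
  expect_equal(ann2$exons, ann$exons)
  expect_equal(ann2$transcripts, ann$transcripts)
  # writing again is byte-identical
  path2 <- withr::local_tempfile(fileext = ".gtf")
  write_annotation(ann2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("malformed annotation lines fail with a line number", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c("# comment", "chr1\tsrc\texon\t1\t100"), path)
  expect_error(load_annotation(path), "line 2")
})

test_that("neighbor_pairs emits immediate pairs with strand-aware order", {
  ann <- toy_annotation()
  np <- neighbor_pairs(ann)
  expect_equal(np$gene5, c("G1", "G2"))
  expect_equal(np$gene3, c("G2", "G3"))
  expect_equal(np$intergenic_distance, c(1000L, 2000L))
  expect_equal(neighbor_pairs(ann, max_distance = 1500)$gene5, "G1")

  # middle gene flipped to minus strand: no same-strand pair survives,
  # and (G1,G3) is blocked by the intervening G2
  g <- ann$genes; g$strand[g$gene_id == "G2"] <- "-"
  ann2 <- genome_annotation(g, ann$exons[, c("transcript_id", "gene_id",
                                             "start", "end")])
  expect_equal(nrow(neighbor_pairs(ann2, same_strand_only = TRUE)), 0L)

  # on the minus strand the genomically right gene is the 5' gene
  g$strand <- "-"
  ann3 <- genome_annotation(g, ann$exons[, c("transcript_id", "gene_id",
                                             "start", "end")])
  np3 <- neighbor_pairs(ann3)
  expect_setequal(paste(np3$gene5, np3$gene3), c("G2 G1", "G3 G2"))
})

test_that("neighbor_pairs matches the brute-force adjacency oracle", {
  for (seed in c(1, 2, 3, 4)) {
    ann <- random_annotation(50, seed = seed)
    np <- neighbor_pairs(ann)
    bf <- brute_same_strand_pairs(ann)
    key <- function(d) sort(paste(d$gene5, d$gene3, d$intergenic_distance))
    expect_identical(key(np), key(bf))
  }
})

test_that("intervening_genes finds any-strand genes in the gap", {
  ann <- toy_annotation()
  expect_equal(intervening_genes(ann, "G1", "G3"), "G2")
  expect_equal(intervening_genes(ann, "G1", "G2"), character(0))

  # a nested antisense gene inside the gap disqualifies immediacy
  g <- rbind(ann$genes,
             data.frame(gene_id = "A1", symbol = "A1", chrom = "chr1",
                        strand = "-", start = 1200L, end = 1600L))
  e <- rbind(ann$exons[, c("transcript_id", "gene_id", "start", "end")],
             data.frame(transcript_id = "A1.t1", gene_id = "A1",
                        start = 1200L, end = 1600L))
  ann2 <- genome_annotation(g, e)
  expect_equal(intervening_genes(ann2, "G1", "G2"), "A1")

  other <- data.frame(gene_id = "H1", symbol = "H1", chrom = "chr2",
                      strand = "+", start = 0L, end = 100L)
  ann3 <- genome_annotation(
    rbind(ann$genes, other),
    rbind(ann$exons[, c("transcript_id", "gene_id", "start", "end")],
          data.frame(transcript_id = "H1.t1", gene_id = "H1",
                     start = 0L, end = 100L)))
  expect_error(intervening_genes(ann3, "G1", "H1"), "different chromosomes")
})

test_that("exon ranks are strand-aware and forward + backward = n + 1", {
  # 5-exon plus-strand transcript
  genes <- data.frame(gene_id = "P", symbol = "P", chrom = "chr1",
                      strand = "+", start = 0L, end = 5000L)
  exons <- data.frame(transcript_id = "P.t1", gene_id = "P",
                      start = seq(0L, 4000L, by = 1000L),
                      end = seq(0L, 4000L, by = 1000L) + 200L)
  annp <- genome_annotation(genes, exons)
  expect_equal(exon_rank(annp, "P.t1", index = 4, direction = "backward"), 2L)
  expect_equal(exon_rank(annp, "P.t1", index = 4, direction = "forward"), 4L)

  # minus strand: the genomically last exon is forward rank 1
  genes$strand <- "-"
  annm <- genome_annotation(genes, exons)
  expect_equal(exon_rank(annm, "P.t1", index = 5, direction = "forward"), 1L)

  for (ann in list(annp, annm)) {
    n <- 5L
    for (i in seq_len(n)) {
      f <- exon_rank(ann, "P.t1", index = i, direction = "forward")
      b <- exon_rank(ann, "P.t1", index = i, direction = "backward")
      expect_equal(f + b, n + 1L)
    }
  }
})

test_that("position-based exon lookup honors boundaries and tolerance", {
  ann <- toy_annotation()
  # exact donor boundary of G1's first exon (end = 300)
  expect_equal(exon_rank(ann, "G1.t1", position = 300), 1L)
  # inside the second exon
  expect_equal(exon_rank(ann, "G1.t1", position = 700), 2L)
  # within default 5 bp slack: matched but flagged non-canonical
  r <- exon_rank(ann, "G1.t1", position = 304)
  expect_equal(as.integer(r), 1L)
  expect_true(isTRUE(attr(r, "non_canonical")))
  # far from any exon: no rank
  expect_true(is.na(exon_rank(ann, "G1.t1", position = 450)))
})

test_that("genome_background matches hand-computed toy distributions", {
  ann <- toy_annotation()
  bg <- genome_background(ann)
  expect_equal(bg$exon_counts, c(2L, 2L, 2L))
  expect_equal(bg$intergenic_distances, c(1000L, 2000L))
  expect_equal(sort(bg$intron_lengths), c(300L, 400L, 400L))

  # single-exon genes contribute exon_count 1 and no introns;
  # intron count = sum(exon_count - 1) over canonical transcripts
  for (seed in c(5, 6)) {
    rann <- random_annotation(30, seed = seed)
    rbg <- genome_background(rann)
    expect_equal(length(rbg$intron_lengths), sum(rbg$exon_counts - 1L))
    expect_equal(length(rbg$intergenic_distances),
                 nrow(neighbor_pairs(rann)))
  }
})

test_that("canonical transcript prefers most exons, then span, then id", {
  genes <- data.frame(gene_id = "G", symbol = "G", chrom = "chr1",
                      strand = "+", start = 0L, end = 10000L)
  exons <- rbind(
    data.frame(transcript_id = "t.b", gene_id = "G",
               start = c(0L, 500L, 1000L), end = c(100L, 600L, 1100L)),
    data.frame(transcript_id = "t.a", gene_id = "G",
               start = c(0L, 9000L), end = c(100L, 9100L)))
  ann <- genome_annotation(genes, exons)
  expect_equal(canonical_transcript(ann, "G")$transcript_id, "t.b")

  # equal exon counts: longest span wins
  exons2 <- rbind(
    data.frame(transcript_id = "t.b", gene_id = "G",
               start = c(0L, 500L), end = c(100L, 600L)),
    data.frame(transcript_id = "t.a", gene_id = "G",
               start = c(0L, 9000L), end = c(100L, 9100L)))
  ann2 <- genome_annotation(genes, exons2)
  expect_equal(canonical_transcript(ann2, "G")$transcript_id, "t.a")
})
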