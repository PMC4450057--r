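test_that("KS statistic matches brute force and is symmetric", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(c(0, 0, 0), c(1, 1, 1))$D, 1)
  set.seed(17)
  for (i in 1:20) {
    x <- sample(0:20, sample(3:12, 1), replace = TRUE)
    y <- sample(0:20, sample(3:12, 1), replace = TRUE)
    r <- ks_two_sample(x, y)
    expect_equal(r$D, brute_ks_D(x, y), tolerance = 1e-12)
    expect_equal(ks_two_sample(y, x)$D, r$D)
    # independent implementation agrees on the statistic
    expect_equal(r$D, unname(suppressWarnings(stats::ks.test(x, y))$statistic),
                 tolerance = 1e-12)
  }
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("KS asymptotic p-value matches the reference implementation", {
  set.seed(23)
  for (i in 1:10) {
    x <- rnorm(30); y <- rnorm(40, mean = runif(1, 0, 2))
    r <- ks_two_sample(x, y)
    ref <- stats::ks.test(x, y, exact = FALSE)
    # the reference truncates its series at tol 1e-6 near its regime
    # switch, so agreement is to ~1e-5, not machine precision
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-4)
  }
})

test_that("junction rank histograms conserve counts and find the 2-2 mode", {
  ann <- toy_annotation()
  calls <- data.frame(
    sample_id = "s", gene5 = "G1", gene3 = "G2", chrom5 = "chr1",
    strand5 = "+", chrom3 = "chr1", strand3 = "+",
    bp5 = 300L, bp3 = 2600L,  # donor = exon 1 (backward rank 2 of 2),
    junction_reads = 1L, spanning_reads = 0L)  # acceptor = exon 2
  calls <- calls[rep(1, 4), ]
  calls$bp3[4] <- 2000L  # one junction at the 3' gene's first exon
  ranked <- junction_exon_ranks(ann, calls)
  h3 <- exon_position_histogram(ranked, side = "3prime",
                                direction = "forward")
  expect_equal(sum(h3$counts), nrow(calls))
  expect_equal(unname(h3$counts[["2"]]), 3L)
  expect_equal(unname(h3$counts[["1"]]), 1L)
  cc <- junction_configuration_counts(ranked)
  expect_equal(cc$rank5_bwd[1], 2L)
  expect_equal(cc$rank3_fwd[1], 2L)
  expect_equal(sum(cc$count), nrow(calls))
  # unranked junctions are excluded with a warning and counted
  calls$bp3[1] <- 2400L  # intronic, beyond tolerance
  ranked2 <- junction_exon_ranks(ann, calls)
  expect_warning(h <- exon_position_histogram(ranked2, side = "3prime",
                                              direction = "forward"),
                 "without an exon rank")
  expect_equal(h$n_unranked, 1L)
  expect_equal(h$n_ranked, 3L)
})

test_that("exact exon-2 tail equals exhaustive enumeration", {
  expect_equal(exon2_usage_exact(c(2, 2), 2), 0.25)
  expect_equal(exon2_usage_exact(c(2, 2), 1), 0.75)
  expect_equal(exon2_usage_exact(c(1, 1, 1), 1), 0)  # rank 2 unreachable
  expect_equal(exon2_usage_exact(c(3, 4), 0), 1)
  set.seed(41)
  for (i in 1:5) {
    E <- sample(1:6, sample(3:8, 1), replace = TRUE)
    k <- sample(0:length(E), 1)
    expect_equal(exon2_usage_exact(E, k), enum_exon2_tail(E, k),
                 tolerance = 1e-12)
  }
  # acceptor-only null excludes exon 1 from the draw
  expect_equal(exon2_usage_exact(c(2, 2), 2, acceptor_only = TRUE), 1)
})

test_that("simulated exon-2 tail converges to the exact tail", {
  r <- exon2_usage_simulation(c(2, 2), observed_k = 2, n_sim = 10000,
                              seed = 5)
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(r$p_sim - 0.25), 3 * se)
  expect_equal(r$p_exact, 0.25)
  # reproducible under a fixed seed
  r2 <- exon2_usage_simulation(c(2, 2), observed_k = 2, n_sim = 10000,
                               seed = 5)
  expect_identical(r$p_sim, r2$p_sim)
  # k = 0 is always reached
  expect_equal(exon2_usage_simulation(c(1, 1, 1), 0, n_sim = 100,
                                      seed = 1)$p_sim, 1.0)
  expect_error(exon2_usage_simulation(c(2, 2), 3), "cannot exceed")
})

test_that("coding impact distinguishes NR, in-frame and out-of-frame", {
  # two plus-strand genes; CDS chosen so the 2-2 junction is in frame:
  # 5' gene: exons [0,100) [200,300) [400,500); CDS starts at 10
  #   junction at donor end 300 -> coding length 190; 190 mod 3 = 1
  # 3' gene: exons [1000,1100) [1200,1300) [1400,1500); CDS starts 1090
  #   acceptor start 1200 -> offset into CDS 10; 10 mod 3 = 1  => in frame
  genes <- data.frame(gene_id = c("U", "D"), symbol = c("U", "D"),
                      chrom = "chr1", strand = "+",
                      start = c(0L, 1000L), end = c(500L, 1500L))
  exons <- data.frame(
    transcript_id = rep(c("U.t1", "D.t1"), each = 3),
    gene_id = rep(c("U", "D"), each = 3),
    start = c(0L, 200L, 400L, 1000L, 1200L, 1400L),
    end = c(100L, 300L, 500L, 1100L, 1300L, 1500L))
  cds <- data.frame(transcript_id = c("U.t1", "D.t1"),
                    cds_start = c(10L, 1090L), cds_end = c(480L, 1480L))
  ann <- genome_annotation(genes, exons, cds)
  expect_equal(classify_coding_impact(ann, "U", "D", 300L, 1200L),
               "in_frame")
  # shift the 5' CDS start by one base: frames now differ
  cds2 <- transform(cds, cds_start = c(11L, 1090L))
  ann2 <- genome_annotation(genes, exons, cds2)
  expect_equal(classify_coding_impact(ann2, "U", "D", 300L, 1200L),
               "out_of_frame")
  # junction upstream of the 5' CDS start is untranslated: NR
  cds3 <- transform(cds, cds_start = c(350L, 1090L))
  ann3 <- genome_annotation(genes, exons, cds3)
  expect_equal(classify_coding_impact(ann3, "U", "D", 300L, 1200L), "NR")
  # acceptor upstream of the 3' CDS start leaves its CDS intact: NR
  cds4 <- transform(cds, cds_start = c(10L, 1250L))
  ann4 <- genome_annotation(genes, exons, cds4)
  expect_equal(classify_coding_impact(ann4, "U", "D", 300L, 1200L), "NR")
  # off-boundary junction inside the CDS is refused
  expect_error(classify_coding_impact(ann, "U", "D", 250L, 1200L),
               "non-canonical")
  # missing CDS: NR by convention, with a warning
  ann5 <- genome_annotation(genes, exons)
  expect_warning(res <- classify_coding_impact(ann5, "U", "D", 300L, 1200L),
                 "missing CDS")
  expect_equal(res, "NR")
})

test_that("coding impact is strand-consistent", {
  # the same gene pair flipped to the minus strand, mirror coordinates
  genes <- data.frame(gene_id = c("D", "U"), symbol = c("D", "U"),
                      chrom = "chr1", strand = "-",
                      start = c(0L, 1000L), end = c(500L, 1500L))
  exons <- data.frame(
    transcript_id = rep(c("D.t1", "U.t1"), each = 3),
    gene_id = rep(c("D", "U"), each = 3),
    start = c(0L, 200L, 400L, 1000L, 1200L, 1400L),
    end = c(100L, 300L, 500L, 1100L, 1300L, 1500L))
  # mirror of the in-frame plus-strand case above: 5' gene is the right one
  cds <- data.frame(transcript_id = c("U.t1", "D.t1"),
                    cds_start = c(1020L, 20L), cds_end = c(1490L, 410L))
  ann <- genome_annotation(genes, exons, cds)
  # donor boundary 1200 (the 3' edge of exon [1200,1300) on '-'):
  #   transcript coord of CDS 5' edge (1490) is 10, of the donor is 200,
  #   so coding5 = 190
  # acceptor boundary 300 (5' edge of exon [200,300) on '-'):
  #   transcript coord 100; CDS 5' edge (410) has coord 90, so offset3 = 10
  # (190 - 10) mod 3 = 0 -> in frame, mirroring the plus-strand case
  res <- classify_coding_impact(ann, "U", "D", 1200L, 300L)
  expect_equal(res, "in_frame")
})

test_that("fractionation cross-tab counts nuclear enrichment per impact", {
  rec <- data.frame(fusion_id = c("f1", "f2", "f3", "f4"),
                    nuclear_level = c(2, 1, 5, 0.5),
                    cytoplasmic_level = c(1, 1, 1, 1))
  imp <- c(f1 = "NR", f2 = "out_of_frame", f3 = "in_frame", f4 = "NR")
  s <- summarize_fractionation(rec, imp)
  expect_true(s$records$enriched[1])          # ratio 2 > 1
  expect_false(s$records$enriched[2])         # ratio exactly 1 is not
  expect_equal(sum(s$crosstab), nrow(rec))    # marginals conserve records
  expect_equal(unname(s$crosstab["NR", "TRUE"]), 1L)
  expect_warning(summarize_fractionation(
    data.frame(fusion_id = "z", nuclear_level = 1, cytoplasmic_level = 0),
    c(z = "NR")), "zero cytoplasmic")
})
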