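#' Assemble a pipeline run configuration
#'
#' Collects the file paths and stage parameters of one analysis run. Can be
#' populated from a YAML file (flat keys named as the arguments) via
#' \code{run_config_from_yaml()}.
#'
#' @param annotation path to the GTF/GFF3 annotation (required).
#' @param fusions path to the fusion-call TSV (required unless
#'   \code{criteria_matrix} is given).
#' @param cnv,peaks,coverage,fusion_expression optional evidence file paths
#'   (CNV segments, CTCF peaks, intergenic coverage, fusion expression per
#'   condition).
#' @param gene_expression optional two-column TSV (\code{gene_id},
#'   \code{fpkm}) used for candidate prediction.
#' @param sanger_flags optional two-column TSV (\code{pair_id},
#'   \code{flag}) of experimental junction confirmations.
#' @param criteria_matrix optional path to a precomputed criteria matrix;
#'   when given, the cascade runs on it directly and skips evidence
#'   assembly.
#' @param out_dir output directory (created if absent).
#' @param seed integer seed for all stochastic steps (default 1).
#' @param filter a [filter_config()].
#' @param rules a [rule_config()].
#' @return List of class \code{RunConfig}.
#' @export
run_config <- function(annotation, fusions = NULL, cnv = NULL, peaks = NULL,
                       coverage = NULL, fusion_expression = NULL,
                       gene_expression = NULL, sanger_flags = NULL,
                       criteria_matrix = NULL, out_dir = "cissage-run",
                       seed = 1L, filter = filter_config(),
                       rules = rule_config()) {
  structure(list(annotation = annotation, fusions = fusions, cnv = cnv,
                 peaks = peaks, coverage = coverage,
                 fusion_expression = fusion_expression,
                 gene_expression = gene_expression,
                 sanger_flags = sanger_flags,
                 criteria_matrix = criteria_matrix, out_dir = out_dir,
                 seed = as.integer(seed), filter = filter, rules = rules),
            class = "RunConfig")
}

#' @rdname run_config
#' @param path YAML file with flat keys named as the \code{run_config}
#'   arguments; \code{filter:} and \code{rules:} may be nested maps.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  filt <- do.call(filter_config, if (is.null(y$filter)) list() else y$filter)
  rl <- do.call(rule_config, if (is.null(y$rules)) list() else y$rules)
  y$filter <- NULL; y$rules <- NULL
  do.call(run_config, c(y, list(filter = filt, rules = rl)))
}

## short fingerprint of a config, stamped into every output header
.config_fingerprint <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

.write_stamped <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stamp, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Run the cis-SAGe discovery pipeline
#'
#' Executes the stages in order — classify fusion calls, collapse to unique
#' pairs, assemble evidence and apply the six-criteria cascade, compute
#' characterization statistics, and enumerate genome-wide candidates — and
#' writes one TSV per stage into the output directory, each stamped with the
#' configuration fingerprint and seed. Missing required inputs raise a named
#' error before any stage runs.
#'
#' @param cfg a [run_config()] (or path to a YAML file accepted by
#'   [run_config_from_yaml()]).
#' @return Invisibly, a list with the in-memory stage results:
#'   \code{calls}, \code{pairs}, \code{criteria}, \code{report},
#'   \code{background}, \code{ks_distance}, \code{exon_usage},
#'   \code{candidates}.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- run_config_from_yaml(cfg)
  stopifnot(inherits(cfg, "RunConfig"))
  inputs <- c(annotation = cfg$annotation, fusions = cfg$fusions,
              cnv = cfg$cnv, peaks = cfg$peaks, coverage = cfg$coverage,
              fusion_expression = cfg$fusion_expression,
              gene_expression = cfg$gene_expression,
              sanger_flags = cfg$sanger_flags,
              criteria_matrix = cfg$criteria_matrix)
  missing <- inputs[!is.na(inputs) & !file.exists(inputs)]
  if (length(missing))
    stop("missing input file(s): ",
         paste(names(missing), "=", missing, collapse = ", "))
  if (is.null(cfg$fusions) && is.null(cfg$criteria_matrix))
    stop("either 'fusions' or 'criteria_matrix' must be provided")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("# cissage run: config %s, seed %d",
                   .config_fingerprint(cfg), cfg$seed)
  logf <- function(...) message(sprintf(...))

  ann <- load_annotation(cfg$annotation)
  logf("annotation: %d genes", nrow(ann$genes))
  out <- list()

  if (!is.null(cfg$criteria_matrix)) {
    ## precomputed-matrix mode: cascade only
    rec <- read_criteria_matrix(cfg$criteria_matrix)
    report <- apply_criteria(rec)
    out$criteria <- rec; out$report <- report
  } else {
    calls <- read_fusion_calls(cfg$fusions)
    calls <- classify_fusions(calls, ann)
    logf("classified %d calls: %s", nrow(calls),
         paste(names(table(calls$fusion_class)),
               table(calls$fusion_class), collapse = ", "))
    .write_stamped(calls[, setdiff(names(calls), c("bp5", "bp3"))],
                   file.path(cfg$out_dir, "classified_calls.tsv"), stamp)
    out$calls <- calls

    ss <- calls[calls$fusion_class == "INTRACHR_SS_0GAP", , drop = FALSE]
    pairs <- collapse_unique_pairs(ss)
    ## fused-exon interval per pair (genomic order), from the first call
    first <- ss[!duplicated(paste(ss$gene5, ss$gene3, sep = "\r")), ]
    key <- paste0(first$gene5, "-", first$gene3)
    m <- match(pairs$pair_id, key)
    pairs$fused_exon5_end <- pmin(first$bp5, first$bp3)[m]
    pairs$fused_exon3_start <- pmax(first$bp5, first$bp3)[m]
    out$pairs <- pairs
    logf("%d unique SS-0GAP pairs enter the cascade", nrow(pairs))

    cnv <- if (!is.null(cfg$cnv)) read_track(cfg$cnv) else NULL
    peaks <- if (!is.null(cfg$peaks)) read_track(cfg$peaks) else NULL
    coverage <- if (!is.null(cfg$coverage)) read_track(cfg$coverage)
                else NULL
    expr <- if (!is.null(cfg$fusion_expression))
      read_expression(cfg$fusion_expression) else NULL
    sanger <- NULL
    if (!is.null(cfg$sanger_flags)) {
      sf <- utils::read.delim(cfg$sanger_flags, stringsAsFactors = FALSE)
      sanger <- stats::setNames(sf$flag, sf$pair_id)
    }
    rec <- build_criteria_records(pairs, ann, cnv = cnv, peaks = peaks,
                                  coverage = coverage, expr = expr,
                                  sanger = sanger, cfg = cfg$filter)
    report <- apply_criteria(rec)
    out$criteria <- rec; out$report <- report

    ## characterization on the final pair set
    ranked <- junction_exon_ranks(ann, ss)
    out$ranked <- ranked
    bg <- genome_background(ann)
    out$background <- bg
    final_calls <- ranked[paste0(ranked$gene5, "-", ranked$gene3) %in%
                            report$final_pairs, , drop = FALSE]
    if (nrow(final_calls) >= 3) {
      np <- neighbor_pairs(ann, same_strand_only = TRUE)
      d <- np$intergenic_distance[
        paste0(np$gene5, "-", np$gene3) %in% report$final_pairs]
      out$ks_distance <- ks_two_sample(d, bg$intergenic_distances)
      e3 <- vapply(unique(final_calls$gene3), function(g)
        canonical_transcript(ann, g)$n_exons, integer(1))
      obs <- sum(vapply(split(final_calls$rank3_fwd, final_calls$gene3),
                        function(r) any(r == 2), logical(1)))
      out$exon_usage <- exon2_usage_simulation(e3, obs, target_rank = 2,
                                               n_sim = 10000,
                                               seed = cfg$seed)
      logf("intergenic-distance KS p = %.3g; exon-2 usage p_sim = %.3g",
           out$ks_distance$p_value, out$exon_usage$p_sim)
    }

    if (!is.null(cfg$gene_expression)) {
      ge <- utils::read.delim(cfg$gene_expression, stringsAsFactors = FALSE)
      fpkm <- stats::setNames(ge$fpkm, ge$gene_id)
      cand <- enumerate_candidates(ann, fpkm, cfg$rules)
      out$candidates <- cand
      .write_stamped(cand, file.path(cfg$out_dir, "candidates.tsv"), stamp)
      logf("%d genome-wide candidate pairs", nrow(cand))
    }
  }

  .write_stamped(out$report$records,
                 file.path(cfg$out_dir, "criteria_report.tsv"), stamp)
  summary_lines <- c(
    stamp,
    sprintf("input_pairs\t%d", out$report$n_input),
    sprintf("after_%s\t%d", names(out$report$stage_counts),
            out$report$stage_counts),
    sprintf("final_pairs\t%s", paste(out$report$final_pairs,
                                     collapse = ",")))
  writeLines(summary_lines, file.path(cfg$out_dir, "cascade_summary.tsv"))
  logf("cascade survivors: %s -> final %d",
       paste(out$report$stage_counts, collapse = "/"),
       length(out$report$final_pairs))
  invisible(out)
}
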