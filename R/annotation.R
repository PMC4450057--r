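#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols
#' @importFrom BiocGenerics start end strand
NULL

## Internal coordinate convention: 0-based half-open [start, end), like BED.
## GTF/GFF3 input and output are 1-based inclusive; conversion happens only at
## the file boundary.

#' Construct a genome annotation from gene and exon tables
#'
#' Builds the in-memory annotation object used throughout the package: a set
#' of gene models, each with one or more transcripts made of non-overlapping
#' exons, plus a per-gene interval index for overlap queries. One transcript
#' per gene is marked canonical: the transcript with the most exons, ties
#' broken by longest genomic span, then by lexicographically smallest id.
#'
#' @param genes data.frame with columns \code{gene_id}, \code{symbol},
#'   \code{chrom}, \code{strand} (\code{"+"} or \code{"-"}), \code{start},
#'   \code{end}. Coordinates are 0-based half-open.
#' @param exons data.frame with columns \code{transcript_id}, \code{gene_id},
#'   \code{start}, \code{end} (0-based half-open). Chromosome and strand are
#'   inherited from the owning gene.
#' @param cds optional data.frame with columns \code{transcript_id},
#'   \code{cds_start}, \code{cds_end} (0-based half-open genomic span of the
#'   coding region).
#' @return An object of class \code{GenomeAnnotation}: a list with elements
#'   \code{genes}, \code{transcripts}, \code{exons} (data.frames, coordinates
#'   0-based half-open, genes sorted by chromosome then start) and
#'   \code{gene_ranges} (a \code{GRanges} parallel to \code{genes}).
#' @export
genome_annotation <- function(genes, exons, cds = NULL) {
  need <- c("gene_id", "symbol", "chrom", "strand", "start", "end")
  if (!all(need %in% names(genes)))
    stop("genes table must have columns: ", paste(need, collapse = ", "))
  need_e <- c("transcript_id", "gene_id", "start", "end")
  if (!all(need_e %in% names(exons)))
    stop("exons table must have columns: ", paste(need_e, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene_id in genes table")
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (any(genes$start >= genes$end))
    stop("gene span must satisfy start < end")
  if (any(exons$start >= exons$end))
    stop("exon must satisfy start < end")
  if (!all(exons$gene_id %in% genes$gene_id))
    stop("exon references unknown gene_id")

  genes <- genes[order(genes$chrom, genes$start, genes$end, genes$gene_id), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)

  gmap <- match(exons$gene_id, genes$gene_id)
  exons$chrom <- genes$chrom[gmap]
  exons$strand <- genes$strand[gmap]
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  exons <- exons[, c("transcript_id", "gene_id", "chrom", "strand",
                     "start", "end")]

  ## transcript-level validation: exons non-overlapping once sorted
  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (idx in by_tx) {
    s <- exons$start[idx]; e <- exons$end[idx]
    if (length(idx) > 1 && any(s[-1] < e[-length(e)]))
      stop("overlapping exons in transcript ", exons$transcript_id[idx[1]])
    g <- unique(exons$gene_id[idx])
    if (length(g) != 1)
      stop("transcript ", exons$transcript_id[idx[1]],
           " assigned to multiple genes")
  }

  tx_ids <- names(by_tx)
  transcripts <- data.frame(
    transcript_id = tx_ids,
    gene_id = vapply(by_tx, function(i) exons$gene_id[i[1]], character(1)),
    start = vapply(by_tx, function(i) min(exons$start[i]), integer(1)),
    end = vapply(by_tx, function(i) max(exons$end[i]), integer(1)),
    n_exons = lengths(by_tx),
    stringsAsFactors = FALSE
  )
  transcripts$cds_start <- NA_integer_
  transcripts$cds_end <- NA_integer_
  if (!is.null(cds) && nrow(cds) > 0) {
    m <- match(transcripts$transcript_id, cds$transcript_id)
    transcripts$cds_start <- as.integer(cds$cds_start[m])
    transcripts$cds_end <- as.integer(cds$cds_end[m])
    bad <- !is.na(transcripts$cds_start) &
      (transcripts$cds_start < transcripts$start |
         transcripts$cds_end > transcripts$end |
         transcripts$cds_start >= transcripts$cds_end)
    if (any(bad))
      stop("CDS outside transcript span for: ",
           paste(transcripts$transcript_id[bad], collapse = ", "))
  }

  ## exons must lie within the declared gene span
  gspan <- genes[match(exons$gene_id, genes$gene_id), c("start", "end")]
  out <- exons$start < gspan$start | exons$end > gspan$end
  if (any(out))
    stop("exon outside declared gene span in gene(s): ",
         paste(unique(exons$gene_id[out]), collapse = ", "))

  ## canonical transcript: most exons, then longest span, then smallest id
  transcripts <- transcripts[order(transcripts$gene_id,
                                   -transcripts$n_exons,
                                   -(transcripts$end - transcripts$start),
                                   transcripts$transcript_id), , drop = FALSE]
  transcripts$canonical <- !duplicated(transcripts$gene_id)
  transcripts <- transcripts[order(transcripts$transcript_id), , drop = FALSE]
  rownames(transcripts) <- NULL

  if (!all(genes$gene_id %in% transcripts$gene_id))
    stop("gene(s) without any transcript/exon records: ",
         paste(setdiff(genes$gene_id, transcripts$gene_id), collapse = ", "))

  ann <- structure(
    list(genes = genes, transcripts = transcripts, exons = exons,
         gene_ranges = GRanges(genes$chrom,
                               IRanges(genes$start + 1L, genes$end),
                               strand = genes$strand)),
    class = "GenomeAnnotation")
  ann
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat("GenomeAnnotation:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts,",
      nrow(x$exons), "exons on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Load a gene annotation from a GTF or GFF3 file
#'
#' Reads exon (and optional CDS and gene) features and assembles a
#' \code{GenomeAnnotation}. Features must carry \code{gene_id} and
#' \code{transcript_id} attributes (\code{gene_name} is used as the symbol
#' when present). File coordinates are 1-based inclusive and are converted to
#' the internal 0-based half-open representation.
#'
#' @param path path to a \code{.gtf}, \code{.gff} or \code{.gff3} file.
#' @return A \code{GenomeAnnotation}.
#' @seealso [write_annotation()] for the inverse operation.
#' @export
load_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  .check_gxf_lines(path)
  fmt <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "gtf"
  gr <- tryCatch(rtracklayer::import(path, format = fmt),
                 error = function(e) stop("failed to parse ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$type)) stop("no feature type column in ", path)
  type <- as.character(mc$type)

  ex <- gr[type == "exon"]
  if (length(ex) == 0) stop("no exon features in ", path)
  exm <- S4Vectors::mcols(ex)
  if (is.null(exm$gene_id) || is.null(exm$transcript_id))
    stop("exon features must carry gene_id and transcript_id attributes")
  exons <- data.frame(
    transcript_id = as.character(exm$transcript_id),
    gene_id = as.character(exm$gene_id),
    start = BiocGenerics::start(ex) - 1L,
    end = BiocGenerics::end(ex),
    stringsAsFactors = FALSE)
  ex_chrom <- as.character(GenomicRanges::seqnames(ex))
  ex_strand <- as.character(BiocGenerics::strand(ex))
  if (!all(ex_strand %in% c("+", "-")))
    stop("every exon must have an explicit strand '+' or '-'")

  ## gene table: from explicit gene features when present, else from exons
  gn <- gr[type == "gene"]
  if (length(gn) > 0) {
    gm <- S4Vectors::mcols(gn)
    genes <- data.frame(
      gene_id = as.character(gm$gene_id),
      symbol = if (!is.null(gm$gene_name)) as.character(gm$gene_name)
               else as.character(gm$gene_id),
      chrom = as.character(GenomicRanges::seqnames(gn)),
      strand = as.character(BiocGenerics::strand(gn)),
      start = BiocGenerics::start(gn) - 1L,
      end = BiocGenerics::end(gn),
      stringsAsFactors = FALSE)
    missing <- setdiff(unique(exons$gene_id), genes$gene_id)
    if (length(missing))
      stop("exons reference gene_id(s) without gene feature: ",
           paste(missing, collapse = ", "))
  } else {
    first <- !duplicated(exons$gene_id)
    genes <- data.frame(
      gene_id = exons$gene_id[first],
      symbol = if (!is.null(exm$gene_name))
        as.character(exm$gene_name)[first] else exons$gene_id[first],
      chrom = ex_chrom[first],
      strand = ex_strand[first],
      stringsAsFactors = FALSE)
    genes$start <- vapply(split(exons$start, exons$gene_id)[genes$gene_id],
                          min, integer(1))
    genes$end <- vapply(split(exons$end, exons$gene_id)[genes$gene_id],
                        max, integer(1))
  }

  cds_gr <- gr[type == "CDS"]
  cds <- NULL
  if (length(cds_gr) > 0) {
    cm <- S4Vectors::mcols(cds_gr)
    cd <- data.frame(transcript_id = as.character(cm$transcript_id),
                     s = BiocGenerics::start(cds_gr) - 1L,
                     e = BiocGenerics::end(cds_gr))
    cds <- do.call(rbind, lapply(split(cd, cd$transcript_id), function(d)
      data.frame(transcript_id = d$transcript_id[1],
                 cds_start = min(d$s), cds_end = max(d$e))))
  }
  genome_annotation(genes, exons, cds)
}

## cheap structural pre-scan so malformed files fail with a line number
.check_gxf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^(#|\\s*$)", lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 8)) {
    bad <- which(body)[which(nf < 8)[1]]
    stop("malformed annotation line ", bad, " in ", path,
         " (fewer than 8 tab-separated fields)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write an annotation to GTF
#'
#' Emits gene, transcript, exon and (where known) CDS features with
#' \code{gene_id}, \code{transcript_id} and \code{gene_name} attributes, in
#' 1-based inclusive GTF coordinates. \code{load_annotation} of the written
#' file reconstructs an identical object.
#'
#' @param ann a \code{GenomeAnnotation}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "GenomeAnnotation"))
  g <- ann$genes; tx <- ann$transcripts; ex <- ann$exons
  attr_gene <- function(gid) {
    sym <- g$symbol[match(gid, g$gene_id)]
    sprintf('gene_id "%s"; gene_name "%s";', gid, sym)
  }
  attr_tx <- function(gid, tid) {
    sym <- g$symbol[match(gid, g$gene_id)]
    sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
            gid, tid, sym)
  }
  rows <- character(0)
  fmt <- function(chrom, feat, s0, e0, strand, attrs)
    sprintf("%s\tcissage\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, feat, s0 + 1L, e0, strand, attrs)
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    rows <- c(rows, fmt(g$chrom[i], "gene", g$start[i], g$end[i],
                        g$strand[i], attr_gene(gid)))
    txi <- tx[tx$gene_id == gid, , drop = FALSE]
    txi <- txi[order(txi$transcript_id), , drop = FALSE]
    for (j in seq_len(nrow(txi))) {
      tid <- txi$transcript_id[j]
      rows <- c(rows, fmt(g$chrom[i], "transcript", txi$start[j], txi$end[j],
                          g$strand[i], attr_tx(gid, tid)))
      exj <- ex[ex$transcript_id == tid, , drop = FALSE]
      rows <- c(rows, fmt(exj$chrom, "exon", exj$start, exj$end, exj$strand,
                          attr_tx(gid, tid)))
      if (!is.na(txi$cds_start[j]))
        rows <- c(rows, fmt(g$chrom[i], "CDS", txi$cds_start[j],
                            txi$cds_end[j], g$strand[i], attr_tx(gid, tid)))
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' Canonical transcript of a gene
#'
#' @param ann a \code{GenomeAnnotation}.
#' @param gene_id gene identifier.
#' @return One-row data.frame from \code{ann$transcripts}.
#' @export
canonical_transcript <- function(ann, gene_id) {
  tx <- ann$transcripts
  hit <- tx[tx$gene_id == gene_id & tx$canonical, , drop = FALSE]
  if (nrow(hit) == 0) stop("unknown gene_id: ", gene_id)
  hit
}

#' Exons of a transcript in genomic order
#' @param ann a \code{GenomeAnnotation}.
#' @param transcript_id transcript identifier.
#' @return data.frame of exons sorted by start.
#' @export
transcript_exons <- function(ann, transcript_id) {
  ex <- ann$exons[ann$exons$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(ex) == 0) stop("unknown transcript_id: ", transcript_id)
  ex[order(ex$start), , drop = FALSE]
}

#' Same-strand immediate neighbor gene pairs
#'
#' Enumerates immediate neighboring gene pairs per chromosome with
#' strand-aware 5'/3' assignment: on \code{+} the leftmost gene of a pair is
#' the transcriptionally upstream (5') gene, on \code{-} the rightmost. With
#' \code{same_strand_only = TRUE} (the cis-SAGe setting) genes are paired with
#' their nearest same-strand neighbor; a pair is emitted only when no other
#' gene, on either strand, overlaps the open intergenic interval between
#' them. Overlapping neighbors are kept with distance 0. Each gene appears as
#' gene5 in at most one emitted pair and as gene3 in at most one.
#'
#' @param ann a \code{GenomeAnnotation}.
#' @param same_strand_only pair only genes on the same strand (default TRUE).
#' @param max_distance keep pairs with intergenic distance less than or equal
#'   to this many bp (default \code{Inf}).
#' @return data.frame with columns \code{gene5}, \code{gene3}, \code{chrom},
#'   \code{strand5}, \code{strand3}, \code{same_strand},
#'   \code{intergenic_distance} (bp, \code{max(0, start3 - end5)} in genomic
#'   coordinates).
#' @export
neighbor_pairs <- function(ann, same_strand_only = TRUE, max_distance = Inf) {
  g <- ann$genes
  out <- list()
  for (chrom in unique(g$chrom)) {
    gc <- g[g$chrom == chrom, , drop = FALSE]
    groups <- if (same_strand_only) split(gc, gc$strand) else list(all = gc)
    for (gs in groups) {
      if (nrow(gs) < 2) next
      gs <- gs[order(gs$start, gs$end, gs$gene_id), , drop = FALSE]
      for (i in seq_len(nrow(gs) - 1)) {
        left <- gs[i, ]; right <- gs[i + 1, ]
        gap_s <- left$end; gap_e <- right$start
        if (gap_s < gap_e) {
          ## any gene (either strand) intruding into the open gap?
          others <- g[g$chrom == chrom &
                        !(g$gene_id %in% c(left$gene_id, right$gene_id)), ,
                      drop = FALSE]
          if (any(others$start < gap_e & others$end > gap_s)) next
        }
        d <- max(0L, right$start - left$end)
        if (d > max_distance) next
        same <- left$strand == right$strand
        if (same && left$strand == "-") { g5 <- right; g3 <- left }
        else { g5 <- left; g3 <- right }
        out[[length(out) + 1L]] <- data.frame(
          gene5 = g5$gene_id, gene3 = g3$gene_id, chrom = chrom,
          strand5 = g5$strand, strand3 = g3$strand,
          same_strand = same, intergenic_distance = d,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(gene5 = character(0), gene3 = character(0),
                      chrom = character(0), strand5 = character(0),
                      strand3 = character(0), same_strand = logical(0),
                      intergenic_distance = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom,
                   pmin(ann$genes$start[match(res$gene5, ann$genes$gene_id)],
                        ann$genes$start[match(res$gene3, ann$genes$gene_id)])), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Genes lying between two genes on one chromosome
#'
#' Returns ids of all other genes (either strand) whose span overlaps the
#' open intergenic interval between the two genes by at least 1 bp. Genes
#' overlapping only the pair's own spans do not count. If the two genes
#' overlap each other the gap is empty and no gene can intervene.
#'
#' @param ann a \code{GenomeAnnotation}.
#' @param gene5_id,gene3_id gene identifiers (order irrelevant; the gap is
#'   taken between the genomically left gene's end and the right gene's
#'   start).
#' @return Character vector of intervening gene ids (possibly empty).
#' @export
intervening_genes <- function(ann, gene5_id, gene3_id) {
  g <- ann$genes
  a <- g[g$gene_id == gene5_id, , drop = FALSE]
  b <- g[g$gene_id == gene3_id, , drop = FALSE]
  if (nrow(a) == 0) stop("unknown gene_id: ", gene5_id)
  if (nrow(b) == 0) stop("unknown gene_id: ", gene3_id)
  if (a$chrom != b$chrom)
    stop("genes ", gene5_id, " and ", gene3_id,
         " are on different chromosomes")
  if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
  gap_s <- a$end; gap_e <- b$start
  if (gap_s >= gap_e) return(character(0))
  others <- g[g$chrom == a$chrom &
                !(g$gene_id %in% c(gene5_id, gene3_id)), , drop = FALSE]
  others$gene_id[others$start < gap_e & others$end > gap_s]
}

#' Exon rank within a transcript
#'
#' Ranks exons in transcription order. Forward rank 1 is the transcript's
#' 5'-most exon (the genomically last exon for a minus-strand transcript);
#' backward rank 1 is the 3'-most exon, so forward + backward = exon count +
#' 1 always. The exon may be addressed by genomic-order index or by a genomic
#' position: a position inside an exon, or within \code{tol} bp of an exon
#' boundary, maps to that exon. A position matched only through the tolerance
#' (not an exact boundary and not inside the exon) is flagged as a
#' non-canonical junction via the \code{"non_canonical"} attribute.
#'
#' @param ann a \code{GenomeAnnotation}.
#' @param transcript_id transcript identifier.
#' @param position genomic position (0-based boundary coordinate), or NULL.
#' @param index 1-based index in genomic order, or NULL. Exactly one of
#'   \code{position}/\code{index} must be given.
#' @param direction \code{"forward"} (from the 5' end) or \code{"backward"}
#'   (from the 3' end).
#' @param tol boundary matching tolerance in bp (default 5).
#' @return Integer rank, or \code{NA} if the position maps to no exon.
#' @export
exon_rank <- function(ann, transcript_id, position = NULL, index = NULL,
                      direction = c("forward", "backward"), tol = 5L) {
  direction <- match.arg(direction)
  ex <- transcript_exons(ann, transcript_id)
  n <- nrow(ex)
  if (is.null(index) == is.null(position))
    stop("give exactly one of 'position' or 'index'")
  non_canonical <- FALSE
  if (!is.null(index)) {
    if (index < 1 || index > n) stop("exon index out of range")
    gi <- as.integer(index)
  } else {
    inside <- which(ex$start <= position & position < ex$end)
    exact <- which(ex$start == position | ex$end == position)
    if (length(exact)) {
      gi <- exact[1]
    } else if (length(inside)) {
      gi <- inside[1]
    } else {
      d <- pmin(abs(ex$start - position), abs(ex$end - position))
      if (min(d) <= tol) { gi <- which.min(d); non_canonical <- TRUE }
      else return(NA_integer_)
    }
  }
  fwd <- if (ex$strand[1] == "+") gi else n - gi + 1L
  r <- if (direction == "forward") fwd else n - fwd + 1L
  r <- as.integer(r)
  if (non_canonical) attr(r, "non_canonical") <- TRUE
  r
}

## transcript-coordinate (bp offset from the transcript 5' end) of a genomic
## boundary position; used by the coding-impact classifier
genomic_to_transcript <- function(ann, transcript_id, gpos) {
  ex <- transcript_exons(ann, transcript_id)
  if (ex$strand[1] == "+") {
    sum(pmax(0L, pmin(gpos, ex$end) - ex$start))
  } else {
    sum(pmax(0L, ex$end - pmax(gpos, ex$start)))
  }
}

#' Genome-wide background distributions
#'
#' Computes the background distributions the cis-SAGe characterization
#' compares against: the number of exons per gene (canonical transcripts),
#' intergenic distances of same-strand immediate neighbor pairs, and all
#' intron lengths of canonical transcripts.
#'
#' @param ann a \code{GenomeAnnotation}.
#' @return List with numeric vectors \code{exon_counts},
#'   \code{intergenic_distances} and \code{intron_lengths}.
#' @export
genome_background <- function(ann) {
  tx <- ann$transcripts[ann$transcripts$canonical, , drop = FALSE]
  exon_counts <- tx$n_exons[match(ann$genes$gene_id, tx$gene_id)]
  introns <- unlist(lapply(tx$transcript_id, function(tid) {
    ex <- transcript_exons(ann, tid)
    if (nrow(ex) < 2) return(integer(0))
    ex$start[-1] - ex$end[-nrow(ex)]
  }), use.names = FALSE)
  np <- neighbor_pairs(ann, same_strand_only = TRUE)
  list(exon_counts = as.integer(exon_counts),
       intergenic_distances = as.integer(np$intergenic_distance),
       intron_lengths = as.integer(introns))
}
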