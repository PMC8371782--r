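#' Read a gene annotation into a gene model table
#'
#' Parses a GTF (ensembl-style, `gene_id "X";` attributes) or BED6 file into
#' a table of gene models.  Coordinates are converted to the 0-based
#' half-open convention used throughout the package (matching BED and
#' bigWig), regardless of the input dialect.  For GTF input the exon length
#' of a gene is the length of the union of all of its exon intervals over
#' all transcripts; for BED input it is simply `end - start`.
#'
#' @param path Path to a GTF or BED file (optionally gzipped).
#' @param dialect One of `"gtf"` or `"bed"`; `"auto"` guesses from the file
#'   extension.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start` (0-based,
#'   inclusive), `end` (exclusive), `strand` (`"+"`/`"-"`) and `exon_length`
#'   (bp), one row per gene.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(c(
#'   'chr1\tsrc\tgene\t101\t300\t.\t+\t.\tgene_id "g1";',
#'   'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1";',
#'   'chr1\tsrc\texon\t151\t300\t.\t+\t.\tgene_id "g1";'), gtf)
#' read_gene_annotation(gtf)
#' @export
read_gene_annotation <- function(path, dialect = c("auto", "gtf", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("annotation file not found: ", path)
  }
  if (dialect == "auto") {
    base <- sub("\\.gz$", "", path)
    dialect <- if (grepl("\\.bed$", base, ignore.case = TRUE)) "bed" else "gtf"
  }
  genes <- switch(dialect,
    gtf = .read_gtf_genes(path),
    bed = .read_bed_genes(path)
  )
  dup <- duplicated(genes$gene_id)
  if (any(dup)) {
    stop("duplicate gene_id in annotation: ",
         paste(unique(genes$gene_id[dup]), collapse = ", "))
  }
  if (any(genes$start >= genes$end)) {
    bad <- genes$gene_id[genes$start >= genes$end][1]
    stop("gene with non-positive span: ", bad)
  }
  rownames(genes) <- NULL
  genes
}

.read_gtf_genes <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("failed to parse GTF '", path, "': ",
                             conditionMessage(e))
  )
  if (is.null(gr$gene_id)) stop("GTF lacks gene_id attributes: ", path)
  type <- as.character(gr$type)
  exons <- gr[type == "exon"]
  if (length(exons) == 0L) {
    # fall back to gene features alone: treat the whole span as one exon
    exons <- gr[type == "gene"]
  }
  if (length(exons) == 0L) {
    stop("GTF has neither exon nor gene features: ", path)
  }
  red <- GenomicRanges::reduce(
    S4Vectors::split(exons, factor(exons$gene_id, levels = unique(exons$gene_id)))
  )
  exon_len <- vapply(IRanges::width(red), sum, numeric(1))

  span_src <- gr[type == "gene"]
  if (length(span_src) == 0L) span_src <- exons
  spans <- range(S4Vectors::split(
    span_src, factor(span_src$gene_id, levels = unique(span_src$gene_id))))
  spans <- unlist(spans)
  strand <- as.character(GenomicRanges::strand(spans))
  if (any(strand == "*")) {
    stop("missing strand for gene(s): ",
         paste(utils::head(names(spans)[strand == "*"], 5), collapse = ", "))
  }
  ids <- names(spans)
  data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(spans)),
    start = GenomicRanges::start(spans) - 1L,  # GTF 1-based -> 0-based
    end = GenomicRanges::end(spans),
    strand = strand,
    exon_length = as.integer(exon_len[ids]),
    stringsAsFactors = FALSE
  )
}

.read_bed_genes <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) stop("failed to parse BED '", path, "': ",
                             conditionMessage(e))
  )
  if (is.null(gr$name)) stop("BED file needs >= 6 columns (name, strand): ", path)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    stop("missing strand in BED for: ",
         paste(utils::head(gr$name[strand == "*"], 5), collapse = ", "))
  }
  data.frame(
    gene_id = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand,
    exon_length = GenomicRanges::width(gr),
    stringsAsFactors = FALSE
  )
}

#' Write gene models to a BED6 file
#'
#' @param models Gene model `data.frame` as returned by
#'   [read_gene_annotation()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(models, path) {
  ord <- order(models$chrom, models$start)
  m <- models[ord, , drop = FALSE]
  lines <- paste(m$chrom, m$start, m$end, m$gene_id, 0L, m$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
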