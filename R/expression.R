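#' Read a gene expression matrix
#'
#' Reads a TSV with gene ids in the first column and one numeric column per
#' sample.  Rows containing any missing value are dropped with a message
#' reporting the count.
#'
#' @param path Path to a tab-separated file with a header row (optionally
#'   gzipped).
#' @param units Expression units of the values: one of `"CPM"`, `"FPKM"`,
#'   `"TPM"` or `"MICROARRAY"` (unlogged microarray intensities).
#' @return An `ExpressionTable`: a list with `values` (genes x samples
#'   numeric matrix, rownames = gene ids), `gene_ids`, `sample_ids` and
#'   `units`.
#' @export
read_expression <- function(path, units = c("CPM", "FPKM", "TPM", "MICROARRAY")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 3L) {
    stop("expression table needs a gene-id column plus >= 2 sample columns")
  }
  gene_ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  keep <- stats::complete.cases(vals)
  if (any(!keep)) {
    message(sum(!keep), " row(s) with missing values dropped")
    vals <- vals[keep, , drop = FALSE]
    gene_ids <- gene_ids[keep]
  }
  expression_table(vals, gene_ids = gene_ids, units = units)
}

#' Construct an ExpressionTable
#'
#' @param values Genes x samples numeric matrix of non-negative expression
#'   values.
#' @param gene_ids Gene identifiers (defaults to `rownames(values)`).
#' @param sample_ids Sample identifiers (defaults to `colnames(values)`).
#' @param units One of `"CPM"`, `"FPKM"`, `"TPM"`, `"MICROARRAY"`.
#' @return An object of class `ExpressionTable`.
#' @export
expression_table <- function(values, gene_ids = rownames(values),
                             sample_ids = colnames(values),
                             units = c("CPM", "FPKM", "TPM", "MICROARRAY")) {
  units <- match.arg(units)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) stop("gene_ids required")
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) stop("gene_ids length mismatch")
  if (length(sample_ids) != ncol(values)) stop("sample_ids length mismatch")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in expression table")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in expression table")
  if (ncol(values) < 2L) stop("expression table needs at least 2 samples")
  if (any(values < 0)) stop("negative expression values are not allowed")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         units = units),
    class = "ExpressionTable"
  )
}

#' @export
print.ExpressionTable <- function(x, ...) {
  cat("ExpressionTable:", length(x$gene_ids), "genes x",
      length(x$sample_ids), "samples,", x$units, "units\n")
  invisible(x)
}

#' Rescale length-normalized expression units to CPM-proportional values
#'
#' FPKM and TPM are read counts normalized by gene length; multiplying each
#' gene's values by its exon length in kilobases undoes that division and
#' yields values proportional, within each sample, to counts per million.
#' CPM and microarray tables are returned unchanged.  Downstream selection
#' of constant genes only uses per-gene cross-sample statistics and
#' within-sample rankings, so per-sample proportionality suffices.
#'
#' @param table An `ExpressionTable`.
#' @param models Gene model table (see [read_gene_annotation()]) supplying
#'   `exon_length`; table genes absent from it are dropped with a warning.
#' @return An `ExpressionTable` with units `"CPM"` (or the input unchanged
#'   for CPM/MICROARRAY units).
#' @export
to_cpm_like <- function(table, models) {
  stopifnot(inherits(table, "ExpressionTable"))
  if (table$units %in% c("CPM", "MICROARRAY")) {
    return(table)
  }
  idx <- match(table$gene_ids, models$gene_id)
  missing <- is.na(idx)
  if (any(missing)) {
    warning(sum(missing), " gene(s) absent from annotation dropped during ",
            "CPM conversion")
  }
  keep <- which(!missing)
  if (length(keep) == 0L) stop("no expression genes found in annotation")
  len <- models$exon_length[idx[keep]]
  if (any(len == 0)) {
    stop("gene(s) with exon_length 0: ",
         paste(utils::head(table$gene_ids[keep][len == 0], 5), collapse = ", "))
  }
  vals <- table$values[keep, , drop = FALSE] * (len / 1000)
  expression_table(vals, gene_ids = table$gene_ids[keep],
                   sample_ids = table$sample_ids, units = "CPM")
}
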