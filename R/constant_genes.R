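#' Select transcriptionally constant genes
#'
#' Identifies the genes whose expression varies least across samples within
#' each expression stratum; these anchor the normalization.  Genes are
#' ranked by mean expression, partitioned into `n_bins` contiguous
#' equal-size groups, and within each group the fraction `percent`/100 of
#' genes with the smallest cross-sample standard deviation is kept (at
#' least one gene per group, via ceiling).  Selecting per stratum rather
#' than globally ensures that every range of expression, including silent
#' genes, is represented in the anchor set.
#'
#' Ties in mean expression and in standard deviation are broken by gene id
#' (lexicographic), so the selection is fully deterministic.  When the gene
#' count is not divisible by `n_bins`, the remainder genes are assigned to
#' the lowest-expression bins (one extra gene each).
#'
#' @param table An `ExpressionTable` in CPM or unlogged microarray units
#'   (convert FPKM/TPM first with [to_cpm_like()]).
#' @param n_bins Number of expression strata (default 100).
#' @param percent Percentage of genes kept per stratum (default 10).
#' @return A `ConstantGeneSet`: list with `gene_ids` (selected genes) and
#'   `params`.
#' @export
select_constant_genes <- function(table, n_bins = 100L, percent = 10) {
  stopifnot(inherits(table, "ExpressionTable"))
  if (!table$units %in% c("CPM", "MICROARRAY")) {
    stop("expression must be in CPM or MICROARRAY units; convert FPKM/TPM ",
         "with to_cpm_like() first")
  }
  if (percent <= 0 || percent > 100) stop("percent must be in (0, 100]")
  n_bins <- as.integer(n_bins)
  n <- nrow(table$values)
  if (n < n_bins) {
    stop("only ", n, " genes but ", n_bins,
         " expression bins requested; reduce n_bins")
  }
  mu <- rowMeans(table$values)
  sdev <- apply(table$values, 1L, stats::sd)
  ids <- table$gene_ids

  ord <- order(mu, ids)            # ascending mean, ties by gene id
  bin_sizes <- rep(n %/% n_bins, n_bins)
  rem <- n %% n_bins
  if (rem > 0) bin_sizes[seq_len(rem)] <- bin_sizes[seq_len(rem)] + 1L
  bin_of <- rep(seq_len(n_bins), times = bin_sizes)

  selected <- character(0)
  for (b in seq_len(n_bins)) {
    members <- ord[bin_of == b]
    k <- ceiling(percent / 100 * length(members))
    pick <- members[order(sdev[members], ids[members])][seq_len(k)]
    selected <- c(selected, ids[pick])
  }
  structure(
    list(gene_ids = selected,
         params = list(n_expression_bins = n_bins, percent = percent)),
    class = "ConstantGeneSet"
  )
}

#' @export
print.ConstantGeneSet <- function(x, ...) {
  cat("ConstantGeneSet:", length(x$gene_ids), "genes (",
      x$params$percent, "% per bin,", x$params$n_expression_bins, "bins )\n")
  invisible(x)
}

#' Write the constant-gene set as a BED6 file
#'
#' @param genes A `ConstantGeneSet`.
#' @param models Gene model table supplying coordinates; selected genes
#'   missing from it are dropped with a warning.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_constant_bed <- function(genes, models, path) {
  stopifnot(inherits(genes, "ConstantGeneSet"))
  idx <- match(genes$gene_ids, models$gene_id)
  if (any(is.na(idx))) {
    warning(sum(is.na(idx)), " selected gene(s) missing from annotation ",
            "dropped from BED output")
    idx <- idx[!is.na(idx)]
  }
  write_gene_bed(models[idx, , drop = FALSE], path)
}
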