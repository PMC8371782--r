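#' Stratify genes into low/medium/high expression groups
#'
#' One-dimensional k-means (k = 3) on log1p-transformed expression of one
#' sample; clusters are relabeled low/medium/high by ascending center.
#' The log transform keeps a handful of very highly expressed genes from
#' dominating the clustering; pass `log_transform = FALSE` to cluster on
#' raw values.  With a fixed seed the assignment is deterministic
#' (multiple random restarts, best within-cluster sum of squares kept).
#'
#' @param table An `ExpressionTable`.
#' @param sample_id Sample whose expression is clustered, or `"mean"` for
#'   the across-sample mean.
#' @param seed Random seed for the k-means restarts (default 42).
#' @param log_transform Cluster on `log1p(x)` (default `TRUE`).
#' @param nstart Number of k-means restarts (default 10).
#' @return An `ExpressionStrata`: list with `assignment` (named factor,
#'   gene id -> low/medium/high) and `centers` (3 ascending values on the
#'   clustering scale).
#' @export
stratify_expression <- function(table, sample_id = "mean", seed = 42L,
                                log_transform = TRUE, nstart = 10L) {
  stopifnot(inherits(table, "ExpressionTable"))
  x <- if (identical(sample_id, "mean")) {
    rowMeans(table$values)
  } else {
    if (!sample_id %in% table$sample_ids) {
      stop("sample '", sample_id, "' not in expression table")
    }
    table$values[, sample_id]
  }
  if (log_transform) x <- log1p(x)
  ux <- sort(unique(x))
  if (length(ux) < 3L) {
    stop("need at least 3 distinct expression values to form strata")
  }
  labels <- c("low", "medium", "high")
  if (length(ux) == 3L) {
    # each distinct value is its own stratum; k-means needs k < n
    cluster <- match(x, ux)
    centers <- ux
  } else {
    set.seed(seed)
    km <- stats::kmeans(x, centers = 3L, nstart = nstart)
    ord <- order(km$centers[, 1L])
    relabel <- integer(3L)
    relabel[ord] <- 1:3
    cluster <- relabel[km$cluster]
    centers <- sort(km$centers[, 1L])
  }
  assignment <- factor(labels[cluster], levels = labels)
  names(assignment) <- table$gene_ids
  structure(
    list(assignment = assignment, centers = centers,
         sample_id = sample_id, log_transform = log_transform),
    class = "ExpressionStrata"
  )
}

#' @export
print.ExpressionStrata <- function(x, ...) {
  cat("ExpressionStrata:",
      paste(sprintf("%s=%d", levels(x$assignment),
                    as.integer(table(x$assignment))), collapse = ", "),
      "\n")
  invisible(x)
}

#' TSS profiles per expression stratum (antibody-specificity diagnostic)
#'
#' Computes the mean TSS-centered signal profile separately for low-,
#' medium- and high-expressed genes and overlays the three curves.  For a
#' specific antibody against an activating mark the curves are expected to
#' be ordered high > medium > low around the TSS; an inverted or flat
#' ordering flags unspecific binding or a repressive mark.
#'
#' @param track A `SignalTrack` or bigWig path.
#' @param strata An `ExpressionStrata` from [stratify_expression()].
#' @param models Gene model table.
#' @param half_window Half-width of the TSS window in bp (default 4000).
#' @param bin_size Bin width in bp (default 10).
#' @param out_prefix Optional path prefix; if given, `<prefix>.svg` and
#'   `<prefix>.png` are written.
#' @return Named list of three profiles (`low`, `medium`, `high`), with
#'   attribute `n_genes` (genes per stratum used).
#' @export
profile_by_stratum <- function(track, strata, models, half_window = 4000L,
                               bin_size = 10L, out_prefix = NULL) {
  stopifnot(inherits(strata, "ExpressionStrata"))
  if (is.character(track)) track <- signal_track(track)
  profiles <- list()
  n_genes <- integer(0)
  for (lev in levels(strata$assignment)) {
    ids <- names(strata$assignment)[strata$assignment == lev]
    sub <- models[models$gene_id %in% ids, , drop = FALSE]
    if (nrow(sub) == 0L) {
      stop("stratum '", lev, "' has no genes in the annotation; missing: ",
           paste(utils::head(setdiff(ids, models$gene_id), 5),
                 collapse = ", "))
    }
    profiles[[lev]] <- tss_mean_profile(track, sub, half_window, bin_size)
    n_genes[lev] <- nrow(sub)
  }
  if (!is.null(out_prefix)) {
    nbin <- length(profiles[[1L]])
    pos <- -half_window + (seq_len(nbin) - 0.5) * bin_size
    df <- do.call(rbind, lapply(names(profiles), function(lev) {
      data.frame(position = pos, signal = profiles[[lev]],
                 stratum = sprintf("%s (n=%d)", lev, n_genes[lev]),
                 stringsAsFactors = FALSE)
    }))
    df$stratum <- factor(df$stratum, levels = unique(df$stratum))
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$position, y = .data$signal, colour = .data$stratum)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "position relative to TSS (bp)",
                    y = "mean signal", colour = "expression") +
      ggplot2::theme_bw()
    .save_figure(p, out_prefix)
  }
  attr(profiles, "n_genes") <- n_genes
  profiles
}
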