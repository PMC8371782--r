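#' Choose the reference sample
#'
#' The reference is the sample whose overall mean matrix value is the
#' median of the per-sample overall means; for an even number of samples
#' the lower median is taken so the choice is deterministic.
#'
#' @param matrices List of `DensityMatrix` objects, one per sample.
#' @return The reference `sample_id`.
#' @export
choose_reference <- function(matrices) {
  if (length(matrices) < 2L) stop("need at least 2 samples to normalize")
  ids <- vapply(matrices, function(m) m$sample_id, character(1))
  means <- vapply(matrices, function(m) mean(m$values), numeric(1))
  ord <- order(means, ids)
  unname(ids[ord[ceiling(length(ord) / 2)]])
}

#' Fit an affine model of a sample profile against the reference
#'
#' Ordinary least squares with intercept of the sample's average
#' constant-gene profile on the reference's: `sample = alpha * reference +
#' beta + error`.  The fitted model is later inverted to correct the
#' sample's track.
#'
#' @param sample_profile,reference_profile Equal-length numeric vectors
#'   (per-bin mean profiles over constant genes).
#' @param sample_id,reference_id Labels stored in the model.
#' @return An `AffineModel` list with `alpha`, `beta`, `sample_id`,
#'   `reference_id`.
#' @export
fit_affine <- function(sample_profile, reference_profile,
                       sample_id = "sample", reference_id = "reference") {
  if (length(sample_profile) != length(reference_profile)) {
    stop("profiles must have equal length")
  }
  if (length(unique(reference_profile)) < 2L) {
    stop("reference profile is constant; slope is unidentifiable")
  }
  fit <- stats::lm(sample_profile ~ reference_profile)
  beta <- unname(stats::coef(fit)[1L])
  alpha <- unname(stats::coef(fit)[2L])
  if (!is.finite(alpha) || alpha <= 0) {
    stop("degenerate affine fit (alpha = ", signif(alpha, 4),
         "); consider quantile normalization instead")
  }
  structure(
    list(sample_id = sample_id, reference_id = reference_id,
         alpha = alpha, beta = beta),
    class = "AffineModel"
  )
}

#' @export
print.AffineModel <- function(x, ...) {
  cat(sprintf("AffineModel %s ~ %s: alpha = %.6g, beta = %.6g\n",
              x$sample_id, x$reference_id, x$alpha, x$beta))
  invisible(x)
}

# Read a track's intervals, transform the score values and write a new
# bigWig with the same interval boundaries and chromosome sizes.
.transform_track <- function(track, out_path, fn) {
  if (is.character(track)) track <- signal_track(track)
  gr <- rtracklayer::import.bw(track$path)
  GenomeInfoDb::seqlengths(gr) <- track$seqlengths[
    GenomeInfoDb::seqlevels(gr)]
  gr$score <- pmax(0, fn(gr$score))
  rtracklayer::export.bw(gr, out_path)
  invisible(out_path)
}

#' Apply an affine normalization model to a bigWig track
#'
#' Every interval value `v` is replaced by `max(0, (v - beta) / alpha)`;
#' interval boundaries and chromosome sizes are preserved.  Applying the
#' identity model (`alpha = 1`, `beta = 0`) passes the signal through
#' unchanged, which is how the reference sample is handled.
#'
#' @param track A `SignalTrack` or bigWig path.
#' @param model An `AffineModel`.
#' @param out_path Output bigWig path.
#' @return `out_path`, invisibly.
#' @export
apply_affine <- function(track, model, out_path) {
  stopifnot(inherits(model, "AffineModel"))
  .transform_track(track, out_path,
                   function(v) (v - model$beta) / model$alpha)
}

#' Identity model used to pass the reference sample through unchanged
#' @param sample_id Sample label.
#' @return An `AffineModel` with `alpha = 1`, `beta = 0`.
#' @export
identity_affine <- function(sample_id = "reference") {
  structure(list(sample_id = sample_id, reference_id = sample_id,
                 alpha = 1, beta = 0), class = "AffineModel")
}

#' Group genes by overall signal intensity
#'
#' For quantile normalization genes are first pooled into `k` groups of
#' similar overall binding intensity: per gene the mean over all bins and
#' all samples is computed, genes are sorted ascending by this mean (ties
#' by gene id), and split into `k` contiguous groups of near-equal size
#' (remainder genes go to the lowest-intensity groups).
#'
#' @param matrices List of `DensityMatrix` objects sharing gene set and
#'   layout.
#' @param k Number of groups (default 20).
#' @return A `GeneGroups` list with `k`, `assignment` (named integer
#'   vector, gene id -> group 1..k ascending intensity) and `group_means`
#'   (overall mean intensity per group).
#' @export
build_gene_groups <- function(matrices, k = 20L) {
  k <- as.integer(k)
  gene_ids <- matrices[[1L]]$gene_ids
  for (m in matrices) {
    if (!identical(m$gene_ids, gene_ids)) {
      stop("all matrices must share the same gene set and order")
    }
  }
  n <- length(gene_ids)
  if (n < k) stop("gene count (", n, ") smaller than k (", k, ")")
  overall <- rowMeans(vapply(matrices, function(m) rowMeans(m$values),
                             numeric(n)))
  ord <- order(overall, gene_ids)
  sizes <- rep(n %/% k, k)
  rem <- n %% k
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  grp <- rep(seq_len(k), times = sizes)
  assignment <- integer(n)
  assignment[ord] <- grp
  names(assignment) <- gene_ids
  gm <- vapply(seq_len(k), function(g) mean(overall[ord][grp == g]),
               numeric(1))
  structure(list(k = k, assignment = assignment, group_means = gm),
            class = "GeneGroups")
}

# k x n_samples matrix of group-mean intensities, one column per sample.
.group_mean_matrix <- function(matrices, groups) {
  vapply(matrices, function(m) {
    grp <- groups$assignment[m$gene_ids]
    vapply(seq_len(groups$k), function(g) {
      mean(m$values[grp == g, , drop = FALSE])
    }, numeric(1))
  }, numeric(groups$k))
}

#' Fit per-sample quantile normalization maps
#'
#' Builds the k x n_samples matrix of group-mean intensities, quantile
#' normalizes it across samples (values are ranked within each sample and
#' replaced by the across-sample mean of the values sharing that rank),
#' and for each sample fits a smooth monotone value-to-value map through
#' the (original group mean, normalized target) knot pairs.  The smoother
#' is a monotone cubic spline (Fritsch-Carlson Hermite interpolation),
#' which passes through every knot, cannot invert the value ordering, and
#' reduces to a straight line when the knots are collinear; with fewer
#' than 4 distinct knots a monotone piecewise-linear interpolant is used
#' instead (with a warning).
#'
#' @param matrices List of `DensityMatrix` objects (>= 2 samples).
#' @param groups A `GeneGroups` from [build_gene_groups()]; built from
#'   `matrices` if omitted.
#' @param k Number of intensity groups when `groups` is omitted.
#' @return A named list of `QuantileMap` objects, one per sample.
#' @export
fit_quantile_map <- function(matrices, groups = NULL, k = 20L) {
  if (length(matrices) < 2L) stop("need at least 2 samples")
  if (is.null(groups)) groups <- build_gene_groups(matrices, k = k)
  G <- .group_mean_matrix(matrices, groups)
  ids <- vapply(matrices, function(m) m$sample_id, character(1))
  colnames(G) <- ids
  target <- rowMeans(apply(G, 2L, sort))
  maps <- lapply(seq_along(ids), function(j) {
    ord <- order(G[, j])
    .make_quantile_map(knots_in = G[ord, j], knots_out = target,
                       sample_id = ids[j])
  })
  names(maps) <- ids
  maps
}

# Build one monotone map through (knots_in ascending, knots_out) pairs.
.make_quantile_map <- function(knots_in, knots_out, sample_id) {
  # collapse duplicate input knots by averaging their targets
  if (anyDuplicated(knots_in)) {
    knots_out <- as.numeric(tapply(knots_out, factor(knots_in), mean))
    knots_in <- sort(unique(knots_in))
  }
  knots_out <- cummax(knots_out)  # targets must be non-decreasing
  n <- length(knots_in)
  if (n < 4L) {
    warning("fewer than 4 distinct intensity knots; using monotone ",
            "piecewise-linear interpolation")
    grid_x <- knots_in
    grid_y <- knots_out
  } else {
    # monotone cubic (Fritsch-Carlson) interpolation through the knots:
    # exact at the knots, monotone by construction, and linear wherever
    # the knots are collinear
    fn <- stats::splinefun(knots_in, knots_out, method = "monoH.FC")
    grid_x <- seq(knots_in[1L], knots_in[n], length.out = 512L)
    grid_y <- cummax(fn(grid_x))  # guard against rounding wiggle
  }
  m <- length(grid_x)
  # extrapolation continues the terminal knot segments linearly
  slope_lo <- (knots_out[2L] - knots_out[1L]) /
    (knots_in[2L] - knots_in[1L])
  slope_hi <- (knots_out[n] - knots_out[n - 1L]) /
    (knots_in[n] - knots_in[n - 1L])
  structure(
    list(sample_id = sample_id, knots_in = knots_in, knots_out = knots_out,
         grid_x = grid_x, grid_y = grid_y,
         slope_lo = slope_lo, slope_hi = slope_hi),
    class = "QuantileMap"
  )
}

#' @export
print.QuantileMap <- function(x, ...) {
  cat("QuantileMap", x$sample_id, "-", length(x$knots_in), "knots on [",
      signif(x$knots_in[1], 4), ",",
      signif(x$knots_in[length(x$knots_in)], 4), "]\n")
  invisible(x)
}

#' Evaluate a quantile map on signal values
#'
#' Values inside the knot range follow the fitted monotone curve; values
#' beyond either end are extended linearly with the terminal segment's
#' slope (strong peaks exceed all group means, and clamping them would
#' flatten real biology).  All outputs are clamped at 0.
#'
#' @param map A `QuantileMap`.
#' @param v Numeric vector of signal values.
#' @return Mapped values, same length as `v`, all `>= 0`.
#' @export
map_values <- function(map, v) {
  stopifnot(inherits(map, "QuantileMap"))
  gx <- map$grid_x
  gy <- map$grid_y
  m <- length(gx)
  out <- stats::approx(gx, gy, xout = pmin(pmax(v, gx[1L]), gx[m]),
                       ties = "ordered")$y
  lo <- v < gx[1L]
  hi <- v > gx[m]
  out[lo] <- gy[1L] + map$slope_lo * (v[lo] - gx[1L])
  out[hi] <- gy[m] + map$slope_hi * (v[hi] - gx[m])
  pmax(0, out)
}

#' Apply a quantile normalization map to a bigWig track
#'
#' @param track A `SignalTrack` or bigWig path.
#' @param map A `QuantileMap` for that sample.
#' @param out_path Output bigWig path.
#' @return `out_path`, invisibly.
#' @export
apply_quantile_map <- function(track, map, out_path) {
  stopifnot(inherits(map, "QuantileMap"))
  .transform_track(track, out_path, function(v) map_values(map, v))
}
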