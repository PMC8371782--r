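#' Scale-regions matrix layout
#'
#' Geometry of the genes x bins signal matrix: every gene body is rescaled
#' to `body_length` and flanked on each side by a fixed, unrescaled `flank`
#' region; all three segments are cut into `bin_size` bins.
#'
#' @param body_length Common length (bp) gene bodies are rescaled to
#'   (default 40000).
#' @param flank Flanking region length (bp) on each side (default 4000).
#' @param bin_size Bin width in bp (default 10).
#' @return A `MatrixLayout` list with the fields above plus `n_bins`.
#' @export
matrix_layout <- function(body_length = 40000L, flank = 4000L, bin_size = 10L) {
  body_length <- as.integer(body_length)
  flank <- as.integer(flank)
  bin_size <- as.integer(bin_size)
  if (body_length <= 0 || flank < 0 || bin_size <= 0) {
    stop("layout dimensions must be positive")
  }
  if (body_length %% bin_size != 0 || flank %% bin_size != 0) {
    stop("body_length and flank must be divisible by bin_size")
  }
  n_bins <- body_length %/% bin_size + 2L * (flank %/% bin_size)
  structure(
    list(body_length = body_length, flank = flank, bin_size = bin_size,
         n_bins = n_bins),
    class = "MatrixLayout"
  )
}

#' Open a bigWig signal track
#'
#' Wraps a bigWig file as a `SignalTrack`.  Chromosome sizes come from the
#' bigWig header; per-chromosome coverage is loaded lazily on first use and
#' cached, with uncovered positions read as signal 0.
#'
#' @param path Path to a bigWig file.
#' @param sample_id Sample label (defaults to the file name without
#'   extension).
#' @return A `SignalTrack` object.
#' @export
signal_track <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("bigWig not found: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(bw|bigwig)$", "", basename(path), ignore.case = TRUE)
  }
  bwf <- rtracklayer::BigWigFile(path)
  si <- GenomeInfoDb::seqinfo(bwf)
  structure(
    list(path = path, sample_id = sample_id,
         seqlengths = stats::setNames(GenomeInfoDb::seqlengths(si),
                                      GenomeInfoDb::seqnames(si)),
         cache = new.env(parent = emptyenv())),
    class = "SignalTrack"
  )
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat("SignalTrack", x$sample_id, "-", length(x$seqlengths),
      "chromosome(s) from", x$path, "\n")
  invisible(x)
}

# Cumulative signal for one chromosome: S[i+1] = sum of signal on bases
# [0, i).  Uncovered tail beyond the last bigWig interval is zero, so S is
# simply extended flat; the lookup clamps coordinates to [0, length].
.track_cumsum <- function(track, chrom) {
  key <- paste0("S_", chrom)
  if (!is.null(track$cache[[key]])) return(track$cache[[key]])
  if (is.null(track$cache$cov)) {
    track$cache$cov <- rtracklayer::import.bw(track$path, as = "RleList")
  }
  L <- track$seqlengths[[chrom]]
  v <- if (chrom %in% names(track$cache$cov)) {
    as.numeric(track$cache$cov[[chrom]])
  } else {
    numeric(0)
  }
  if (length(v) < L) v <- c(v, numeric(L - length(v)))
  S <- c(0, cumsum(v))
  track$cache[[key]] <- S
  S
}

# Interpolated cumulative signal at real-valued 0-based coordinates,
# clamped so positions outside the chromosome contribute 0 signal.
.cum_at <- function(S, x) {
  n <- length(S) - 1L
  x <- pmin(pmax(x, 0), n)
  i <- floor(x)
  frac <- x - i
  base <- S[i + 1L]
  nxt <- S[pmin(i + 2L, n + 1L)]
  base + frac * (nxt - base)
}

# Mean signal over real-valued half-open windows [a, b) given the
# chromosome cumulative vector.  Bases outside the chromosome count in the
# width but contribute 0 signal (edge-truncation semantics).
.window_means <- function(S, a, b) {
  (.cum_at(S, b) - .cum_at(S, a)) / (b - a)
}

#' Build a scale-regions density matrix from a bigWig track
#'
#' For each gene, the upstream flank (5' of the TSS in gene orientation),
#' the gene body rescaled to a common length, and the downstream flank are
#' each divided into equal-width genomic sub-intervals and the mean track
#' signal is computed in each with exact fractional-base weighting.  Rows
#' of minus-strand genes are reversed so every row reads 5' to 3'.  Flank
#' windows extending past a chromosome edge count the missing bases as
#' signal 0.
#'
#' @param track A `SignalTrack` (or bigWig path).
#' @param models Gene model table; genes on chromosomes absent from the
#'   bigWig header, or with bodies shorter than one bin, are dropped with a
#'   warning.
#' @param layout A `MatrixLayout` (default [matrix_layout()]).
#' @return A `DensityMatrix`: list with `sample_id`, `gene_ids`, `layout`
#'   and `values` (genes x `layout$n_bins` matrix).
#' @export
compute_matrix <- function(track, models, layout = matrix_layout()) {
  if (is.character(track)) track <- signal_track(track)
  stopifnot(inherits(track, "SignalTrack"), inherits(layout, "MatrixLayout"))
  if (nrow(models) == 0L) stop("empty gene list")

  known <- models$chrom %in% names(track$seqlengths)
  if (any(!known)) {
    warning(sum(!known), " gene(s) on chromosome(s) absent from the bigWig ",
            "dropped")
    models <- models[known, , drop = FALSE]
  }
  wide <- (models$end - models$start) >= layout$bin_size
  if (any(!wide)) {
    warning(sum(!wide), " gene(s) with body shorter than one bin dropped")
    models <- models[wide, , drop = FALSE]
  }
  if (nrow(models) == 0L) stop("no usable genes left for the matrix")

  nfl <- layout$flank %/% layout$bin_size
  nb <- layout$body_length %/% layout$bin_size
  vals <- matrix(0, nrow = nrow(models), ncol = layout$n_bins)
  for (g in seq_len(nrow(models))) {
    S <- .track_cumsum(track, models$chrom[g])
    st <- models$start[g]
    en <- models$end[g]
    edges <- c(
      st - layout$flank + (0:nfl) * layout$bin_size,
      st + (1:nb) * (en - st) / nb,
      en + (1:nfl) * layout$bin_size
    )
    row <- .window_means(S, edges[-length(edges)], edges[-1L])
    if (models$strand[g] == "-") row <- rev(row)
    vals[g, ] <- row
  }
  rownames(vals) <- models$gene_id
  structure(
    list(sample_id = track$sample_id, gene_ids = models$gene_id,
         layout = layout, values = vals),
    class = "DensityMatrix"
  )
}

#' @export
print.DensityMatrix <- function(x, ...) {
  cat("DensityMatrix", x$sample_id, "-", length(x$gene_ids), "genes x",
      x$layout$n_bins, "bins\n")
  invisible(x)
}

#' Average profile of a density matrix
#'
#' Column-wise mean across genes: the average signal per bin used to fit
#' the normalization models.
#'
#' @param matrix A `DensityMatrix`.
#' @return Numeric vector of length `layout$n_bins`.
#' @export
mean_profile <- function(matrix) {
  stopifnot(inherits(matrix, "DensityMatrix"))
  if (nrow(matrix$values) < 1L) stop("matrix has no gene rows")
  colMeans(matrix$values)
}

#' TSS-centered mean signal profile
#'
#' Mean signal in fixed-width bins across a window centered on each gene's
#' transcription start site, oriented 5' to 3' and averaged over genes.
#'
#' @param track A `SignalTrack` (or bigWig path).
#' @param models Gene model table for the genes to profile.
#' @param half_window Half-width of the window in bp (default 4000, i.e. an
#'   8 kb window).
#' @param bin_size Bin width in bp (default 10).
#' @return Numeric vector of `2 * half_window / bin_size` bin means; bin
#'   `i` covers offsets `[-half_window + (i-1)*bin_size, ...)` relative to
#'   the TSS.
#' @export
tss_mean_profile <- function(track, models, half_window = 4000L,
                             bin_size = 10L) {
  if (is.character(track)) track <- signal_track(track)
  stopifnot(inherits(track, "SignalTrack"))
  if ((2L * half_window) %% bin_size != 0) {
    stop("window must be divisible by bin_size")
  }
  known <- models$chrom %in% names(track$seqlengths)
  if (any(!known)) {
    warning(sum(!known), " gene(s) on chromosome(s) absent from the bigWig ",
            "dropped")
    models <- models[known, , drop = FALSE]
  }
  if (nrow(models) == 0L) stop("no usable genes for the TSS profile")
  nbin <- (2L * half_window) %/% bin_size
  acc <- numeric(nbin)
  for (g in seq_len(nrow(models))) {
    S <- .track_cumsum(track, models$chrom[g])
    tss <- if (models$strand[g] == "+") models$start[g] else models$end[g]
    edges <- tss - half_window + (0:nbin) * bin_size
    row <- .window_means(S, edges[-length(edges)], edges[-1L])
    if (models$strand[g] == "-") row <- rev(row)
    acc <- acc + row
  }
  acc / nrow(models)
}
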