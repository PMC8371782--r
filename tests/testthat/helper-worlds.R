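# Shared fixtures and independent oracles used across test files.

# A small affine-distorted two-sample world, built once per test run.
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- fixture_spec(n_genes = 150, n_samples = 2, n_chroms = 2,
                           alpha = c(1, 2), beta = c(0, 5),
                           noise_sd = 0, seed = 101)
      cache <<- make_world(spec, file.path(tempdir(), "world_small"))
    }
    cache
  }
})

# Same geometry with 1% multiplicative noise and three samples.
noisy_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- fixture_spec(n_genes = 150, n_samples = 3, n_chroms = 2,
                           alpha = c(1, 1.6, 2.4), beta = c(0, 2, 5),
                           noise_sd = 0.01, seed = 202)
      cache <<- make_world(spec, file.path(tempdir(), "world_noisy"))
    }
    cache
  }
})

# Write a bigWig holding the given per-base arrays and return its path.
write_bw <- function(arrays, chrom_sizes, step = 1L) {
  path <- tempfile(fileext = ".bw")
  write_bigwig_from_array(chrom_sizes, arrays, path, step = step)
  path
}

# Values exactly representable in the bigWig's 32-bit floats, so container
# precision cannot blur exactness checks on operator algebra.
float32_clean <- function(n, scale = 4, grid = 64) {
  sample.int(scale * grid, n, replace = TRUE) / grid
}

# Independent brute-force oracle for constant-gene selection: sort by mean
# (ties by id), cut into contiguous equal bins (remainder to lowest bins),
# keep the ceil(percent% ) smallest-SD genes of each bin (ties by id).
oracle_select_constant <- function(values, ids, n_bins, percent) {
  mu <- apply(values, 1, mean)
  sd_ <- apply(values, 1, sd)
  ord <- order(mu, ids)
  n <- length(ids)
  sizes <- rep(floor(n / n_bins), n_bins)
  if (n %% n_bins > 0) {
    sizes[1:(n %% n_bins)] <- sizes[1:(n %% n_bins)] + 1
  }
  out <- character(0)
  at <- 1
  for (b in 1:n_bins) {
    members <- ord[at:(at + sizes[b] - 1)]
    at <- at + sizes[b]
    take <- ceiling(percent / 100 * length(members))
    ranked <- members[order(sd_[members], ids[members])]
    out <- c(out, ids[ranked[1:take]])
  }
  out
}

# Brute-force optimal 1-D 3-means over contiguous partitions of the sorted
# values (the optimal k-means partition in one dimension is contiguous).
oracle_kmeans3_sizes <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- NULL
  best_ss <- Inf
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      parts <- list(xs[1:i], xs[(i + 1):j], xs[(j + 1):n])
      ss <- sum(vapply(parts, function(p) sum((p - mean(p))^2), numeric(1)))
      if (ss < best_ss) {
        best_ss <- ss
        best <- c(i, j - i, n - j)
      }
    }
  }
  best
}

# Minimal DensityMatrix-shaped object for unit tests of the model fitters.
fake_matrix <- function(values, sample_id,
                        layout = matrix_layout(100L, 20L, 10L)) {
  structure(
    list(sample_id = sample_id, gene_ids = rownames(values),
         layout = layout, values = values),
    class = "DensityMatrix"
  )
}
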