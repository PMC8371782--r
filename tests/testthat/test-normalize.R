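mat_with_mean <- function(mu, id) {
  fake_matrix(matrix(mu, 4, 14, dimnames = list(paste0("g", 1:4), NULL)), id)
}

test_that("the reference is the sample with the (lower) median intensity", {
  ms <- list(mat_with_mean(9, "a"), mat_with_mean(2, "b"),
             mat_with_mean(5, "c"))
  expect_equal(choose_reference(ms), "c")
  expect_equal(choose_reference(ms[1:2]), "b")  # lower median of two
  ms5 <- list(mat_with_mean(3, "a"), mat_with_mean(8, "b"),
              mat_with_mean(1, "c"), mat_with_mean(9, "d"),
              mat_with_mean(6, "e"))
  mus <- c(3, 8, 1, 9, 6)
  expect_equal(choose_reference(ms5),
               c("a", "b", "c", "d", "e")[which(mus == sort(mus)[3])])
  expect_error(choose_reference(ms[1]), "2 samples")
})

test_that("affine fitting recovers exact and noisy relationships", {
  ref <- seq(0, 10, length.out = 200)
  fit0 <- fit_affine(ref, ref)
  expect_equal(fit0$alpha, 1, tolerance = 1e-10)
  expect_equal(fit0$beta, 0, tolerance = 1e-10)

  fit1 <- fit_affine(2 * ref + 5, ref)
  expect_equal(fit1$alpha, 2, tolerance = 1e-10)
  expect_equal(fit1$beta, 5, tolerance = 1e-10)

  set.seed(11)
  x <- runif(4800, 0, 5)
  y <- 1.7 * x + 3 + rnorm(4800, 0, 0.1)
  fit2 <- fit_affine(y, x)
  # closed-form OLS oracle
  a_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b_hat <- mean(y) - a_hat * mean(x)
  expect_equal(fit2$alpha, a_hat, tolerance = 1e-12)
  expect_equal(fit2$beta, b_hat, tolerance = 1e-12)
  expect_lt(abs(fit2$alpha - 1.7), 0.01)
  expect_lt(abs(fit2$beta - 3), 0.05)

  expect_error(fit_affine(ref, rep(1, 200)), "constant")
  expect_error(fit_affine(-2 * ref + 30, ref), "degenerate|quantile")
})

test_that("affine application transforms, clamps and inverts tracks", {
  v <- c(5, 25, 1, 0)
  path <- write_bw(list(chr1 = rep(v, each = 100)), c(chr1 = 400L))
  model <- structure(list(sample_id = "s", reference_id = "r",
                          alpha = 2, beta = 5), class = "AffineModel")
  out <- tempfile(fileext = ".bw")
  apply_affine(path, model, out)
  cov <- rtracklayer::import.bw(out, as = "RleList")$chr1
  got <- as.numeric(cov)[seq(50, 400, by = 100)]
  expect_equal(got, pmax(0, (v - 5) / 2))  # 5 -> 0 hits the clamp

  # constructing alpha*ref + beta and applying (alpha, beta) recovers ref
  set.seed(21)
  ref_v <- float32_clean(3000)
  distorted <- write_bw(list(chr1 = 2 * ref_v + 5), c(chr1 = 3000L))
  back <- tempfile(fileext = ".bw")
  apply_affine(distorted, model, back)
  got <- as.numeric(rtracklayer::import.bw(back, as = "RleList")$chr1)
  expect_lt(max(abs(got - ref_v)), 1e-6)
})

test_that("gene groups follow the sort-and-split oracle", {
  set.seed(31)
  n <- 47
  ids <- sprintf("g%02d", 1:n)
  v1 <- matrix(rlnorm(n * 14), n, dimnames = list(ids, NULL))
  v2 <- matrix(rlnorm(n * 14), n, dimnames = list(ids, NULL))
  ms <- list(fake_matrix(v1, "a"), fake_matrix(v2, "b"))
  k <- 10
  grp <- build_gene_groups(ms, k = k)
  # oracle: mean over bins and samples, ascending sort, contiguous split
  overall <- (rowMeans(v1) + rowMeans(v2)) / 2
  ord <- order(overall, ids)
  sizes <- rep(n %/% k, k)
  sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1
  want <- integer(n)
  want[ord] <- rep(1:k, times = sizes)
  expect_equal(unname(grp$assignment[ids]), want)

  m40 <- list(fake_matrix(v1[1:40, ], "a"), fake_matrix(v2[1:40, ], "b"))
  g20 <- build_gene_groups(m40, k = 20)
  expect_true(all(table(g20$assignment) == 2))
  expect_error(build_gene_groups(m40, k = 50), "smaller than k")
})

test_that("the hand-worked 3-group quantile example gives targets (2,4,6)", {
  ids <- c("g1", "g2", "g3")
  m1 <- fake_matrix(matrix(c(1, 2, 3), 3, 5, dimnames = list(ids, NULL)), "a")
  m2 <- fake_matrix(matrix(c(3, 6, 9), 3, 5, dimnames = list(ids, NULL)), "b")
  grp <- build_gene_groups(list(m1, m2), k = 3)
  ws <- capture_warnings(
    maps <- fit_quantile_map(list(m1, m2), groups = grp))
  expect_match(ws, "piecewise-linear", all = TRUE)  # one per sample map
  expect_equal(maps[["a"]]$knots_in, c(1, 2, 3))
  expect_equal(maps[["a"]]$knots_out, c(2, 4, 6))
  expect_equal(maps[["b"]]$knots_in, c(3, 6, 9))
  expect_equal(maps[["b"]]$knots_out, c(2, 4, 6))
  expect_equal(map_values(maps[["a"]], 2), 4)
  expect_equal(map_values(maps[["a"]], c(1, 3)), c(2, 6))
})

test_that("identical samples give an identity map at the knots", {
  set.seed(41)
  n <- 60
  ids <- sprintf("g%02d", 1:n)
  v <- matrix(rlnorm(n * 14, 1, 0.8), n, dimnames = list(ids, NULL))
  ms <- list(fake_matrix(v, "a"), fake_matrix(v, "b"))
  maps <- fit_quantile_map(ms, k = 20)
  for (m in maps) {
    expect_equal(m$knots_out, m$knots_in, tolerance = 1e-10)
    expect_equal(map_values(m, m$knots_in), m$knots_in, tolerance = 1e-4)
  }
})

test_that("fitted maps send each sample's group means to the common target", {
  w <- noisy_world()
  tab <- read_expression(w$expression, "CPM")
  sel <- select_constant_genes(tab, n_bins = 15, percent = 20)
  cm <- w$models[w$models$gene_id %in% sel$gene_ids, ]
  lay <- matrix_layout(2000L, 1000L, 50L)
  ms <- lapply(names(w$tracks), function(id) {
    compute_matrix(signal_track(w$tracks[[id]], id), cm, lay)
  })
  grp <- build_gene_groups(ms, k = 10)
  maps <- fit_quantile_map(ms, groups = grp)
  targets <- lapply(maps, function(m) map_values(m, m$knots_in))
  common <- maps[[1]]$knots_out
  for (tg in targets) {
    expect_equal(tg, common, tolerance = 1e-2)
  }
})

test_that("quantile maps are monotone, non-negative and extend linearly", {
  w <- noisy_world()
  tab <- read_expression(w$expression, "CPM")
  sel <- select_constant_genes(tab, n_bins = 15, percent = 20)
  cm <- w$models[w$models$gene_id %in% sel$gene_ids, ]
  lay <- matrix_layout(2000L, 1000L, 50L)
  ms <- lapply(names(w$tracks), function(id) {
    compute_matrix(signal_track(w$tracks[[id]], id), cm, lay)
  })
  maps <- fit_quantile_map(ms, k = 10)
  set.seed(51)
  for (m in maps) {
    hi <- max(m$knots_in) * 2
    v <- sort(runif(1000, 0, hi))
    out <- map_values(m, v)
    expect_true(all(diff(out) >= -1e-12))
    expect_true(all(out >= 0))
  }
})

test_that("quantile application matches map_values on the track", {
  w <- small_world()
  tab <- read_expression(w$expression, "CPM")
  sel <- select_constant_genes(tab, n_bins = 15, percent = 20)
  cm <- w$models[w$models$gene_id %in% sel$gene_ids, ]
  lay <- matrix_layout(2000L, 1000L, 50L)
  ms <- lapply(names(w$tracks), function(id) {
    compute_matrix(signal_track(w$tracks[[id]], id), cm, lay)
  })
  maps <- fit_quantile_map(ms, k = 10)
  out <- tempfile(fileext = ".bw")
  apply_quantile_map(w$tracks[["sample2"]], maps[["sample2"]], out)
  orig <- rtracklayer::import.bw(w$tracks[["sample2"]])
  norm <- rtracklayer::import.bw(out)
  expect_equal(norm$score, map_values(maps[["sample2"]], orig$score),
               tolerance = 1e-6)
})
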