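#' Specification of a synthetic test world
#'
#' Describes a toy genome with annotated genes, an expression matrix and
#' one distorted signal track per sample, used to exercise the whole
#' pipeline with known ground truth.  A designated fraction of genes gets
#' identical expression across samples (the "constant" genes the pipeline
#' should recover); the rest receive sample-specific log-normal fold
#' changes.  Each gene contributes a Gaussian promoter peak (SD 300 bp,
#' centered on the TSS) whose height is proportional to its expression, on
#' top of a uniform background; sample `s`'s track is
#' `alpha[s] * base + beta[s]`, optionally with multiplicative Gaussian
#' noise.
#'
#' @param n_genes Number of genes (default 200).
#' @param n_samples Number of samples (default 2).
#' @param n_chroms Number of chromosomes genes are spread over (default 2).
#' @param constant_fraction Fraction of genes with identical expression
#'   across samples (default 0.1).
#' @param alpha,beta Per-sample affine distortion of the shared base track
#'   (defaults: no distortion).
#' @param noise_sd SD of multiplicative Gaussian noise applied per signal
#'   step (default 0 = noise-free).
#' @param seed Random seed; the same spec and seed give byte-identical
#'   outputs.
#' @param gene_length Range (bp) gene body lengths are drawn from.
#' @param spacing Minimum gap between genes and to chromosome edges (bp).
#' @param chrom_length Chromosome length (bp); computed from the gene
#'   complement when `NULL`, error if the genes do not fit an explicit
#'   length.
#' @param step Resolution (bp) of the generated piecewise-constant signal.
#' @param peak_sd SD of the Gaussian promoter peak (bp).
#' @param peak_height_scale Peak height per expression unit.
#' @param background Uniform background signal level.
#' @param expr_meanlog,expr_sdlog Log-normal parameters of base expression.
#' @param fold_sdlog Log-SD of the per-sample fold changes of
#'   non-constant genes.
#' @return A `FixtureSpec` list.
#' @export
fixture_spec <- function(n_genes = 200L, n_samples = 2L, n_chroms = 2L,
                         constant_fraction = 0.1,
                         alpha = rep(1, n_samples),
                         beta = rep(0, n_samples),
                         noise_sd = 0, seed = 1L,
                         gene_length = c(1000L, 5000L),
                         spacing = 10000L, chrom_length = NULL,
                         step = 10L, peak_sd = 300, peak_height_scale = 0.1,
                         background = 0.5,
                         expr_meanlog = 3, expr_sdlog = 1.5,
                         fold_sdlog = 0.5) {
  if (length(alpha) != n_samples || length(beta) != n_samples) {
    stop("alpha and beta must have one value per sample")
  }
  if (constant_fraction <= 0 || constant_fraction >= 1) {
    stop("constant_fraction must be in (0, 1)")
  }
  structure(
    list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
         n_chroms = as.integer(n_chroms),
         constant_fraction = constant_fraction,
         alpha = alpha, beta = beta, noise_sd = noise_sd,
         seed = as.integer(seed), gene_length = as.integer(gene_length),
         spacing = as.integer(spacing), chrom_length = chrom_length,
         step = as.integer(step), peak_sd = peak_sd,
         peak_height_scale = peak_height_scale, background = background,
         expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
         fold_sdlog = fold_sdlog),
    class = "FixtureSpec"
  )
}

#' Generate a synthetic test world
#'
#' Writes a GTF annotation, an expression TSV (CPM units), one bigWig per
#' sample, and a `truth.json` recording every generated parameter
#' (including the constant-gene ids and per-sample distortions).
#'
#' @param spec A `FixtureSpec`.
#' @param out_dir Output directory (created if needed).
#' @return Named list of output paths (`gtf`, `expression`, `tracks`
#'   (named per sample), `truth`) plus the `truth` record itself,
#'   invisibly structured as a list.
#' @export
make_world <- function(spec, out_dir) {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)

  # --- gene placement ------------------------------------------------
  n <- spec$n_genes
  lens <- spec$step * sample.int(
    spec$gene_length[2L] %/% spec$step - spec$gene_length[1L] %/% spec$step + 1L,
    n, replace = TRUE) + spec$gene_length[1L] - spec$step
  chrom_of <- rep(seq_len(spec$n_chroms), length.out = n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  start <- integer(n)
  chrom_needed <- integer(spec$n_chroms)
  for (c in seq_len(spec$n_chroms)) {
    idx <- which(chrom_of == c)
    pos <- spec$spacing
    for (g in idx) {
      start[g] <- pos
      pos <- pos + lens[g] + spec$spacing
    }
    chrom_needed[c] <- pos
  }
  if (is.null(spec$chrom_length)) {
    chrom_len <- max(chrom_needed)
  } else {
    chrom_len <- as.integer(spec$chrom_length)
    if (any(chrom_needed > chrom_len)) {
      stop("genes do not fit: need ", max(chrom_needed),
           " bp but chrom_length is ", chrom_len)
    }
  }
  chroms <- paste0("chr", seq_len(spec$n_chroms))
  models <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n)),
    chrom = chroms[chrom_of],
    start = start, end = start + lens, strand = strand,
    exon_length = lens, stringsAsFactors = FALSE
  )

  # --- expression -----------------------------------------------------
  # Non-constant genes: log-normal base level with sample-specific fold
  # changes.  Constant genes: identical expression in every sample, with
  # levels planted at evenly spaced quantiles of the non-constant genes'
  # observed mean expression, so that every expression stratum contains
  # anchor genes -- the structural assumption the normalization rests on.
  n_const <- round(spec$constant_fraction * n)
  const_idx <- sort(sample.int(n, n_const))
  var_idx <- setdiff(seq_len(n), const_idx)
  base_expr <- numeric(n)
  base_expr[var_idx] <- stats::rlnorm(length(var_idx), spec$expr_meanlog,
                                      spec$expr_sdlog)
  expr <- matrix(0, n, spec$n_samples)
  for (s in seq_len(spec$n_samples)) {
    expr[var_idx, s] <- base_expr[var_idx] *
      stats::rlnorm(length(var_idx), 0, spec$fold_sdlog)
  }
  s_means <- sort(rowMeans(expr[var_idx, , drop = FALSE]))
  nn <- length(var_idx)
  for (i in seq_len(n_const)) {
    q <- (i - 0.5) * nn / n_const
    lo <- min(max(1L, floor(q)), nn - 1L)
    level <- exp((log(s_means[lo]) + log(s_means[lo + 1L])) / 2)
    base_expr[const_idx[i]] <- level
    expr[const_idx[i], ] <- level
  }
  sample_ids <- paste0("sample", seq_len(spec$n_samples))
  colnames(expr) <- sample_ids
  rownames(expr) <- models$gene_id

  # --- base signal per chromosome (piecewise constant at `step` bp) ---
  base_sig <- lapply(seq_len(spec$n_chroms), function(c) {
    nstep <- ceiling(chrom_len / spec$step)
    v <- rep(spec$background, nstep)
    centers <- (seq_len(nstep) - 0.5) * spec$step
    for (g in which(chrom_of == c)) {
      tss <- if (strand[g] == "+") start[g] else start[g] + lens[g]
      h <- spec$peak_height_scale * base_expr[g]
      win <- which(abs(centers - tss) <= 5 * spec$peak_sd)
      v[win] <- v[win] + h * exp(-(centers[win] - tss)^2 / (2 * spec$peak_sd^2))
    }
    v
  })
  names(base_sig) <- chroms

  # --- per-sample tracks ---------------------------------------------
  chrom_sizes <- stats::setNames(rep(chrom_len, spec$n_chroms), chroms)
  track_paths <- character(spec$n_samples)
  for (s in seq_len(spec$n_samples)) {
    arrays <- lapply(base_sig, function(v) {
      out <- spec$alpha[s] * v + spec$beta[s]
      if (spec$noise_sd > 0) {
        out <- out * (1 + stats::rnorm(length(out), 0, spec$noise_sd))
      }
      pmax(0, out)
    })
    path <- file.path(out_dir, paste0(sample_ids[s], ".bw"))
    write_bigwig_from_array(chrom_sizes, arrays, path, step = spec$step)
    track_paths[s] <- path
  }
  names(track_paths) <- sample_ids

  # --- annotation, expression table, truth ----------------------------
  gtf_path <- file.path(out_dir, "genes.gtf")
  .write_gtf(models, gtf_path)
  expr_path <- file.path(out_dir, "expression.tsv")
  utils::write.table(
    data.frame(gene_id = models$gene_id, expr, check.names = FALSE),
    expr_path, sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- list(
    seed = spec$seed, n_genes = n, n_samples = spec$n_samples,
    constant_genes = models$gene_id[const_idx],
    alpha = stats::setNames(as.list(spec$alpha), sample_ids),
    beta = stats::setNames(as.list(spec$beta), sample_ids),
    noise_sd = spec$noise_sd, background = spec$background,
    peak_sd = spec$peak_sd, peak_height_scale = spec$peak_height_scale,
    chrom_sizes = as.list(chrom_sizes)
  )
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(gtf = gtf_path, expression = expr_path,
                 tracks = track_paths, truth = truth_path,
                 models = models, truth_record = truth))
}

.write_gtf <- function(models, path) {
  lines <- character(0)
  for (g in seq_len(nrow(models))) {
    attrs <- sprintf('gene_id "%s";', models$gene_id[g])
    lines <- c(lines,
      paste(models$chrom[g], "synthetic", "gene", models$start[g] + 1L,
            models$end[g], ".", models$strand[g], ".", attrs, sep = "\t"),
      paste(models$chrom[g], "synthetic", "exon", models$start[g] + 1L,
            models$end[g], ".", models$strand[g], ".", attrs, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write per-base (or per-step) signal arrays as a bigWig
#'
#' Values are run-length encoded; bigWig stores single-precision floats,
#' so values survive a write/read round trip at 32-bit float precision.
#'
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param arrays Named list (same names) of non-negative numeric vectors;
#'   with `step = 1` one value per base, otherwise one value per `step`
#'   bp window (the last window is truncated at the chromosome end).
#' @param path Output bigWig path.
#' @param step Width in bp represented by each array element (default 1).
#' @return `path`, invisibly.
#' @export
write_bigwig_from_array <- function(chrom_sizes, arrays, path, step = 1L) {
  if (!all(names(arrays) %in% names(chrom_sizes))) {
    stop("array names must match chrom_sizes names")
  }
  runs <- lapply(names(arrays), function(chrom) {
    v <- arrays[[chrom]]
    if (any(v < 0)) stop("negative signal values in ", chrom)
    L <- chrom_sizes[[chrom]]
    r <- S4Vectors::Rle(v, rep.int(as.integer(step), length(v)))
    if (length(r) > L) r <- r[seq_len(L)]
    len <- S4Vectors::runLength(r)
    starts <- cumsum(c(1L, len))
    list(chrom = rep(chrom, S4Vectors::nrun(r)),
         start = starts[seq_len(S4Vectors::nrun(r))], width = len,
         score = S4Vectors::runValue(r))
  })
  gr <- GenomicRanges::GRanges(
    seqnames = factor(unlist(lapply(runs, `[[`, "chrom")),
                      levels = names(chrom_sizes)),
    ranges = IRanges::IRanges(
      start = unlist(lapply(runs, `[[`, "start")),
      width = unlist(lapply(runs, `[[`, "width"))),
    score = unlist(lapply(runs, `[[`, "score")),
    seqlengths = chrom_sizes)
  rtracklayer::export.bw(gr, path)
  invisible(path)
}
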