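#' Normalize a set of ChIP-seq density tracks
#'
#' End-to-end pipeline: select constant genes from the expression matrix,
#' build a scale-regions matrix per sample over them, learn either an
#' affine model against a reference sample or per-sample quantile maps,
#' apply the learned transformation to each full bigWig, and score the
#' result with zone statistics on TSS profiles before and after.
#'
#' Outputs written to `out_dir`: one `<sample>.<method>.normalized.bw` per
#' sample, `constant_genes.bed`, `report.json` (fitted parameters,
#' per-zone percent differences before/after, effective parameters),
#' `zone_stats.tsv` and a before/after TSS profile figure
#' (`tss_profiles.svg`/`.png`).
#'
#' @param tracks Named character vector of bigWig paths (names = sample
#'   ids), >= 2 samples.
#' @param expression An `ExpressionTable`, or a path to an expression TSV.
#' @param annotation A gene model `data.frame`, or a path to a GTF/BED
#'   file.
#' @param out_dir Output directory.
#' @param method `"linear"` (affine regression to a reference) or
#'   `"quantile"`.
#' @param units Expression units when `expression` is a path.
#' @param percent,expression_bins Constant-gene selection parameters (see
#'   [select_constant_genes()]).
#' @param layout A `MatrixLayout` for the scale-regions matrices.
#' @param k Number of intensity groups for quantile normalization.
#' @param reference `"auto"` (median-intensity sample) or a sample id.
#' @param half_window,eval_bin_size Geometry of the evaluation TSS
#'   profiles.
#' @return The report, invisibly: a list with `method`, `reference`,
#'   `models` (alpha/beta or knot tables), `zones_before`, `zones_after`
#'   (average percent difference per zone), `constant_genes`, `outputs`.
#' @export
normalize_tracks <- function(tracks, expression, annotation, out_dir,
                             method = c("linear", "quantile"),
                             units = "CPM",
                             percent = 10, expression_bins = 100L,
                             layout = matrix_layout(), k = 20L,
                             reference = "auto",
                             half_window = 4000L, eval_bin_size = 10L) {
  method <- match.arg(method)
  if (length(tracks) < 2L) stop("need at least 2 sample tracks")
  if (is.null(names(tracks)) || any(names(tracks) == "")) {
    stop("tracks must be a named vector (names are sample ids)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  models <- if (is.character(annotation)) {
    read_gene_annotation(annotation)
  } else annotation
  expr <- if (is.character(expression)) {
    read_expression(expression, units = units)
  } else expression
  expr <- to_cpm_like(expr, models)

  const <- select_constant_genes(expr, n_bins = expression_bins,
                                 percent = percent)
  bed_path <- file.path(out_dir, "constant_genes.bed")
  write_constant_bed(const, models, bed_path)
  cmodels <- models[models$gene_id %in% const$gene_ids, , drop = FALSE]

  sts <- lapply(names(tracks), function(id) signal_track(tracks[[id]], id))
  names(sts) <- names(tracks)
  mats <- lapply(sts, compute_matrix, models = cmodels, layout = layout)

  before <- lapply(sts, tss_mean_profile, models = cmodels,
                   half_window = half_window, bin_size = eval_bin_size)
  zones_before <- zone_percent_difference(before, bin_size = eval_bin_size)

  out_tracks <- character(0)
  fitted <- list()
  if (method == "linear") {
    ref_id <- if (identical(reference, "auto")) {
      choose_reference(mats)
    } else {
      if (!reference %in% names(tracks)) {
        stop("reference sample '", reference, "' not among tracks")
      }
      reference
    }
    ref_profile <- mean_profile(mats[[ref_id]])
    for (id in names(tracks)) {
      model <- if (id == ref_id) {
        identity_affine(id)
      } else {
        fit_affine(mean_profile(mats[[id]]), ref_profile,
                   sample_id = id, reference_id = ref_id)
      }
      out <- file.path(out_dir, paste0(id, ".linear.normalized.bw"))
      apply_affine(sts[[id]], model, out)
      out_tracks[id] <- out
      fitted[[id]] <- list(alpha = model$alpha, beta = model$beta,
                           reference = ref_id)
    }
  } else {
    ref_id <- NA_character_
    groups <- build_gene_groups(mats, k = k)
    qmaps <- fit_quantile_map(mats, groups = groups)
    for (id in names(tracks)) {
      out <- file.path(out_dir, paste0(id, ".quantile.normalized.bw"))
      apply_quantile_map(sts[[id]], qmaps[[id]], out)
      out_tracks[id] <- out
      fitted[[id]] <- list(knots_in = qmaps[[id]]$knots_in,
                           knots_out = qmaps[[id]]$knots_out)
    }
  }

  after_sts <- lapply(names(out_tracks), function(id) {
    signal_track(out_tracks[[id]], id)
  })
  names(after_sts) <- names(out_tracks)
  after <- lapply(after_sts, tss_mean_profile, models = cmodels,
                  half_window = half_window, bin_size = eval_bin_size)
  zones_after <- zone_percent_difference(after, bin_size = eval_bin_size)

  plot_before_after(before, after, file.path(out_dir, "tss_profiles"),
                    bin_size = eval_bin_size)

  zone_tab <- data.frame(
    zone = names(zone_spec()),
    before_pct = unname(zone_averages(zones_before)),
    after_pct = unname(zone_averages(zones_after))
  )
  utils::write.table(zone_tab, file.path(out_dir, "zone_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  report <- list(
    method = method,
    reference = ref_id,
    parameters = list(percent = percent, expression_bins = expression_bins,
                      body_length = layout$body_length,
                      flank = layout$flank, bin_size = layout$bin_size,
                      k = k, half_window = half_window,
                      eval_bin_size = eval_bin_size),
    models = fitted,
    n_constant_genes = length(const$gene_ids),
    zones_before = as.list(zone_averages(zones_before)),
    zones_after = as.list(zone_averages(zones_after)),
    outputs = as.list(stats::setNames(basename(out_tracks),
                                      names(out_tracks)))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Expression-stratified TSS profile (antibody-specificity plot)
#'
#' Clusters genes into low/medium/high expression and profiles the track
#' signal around the TSSs of each stratum; writes the figure, a strata
#' TSV and a provenance JSON to `out_dir`.
#'
#' @param track bigWig path (one sample).
#' @param expression An `ExpressionTable` or TSV path.
#' @param annotation A gene model `data.frame` or GTF/BED path.
#' @param out_dir Output directory.
#' @param units Expression units when `expression` is a path.
#' @param sample_id Expression column to stratify on, or `"mean"`.
#' @param seed k-means seed.
#' @param log_transform Cluster on log1p expression (default `TRUE`).
#' @param half_window,bin_size TSS window geometry.
#' @return Invisibly, the list of three stratum profiles.
#' @export
plot_expression_profile <- function(track, expression, annotation, out_dir,
                                    units = "CPM", sample_id = "mean",
                                    seed = 42L, log_transform = TRUE,
                                    half_window = 4000L, bin_size = 10L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  models <- if (is.character(annotation)) {
    read_gene_annotation(annotation)
  } else annotation
  expr <- if (is.character(expression)) {
    read_expression(expression, units = units)
  } else expression

  strata <- stratify_expression(expr, sample_id = sample_id, seed = seed,
                                log_transform = log_transform)
  profiles <- profile_by_stratum(
    track, strata, models, half_window = half_window, bin_size = bin_size,
    out_prefix = file.path(out_dir, "expression_profile"))

  utils::write.table(
    data.frame(gene_id = names(strata$assignment),
               stratum = as.character(strata$assignment)),
    file.path(out_dir, "strata.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(sample_id = sample_id, seed = seed, log_transform = log_transform,
         half_window = half_window, bin_size = bin_size,
         n_genes = as.list(attr(profiles, "n_genes"))),
    file.path(out_dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(profiles)
}
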