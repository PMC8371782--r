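#' TSS zone specification
#'
#' Three zones around the TSS used to score normalization success: an
#' upstream zone (-4 kb, -1 kb), the promoter-proximal zone (-1 kb, +1 kb)
#' and a downstream zone (+1 kb, +4 kb).  Together they tile the standard
#' 8 kb profiling window exactly.
#'
#' @return A named list of `c(lo, hi)` offsets in bp relative to the TSS.
#' @export
zone_spec <- function() {
  list(zone1 = c(-4000, -1000), zone2 = c(-1000, 1000),
       zone3 = c(1000, 4000))
}

#' Area under a TSS profile within a zone
#'
#' Riemann sum: sum of (bin value x bin width) over bins whose centers
#' fall in `[zone[1], zone[2])`.
#'
#' @param profile Numeric vector of bin means covering
#'   `(-half_window, +half_window)` around the TSS.
#' @param zone Numeric `c(lo, hi)` offsets in bp relative to the TSS.
#' @param bin_size Bin width in bp (default 10).
#' @return The area (signal x bp).
#' @export
zone_auc <- function(profile, zone, bin_size = 10L) {
  nbin <- length(profile)
  half <- nbin * bin_size / 2
  centers <- -half + (seq_len(nbin) - 0.5) * bin_size
  if (zone[1] < -half || zone[2] > half) {
    stop("zone [", zone[1], ", ", zone[2], ") outside the profile extent")
  }
  inside <- centers >= zone[1] & centers < zone[2]
  sum(profile[inside]) * bin_size
}

#' Pairwise percent area differences between samples, per zone
#'
#' For every unordered sample pair the percent difference of the areas in
#' each zone is `100 * |A_i - A_j| / ((A_i + A_j) / 2)`; the pair-mean
#' denominator makes the statistic symmetric and bounded in \[0, 200\]%.
#' The reported per-zone statistic is the average over all pairs.  A pair
#' whose areas are both zero contributes 0% with a warning.
#'
#' @param profiles Named list of equal-length TSS profiles, one per sample.
#' @param zones Zone list as from [zone_spec()].
#' @param bin_size Bin width in bp of the profiles.
#' @return A `ZoneStats` list with, per zone, the symmetric `pairwise`
#'   percent-difference matrix and the pair-`average`; plus an `areas`
#'   matrix (zones x samples).
#' @export
zone_percent_difference <- function(profiles, zones = zone_spec(),
                                    bin_size = 10L) {
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  lens <- lengths(profiles)
  if (length(unique(lens)) != 1L) stop("profiles must have equal length")
  ids <- names(profiles)
  if (is.null(ids)) ids <- paste0("sample", seq_along(profiles))
  areas <- vapply(profiles, function(p) {
    vapply(zones, function(z) zone_auc(p, z, bin_size), numeric(1))
  }, numeric(length(zones)))
  rownames(areas) <- names(zones)
  colnames(areas) <- ids

  per_zone <- lapply(names(zones), function(zn) {
    a <- areas[zn, ]
    n <- length(a)
    pd <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        denom <- (a[i] + a[j]) / 2
        d <- if (denom == 0) {
          warning("both areas zero in ", zn, " for pair ", ids[i], "/",
                  ids[j], "; percent difference set to 0")
          0
        } else {
          100 * abs(a[i] - a[j]) / denom
        }
        pd[i, j] <- d
        pd[j, i] <- d
      }
    }
    list(pairwise = pd, average = mean(pd[upper.tri(pd)]))
  })
  names(per_zone) <- names(zones)
  structure(list(zones = per_zone, areas = areas), class = "ZoneStats")
}

#' @export
print.ZoneStats <- function(x, ...) {
  for (zn in names(x$zones)) {
    cat(sprintf("%s: average percent difference %.3g%%\n",
                zn, x$zones[[zn]]$average))
  }
  invisible(x)
}

#' Average percent differences per zone as a named vector
#' @param stats A `ZoneStats`.
#' @return Named numeric vector (one value per zone, in %).
#' @export
zone_averages <- function(stats) {
  stopifnot(inherits(stats, "ZoneStats"))
  vapply(stats$zones, function(z) z$average, numeric(1))
}

.profile_frame <- function(profiles, bin_size, panel) {
  nbin <- length(profiles[[1L]])
  half <- nbin * bin_size / 2
  pos <- -half + (seq_len(nbin) - 0.5) * bin_size
  do.call(rbind, lapply(names(profiles), function(id) {
    data.frame(position = pos, signal = profiles[[id]], sample = id,
               panel = panel, stringsAsFactors = FALSE)
  }))
}

#' Plot TSS profiles before and after normalization
#'
#' Overlays per-sample average TSS profiles with zone boundaries, one
#' panel for the unnormalized and one for the normalized profiles.
#' Written as both SVG and PNG.
#'
#' @param profiles_before Named list of profiles before normalization.
#' @param profiles_after Named list of profiles after normalization (may
#'   be `NULL` for a before-only figure).
#' @param out_prefix Output path prefix; `<prefix>.svg` and `<prefix>.png`
#'   are written.
#' @param zones Zone list for boundary lines.
#' @param bin_size Bin width in bp of the profiles.
#' @return Paths of the written files, invisibly.
#' @export
plot_before_after <- function(profiles_before, profiles_after, out_prefix,
                              zones = zone_spec(), bin_size = 10L) {
  df <- .profile_frame(profiles_before, bin_size, "before normalization")
  if (!is.null(profiles_after) && length(profiles_after) > 0) {
    df <- rbind(df, .profile_frame(profiles_after, bin_size,
                                   "after normalization"))
  }
  df$panel <- factor(df$panel,
                     levels = c("before normalization",
                                "after normalization"))
  bounds <- sort(unique(unlist(zones)))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$position, y = .data$signal, colour = .data$sample)) +
    ggplot2::geom_vline(xintercept = bounds, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1) +
    ggplot2::labs(x = "position relative to TSS (bp)",
                  y = "mean signal", colour = NULL) +
    ggplot2::theme_bw()
  paths <- .save_figure(p, out_prefix)
  invisible(paths)
}

# Write a ggplot as <prefix>.svg and <prefix>.png using base devices
# (cairo), returning both paths.
.save_figure <- function(p, out_prefix, width = 7, height = 5) {
  svg_path <- paste0(out_prefix, ".svg")
  png_path <- paste0(out_prefix, ".png")
  grDevices::svg(svg_path, width = width, height = height)
  print(p)
  grDevices::dev.off()
  grDevices::png(png_path, width = width * 100, height = height * 100,
                 res = 100, type = "cairo")
  print(p)
  grDevices::dev.off()
  c(svg = svg_path, png = png_path)
}
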