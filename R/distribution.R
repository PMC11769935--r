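#' Normalize a histogram into a fragment-size distribution
#'
#' Scales per-size counts so the densities sum to exactly 1 for the sample,
#' putting samples of different depth on a common footing.
#'
#' @param hist A [frag_histogram()] with `total > 0`.
#' @return A `frag_distribution`: list with `sample_id`, `sizes`, `density`.
#' @examples
#' d <- normalize_histogram(frag_histogram(c(`100` = 1, `200` = 3)))
#' d$density[d$sizes %in% c(100, 200)]
#' @export
normalize_histogram <- function(hist) {
  stopifnot(inherits(hist, "frag_histogram"))
  if (hist$total <= 0) stop_arg("empty sample: histogram total is 0")
  frag_distribution(hist$counts / hist$total, sizes = hist$sizes,
                    sample_id = hist$sample_id)
}

#' Construct a fragment-size distribution
#'
#' @param density Non-negative densities per 1-bp size, summing to 1
#'   (within 1e-9).
#' @param sizes Integer size grid in bp; default `74:439`.
#' @param sample_id Sample identifier.
#' @return A `frag_distribution` object.
#' @export
frag_distribution <- function(density, sizes = 74:439, sample_id = "sample") {
  if (length(density) != length(sizes))
    stop_arg("density length (%d) != grid length (%d)",
             length(density), length(sizes))
  if (any(density < 0)) stop_arg("densities must be non-negative")
  if (abs(sum(density) - 1) > 1e-9)
    stop_arg("densities must sum to 1 (got %.12f)", sum(density))
  structure(list(sample_id = sample_id, sizes = as.integer(sizes),
                 density = as.numeric(density)),
            class = "frag_distribution")
}

#' @export
print.frag_distribution <- function(x, ...) {
  cat(sprintf("Fragment-size distribution: %s\n", x$sample_id))
  cat(sprintf("  grid [%d, %d] bp; mode at %d bp (density %.4f)\n",
              min(x$sizes), max(x$sizes),
              x$sizes[which.max(x$density)], max(x$density)))
  invisible(x)
}

#' @export
plot.frag_distribution <- function(x, ..., xlab = "Fragment size (bp)",
                                   ylab = "Density", type = "l") {
  graphics::plot(x$sizes, x$density, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Rebin a 1-bp distribution into fixed-width bins
#'
#' Aggregates 1-bp densities into half-open bins `[start, start + width)`
#' anchored at the grid minimum, the resolution used for display (width 5
#' over 74-439 bp gives 73 full bins starting 74, 79, ..., 434, plus the
#' single trailing size 439 folded into the last bin).
#'
#' @param dist A [frag_distribution()].
#' @param width Bin width in bp (default 5).
#' @return A `binned_distribution`: list with `bin_starts`, `width`,
#'   `density`.
#' @examples
#' d <- normalize_histogram(frag_histogram(c(`78` = 1)))
#' b <- bin_distribution(d)
#' b$density[b$bin_starts == 74]
#' @export
bin_distribution <- function(dist, width = 5L) {
  stopifnot(inherits(dist, "frag_distribution"))
  check_number(width, "width", lower = 1)
  width <- as.integer(width)
  lo <- min(dist$sizes)
  idx <- (dist$sizes - lo) %/% width
  n_full <- (max(dist$sizes) - lo + 1L) %/% width
  idx[idx >= n_full] <- n_full - 1L  # fold trailing partial bin into the last
  dens <- as.numeric(tapply(dist$density, factor(idx, levels = 0:(n_full - 1L)), sum))
  dens[is.na(dens)] <- 0
  structure(list(bin_starts = lo + width * (0:(n_full - 1L)),
                 width = width, density = dens,
                 sample_id = dist$sample_id),
            class = "binned_distribution")
}

#' Cohort mean and dispersion of fragment-size distributions
#'
#' Per-size arithmetic mean and sample (n-1 denominator) standard deviation
#' over a group of samples on a common grid; the group curves drawn in
#' cohort overview figures.
#'
#' @param dists List of [frag_distribution()] objects on identical grids.
#' @param group_label Label for the group (e.g. "normal",
#'   "hemangiosarcoma").
#' @return A `cohort_summary`: list with `group_label`, `sizes`,
#'   `mean_density`, `sd_density`, `n_samples`. For a single sample the sd
#'   is defined as 0 (with a warning).
#' @export
cohort_summary <- function(dists, group_label = "cohort") {
  if (!length(dists)) stop_arg("need at least one distribution")
  if (!all(vapply(dists, inherits, logical(1), "frag_distribution")))
    stop_arg("all elements must be frag_distribution objects")
  grid <- dists[[1]]$sizes
  ok <- vapply(dists, function(d) identical(d$sizes, grid), logical(1))
  if (!all(ok)) stop_arg("distributions are on different size grids")
  m <- vapply(dists, `[[`, numeric(length(grid)), "density")
  m <- matrix(m, nrow = length(grid))
  mu <- rowMeans(m)
  if (ncol(m) == 1L) {
    warning("single-sample cohort: standard deviation set to 0")
    sdv <- numeric(length(grid))
  } else {
    sdv <- apply(m, 1, stats::sd)
  }
  structure(list(group_label = group_label, sizes = grid,
                 mean_density = mu, sd_density = sdv, n_samples = ncol(m)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary: %s (n = %d)\n", x$group_label, x$n_samples))
  cat(sprintf("  mean-curve mode at %d bp (density %.4f)\n",
              x$sizes[which.max(x$mean_density)], max(x$mean_density)))
  invisible(x)
}

#' Mean distribution of a cohort as a frag_distribution
#'
#' @param summary A [cohort_summary()].
#' @return A [frag_distribution()] holding the cohort mean curve (renormalized
#'   against numerical drift, which is below 1e-12 for valid inputs).
#' @export
cohort_mean_distribution <- function(summary) {
  stopifnot(inherits(summary, "cohort_summary"))
  frag_distribution(summary$mean_density / sum(summary$mean_density),
                    sizes = summary$sizes,
                    sample_id = paste0(summary$group_label, "_mean"))
}

#' Plot cohort mean curves with dispersion ribbons
#'
#' @param x A `cohort_summary`.
#' @param add Logical; add to an existing plot.
#' @param col,band_col Line and ribbon colours.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cohort_summary <- function(x, add = FALSE, col = "black",
                                band_col = grDevices::adjustcolor(col, 0.3),
                                ...) {
  lo <- pmax(x$mean_density - x$sd_density, 0)
  hi <- x$mean_density + x$sd_density
  if (!add)
    graphics::plot(x$sizes, x$mean_density, type = "n", ylim = c(0, max(hi)),
                   xlab = "Fragment size (bp)", ylab = "Density", ...)
  graphics::polygon(c(x$sizes, rev(x$sizes)), c(hi, rev(lo)),
                    col = band_col, border = NA)
  graphics::lines(x$sizes, x$mean_density, col = col, lwd = 2)
  invisible(x)
}

#' Proportion of fragments below a size threshold
#'
#' Sum of density strictly below `threshold_bp`. The 174 bp default marks the
#' short-fragment regime enriched in tumor-derived cfDNA.
#'
#' @param dist A [frag_distribution()].
#' @param threshold_bp Threshold in bp (default 174); must lie within the
#'   grid.
#' @return Numeric fraction in `[0, 1]`.
#' @examples
#' d <- normalize_histogram(frag_histogram(c(`160` = 1)))
#' proportion_below(d)          # 1: all mass below 174
#' @export
proportion_below <- function(dist, threshold_bp = 174L) {
  stopifnot(inherits(dist, "frag_distribution"))
  if (threshold_bp < min(dist$sizes) || threshold_bp > max(dist$sizes) + 1L)
    stop_arg("threshold %d outside grid [%d, %d]",
             threshold_bp, min(dist$sizes), max(dist$sizes))
  sum(dist$density[dist$sizes < threshold_bp])
}

#' Read and write cohort manifests
#'
#' A manifest is a TSV with columns `sample_id`, `group` (one of `normal`,
#' `hemangiosarcoma`, `post_operative`) and `path` (per-sample histogram
#' TSV, relative paths resolved against the manifest location).
#'
#' @param path Manifest file path.
#' @return A data frame with columns `sample_id`, `group`, `path`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_arg("manifest not found: %s", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "path")
  if (!all(need %in% names(m)))
    stop_arg("manifest needs columns: %s", paste(need, collapse = ", "))
  if (!nrow(m)) stop_arg("manifest is empty")
  bad <- setdiff(unique(m$group), c("normal", "hemangiosarcoma", "post_operative"))
  if (length(bad))
    stop_arg("unknown group label(s): %s", paste(bad, collapse = ", "))
  rel <- !file.exists(m$path) & file.exists(file.path(dirname(path), m$path))
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}

#' @rdname read_manifest
#' @param manifest Data frame with columns `sample_id`, `group`, `path`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest[, c("sample_id", "group", "path")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
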