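#' Define a feature set over the fragment-size grid
#'
#' Three kinds of feature sets are used for classification: the full 1-bp
#' grid (366 densities per sample), a list of selected positions (e.g. the
#' oscillation peaks and valleys), or 5-bp bin densities.
#'
#' @param name Feature-set name.
#' @param kind One of `"full_grid"`, `"positions"`, `"bins"`.
#' @param positions Integer bp positions (required for `kind =
#'   "positions"`); must be unique and inside `[74, 439]`.
#' @param bin_width Bin width for `kind = "bins"` (default 5).
#' @param description Free-text description.
#' @return A `feature_spec` object.
#' @export
feature_spec <- function(name, kind = c("full_grid", "positions", "bins"),
                         positions = NULL, bin_width = 5L, description = "") {
  kind <- match.arg(kind)
  if (kind == "positions") {
    if (is.null(positions) || !length(positions))
      stop_arg("kind = 'positions' requires `positions`")
    positions <- as.integer(positions)
    if (anyDuplicated(positions)) stop_arg("duplicate feature positions")
    if (any(positions < 74L) || any(positions > 439L))
      stop_arg("feature positions must lie in [74, 439]")
    positions <- sort(positions)
  }
  structure(list(name = name, kind = kind, positions = positions,
                 bin_width = as.integer(bin_width),
                 description = description),
            class = "feature_spec")
}

#' Canine peak/valley feature positions from oscillation profiles
#'
#' Derives the dog-specific classification feature set from detected
#' oscillation profiles of the two groups: the sub-peak positions of both
#' groups plus both principal peaks form the peak features, and the valley
#' positions of both groups the valley features. When the two groups share
#' all eight sub-peak positions this yields 10 peak positions; valley
#' positions typically differ slightly between groups, giving ~11 valley
#' features.
#'
#' @param profile_normal,profile_tumor `oscillation_profile` objects.
#' @param name Feature-set name.
#' @return A `feature_spec` of kind `"positions"`.
#' @export
dog_feature_spec <- function(profile_normal, profile_tumor,
                             name = "dog_peaks_valleys") {
  stopifnot(inherits(profile_normal, "oscillation_profile"),
            inherits(profile_tumor, "oscillation_profile"))
  peaks <- sort(unique(c(profile_normal$cycles$peak_bp,
                         profile_tumor$cycles$peak_bp,
                         profile_normal$main_peak_bp,
                         profile_tumor$main_peak_bp)))
  valleys <- sort(unique(c(profile_normal$cycles$valley_bp,
                           profile_tumor$cycles$valley_bp)))
  feature_spec(name, "positions", positions = unique(c(peaks, valleys)),
               description = sprintf("%d peak + %d valley positions derived from canine oscillation profiles",
                                     length(peaks), length(setdiff(valleys, peaks))))
}

#' Human-analog peak/valley feature positions
#'
#' A 14-position feature set (seven peaks, seven valleys) analogous to the
#' peak/valley positions reported for human cfDNA oscillations. The exact
#' published human positions are not redistributed here; the default is a
#' synthetic stand-in built from the ~10.4 bp nucleosomal periodicity below
#' the 167 bp human main peak, and real positions can be supplied directly.
#'
#' @param peaks,valleys Integer positions in bp (seven each by convention).
#' @param name Feature-set name.
#' @return A `feature_spec` of kind `"positions"`.
#' @export
human_feature_spec <- function(peaks = c(84, 94, 104, 115, 125, 136, 146),
                               valleys = c(89, 99, 110, 120, 131, 141, 151),
                               name = "human_peaks_valleys") {
  feature_spec(name, "positions", positions = c(peaks, valleys),
               description = "synthetic stand-in for published human cfDNA peak/valley positions")
}

#' Build a sample-by-feature matrix from fragment-size distributions
#'
#' @param dists List of [frag_distribution()] objects on a common grid.
#' @param labels Binary labels, 1 = hemangiosarcoma (positive), 0 = normal;
#'   or a character vector of group labels (`"normal"` mapped to 0,
#'   everything else to 1).
#' @param spec A [feature_spec()].
#' @return A `feature_matrix`: list with `values` (numeric matrix),
#'   `sample_ids`, `labels` (0/1 integer), `feature_names`,
#'   `feature_positions` (bp per column, NA for non-positional), `spec`.
#' @export
build_feature_matrix <- function(dists, labels, spec = feature_spec("full_grid")) {
  stopifnot(inherits(spec, "feature_spec"))
  if (!length(dists)) stop_arg("no distributions supplied")
  if (length(labels) != length(dists))
    stop_arg("labels length (%d) != number of samples (%d)",
             length(labels), length(dists))
  if (is.character(labels) || is.factor(labels))
    labels <- as.integer(as.character(labels) != "normal")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop_arg("labels must be binary 0/1")
  grid <- dists[[1]]$sizes
  if (!all(vapply(dists, function(d) identical(d$sizes, grid), logical(1))))
    stop_arg("distributions are on different size grids")

  if (spec$kind == "full_grid") {
    vals <- t(vapply(dists, `[[`, numeric(length(grid)), "density"))
    pos <- grid
  } else if (spec$kind == "positions") {
    idx <- match(spec$positions, grid)
    if (anyNA(idx))
      stop_arg("positions off-grid: %s",
               paste(spec$positions[is.na(idx)], collapse = ", "))
    vals <- t(vapply(dists, function(d) d$density[idx],
                     numeric(length(idx))))
    pos <- spec$positions
  } else {
    binned <- lapply(dists, bin_distribution, width = spec$bin_width)
    pos <- binned[[1]]$bin_starts
    vals <- t(vapply(binned, `[[`, numeric(length(pos)), "density"))
  }
  vals <- matrix(vals, nrow = length(dists))
  ids <- vapply(dists, `[[`, character(1), "sample_id")
  colnames(vals) <- paste0("bp_", pos)
  rownames(vals) <- ids
  if (anyNA(vals)) stop_arg("feature matrix contains missing values")
  structure(list(values = vals, sample_ids = ids, labels = labels,
                 feature_names = colnames(vals),
                 feature_positions = as.integer(pos), spec = spec),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix '%s': %d samples x %d features (%d positive)\n",
              x$spec$name, nrow(x$values), ncol(x$values), sum(x$labels)))
  invisible(x)
}

# column-standardize with train statistics; zero-variance columns pass through
.standardize <- function(train, test = NULL) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  out <- list(train = sweep(sweep(train, 2, mu), 2, sdv, "/"))
  if (!is.null(test)) out$test <- sweep(sweep(test, 2, mu), 2, sdv, "/")
  out
}

# stratified index sample: `fraction` of each class, at least one per class
.stratified_sample <- function(labels, fraction) {
  unlist(lapply(split(seq_along(labels), labels), function(ix) {
    k <- max(1L, round(length(ix) * fraction))
    sample(ix, k)
  }), use.names = FALSE)
}

# one linear-SVM RFE pass: returns indices of the surviving features
.rfe_once <- function(x, y, n_keep, drop_fraction) {
  surviving <- seq_len(ncol(x))
  yf <- factor(y, levels = c(0, 1))
  while (length(surviving) > n_keep) {
    fit <- e1071::svm(x[, surviving, drop = FALSE], yf, kernel = "linear",
                      scale = FALSE, cost = 1)
    w <- t(fit$coefs) %*% fit$SV        # primal weights of the linear SVM
    rank_w <- as.numeric(w)^2
    n_drop <- max(1L, floor(length(surviving) * drop_fraction))
    n_drop <- min(n_drop, length(surviving) - n_keep)
    surviving <- surviving[order(rank_w, decreasing = TRUE)]
    surviving <- sort(surviving[seq_len(length(surviving) - n_drop)])
  }
  surviving
}

#' Repeated SVM-RFE feature-region discovery
#'
#' Runs recursive feature elimination with a linear maximum-margin
#' classifier on repeated stratified random subsets of the cohort (default
#' 100 iterations at 70% training fraction), aggregates how often each
#' feature survives to the final set, and merges high-frequency positions
#' into maximal contiguous bp regions. This is the discovery procedure that
#' isolates the discriminative fragment-size regions (third oscillation
#' peak, the ~174 bp crossover, and the 336-395 bp long-fragment window in
#' canine hemangiosarcoma cohorts).
#'
#' @param fm A [build_feature_matrix()] result.
#' @param n_iterations Number of repeated subsample+RFE runs (default 100).
#' @param train_fraction Stratified subsample fraction (default 0.7).
#' @param n_keep Features retained by each RFE run (default 20).
#' @param drop_fraction Fraction of remaining features eliminated per RFE
#'   step (default 0.1).
#' @param frequency_cutoff Selection frequency at or above which a position
#'   enters a region (default 0.5).
#' @param gap_tolerance Maximum bp gap bridged when merging selected
#'   positions into regions (default 2).
#' @param seed Integer seed; every iteration derives its own subseed.
#' @return An `rfe_selection`: list with `frequency` (per feature),
#'   `positions`, `selected` (logical), `regions` (data frame `start_bp`,
#'   `end_bp`, inclusive), and the parameters.
#' @export
svm_rfe_select <- function(fm, n_iterations = 100L, train_fraction = 0.7,
                           n_keep = 20L, drop_fraction = 0.1,
                           frequency_cutoff = 0.5, gap_tolerance = 2L,
                           seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (length(unique(fm$labels)) < 2L)
    stop_arg("both classes required for stratified subsampling")
  if (min(table(fm$labels)) < 2L)
    stop_arg("need at least 2 samples per class")
  check_number(train_fraction, "train_fraction", lower = 1e-6, upper = 1)
  nf <- ncol(fm$values)
  hits <- numeric(nf)
  for (it in seq_len(n_iterations)) {
    idx <- with_seed(derive_seed(seed, paste0("rfe_", it)),
                     .stratified_sample(fm$labels, train_fraction))
    x <- .standardize(fm$values[idx, , drop = FALSE])$train
    surv <- .rfe_once(x, fm$labels[idx], min(n_keep, nf), drop_fraction)
    hits[surv] <- hits[surv] + 1
  }
  freq <- hits / n_iterations
  selected <- freq >= frequency_cutoff
  regions <- merge_positions(fm$feature_positions[selected], gap_tolerance)
  structure(list(frequency = stats::setNames(freq, fm$feature_names),
                 positions = fm$feature_positions, selected = selected,
                 regions = regions,
                 n_iterations = n_iterations, train_fraction = train_fraction,
                 n_keep = n_keep, frequency_cutoff = frequency_cutoff,
                 gap_tolerance = gap_tolerance, seed = seed),
            class = "rfe_selection")
}

#' @export
print.rfe_selection <- function(x, ...) {
  cat(sprintf("SVM-RFE selection over %d iterations (train fraction %.2f)\n",
              x$n_iterations, x$train_fraction))
  cat(sprintf("  %d/%d positions at frequency >= %.2f; %d region(s)\n",
              sum(x$selected), length(x$selected), x$frequency_cutoff,
              nrow(x$regions)))
  if (nrow(x$regions)) print(x$regions, row.names = FALSE)
  invisible(x)
}

#' Merge selected positions into maximal contiguous regions
#'
#' Sorted positions are grouped into maximal runs in which consecutive
#' positions are at most `gap_tolerance + 1` bp apart (i.e. gaps of up to
#' `gap_tolerance` missing positions are bridged). Idempotent: merging the
#' positions of the output regions reproduces them.
#'
#' @param positions Integer bp positions.
#' @param gap_tolerance Maximum bridged gap in bp (default 2).
#' @return Data frame with `start_bp`, `end_bp` (inclusive), `n_positions`.
#' @export
merge_positions <- function(positions, gap_tolerance = 2L) {
  if (!length(positions))
    return(data.frame(start_bp = integer(), end_bp = integer(),
                      n_positions = integer()))
  p <- sort(unique(as.integer(positions)))
  brk <- c(0L, which(diff(p) > gap_tolerance + 1L), length(p))
  out <- lapply(seq_len(length(brk) - 1L), function(i) {
    seg <- p[(brk[i] + 1L):brk[i + 1L]]
    data.frame(start_bp = seg[1], end_bp = seg[length(seg)],
               n_positions = length(seg))
  })
  do.call(rbind, out)
}

#' Per-position fold change between two cohort summaries
#'
#' Ratio of group mean densities (A over B) on a bp region; used to verify
#' the 5-20x excess of control-fragment density in the selected regions.
#' Positions where the denominator is 0 yield `Inf` and are flagged.
#'
#' @param summary_a,summary_b [cohort_summary()] objects on a common grid.
#' @param region Length-2 inclusive bp range (default: whole grid).
#' @return Data frame with `size_bp`, `ratio`, `infinite` (logical).
#' @export
fold_change_screen <- function(summary_a, summary_b, region = NULL) {
  stopifnot(inherits(summary_a, "cohort_summary"),
            inherits(summary_b, "cohort_summary"))
  if (!identical(summary_a$sizes, summary_b$sizes))
    stop_arg("cohort summaries are on different grids")
  keep <- if (is.null(region)) seq_along(summary_a$sizes)
  else which(summary_a$sizes >= region[1] & summary_a$sizes <= region[2])
  num <- summary_a$mean_density[keep]
  den <- summary_b$mean_density[keep]
  ratio <- ifelse(den > 0, num / den, Inf)
  data.frame(size_bp = summary_a$sizes[keep], ratio = ratio,
             infinite = !is.finite(ratio))
}
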