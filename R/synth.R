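#' Generative parameters for a cfDNA fragment-size profile
#'
#' A fragment-size density on the 1-bp grid `[74, 439]` is modelled as a
#' normalized mixture of four components: an exponential short-fragment
#' floor, a Gaussian mono-nucleosome main peak, a Gaussian di-nucleosome
#' shoulder, and narrow Gaussian sub-peaks producing the ~10-bp oscillation
#' left of the main peak. Defaults encode the structure observed in canine
#' cohorts: normal profiles peak at 165 bp; hemangiosarcoma profiles peak at
#' 160 bp with roughly doubled sub-peak mass and a sharper main peak. The
#' per-cycle sub-peak weights default to the published reference peak
#' densities of the matching group (see [canine_reference_cycles()]),
#' rescaled to the component's total mass.
#'
#' @param group `"normal"` or `"tumor"`; selects the default parameter set.
#' @param main_peak_bp Mono-nucleosome mode (bp).
#' @param main_peak_sd Main-peak Gaussian sd (bp).
#' @param main_weight Mixture mass of the main peak.
#' @param dinucleosome_bp,dinucleosome_sd,dinucleosome_weight Di-nucleosome
#'   shoulder location (bp), width (bp) and mixture mass.
#' @param subpeak_positions Sub-peak centres (bp), default the eight
#'   reference cycle positions 81...154.
#' @param subpeak_weights Relative mass per sub-peak (rescaled to
#'   `subpeak_mass`).
#' @param subpeak_mass Total mixture mass of all sub-peaks.
#' @param subpeak_sd Sub-peak Gaussian sd (bp).
#' @param baseline_weight Mixture mass of the exponential floor.
#' @param baseline_decay Decay length (bp) of the floor.
#' @param size_min,size_max Grid limits (bp).
#' @return A `profile_params` object.
#' @export
profile_params <- function(group = c("normal", "tumor"),
                           main_peak_bp = NULL, main_peak_sd = NULL,
                           main_weight = NULL,
                           dinucleosome_bp = 332, dinucleosome_sd = 18,
                           dinucleosome_weight = NULL,
                           subpeak_positions = c(81, 91, 102, 112, 122, 133, 144, 154),
                           subpeak_weights = NULL,
                           subpeak_mass = NULL, subpeak_sd = 1.2,
                           baseline_weight = NULL, baseline_decay = 150,
                           size_min = 74L, size_max = 439L) {
  group <- match.arg(group)
  if (group == "normal") {
    main_peak_bp <- main_peak_bp %||% 165
    main_peak_sd <- main_peak_sd %||% 11
    main_weight <- main_weight %||% 0.52
    dinucleosome_weight <- dinucleosome_weight %||% 0.13
    subpeak_mass <- subpeak_mass %||% 0.05
    baseline_weight <- baseline_weight %||% 0.30
    ref <- canine_reference_cycles("normal")
  } else {
    main_peak_bp <- main_peak_bp %||% 160
    main_peak_sd <- main_peak_sd %||% 6.5
    main_weight <- main_weight %||% 0.50
    dinucleosome_weight <- dinucleosome_weight %||% 0.10
    subpeak_mass <- subpeak_mass %||% 0.13
    baseline_weight <- baseline_weight %||% 0.27
    ref <- canine_reference_cycles("hemangiosarcoma")
  }
  if (is.null(subpeak_weights)) {
    subpeak_weights <-
      if (length(subpeak_positions) == nrow(ref)) ref$peak_density
      else rep(1, length(subpeak_positions))
  }
  if (main_peak_sd <= 0 || dinucleosome_sd <= 0 || subpeak_sd <= 0)
    stop_arg("component standard deviations must be positive")
  if (length(subpeak_weights) != length(subpeak_positions))
    stop_arg("subpeak_weights and subpeak_positions lengths differ")
  if (any(c(main_weight, dinucleosome_weight, subpeak_mass, baseline_weight,
            subpeak_weights) < 0))
    stop_arg("all component weights must be non-negative")
  structure(list(group = group, main_peak_bp = main_peak_bp,
                 main_peak_sd = main_peak_sd, main_weight = main_weight,
                 dinucleosome_bp = dinucleosome_bp,
                 dinucleosome_sd = dinucleosome_sd,
                 dinucleosome_weight = dinucleosome_weight,
                 subpeak_positions = subpeak_positions,
                 subpeak_weights = subpeak_weights,
                 subpeak_mass = subpeak_mass, subpeak_sd = subpeak_sd,
                 baseline_weight = baseline_weight,
                 baseline_decay = baseline_decay,
                 size_min = as.integer(size_min),
                 size_max = as.integer(size_max)),
            class = "profile_params")
}

# one grid-normalized Gaussian component
.gauss_on_grid <- function(sizes, mu, sd) {
  d <- stats::dnorm(sizes, mu, sd)
  d / sum(d)
}

#' Build a fragment-size density from generative parameters
#'
#' Evaluates each mixture component on the grid, normalizes it to unit mass,
#' and combines with the configured weights (themselves renormalized to sum
#' to 1), yielding an exact probability vector.
#'
#' @param params A [profile_params()].
#' @return A [frag_distribution()].
#' @examples
#' p <- build_profile(profile_params("normal"))
#' detect_main_peak(p)  # 165
#' @export
build_profile <- function(params) {
  stopifnot(inherits(params, "profile_params"))
  sizes <- seq.int(params$size_min, params$size_max)
  floor_d <- exp(-(sizes - params$size_min) / params$baseline_decay)
  floor_d <- floor_d / sum(floor_d)
  main_d <- .gauss_on_grid(sizes, params$main_peak_bp, params$main_peak_sd)
  di_d <- .gauss_on_grid(sizes, params$dinucleosome_bp, params$dinucleosome_sd)
  dens <- params$baseline_weight * floor_d + params$main_weight * main_d +
    params$dinucleosome_weight * di_d
  if (length(params$subpeak_positions) && params$subpeak_mass > 0 &&
      sum(params$subpeak_weights) > 0) {
    w <- params$subpeak_weights / sum(params$subpeak_weights) * params$subpeak_mass
    for (j in seq_along(params$subpeak_positions))
      dens <- dens + w[j] * .gauss_on_grid(sizes, params$subpeak_positions[j],
                                           params$subpeak_sd)
  }
  dens <- dens / sum(dens)
  frag_distribution(dens, sizes = sizes,
                    sample_id = paste0("profile_", params$group))
}

#' Draw a fragment-length histogram from a profile mixture
#'
#' Multinomial sampling of `n_fragments` from the per-sample mixture
#' `(1 - f) * background + f * profile`, modelling a plasma sample whose
#' cfDNA is a tumor fraction `f` of tumor-derived fragments on a healthy
#' background.
#'
#' @param profile [frag_distribution()] sampled with weight
#'   `tumor_fraction`.
#' @param n_fragments Number of fragments to draw.
#' @param tumor_fraction Mixing weight in `[0, 1]` (default 1: pure
#'   profile).
#' @param background_profile [frag_distribution()] for the `1 - f`
#'   component; required when `tumor_fraction < 1`.
#' @param seed Integer seed.
#' @param sample_id Sample identifier.
#' @return A [frag_histogram()].
#' @export
sample_histogram <- function(profile, n_fragments, tumor_fraction = 1,
                             background_profile = NULL, seed = 1L,
                             sample_id = "synthetic") {
  stopifnot(inherits(profile, "frag_distribution"))
  check_number(n_fragments, "n_fragments", lower = 1)
  check_number(tumor_fraction, "tumor_fraction", lower = 0, upper = 1)
  mix <- profile$density * tumor_fraction
  if (tumor_fraction < 1) {
    if (is.null(background_profile))
      stop_arg("background_profile required when tumor_fraction < 1")
    stopifnot(inherits(background_profile, "frag_distribution"))
    if (!identical(background_profile$sizes, profile$sizes))
      stop_arg("profile and background grids differ")
    mix <- mix + (1 - tumor_fraction) * background_profile$density
  }
  cnt <- with_seed(seed, stats::rmultinom(1, size = n_fragments, prob = mix))
  frag_histogram(as.integer(cnt), sample_id = sample_id,
                 size_min = min(profile$sizes), size_max = max(profile$sizes))
}

#' Configuration of a synthetic cfDNA cohort
#'
#' Defaults reproduce the study design of the canine hemangiosarcoma cohort:
#' 36 normal and 21 tumor samples, 2e6 fragments per sample (the
#' fragment-count scale of ~2x canine WGS after filtering is far larger;
#' 2e6 is ample for 1-bp densities with sampling error ~1e-4), per-tumor
#' tumor fractions drawn from Beta(5, 2), and mild lognormal jitter of the
#' mixture weights between samples.
#'
#' @param n_normal,n_tumor Samples per group (defaults 36, 21).
#' @param fragments_per_sample Multinomial draw size (default 2e6).
#' @param tumor_fraction_shape Beta shape parameters of per-tumor fractions
#'   (default c(5, 2)).
#' @param jitter_sd Sd of the per-sample lognormal perturbation applied to
#'   component weights (default 0.05; 0 disables jitter).
#' @param seed Master seed.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_normal = 36L, n_tumor = 21L,
                          fragments_per_sample = 2e6,
                          tumor_fraction_shape = c(5, 2),
                          jitter_sd = 0.05, seed = 1L) {
  check_number(n_normal, "n_normal", lower = 1)
  check_number(n_tumor, "n_tumor", lower = 0)
  check_number(fragments_per_sample, "fragments_per_sample", lower = 1)
  check_number(jitter_sd, "jitter_sd", lower = 0)
  structure(list(n_normal = as.integer(n_normal), n_tumor = as.integer(n_tumor),
                 fragments_per_sample = fragments_per_sample,
                 tumor_fraction_shape = tumor_fraction_shape,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "cohort_config")
}

.jitter_params <- function(params, jitter_sd, seed) {
  if (jitter_sd <= 0) return(params)
  f <- with_seed(seed, exp(stats::rnorm(4, 0, jitter_sd)))
  params$baseline_weight <- params$baseline_weight * f[1]
  params$main_weight <- params$main_weight * f[2]
  params$dinucleosome_weight <- params$dinucleosome_weight * f[3]
  params$subpeak_mass <- params$subpeak_mass * f[4]
  params
}

#' Generate a labeled synthetic cohort of fragment histograms
#'
#' Builds per-sample profiles (group defaults plus per-sample weight
#' jitter), mixes each tumor sample's profile into the normal background at
#' its drawn tumor fraction, samples multinomial histograms at the
#' configured depth, and returns histograms, labels and a truth record for
#' parameter-recovery tests. A pure function of `(config, params, seed)`.
#'
#' @param config A [cohort_config()].
#' @param normal_params,tumor_params [profile_params()] for the two groups.
#' @return A `synthetic_cohort`: list with `histograms` (named list of
#'   [frag_histogram()]), `truth` (data frame: `sample_id`, `group`,
#'   `tumor_fraction`), and `config`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            normal_params = profile_params("normal"),
                            tumor_params = profile_params("tumor")) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_normal + config$n_tumor
  ids <- c(sprintf("normal_%02d", seq_len(config$n_normal)),
           sprintf("hsa_%02d", seq_len(config$n_tumor)))
  grp <- c(rep("normal", config$n_normal),
           rep("hemangiosarcoma", config$n_tumor))
  tf <- numeric(n)
  if (config$n_tumor > 0) {
    tf[grp == "hemangiosarcoma"] <- with_seed(
      derive_seed(config$seed, "tumor_fraction"),
      stats::rbeta(config$n_tumor, config$tumor_fraction_shape[1],
                   config$tumor_fraction_shape[2]))
  }
  hists <- vector("list", n)
  names(hists) <- ids
  for (i in seq_len(n)) {
    s_bg <- derive_seed(config$seed, paste0("bg_", ids[i]))
    bg <- build_profile(.jitter_params(normal_params, config$jitter_sd, s_bg))
    if (grp[i] == "normal") {
      hists[[i]] <- sample_histogram(bg, config$fragments_per_sample,
                                     tumor_fraction = 1,
                                     seed = derive_seed(config$seed, ids[i]),
                                     sample_id = ids[i])
    } else {
      s_tm <- derive_seed(config$seed, paste0("tm_", ids[i]))
      tm <- build_profile(.jitter_params(tumor_params, config$jitter_sd, s_tm))
      hists[[i]] <- sample_histogram(tm, config$fragments_per_sample,
                                     tumor_fraction = tf[i],
                                     background_profile = bg,
                                     seed = derive_seed(config$seed, ids[i]),
                                     sample_id = ids[i])
    }
  }
  structure(list(histograms = hists,
                 truth = data.frame(sample_id = ids, group = grp,
                                    tumor_fraction = tf,
                                    stringsAsFactors = FALSE),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tb <- table(x$truth$group)
  cat(sprintf("Synthetic cfDNA cohort: %s (%s fragments/sample, seed %d)\n",
              paste(sprintf("%d %s", tb, names(tb)), collapse = " + "),
              format(x$config$fragments_per_sample, big.mark = ","),
              x$config$seed))
  invisible(x)
}

#' Normalized distributions of a cohort, by group
#'
#' @param cohort A `synthetic_cohort` (or any list with `histograms` and
#'   `truth`).
#' @param group Optional group label filter.
#' @return Named list of [frag_distribution()] objects.
#' @export
cohort_distributions <- function(cohort, group = NULL) {
  keep <- if (is.null(group)) seq_len(nrow(cohort$truth))
  else which(cohort$truth$group == group)
  lapply(cohort$histograms[keep], normalize_histogram)
}

#' Write a synthetic cohort to disk
#'
#' Emits one histogram TSV per sample, a cohort manifest TSV and a truth
#' JSON; the manifest round-trips through [read_manifest()].
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(cohort$truth$sample_id, ".hist.tsv"))
  for (i in seq_along(paths))
    write_histogram_tsv(cohort$histograms[[i]], paths[i])
  manifest <- data.frame(sample_id = cohort$truth$sample_id,
                         group = cohort$truth$group,
                         path = basename(paths))
  mp <- file.path(dir, "manifest.tsv")
  write_manifest(manifest, mp)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(mp)
}
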