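# Shared fixtures, generated once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# moderate-size synthetic cohort: fast, but large enough that oscillation
# detection on the cohort mean is stable
small_cohort <- function() memo("small_cohort", generate_cohort(
  cohort_config(n_normal = 10L, n_tumor = 8L, fragments_per_sample = 5e5,
                seed = 202L)))

small_dists <- function() memo("small_dists", cohort_distributions(small_cohort()))

small_fm <- function() memo("small_fm", build_feature_matrix(
  small_dists(), small_cohort()$truth$group, feature_spec("grid", "full_grid")))

# the full default-preset cohort (36 + 21 samples, 2e6 fragments each):
# the study conditions, shared by the acceptance and null-distribution tests
default_cohort <- function() memo("default_cohort",
                                  generate_cohort(cohort_config(seed = 1L)))

default_fm <- function() memo("default_fm", build_feature_matrix(
  cohort_distributions(default_cohort()), default_cohort()$truth$group,
  feature_spec("grid", "full_grid")))

# brute-force local-extrema enumeration used as the oscillation oracle
brute_local_extrema <- function(y) {
  peaks <- integer(0); valleys <- integer(0)
  for (i in 2:(length(y) - 1L)) {
    if (y[i] > y[i - 1L] && y[i] >= y[i + 1L]) peaks <- c(peaks, i)
    if (y[i] < y[i - 1L] && y[i] <= y[i + 1L]) valleys <- c(valleys, i)
  }
  list(peaks = peaks, valleys = valleys)
}

# brute-force AUC / thresholded metrics by exhaustive pair counting
brute_metrics <- function(labels, scores, threshold = 0.5) {
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  conc <- 0
  for (i in pos) for (j in neg) {
    if (scores[i] > scores[j]) conc <- conc + 1
    else if (scores[i] == scores[j]) conc <- conc + 0.5
  }
  pred <- as.integer(scores >= threshold)
  c(auc = conc / (length(pos) * length(neg)),
    accuracy = mean(pred == labels),
    sensitivity = sum(pred == 1 & labels == 1) / length(pos),
    specificity = sum(pred == 0 & labels == 0) / length(neg))
}

# per-bin brute-force tally of interval call sets on a toy binned genome
brute_bin_states <- function(calls, bins) {
  vapply(seq_len(nrow(bins)), function(i) {
    hit <- calls$chrom == bins$chrom[i] & calls$start < bins$end[i] &
      calls$end > bins$start[i]
    if (!any(hit)) "" else paste(sort(unique(calls$state[hit])), collapse = "+")
  }, character(1))
}

make_callset <- function(sample_id, chrom, start, end, state) {
  cna_callset(data.frame(chrom = chrom, start = start, end = end,
                         state = state, stringsAsFactors = FALSE),
              sample_id = sample_id, caller_id = "test")
}
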