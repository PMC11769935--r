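#' Configuration of the synthetic binned-coverage cohort
#'
#' Generates per-sample 500 kb bin counts with GC bias and negative-binomial
#' noise on a toy genome, plus gain/loss segments spiked into a configured
#' fraction of tumor samples, so that the bias-correction, calling,
#' consensus and recurrence chain can be exercised against known truth.
#'
#' @param genome Named chromosome lengths (default [toy_genome()]: 5 x 25
#'   Mb).
#' @param bin_width Bin width in bp (default 500 kb).
#' @param mean_count Mean fragment count per bin at copy-neutral state
#'   (default 6000, the scale of 2x coverage in 500 kb bins).
#' @param dispersion Negative-binomial size parameter (default 800, i.e.
#'   ~3.5% overdispersion beyond Poisson; larger = less overdispersed).
#' @param gc_beta Beta shape parameters of per-bin GC content
#'   (default c(25, 32), mean ~0.44).
#' @param gc_bias_sd Width of the Gaussian GC efficiency curve centred at
#'   0.45 (default 0.25).
#' @param mappability_beta Beta shapes of per-bin mappability
#'   (default c(50, 3)).
#' @param spikes Data frame `chrom`, `start`, `end`, `copy_ratio`,
#'   `carrier_fraction`: segments multiplied into `copy_ratio` times the
#'   neutral mean for a `carrier_fraction` of tumor samples.
#' @param n_normal,n_tumor Cohort sizes (defaults 27 panel normals, 21
#'   tumors).
#' @param seed Master seed.
#' @return A `cna_sim_config` object.
#' @export
cna_sim_config <- function(genome = toy_genome(), bin_width = 5e5,
                           mean_count = 6000, dispersion = 800,
                           gc_beta = c(25, 32), gc_bias_sd = 0.25,
                           mappability_beta = c(50, 3),
                           spikes = default_cna_spikes(),
                           n_normal = 27L, n_tumor = 21L, seed = 1L) {
  if (nrow(spikes)) {
    need <- c("chrom", "start", "end", "copy_ratio", "carrier_fraction")
    if (!all(need %in% names(spikes)))
      stop_arg("spikes need columns: %s", paste(need, collapse = ", "))
    if (any(!spikes$chrom %in% names(genome)))
      stop_arg("spike chromosome not in genome")
    if (any(spikes$end > genome[spikes$chrom]) || any(spikes$start < 0))
      stop_arg("spike outside genome")
    if (any(spikes$copy_ratio <= 0)) stop_arg("copy_ratio must be positive")
  }
  structure(list(genome = genome, bin_width = bin_width,
                 mean_count = mean_count, dispersion = dispersion,
                 gc_beta = gc_beta, gc_bias_sd = gc_bias_sd,
                 mappability_beta = mappability_beta, spikes = spikes,
                 n_normal = as.integer(n_normal), n_tumor = as.integer(n_tumor),
                 seed = as.integer(seed)),
            class = "cna_sim_config")
}

#' Default spiked CNA truth used by the simulator
#'
#' One 5 Mb (10-bin) gain on chr2 carried by 8 of 21 tumors (passes the
#' >6-sample recurrence filter) and one 5 Mb loss on chr4 carried by 10
#' (passes), on the 5 x 25 Mb toy genome.
#'
#' @return Data frame of spike definitions.
#' @export
default_cna_spikes <- function() {
  data.frame(chrom = c("chr2", "chr4"),
             start = c(5e6, 1e7), end = c(1e7, 1.5e7),
             copy_ratio = c(1.5, 0.6),
             carrier_fraction = c(8 / 21, 10 / 21),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic binned-coverage cohort
#'
#' Draws a shared bin layout with per-bin GC and mappability, then per
#' sample negative-binomial counts with mean
#' `mean_count * gc_efficiency(gc) * copy_ratio`, where `copy_ratio` is 1
#' except inside spiked segments of carrier tumors. Carriers of each spike
#' are the first `round(carrier_fraction * n_tumor)` tumor samples, so the
#' truth is deterministic given the config.
#'
#' @param config A [cna_sim_config()].
#' @return A `cna_cohort`: list with `normals` and `tumors` (named lists of
#'   bin data frames with `gc`, `mappability`, `count`), `truth` (spike
#'   table with `carriers` listing carrier sample ids), `config`.
#' @export
generate_cna_cohort <- function(config = cna_sim_config()) {
  stopifnot(inherits(config, "cna_sim_config"))
  layout <- genome_bins(config$genome, config$bin_width)
  nb <- nrow(layout)
  layout$gc <- with_seed(derive_seed(config$seed, "gc"),
                         stats::rbeta(nb, config$gc_beta[1], config$gc_beta[2]))
  layout$mappability <- with_seed(derive_seed(config$seed, "map"),
                                  stats::rbeta(nb, config$mappability_beta[1],
                                               config$mappability_beta[2]))
  eff <- exp(-((layout$gc - 0.45)^2) / (2 * config$gc_bias_sd^2))

  spike_bins <- function(sp) which(layout$chrom == sp$chrom &
                                     layout$start < sp$end &
                                     layout$end > sp$start)
  draw <- function(id, copy) {
    mu <- config$mean_count * eff * copy
    cnt <- with_seed(derive_seed(config$seed, id),
                     stats::rnbinom(nb, mu = mu, size = config$dispersion))
    out <- layout
    out$count <- cnt
    out
  }
  normals <- stats::setNames(
    lapply(seq_len(config$n_normal), function(i)
      draw(sprintf("normal_%02d", i), rep(1, nb))),
    sprintf("normal_%02d", seq_len(config$n_normal)))

  carriers <- vector("list", nrow(config$spikes))
  tumors <- vector("list", config$n_tumor)
  names(tumors) <- sprintf("tumor_%02d", seq_len(config$n_tumor))
  for (i in seq_len(config$n_tumor)) {
    copy <- rep(1, nb)
    if (nrow(config$spikes)) for (k in seq_len(nrow(config$spikes))) {
      n_car <- round(config$spikes$carrier_fraction[k] * config$n_tumor)
      if (i <= n_car) {
        copy[spike_bins(config$spikes[k, ])] <- config$spikes$copy_ratio[k]
        carriers[[k]] <- c(carriers[[k]], names(tumors)[i])
      }
    }
    tumors[[i]] <- draw(names(tumors)[i], copy)
  }
  truth <- config$spikes
  truth$carriers <- I(carriers)
  structure(list(normals = normals, tumors = tumors, truth = truth,
                 config = config),
            class = "cna_cohort")
}

#' Run the two-caller consensus + recurrence chain on a binned cohort
#'
#' Builds the panel of normals, GC-corrects every tumor, calls states under
#' the two threshold presets, intersects the two call sets per sample, and
#' applies the cross-sample recurrence filter.
#'
#' @param cohort A [generate_cna_cohort()] result (or equivalent list).
#' @param config A [consensus_config()].
#' @param intersect Logical; intersect the two callers per sample before
#'   recurrence (default TRUE, the published order). FALSE uses the union.
#' @return List with `panel`, `consensus` (per-tumor `cna_callset`s) and
#'   `recurrence` (a `recurrence_result`).
#' @export
cna_consensus_pipeline <- function(cohort, config = consensus_config(),
                                   intersect = TRUE) {
  panel <- panel_of_normals(cohort$normals)
  consensus <- lapply(names(cohort$tumors), function(id) {
    corr <- correct_bias(cohort$tumors[[id]], panel)
    a <- call_states(corr, sample_id = id, caller_id = "caller_a")
    b <- call_states(corr, sample_id = id, caller_id = "caller_b")
    if (intersect) intersect_callsets(a, b) else union_callsets(a, b)
  })
  names(consensus) <- names(cohort$tumors)
  rec <- recurrence_filter(consensus, config)
  list(panel = panel, consensus = consensus, recurrence = rec)
}

#' Union of two call sets (alternative consensus order)
#'
#' @param a,b `cna_callset` objects for the same sample.
#' @return A `cna_callset` with per-state merged union intervals.
#' @export
union_callsets <- function(a, b) {
  out <- lapply(c("gain", "loss"), function(s) {
    g <- GenomicRanges::reduce(suppressWarnings(GenomicRanges::union(
      .calls_to_granges(a$calls, s), .calls_to_granges(b$calls, s))))
    .granges_to_calls(g, s)
  })
  cna_callset(do.call(rbind, out), sample_id = a$sample_id,
              caller_id = "union")
}
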