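#' End-to-end run configuration
#'
#' Orchestrates the full chain: cohort simulation (or manifest ingestion),
#' normalization and cohort summaries, oscillation statistics, feature
#' construction, optional SVM-RFE region discovery, the classifier bench,
#' and the CNA consensus chain. One master seed deterministically derives
#' every stage seed, so a run is a pure function of its configuration.
#'
#' @param manifest Optional cohort manifest path (see [read_manifest()]);
#'   when NULL a synthetic cohort is generated.
#' @param cohort [cohort_config()] for simulation (ignored with a
#'   manifest).
#' @param bench [bench_config()]; its seed is overridden by the master
#'   seed.
#' @param cna [cna_sim_config()] or NULL to skip the CNA stage.
#' @param consensus [consensus_config()].
#' @param run_rfe Logical: run SVM-RFE region discovery (slowest stage).
#' @param rfe_iterations Iterations for the RFE stage (default 100).
#' @param out_dir Optional output directory for TSV/BED/JSON/PNG artifacts.
#' @param seed Master seed.
#' @return A `run_config` object.
#' @export
run_config <- function(manifest = NULL, cohort = cohort_config(),
                       bench = bench_config(), cna = cna_sim_config(),
                       consensus = consensus_config(),
                       run_rfe = FALSE, rfe_iterations = 100L,
                       out_dir = NULL, seed = 1L) {
  if (!is.null(manifest) && !file.exists(manifest))
    stop_arg("manifest not found: %s", manifest)
  structure(list(manifest = manifest, cohort = cohort, bench = bench,
                 cna = cna, consensus = consensus, run_rfe = run_rfe,
                 rfe_iterations = as.integer(rfe_iterations),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Execute the full analysis pipeline
#'
#' @param config A [run_config()].
#' @return A `frag_run`: list with the stage objects (`cohort_summaries`,
#'   `oscillation`, `selection`, `bench`, `cna`) and a machine-readable
#'   `report` list (cohort sizes, main peaks, cycle counts, per-cycle
#'   statistics, classification metrics, recurrent chromosome lists).
#'   Identical `(config, seed)` give identical reports.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log_msg <- function(...) message(sprintf(...))

  # --- stage 1: cohort --------------------------------------------------
  if (is.null(config$manifest)) {
    cc <- config$cohort
    cc$seed <- derive_seed(config$seed, "cohort")
    log_msg("stage cohort: simulating %d + %d samples", cc$n_normal, cc$n_tumor)
    cohort <- generate_cohort(cc)
    truth <- cohort$truth
    hists <- cohort$histograms
  } else {
    man <- read_manifest(config$manifest)
    log_msg("stage cohort: loading %d samples from manifest", nrow(man))
    hists <- lapply(seq_len(nrow(man)), function(i)
      read_histogram_tsv(man$path[i], sample_id = man$sample_id[i]))
    names(hists) <- man$sample_id
    truth <- data.frame(sample_id = man$sample_id, group = man$group,
                        tumor_fraction = NA_real_, stringsAsFactors = FALSE)
  }
  dists <- lapply(hists, normalize_histogram)
  groups <- split(seq_along(dists), truth$group)
  log_msg("stage distributions: %d samples normalized (groups: %s)",
          length(dists), paste(names(groups), collapse = ", "))

  # --- stage 2: cohort summaries + oscillation --------------------------
  summaries <- lapply(names(groups), function(g)
    cohort_summary(dists[groups[[g]]], g))
  names(summaries) <- names(groups)
  osc <- lapply(summaries, detect_oscillations)
  for (g in names(osc))
    log_msg("stage oscillation: %s main peak %d bp, %d cycle(s)",
            g, osc[[g]]$main_peak_bp, nrow(osc[[g]]$cycles))

  # --- stage 3: features + selection ------------------------------------
  labels <- as.integer(truth$group != "normal")
  fm <- build_feature_matrix(dists, labels, feature_spec("full_grid"))
  selection <- NULL
  if (config$run_rfe) {
    log_msg("stage selection: SVM-RFE, %d iterations", config$rfe_iterations)
    selection <- svm_rfe_select(fm, n_iterations = config$rfe_iterations,
                                seed = derive_seed(config$seed, "rfe"))
  }

  # --- stage 4: classification bench ------------------------------------
  bc <- config$bench
  bc$seed <- derive_seed(config$seed, "bench")
  log_msg("stage bench: %d algorithms x %d repeats",
          length(bc$algorithms), bc$n_repeats)
  bench <- repeated_holdout(fm, bc)
  cv <- kfold_cv(fm, bc)

  # --- stage 5: CNA ------------------------------------------------------
  cna_res <- NULL
  if (!is.null(config$cna)) {
    sc <- config$cna
    sc$seed <- derive_seed(config$seed, "cna")
    log_msg("stage cna: simulating %d normals + %d tumors, consensus >= %d",
            sc$n_normal, sc$n_tumor, config$consensus$min_recurrent_samples)
    cna_cohort <- generate_cna_cohort(sc)
    cna_res <- cna_consensus_pipeline(cna_cohort, config$consensus)
    cna_res$truth <- cna_cohort$truth
  }

  report <- list(
    seed = config$seed,
    cohort = list(n_samples = length(dists),
                  groups = as.list(vapply(groups, length, integer(1)))),
    main_peak_bp = lapply(osc, `[[`, "main_peak_bp"),
    n_cycles = lapply(osc, function(o) nrow(o$cycles)),
    cycles = lapply(osc, function(o) o$cycles),
    proportion_below_174 = lapply(summaries, function(s)
      proportion_below(cohort_mean_distribution(s))),
    selection_regions = if (!is.null(selection)) selection$regions,
    bench_holdout = as.data.frame(bench),
    bench_cv = as.data.frame(cv),
    cna_chromosomes = if (!is.null(cna_res)) cna_res$recurrence$chromosomes
  )

  run <- structure(list(truth = truth, summaries = summaries,
                        oscillation = osc, feature_matrix = fm,
                        selection = selection, bench = bench, cv = cv,
                        cna = cna_res, report = report, config = config),
                   class = "frag_run")
  if (!is.null(config$out_dir)) write_run_outputs(run, config$out_dir)
  run
}

#' @export
print.frag_run <- function(x, ...) {
  cat("fraghound pipeline run\n")
  cat(sprintf("  samples: %d (%s)\n", length(x$truth$sample_id),
              paste(sprintf("%d %s", table(x$truth$group),
                            names(table(x$truth$group))), collapse = ", ")))
  for (g in names(x$oscillation))
    cat(sprintf("  %s: main peak %d bp, %d cycles\n", g,
                x$oscillation[[g]]$main_peak_bp,
                nrow(x$oscillation[[g]]$cycles)))
  best <- x$bench[which.max(x$bench$auc), ]
  cat(sprintf("  best hold-out AUC: %.3f (%s)\n", best$auc, best$algorithm))
  if (!is.null(x$cna))
    cat(sprintf("  recurrent CNA: gain on %s; loss on %s\n",
                paste(x$cna$recurrence$chromosomes$gain, collapse = ","),
                paste(x$cna$recurrence$chromosomes$loss, collapse = ",")))
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Emits the cycle-statistics TSV per group, the bench TSVs, the cohort
#' summary TSV, selection regions BED (when present), consensus/recurrence
#' BEDs (when present), a cohort overview PNG and the JSON report.
#'
#' @param run A `frag_run`.
#' @param dir Output directory.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, f) utils::write.table(d, file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  cyc <- do.call(rbind, lapply(names(run$oscillation), function(g) {
    o <- run$oscillation[[g]]
    if (!nrow(o$cycles)) return(NULL)
    data.frame(group = g, o$cycles,
               main_peak_bp = o$main_peak_bp)
  }))
  if (!is.null(cyc)) tsv(cyc, "oscillation_cycles.tsv")
  summ <- do.call(rbind, lapply(run$summaries, function(s)
    data.frame(size_bp = s$sizes, group = s$group_label,
               mean = s$mean_density, sd = s$sd_density)))
  tsv(summ, "cohort_summary.tsv")
  tsv(as.data.frame(run$bench), "bench_holdout.tsv")
  tsv(as.data.frame(run$cv), "bench_cv.tsv")
  if (!is.null(run$selection))
    tsv(run$selection$regions, "selection_regions.tsv")
  if (!is.null(run$cna)) {
    write_cna_bed(run$cna$recurrence, file.path(dir, "recurrent_cna.bed"))
    tsv(data.frame(state = c("gain", "loss"),
                   chromosomes = c(paste(run$cna$recurrence$chromosomes$gain,
                                         collapse = ","),
                                   paste(run$cna$recurrence$chromosomes$loss,
                                         collapse = ","))),
        "cna_chromosomes.tsv")
  }
  grDevices::png(file.path(dir, "cohort_overview.png"), width = 900,
                 height = 500, res = 110)
  cols <- c(normal = "black", hemangiosarcoma = "red3",
            post_operative = "orange3")
  first <- TRUE
  for (g in names(run$summaries)) {
    plot(run$summaries[[g]], add = !first,
         col = cols[[g]] %||% "grey40",
         main = if (first) "cfDNA fragment-size distributions" else NULL)
    first <- FALSE
  }
  graphics::legend("topright", legend = names(run$summaries),
                   col = vapply(names(run$summaries),
                                function(g) cols[[g]] %||% "grey40",
                                character(1)), lwd = 2, bty = "n")
  grDevices::dev.off()
  jsonlite::write_json(run$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  invisible(dir)
}
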