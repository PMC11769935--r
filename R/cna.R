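#' Toy genome and genome binning
#'
#' `toy_genome()` returns named chromosome lengths (default 5 chromosomes of
#' 25 Mb, a desk-scale stand-in for canFam3.1; real sizes can be loaded with
#' [read_chrom_sizes()]). `genome_bins()` tiles a genome into half-open
#' `[start, end)` 0-based bins of fixed width; the trailing bin of each
#' chromosome may be short and is flagged.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @return Named numeric vector of chromosome lengths.
#' @export
toy_genome <- function(n_chrom = 5L, chrom_length = 2.5e7) {
  stats::setNames(rep(chrom_length, n_chrom), paste0("chr", seq_len(n_chrom)))
}

#' @rdname toy_genome
#' @param path Two-column `chrom<TAB>length` file (UCSC chrom.sizes format).
#' @export
read_chrom_sizes <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(x[[2]]), x[[1]])
}

#' @rdname toy_genome
#' @param genome Named chromosome lengths.
#' @param bin_width Bin width in bp (default 500 kb).
#' @return `genome_bins` returns a data frame `chrom`, `start`, `end`,
#'   `short` (logical: trailing short bin).
#' @export
genome_bins <- function(genome, bin_width = 5e5) {
  check_number(bin_width, "bin_width", lower = 1)
  out <- lapply(names(genome), function(ch) {
    len <- genome[[ch]]
    starts <- seq(0, len - 1, by = bin_width)
    ends <- pmin(starts + bin_width, len)
    data.frame(chrom = ch, start = starts, end = ends,
               short = (ends - starts) < bin_width,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Count read starts per genomic bin
#'
#' @param read_positions Named list (per chromosome) of 0-based read start
#'   positions.
#' @param genome Named chromosome lengths.
#' @param bin_width Bin width in bp (default 500 kb).
#' @return Data frame of bins (`chrom`, `start`, `end`, `short`, `count`);
#'   attribute `n_rejected` counts positions beyond their chromosome (or on
#'   unknown chromosomes).
#' @examples
#' g <- toy_genome(1, 2e6)
#' b <- bin_reads(list(chr1 = c(100, 750000)), g)
#' b$count
#' @export
bin_reads <- function(read_positions, genome, bin_width = 5e5) {
  bins <- genome_bins(genome, bin_width)
  bins$count <- 0L
  rejected <- 0L
  for (ch in names(read_positions)) {
    pos <- read_positions[[ch]]
    if (!ch %in% names(genome)) { rejected <- rejected + length(pos); next }
    bad <- pos < 0 | pos >= genome[[ch]]
    rejected <- rejected + sum(bad)
    pos <- pos[!bad]
    if (!length(pos)) next
    idx <- floor(pos / bin_width)
    tab <- table(idx)
    sel <- which(bins$chrom == ch)
    bins$count[sel[as.integer(names(tab)) + 1L]] <-
      bins$count[sel[as.integer(names(tab)) + 1L]] + as.integer(tab)
  }
  attr(bins, "n_rejected") <- rejected
  bins
}

# scale a count vector to mean 1 over unmasked bins
.normalize_counts <- function(count, mask) {
  m <- mean(count[!mask])
  if (!is.finite(m) || m <= 0) stop_arg("cannot normalize: no usable bins")
  count / m
}

#' Build a panel of normals for binned coverage
#'
#' Per-bin median of depth-normalized counts over the normal cohort, and a
#' per-bin dispersion of log2 ratios against that median (floored at a
#' minimum so z-scores stay finite), used to normalize and scale tumor
#' profiles.
#'
#' @param bin_tables List of bin data frames (as from [bin_reads()], plus
#'   columns `gc` and `mappability`) for at least two normal samples,
#'   identical bin layouts.
#' @param mappability_cutoff Bins below this mappability are masked
#'   (default 0.8).
#' @param min_dispersion Floor of the per-bin log2-ratio sd (default 0.02).
#' @return A `panel_of_normals`: list with `bins`, `median_norm`,
#'   `dispersion`, `mask`, `n_normals`.
#' @export
panel_of_normals <- function(bin_tables, mappability_cutoff = 0.8,
                             min_dispersion = 0.02) {
  if (length(bin_tables) < 2L) stop_arg("panel needs at least 2 normal samples")
  ref <- bin_tables[[1]][, c("chrom", "start", "end")]
  for (b in bin_tables)
    if (!identical(b[, c("chrom", "start", "end")], ref))
      stop_arg("panel samples have mismatched bin layouts")
  mask <- bin_tables[[1]]$mappability < mappability_cutoff
  norm <- vapply(bin_tables, function(b) .normalize_counts(b$count, mask),
                 numeric(nrow(ref)))
  med <- apply(norm, 1, stats::median)
  mask <- mask | med <= 0
  lr <- log2(sweep(norm, 1, pmax(med, 1e-12), "/"))
  disp <- pmax(apply(lr, 1, stats::sd), min_dispersion)
  structure(list(bins = ref, gc = bin_tables[[1]]$gc,
                 median_norm = med, dispersion = disp, mask = mask,
                 n_normals = length(bin_tables)),
            class = "panel_of_normals")
}

#' GC-correct a sample against a panel of normals
#'
#' Depth-normalizes the sample, removes the GC trend of the ratio to the
#' panel median by lowess, and reports per-bin log2 ratios and z-scores
#' (ratio over the panel's per-bin log2 dispersion). Masked bins (low
#' mappability or zero panel median) get NA and never receive calls.
#'
#' @param bins Sample bin data frame (`chrom`, `start`, `end`, `gc`,
#'   `mappability`, `count`).
#' @param panel A [panel_of_normals()].
#' @return Data frame `chrom`, `start`, `end`, `log2_ratio`, `z`, `masked`.
#' @export
correct_bias <- function(bins, panel) {
  stopifnot(inherits(panel, "panel_of_normals"))
  if (!identical(bins[, c("chrom", "start", "end")], panel$bins))
    stop_arg("sample bins do not match panel bins")
  mask <- panel$mask | bins$mappability < 0.8
  if (all(mask)) stop_arg("all bins masked")
  norm <- .normalize_counts(bins$count, mask)
  rel <- norm / pmax(panel$median_norm, 1e-12)
  ok <- !mask & is.finite(rel) & rel > 0
  fit <- stats::lowess(bins$gc[ok], log2(rel[ok]), f = 0.5)
  trend <- stats::approx(fit$x, fit$y, xout = bins$gc, rule = 2)$y
  lr <- ifelse(ok, log2(rel) - trend, NA_real_)
  z <- lr / panel$dispersion
  data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
             log2_ratio = lr, z = z, masked = mask,
             stringsAsFactors = FALSE)
}

#' Threshold-based gain/loss calling on corrected bins
#'
#' A deliberately simple stand-in for external single-sample CNA callers:
#' a bin is a gain when `z >= z_hi` and `log2_ratio >= r_hi`, a loss when
#' `z <= -z_hi` and `log2_ratio <= -r_hi`; adjacent same-state bins are
#' merged into intervals (singletons kept). Two threshold presets play the
#' role of two independent callers feeding the consensus step.
#'
#' @param corrected Output of [correct_bias()].
#' @param sample_id Sample identifier.
#' @param caller_id `"caller_a"`, `"caller_b"` or a custom id.
#' @param z_hi,r_hi Thresholds; presets: caller_a z 5 / ratio 0.3,
#'   caller_b z 4 / ratio 0.25.
#' @return A `cna_callset`: list with `sample_id`, `caller_id`, `calls`
#'   (data frame `chrom`, `start`, `end`, `state`).
#' @export
call_states <- function(corrected, sample_id = "sample",
                        caller_id = c("caller_a", "caller_b"),
                        z_hi = NULL, r_hi = NULL) {
  caller_id <- if (is.character(caller_id) && length(caller_id) > 1)
    match.arg(caller_id) else caller_id
  preset <- switch(caller_id, caller_a = c(5, 0.3), caller_b = c(4, 0.25),
                   c(5, 0.3))
  z_hi <- z_hi %||% preset[1]
  r_hi <- r_hi %||% preset[2]
  st <- rep(NA_character_, nrow(corrected))
  ok <- !corrected$masked & is.finite(corrected$z)
  st[ok & corrected$z >= z_hi & corrected$log2_ratio >= r_hi] <- "gain"
  st[ok & corrected$z <= -z_hi & corrected$log2_ratio <= -r_hi] <- "loss"
  keep <- which(!is.na(st))
  if (!length(keep)) {
    calls <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), state = character(),
                        stringsAsFactors = FALSE)
  } else {
    d <- corrected[keep, c("chrom", "start", "end")]
    d$state <- st[keep]
    # merge bins that touch and share chrom+state
    newblock <- c(TRUE, !(d$chrom[-1] == d$chrom[-nrow(d)] &
                            d$state[-1] == d$state[-nrow(d)] &
                            d$start[-1] == d$end[-nrow(d)]))
    grp <- cumsum(newblock)
    calls <- do.call(rbind, lapply(split(d, grp), function(g)
      data.frame(chrom = g$chrom[1], start = min(g$start), end = max(g$end),
                 state = g$state[1], stringsAsFactors = FALSE)))
    calls <- calls[order(calls$chrom, calls$start), ]
    rownames(calls) <- NULL
  }
  cna_callset(calls, sample_id = sample_id, caller_id = caller_id)
}

#' Construct a CNA call set
#'
#' @param calls Data frame `chrom`, `start`, `end` (0-based half-open),
#'   `state` in `gain`/`loss`; intervals must be non-overlapping within a
#'   state.
#' @param sample_id,caller_id Identifiers.
#' @return A `cna_callset` object.
#' @export
cna_callset <- function(calls, sample_id = "sample", caller_id = "caller") {
  need <- c("chrom", "start", "end", "state")
  if (!all(need %in% names(calls)))
    stop_arg("calls need columns: %s", paste(need, collapse = ", "))
  if (nrow(calls)) {
    if (!all(calls$state %in% c("gain", "loss")))
      stop_arg("states must be 'gain' or 'loss'")
    if (any(calls$start >= calls$end)) stop_arg("empty or inverted interval")
    for (s in c("gain", "loss")) {
      cs <- calls[calls$state == s, ]
      cs <- cs[order(cs$chrom, cs$start), ]
      if (nrow(cs) > 1L) {
        same <- cs$chrom[-1] == cs$chrom[-nrow(cs)]
        if (any(same & cs$start[-1] < cs$end[-nrow(cs)]))
          stop_arg("overlapping %s intervals within one call set", s)
      }
    }
    calls <- calls[order(calls$chrom, calls$start), ]
    rownames(calls) <- NULL
  }
  structure(list(sample_id = sample_id, caller_id = caller_id, calls = calls),
            class = "cna_callset")
}

#' @export
print.cna_callset <- function(x, ...) {
  cat(sprintf("CNA call set: %s (%s): %d gain, %d loss interval(s)\n",
              x$sample_id, x$caller_id, sum(x$calls$state == "gain"),
              sum(x$calls$state == "loss")))
  invisible(x)
}

.calls_to_granges <- function(calls, state) {
  c2 <- calls[calls$state == state, , drop = FALSE]
  GenomicRanges::GRanges(c2$chrom,
                         IRanges::IRanges(start = c2$start + 1, end = c2$end))
}

.granges_to_calls <- function(gr, state) {
  if (!length(gr))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      state = character(), stringsAsFactors = FALSE))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             state = state, stringsAsFactors = FALSE)
}

#' Intersect two call sets of the same sample
#'
#' Per state, the interval intersection of the two callers' calls
#' (bedtools-intersect semantics on 0-based half-open coordinates): the
#' consensus step that keeps only gains/losses supported by both methods.
#'
#' @param a,b `cna_callset` objects for the same sample.
#' @return A `cna_callset` with `caller_id = "consensus"`.
#' @examples
#' a <- cna_callset(data.frame(chrom = "chr1", start = 0, end = 1e6,
#'                             state = "gain"))
#' b <- cna_callset(data.frame(chrom = "chr1", start = 5e5, end = 1.5e6,
#'                             state = "gain"))
#' intersect_callsets(a, b)$calls
#' @export
intersect_callsets <- function(a, b) {
  stopifnot(inherits(a, "cna_callset"), inherits(b, "cna_callset"))
  out <- lapply(c("gain", "loss"), function(s) {
    ga <- .calls_to_granges(a$calls, s)
    gb <- .calls_to_granges(b$calls, s)
    .granges_to_calls(suppressWarnings(GenomicRanges::intersect(ga, gb)), s)
  })
  cna_callset(do.call(rbind, out), sample_id = a$sample_id,
              caller_id = "consensus")
}

#' Consensus/recurrence configuration
#'
#' @param min_recurrent_samples Minimum number of carrying samples for a
#'   region to be recurrent; default 7, i.e. "more than 6 samples" of the
#'   21-tumor cohort.
#' @param n_samples Cohort size the threshold refers to (default 21).
#' @return A `consensus_config` object.
#' @export
consensus_config <- function(min_recurrent_samples = 7L, n_samples = 21L) {
  check_number(min_recurrent_samples, "min_recurrent_samples", lower = 1)
  check_number(n_samples, "n_samples", lower = min_recurrent_samples)
  structure(list(min_recurrent_samples = as.integer(min_recurrent_samples),
                 n_samples = as.integer(n_samples)),
            class = "consensus_config")
}

#' Cross-sample recurrence filter
#'
#' Counts, per genomic position and state, how many samples carry a call
#' (each sample counted once even if its call set is fragmented), keeps
#' maximal regions where the count reaches `min_recurrent_samples`, and
#' reports the chromosomes containing any recurrent region per state.
#'
#' @param callsets List of `cna_callset` objects (one per sample).
#' @param config A [consensus_config()].
#' @return A `recurrence_result`: list with `regions` (data frame `chrom`,
#'   `start`, `end`, `state`, `n_samples`), `chromosomes` (list with
#'   `gain`, `loss` character vectors), `config`.
#' @export
recurrence_filter <- function(callsets, config = consensus_config()) {
  if (!length(callsets)) stop_arg("need at least one call set")
  stopifnot(all(vapply(callsets, inherits, logical(1), "cna_callset")),
            inherits(config, "consensus_config"))
  out <- lapply(c("gain", "loss"), function(s) {
    per_sample <- lapply(callsets, function(cs)
      GenomicRanges::reduce(.calls_to_granges(cs$calls, s)))
    cov <- GenomicRanges::coverage(suppressWarnings(
      do.call(c, unname(per_sample))))
    if (!length(cov)) return(NULL)  # no sample carries this state anywhere
    sl <- IRanges::slice(cov, lower = config$min_recurrent_samples,
                         rangesOnly = FALSE)
    rows <- lapply(names(sl), function(ch) {
      v <- sl[[ch]]
      if (!length(v)) return(NULL)
      data.frame(chrom = ch, start = IRanges::start(v) - 1,
                 end = IRanges::end(v), state = s,
                 n_samples = as.numeric(IRanges::viewMaxs(v)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  regions <- do.call(rbind, out)
  if (is.null(regions))
    regions <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), state = character(),
                          n_samples = numeric(), stringsAsFactors = FALSE)
  regions <- regions[order(regions$state, regions$chrom, regions$start), ]
  rownames(regions) <- NULL
  structure(list(regions = regions,
                 chromosomes = list(
                   gain = sort(unique(regions$chrom[regions$state == "gain"])),
                   loss = sort(unique(regions$chrom[regions$state == "loss"]))),
                 config = config),
            class = "recurrence_result")
}

#' @export
print.recurrence_result <- function(x, ...) {
  cat(sprintf("Recurrent CNA regions (>= %d of %d samples)\n",
              x$config$min_recurrent_samples, x$config$n_samples))
  cat("  gain chromosomes:", paste(x$chromosomes$gain, collapse = ", "), "\n")
  cat("  loss chromosomes:", paste(x$chromosomes$loss, collapse = ", "), "\n")
  invisible(x)
}

#' Read external caller output into call sets
#'
#' `read_seg` ingests an ichorCNA-style `.seg` table (1-based inclusive
#' coordinates; a call column containing GAIN/AMP/HLAMP marks gains and
#' HETD/HOMD/DEL losses). `read_aberration_bed` ingests a WisecondorX-style
#' aberration BED (0-based half-open; a type column with gain/loss).
#'
#' @param path Input file.
#' @param sample_id,caller_id Identifiers for the resulting call set.
#' @return A `cna_callset`.
#' @export
read_seg <- function(path, sample_id = NULL, caller_id = "ichorCNA") {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(x) <- tolower(names(x))
  callcol <- intersect(c("call", "event", "state"), names(x))[1]
  if (is.na(callcol)) stop_arg("%s: no call/event/state column", path)
  chromcol <- intersect(c("chrom", "chr", "chromosome"), names(x))[1]
  if (is.na(chromcol)) stop_arg("%s: no chromosome column", path)
  up <- toupper(x[[callcol]])
  state <- rep(NA_character_, nrow(x))
  state[grepl("GAIN|AMP", up)] <- "gain"
  state[grepl("HETD|HOMD|DEL|LOSS", up)] <- "loss"
  keep <- !is.na(state)
  calls <- data.frame(chrom = as.character(x[[chromcol]][keep]),
                      start = x$start[keep] - 1, end = x$end[keep],
                      state = state[keep], stringsAsFactors = FALSE)
  cna_callset(calls, sample_id = sample_id %||% basename(path),
              caller_id = caller_id)
}

#' @rdname read_seg
#' @export
read_aberration_bed <- function(path, sample_id = NULL,
                                caller_id = "WisecondorX") {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         comment.char = "#")
  if (ncol(x) < 4L) stop_arg("%s: need chrom, start, end, type columns", path)
  ty <- tolower(x[[4]])
  keep <- ty %in% c("gain", "loss")
  calls <- data.frame(chrom = as.character(x[[1]][keep]),
                      start = as.numeric(x[[2]][keep]),
                      end = as.numeric(x[[3]][keep]),
                      state = ty[keep], stringsAsFactors = FALSE)
  cna_callset(calls, sample_id = sample_id %||% basename(path),
              caller_id = caller_id)
}

#' Write consensus calls as BED
#'
#' @param x A `cna_callset` or `recurrence_result`.
#' @param path Output file; 0-based half-open BED with the state (and
#'   sample count, for recurrence results) in columns 4+.
#' @export
write_cna_bed <- function(x, path) {
  d <- if (inherits(x, "recurrence_result")) x$regions else x$calls
  cols <- c("chrom", "start", "end", "state",
            intersect("n_samples", names(d)))
  utils::write.table(format(d[, cols], scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
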