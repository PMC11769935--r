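#' Fragment filter for paired-end cfDNA alignments
#'
#' Encodes the samtools-style record filter used when tallying cfDNA template
#' lengths: only paired, properly-paired, first-in-pair records (all bits of
#' flag 66 set, i.e. `samtools view -f 66`) with mapping quality at or above a
#' threshold and absolute template length inside a size window are counted.
#' Requiring first-in-pair records ensures each sequenced fragment is counted
#' exactly once.
#'
#' @param required_flag_bits Integer alignment-flag mask; a record passes when
#'   all of these bits are set. Default 66L = paired (1) + proper pair (2) +
#'   first in pair (64)... strictly 2 + 64; see Details.
#' @param min_mapping_quality Minimum mapping quality (default 30).
#' @param size_min,size_max Inclusive fragment-size window in bp
#'   (defaults 74 and 439, the mono- to di-nucleosome range).
#'
#' @details Flag 66 is the sum of bit 2 (proper pair) and bit 64 (first in
#' pair); proper pairing implies bit 1 (paired) in well-formed BAMs. The test
#' is `bitwAnd(flag, required_flag_bits) == required_flag_bits`, matching
#' `samtools view -f` semantics.
#'
#' @return An object of class `frag_filter`.
#' @examples
#' fragment_filter()
#' fragment_filter(min_mapping_quality = 20, size_max = 500)
#' @export
fragment_filter <- function(required_flag_bits = 66L,
                            min_mapping_quality = 30L,
                            size_min = 74L, size_max = 439L) {
  check_number(min_mapping_quality, "min_mapping_quality", lower = 0)
  check_number(size_min, "size_min", lower = 1)
  check_number(size_max, "size_max")
  if (size_min >= size_max) stop_arg("size_min must be < size_max")
  structure(list(required_flag_bits = as.integer(required_flag_bits),
                 min_mapping_quality = as.integer(min_mapping_quality),
                 size_min = as.integer(size_min),
                 size_max = as.integer(size_max)),
            class = "frag_filter")
}

#' Construct a fragment-length histogram
#'
#' Integer counts of cfDNA template lengths on the inclusive 1-bp grid
#' `[size_min, size_max]` for one sample.
#'
#' @param counts Named or unnamed non-negative integer vector; if unnamed it
#'   must cover the full grid, if named the names are sizes in bp and missing
#'   sizes get count 0.
#' @param sample_id Sample identifier.
#' @param size_min,size_max Grid limits in bp (inclusive).
#' @return A `frag_histogram`: list with `sample_id`, `sizes`, `counts`,
#'   `total`.
#' @examples
#' h <- frag_histogram(c(`160` = 5, `165` = 10), sample_id = "s1")
#' h$total
#' @export
frag_histogram <- function(counts = integer(), sample_id = "sample",
                           size_min = 74L, size_max = 439L) {
  sizes <- seq.int(size_min, size_max)
  full <- integer(length(sizes))
  names(full) <- sizes
  if (length(counts)) {
    if (is.null(names(counts))) {
      if (length(counts) != length(sizes))
        stop_arg("unnamed counts must have length %d (one per size in [%d, %d])",
                 length(sizes), size_min, size_max)
      full[] <- counts
    } else {
      at <- as.integer(names(counts))
      if (anyNA(at) || any(at < size_min) || any(at > size_max))
        stop_arg("count names must be sizes within [%d, %d]", size_min, size_max)
      full[as.character(at)] <- full[as.character(at)] + counts
    }
  }
  if (any(full < 0) || any(full != round(full)))
    stop_arg("counts must be non-negative integers")
  structure(list(sample_id = sample_id, sizes = sizes,
                 counts = as.integer(round(full)), total = sum(full)),
            class = "frag_histogram")
}

#' @export
print.frag_histogram <- function(x, ...) {
  cat(sprintf("Fragment-length histogram: %s\n", x$sample_id))
  cat(sprintf("  grid [%d, %d] bp (%d sizes), %d fragments\n",
              min(x$sizes), max(x$sizes), length(x$sizes), x$total))
  if (x$total > 0) {
    m <- x$sizes[which.max(x$counts)]
    cat(sprintf("  modal size %d bp (count %d)\n", m, max(x$counts)))
  }
  invisible(x)
}

#' Extract fragment lengths from paired-end alignments
#'
#' Tallies absolute template lengths (TLEN) of alignment records that pass a
#' [fragment_filter()] into a [frag_histogram()]. Input is either a BAM/SAM
#' file path (read via Rsamtools) or a data frame of records with columns
#' `flag`, `mapq` and `isize` (as returned by `Rsamtools::scanBam`, or built
#' by hand).
#'
#' @param alignments BAM file path or a data frame with columns
#'   `flag`, `mapq`, `isize`.
#' @param filter A [fragment_filter()].
#' @param sample_id Sample identifier for the histogram.
#' @return A `frag_histogram`. The number of records skipped for a missing
#'   template length is attached as attribute `n_missing_tlen`.
#' @examples
#' recs <- data.frame(flag = c(99L, 99L, 83L), mapq = c(60L, 60L, 10L),
#'                    isize = c(165L, -160L, 170L))
#' extract_fragment_lengths(recs)
#' @export
extract_fragment_lengths <- function(alignments, filter = fragment_filter(),
                                     sample_id = "sample") {
  stopifnot(inherits(filter, "frag_filter"))
  if (is.character(alignments) && length(alignments) == 1L) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop_arg("reading BAM files requires the Rsamtools package")
    if (!file.exists(alignments))
      stop_arg("cannot read alignments: '%s' does not exist", alignments)
    p <- Rsamtools::ScanBamParam(what = c("flag", "mapq", "isize"))
    b <- Rsamtools::scanBam(alignments, param = p)[[1]]
    rec <- data.frame(flag = b$flag, mapq = b$mapq, isize = b$isize)
  } else if (is.data.frame(alignments)) {
    need <- c("flag", "mapq", "isize")
    if (!all(need %in% names(alignments)))
      stop_arg("alignment data frame needs columns: %s",
               paste(need, collapse = ", "))
    rec <- alignments
  } else stop_arg("`alignments` must be a file path or a data frame")

  missing_tlen <- is.na(rec$isize)
  rec <- rec[!missing_tlen, , drop = FALSE]
  keep <- bitwAnd(rec$flag, filter$required_flag_bits) == filter$required_flag_bits &
    !is.na(rec$mapq) & rec$mapq >= filter$min_mapping_quality
  len <- abs(rec$isize[keep])
  len <- len[len >= filter$size_min & len <= filter$size_max]
  cnt <- table(factor(len, levels = seq.int(filter$size_min, filter$size_max)))
  out <- frag_histogram(as.integer(cnt), sample_id = sample_id,
                        size_min = filter$size_min, size_max = filter$size_max)
  attr(out, "n_missing_tlen") <- sum(missing_tlen)
  out
}

#' Depth-capping policy
#'
#' Samples sequenced deeper than a maximum mean depth are downscaled to that
#' depth, so that cohort members contribute at comparable coverage (default
#' cap 2x of a ~2.4 Gb canine genome).
#'
#' @param max_mean_depth Maximum mean fold-coverage retained (default 2).
#' @param genome_size Genome size in bp used when estimating mean depth
#'   (default 2.4e9).
#' @param seed Integer seed for the stochastic thinning.
#' @return A `depth_cap_policy` object.
#' @export
depth_cap_policy <- function(max_mean_depth = 2.0, genome_size = 2.4e9,
                             seed = 1L) {
  check_number(max_mean_depth, "max_mean_depth", lower = 1e-9)
  check_number(genome_size, "genome_size", lower = 1)
  structure(list(max_mean_depth = max_mean_depth, genome_size = genome_size,
                 seed = as.integer(seed)), class = "depth_cap_policy")
}

#' Cap a histogram at a maximum mean depth
#'
#' If the observed mean depth exceeds the policy cap, every size bin is
#' independently binomially thinned with retention probability
#' `cap / observed`, the histogram-level equivalent of subsampling the BAM.
#' Below the cap the histogram is returned unchanged.
#'
#' @param hist A [frag_histogram()].
#' @param observed_mean_depth Observed mean fold-coverage of the sample.
#' @param policy A [depth_cap_policy()].
#' @return A `frag_histogram`; attribute `retention` records the thinning
#'   probability applied (1 when unchanged).
#' @examples
#' h <- frag_histogram(c(`160` = 1000, `165` = 2000))
#' cap_depth(h, observed_mean_depth = 4, depth_cap_policy(seed = 7))$total
#' @export
cap_depth <- function(hist, observed_mean_depth, policy = depth_cap_policy()) {
  stopifnot(inherits(hist, "frag_histogram"), inherits(policy, "depth_cap_policy"))
  check_number(observed_mean_depth, "observed_mean_depth", lower = 1e-12)
  if (observed_mean_depth <= policy$max_mean_depth) {
    attr(hist, "retention") <- 1
    return(hist)
  }
  p <- policy$max_mean_depth / observed_mean_depth
  thinned <- with_seed(policy$seed,
                       rbinom(length(hist$counts), hist$counts, p))
  out <- frag_histogram(as.integer(thinned), sample_id = hist$sample_id,
                        size_min = min(hist$sizes), size_max = max(hist$sizes))
  attr(out, "retention") <- p
  out
}

#' Read / write fragment-length histograms as TSV
#'
#' Plain-text interchange format: a header line `size_bp<TAB>count` followed
#' by one row per 1-bp size. `read_histogram_tsv` rejects malformed rows,
#' negative counts and sizes outside the configured grid; the round trip
#' through `write_histogram_tsv` is lossless.
#'
#' @param path File path.
#' @param sample_id Sample identifier (defaults to the file name).
#' @param size_min,size_max Grid limits the file must respect.
#' @return `read_histogram_tsv` returns a `frag_histogram`;
#'   `write_histogram_tsv` invisibly returns `path`.
#' @export
read_histogram_tsv <- function(path, sample_id = NULL,
                               size_min = 74L, size_max = 439L) {
  if (!file.exists(path)) stop_arg("histogram file not found: %s", path)
  lines <- readLines(path)
  if (!length(lines) || !identical(strsplit(lines[1], "\t")[[1]][1:2],
                                   c("size_bp", "count")))
    stop_arg("%s: expected header 'size_bp\\tcount'", path)
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    ln <- i + 1L
    if (length(p) != 2L)
      stop_arg("%s line %d: expected 2 tab-separated fields", path, ln)
    sz <- suppressWarnings(as.numeric(p[1])); ct <- suppressWarnings(as.numeric(p[2]))
    if (is.na(sz) || is.na(ct) || sz != round(sz) || ct != round(ct))
      stop_arg("%s line %d: non-integer size or count", path, ln)
    if (ct < 0) stop_arg("%s line %d: negative count", path, ln)
    if (sz < size_min || sz > size_max)
      stop_arg("%s line %d: size %d outside grid [%d, %d]",
               path, ln, as.integer(sz), size_min, size_max)
  }
  sz <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  ct <- vapply(parts, function(p) as.integer(p[2]), integer(1))
  if (anyDuplicated(sz)) stop_arg("%s: duplicated size rows", path)
  names(ct) <- sz
  frag_histogram(ct, sample_id = sample_id %||% basename(path),
                 size_min = size_min, size_max = size_max)
}

#' @rdname read_histogram_tsv
#' @param hist A `frag_histogram` to write.
#' @export
write_histogram_tsv <- function(hist, path) {
  stopifnot(inherits(hist, "frag_histogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("size_bp\tcount", con)
  writeLines(sprintf("%d\t%d", hist$sizes, hist$counts), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
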