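test_that("read binning follows half-open 500 kb bin arithmetic", {
  g <- toy_genome(2, 2e6)
  b <- bin_reads(list(), g)
  expect_true(all(b$count == 0L))
  expect_equal(nrow(b), 8L)
  expect_true(all(b$end - b$start == 5e5))

  b2 <- bin_reads(list(chr1 = c(0, 499999, 500000, 750000, 1999999),
                       chr2 = 1e6), g)
  expect_equal(b2$count[b2$chrom == "chr1"], c(2L, 2L, 0L, 1L))
  expect_equal(b2$count[b2$chrom == "chr2"], c(0L, 0L, 1L, 0L))

  # out-of-range and unknown-chromosome positions rejected with a count
  b3 <- bin_reads(list(chr1 = c(100, 2e6, -5), chrX = 10), g)
  expect_equal(sum(b3$count), 1L)
  expect_equal(attr(b3, "n_rejected"), 3L)

  # trailing short bin kept and flagged
  gb <- genome_bins(c(chr1 = 1.2e6))
  expect_equal(gb$end - gb$start, c(5e5, 5e5, 2e5))
  expect_equal(gb$short, c(FALSE, FALSE, TRUE))
})

test_that("interval intersection matches bedtools semantics and a per-bin oracle", {
  a <- make_callset("s", "chr1", 0, 1e6, "gain")
  b <- make_callset("s", "chr1", 5e5, 1.5e6, "gain")
  ab <- intersect_callsets(a, b)
  expect_equal(ab$calls[, c("start", "end")],
               data.frame(start = 5e5, end = 1e6))

  disj <- intersect_callsets(make_callset("s", "chr1", 0, 1e5, "gain"),
                             make_callset("s", "chr1", 2e5, 3e5, "gain"))
  expect_equal(nrow(disj$calls), 0L)

  # idempotent and commutative
  expect_equal(intersect_callsets(a, a)$calls[, 1:4], a$calls)
  ba <- intersect_callsets(b, a)
  expect_equal(ab$calls, ba$calls)

  # gain does not intersect loss
  gl <- intersect_callsets(make_callset("s", "chr1", 0, 1e6, "gain"),
                           make_callset("s", "chr1", 0, 1e6, "loss"))
  expect_equal(nrow(gl$calls), 0L)

  # per-bin brute force on random toy call sets (10-bin genome)
  bins <- genome_bins(c(chr1 = 5e6), 5e5)
  for (s in 1:8) {
    set.seed(s)
    rand_calls <- function(id) {
      k <- sample(1:3, 1)
      st <- sort(sample(0:9, k)) * 5e5
      make_callset(id, "chr1", st, st + sample(1:2, k, replace = TRUE) * 5e5,
                   sample(c("gain", "loss"), k, replace = TRUE))
    }
    ca <- tryCatch(rand_calls("s"), error = function(e) NULL)
    cb <- tryCatch(rand_calls("s"), error = function(e) NULL)
    if (is.null(ca) || is.null(cb)) next  # overlapping random draw: skip case
    got <- brute_bin_states(intersect_callsets(ca, cb)$calls, bins)
    sa <- brute_bin_states(ca$calls, bins); sb <- brute_bin_states(cb$calls, bins)
    want <- vapply(seq_len(nrow(bins)), function(i) {
      common <- intersect(strsplit(sa[i], "\\+")[[1]], strsplit(sb[i], "\\+")[[1]])
      paste(sort(common), collapse = "+")
    }, character(1))
    expect_equal(got, want)
  }
})

test_that("recurrence keeps regions in more than six samples and drops the rest", {
  mk <- function(n) lapply(seq_len(n), function(i)
    make_callset(paste0("t", i), "chr2", 5e6, 1e7, "gain"))
  # 7 of 21: retained; 6 of 21: dropped
  r7 <- recurrence_filter(mk(7))
  expect_equal(r7$chromosomes$gain, "chr2")
  expect_equal(r7$regions$n_samples, 7)
  r6 <- recurrence_filter(mk(6))
  expect_equal(nrow(r6$regions), 0L)
  # present in all samples: retained
  expect_equal(recurrence_filter(mk(21))$regions$n_samples, 21)

  # fragmented per-sample calls count once per sample
  split_cs <- cna_callset(data.frame(chrom = "chr2",
                                     start = c(5e6, 5.5e6),
                                     end = c(5.5e6, 6e6),
                                     state = "gain"), "tx", "test")
  r <- recurrence_filter(c(mk(6), list(split_cs)))
  expect_equal(r$regions$start, 5e6)
  expect_equal(r$regions$end, 6e6)

  # per-bin counts equal a brute-force tally on random cohorts
  bins <- genome_bins(c(chr1 = 5e6), 5e5)
  for (s in 1:5) {
    set.seed(s)
    cohort <- lapply(1:10, function(i) {
      st <- sort(sample(0:9, sample(1:3, 1))) * 5e5
      make_callset(paste0("t", i), "chr1", st, st + 5e5,
                   sample(c("gain", "loss"), length(st), replace = TRUE))
    })
    tally <- sapply(cohort, function(cs)
      brute_bin_states(cs$calls, bins))
    for (st in c("gain", "loss")) {
      counts <- rowSums(matrix(grepl(st, tally), nrow = nrow(bins)))
      thr <- 3L
      rr <- recurrence_filter(cohort, consensus_config(thr, 10))
      rec_bins <- brute_bin_states(rr$regions, bins)
      expect_equal(grepl(st, rec_bins), counts >= thr)
    }
  }
})

test_that("bias correction is self-consistent and removes GC trend", {
  cfg <- cna_sim_config(n_normal = 8, n_tumor = 1,
                        spikes = default_cna_spikes()[0, ], seed = 33)
  cc <- generate_cna_cohort(cfg)
  panel <- panel_of_normals(cc$normals)

  # a sample equal to the panel median profile: ratios ~0, |z| small
  synth <- cc$normals[[1]]
  synth$count <- round(panel$median_norm * mean(synth$count[!panel$mask]))
  corr <- correct_bias(synth, panel)
  expect_lt(max(abs(corr$log2_ratio), na.rm = TRUE), 0.1)
  expect_lt(max(abs(corr$z), na.rm = TRUE), 3)

  # counts as an exact smooth function of GC: correction shrinks variance
  fake <- cc$normals[[1]]
  fake$count <- round(4000 * exp(1.5 * fake$gc))
  corr2 <- correct_bias(fake, panel)
  raw_lr <- log2((fake$count / mean(fake$count[!panel$mask])) /
                   pmax(panel$median_norm, 1e-12))
  expect_lt(var(corr2$log2_ratio[!corr2$masked]),
            var(raw_lr[!panel$mask]))

  # masked bins never receive calls
  masked_sample <- cc$normals[[2]]
  masked_sample$mappability[5] <- 0.1
  masked_sample$count[5] <- masked_sample$count[5] * 10
  corr3 <- correct_bias(masked_sample, panel)
  expect_true(corr3$masked[5])
  calls <- call_states(corr3, "m", "caller_b")
  if (nrow(calls$calls))
    expect_false(any(calls$calls$start <= corr3$start[5] &
                       calls$calls$end >= corr3$end[5]))
})

test_that("spiked segments are recovered with reciprocal overlap >= 80%", {
  cfg <- cna_sim_config(n_normal = 10, n_tumor = 1,
                        spikes = data.frame(chrom = "chr2", start = 5e6,
                                            end = 1e7, copy_ratio = 1.5,
                                            carrier_fraction = 1),
                        seed = 14)
  cc <- generate_cna_cohort(cfg)
  panel <- panel_of_normals(cc$normals)
  corr <- correct_bias(cc$tumors[[1]], panel)
  a <- call_states(corr, "t1", "caller_a")
  gains <- a$calls[a$calls$state == "gain", ]
  expect_equal(nrow(gains), 1L)
  ov <- min(gains$end, 1e7) - max(gains$start, 5e6)
  expect_gte(ov / 5e6, 0.8)
  expect_gte(ov / (gains$end - gains$start), 0.8)

  # two callers: overlapping but potentially unequal intervals
  b <- call_states(corr, "t1", "caller_b")
  both <- intersect_callsets(a, b)
  expect_gte(nrow(both$calls), 1L)

  # all-neutral input gives an empty call set
  neutral <- corr
  neutral$z[] <- 0; neutral$log2_ratio[] <- 0
  expect_equal(nrow(call_states(neutral, "n")$calls), 0L)
})

test_that("external caller formats are ingested with coordinate conversion", {
  seg <- tempfile(fileext = ".seg")
  writeLines(c("ID\tchrom\tstart\tend\tnum.mark\tseg.median.logR\tcall",
               "s1\tchr1\t1\t500000\t100\t0.8\tGAIN",
               "s1\tchr2\t1000001\t2000000\t200\t-0.9\tHETD",
               "s1\tchr3\t1\t500000\t100\t0.0\tNEUT"), seg)
  cs <- read_seg(seg)
  expect_equal(nrow(cs$calls), 2L)
  expect_equal(cs$calls$start[cs$calls$chrom == "chr1"], 0)  # 1-based -> 0-based
  expect_equal(cs$calls$state, c("gain", "loss"))

  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t500000\tgain\t1.2", "chr2\t1000000\t2000000\tloss\t-1.1"),
             bed)
  cb <- read_aberration_bed(bed)
  expect_equal(cb$calls$start, c(0, 1e6))
  expect_equal(cb$calls$state, c("gain", "loss"))

  # BED output round-trips through the aberration reader
  out <- tempfile(fileext = ".bed")
  write_cna_bed(cb, out)
  expect_equal(read_aberration_bed(out)$calls, cb$calls)
})

test_that("call-set construction enforces its invariants", {
  expect_error(make_callset("s", "chr1", c(0, 5e5), c(1e6, 1.5e6),
                            c("gain", "gain")), "overlapping")
  expect_error(make_callset("s", "chr1", 10, 10, "gain"), "interval")
  expect_error(make_callset("s", "chr1", 0, 10, "dup"), "gain")
  # same coordinates in different states are allowed
  cs <- make_callset("s", "chr1", c(0, 0), c(1e6, 1e6), c("gain", "loss"))
  expect_equal(nrow(cs$calls), 2L)
})
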