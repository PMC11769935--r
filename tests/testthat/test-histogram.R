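test_that("extraction applies flag, quality and size filters exactly", {
  # flag 99 = paired + proper + mate-reverse + first-in-pair (contains 66)
  recs <- data.frame(
    flag = c(99L, 99L, 99L, 99L, 99L, 99L),
    mapq = c(60L, 60L, 60L, 60L, 60L, 10L),
    isize = c(160L, -160L, 165L, 300L, 500L, 160L))
  h <- extract_fragment_lengths(recs)
  # manual enumeration: 500 out of range, MAPQ 10 dropped
  expect_equal(h$counts[h$sizes == 160], 2L)
  expect_equal(h$counts[h$sizes == 165], 1L)
  expect_equal(h$counts[h$sizes == 300], 1L)
  expect_equal(h$total, 4L)

  # proper-pair bit unset (flag 65 = paired + first) contributes nothing
  h2 <- extract_fragment_lengths(data.frame(flag = 65L, mapq = 60L,
                                            isize = 160L))
  expect_equal(h2$total, 0L)

  # second-in-pair (flag 147) excluded: no double counting
  h3 <- extract_fragment_lengths(data.frame(flag = c(99L, 147L),
                                            mapq = c(60L, 60L),
                                            isize = c(160L, -160L)))
  expect_equal(h3$total, 1L)

  # empty stream
  h0 <- extract_fragment_lengths(data.frame(flag = integer(),
                                            mapq = integer(),
                                            isize = integer()))
  expect_true(all(h0$counts == 0L))
  expect_equal(h0$total, 0L)

  # missing TLEN skipped and counted
  h4 <- extract_fragment_lengths(data.frame(flag = c(99L, 99L),
                                            mapq = c(60L, 60L),
                                            isize = c(NA, 165L)))
  expect_equal(h4$total, 1L)
  expect_equal(attr(h4, "n_missing_tlen"), 1L)
})

test_that("filtering is order-independent and total bounded by record count", {
  for (s in 1:5) {
    set.seed(s)
    n <- 200L
    recs <- data.frame(flag = sample(c(99L, 147L, 65L, 83L), n, replace = TRUE),
                       mapq = sample(0:60, n, replace = TRUE),
                       isize = sample(c(-600:600), n, replace = TRUE))
    h1 <- extract_fragment_lengths(recs)
    h2 <- extract_fragment_lengths(recs[sample(n), ])
    expect_identical(h1$counts, h2$counts)
    expect_lte(h1$total, n)
  }
})

test_that("extraction from a BAM file matches the record-level path", {
  sam <- file.path(tempdir(), "toy.sam")
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:100000",
    # read pairs: flag 99/147 proper, insert 165; one low-MAPQ; one flag 65
    "r1\t99\tchr1\t1000\t60\t50M\t=\t1115\t165\t*\t*",
    "r1\t147\tchr1\t1115\t60\t50M\t=\t1000\t-165\t*\t*",
    "r2\t99\tchr1\t2000\t60\t50M\t=\t2110\t160\t*\t*",
    "r2\t147\tchr1\t2110\t60\t50M\t=\t2000\t-160\t*\t*",
    "r3\t99\tchr1\t3000\t10\t50M\t=\t3110\t160\t*\t*",
    "r3\t147\tchr1\t3110\t10\t50M\t=\t3000\t-160\t*\t*",
    "r4\t65\tchr1\t4000\t60\t50M\t=\t4500\t550\t*\t*")
  writeLines(lines, sam)
  bam <- Rsamtools::asBam(sam, file.path(tempdir(), "toy"), overwrite = TRUE)
  h <- extract_fragment_lengths(bam)
  expect_equal(h$total, 2L)
  expect_equal(h$counts[h$sizes %in% c(160, 165)], c(1L, 1L))
})

test_that("depth capping thins binomially below the cap and not above", {
  h <- frag_histogram(rep(100L, 100), sample_id = "s",
                      size_min = 100L, size_max = 199L)
  expect_equal(h$total, 10000L)

  # below cap: identity
  expect_identical(cap_depth(h, 1.5, depth_cap_policy(seed = 3))$counts,
                   h$counts)

  # observed 4x vs cap 2x: retention 0.5, total inside central 99% binomial
  capped <- cap_depth(h, 4, depth_cap_policy(seed = 3))
  expect_equal(attr(capped, "retention"), 0.5)
  lo <- qbinom(0.005, 10000, 0.5); hi <- qbinom(0.995, 10000, 0.5)
  expect_gte(capped$total, lo)
  expect_lte(capped$total, hi)

  # expected totals scale linearly with retention across seeds
  for (obs in c(4, 8)) {
    tot <- vapply(1:20, function(s)
      cap_depth(h, obs, depth_cap_policy(seed = s))$total, numeric(1))
    expect_equal(mean(tot), 10000 * 2 / obs, tolerance = 0.03)
  }

  expect_error(cap_depth(h, 0), "observed_mean_depth")
})

test_that("histogram TSV round-trips losslessly and rejects bad input", {
  h <- small_cohort()$histograms[[1]]
  p <- tempfile(fileext = ".tsv")
  write_histogram_tsv(h, p)
  h2 <- read_histogram_tsv(p, sample_id = h$sample_id)
  expect_identical(h$counts, h2$counts)
  expect_identical(h$sizes, h2$sizes)

  # full-grid unit counts: total = grid size
  writeLines(c("size_bp\tcount", sprintf("%d\t1", 74:439)), p)
  expect_equal(read_histogram_tsv(p)$total, 366L)

  writeLines(c("size_bp\tcount", "160\t-3"), p)
  expect_error(read_histogram_tsv(p), "line 2")
  writeLines(c("size_bp\tcount", "73\t5"), p)
  expect_error(read_histogram_tsv(p), "outside grid")
  writeLines(c("size_bp\tcount", "160\t1\textra"), p)
  expect_error(read_histogram_tsv(p), "2 tab-separated")
})
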