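test_that("main-peak detection equals an exhaustive scan with low tie-break", {
  # symmetric unimodal density centred at 200
  d <- frag_distribution(local({
    x <- dnorm(74:439, 200, 15); x / sum(x)
  }))
  expect_equal(detect_main_peak(d), 200L)

  for (s in 1:10) {
    set.seed(s)
    dens <- runif(366); dens <- dens / sum(dens)
    d <- frag_distribution(dens)
    # brute force: scan every grid point
    best <- 74L; bv <- -Inf
    for (i in seq_along(dens)) if (dens[i] > bv) { bv <- dens[i]; best <- 73L + i }
    expect_equal(detect_main_peak(d), best)
  }

  # exact tie broken toward the smaller position
  dens <- rep(0.5 / 364, 366)
  dens[c(50, 80)] <- dens[c(50, 80)] + 0.25
  expect_equal(detect_main_peak(frag_distribution(dens / sum(dens))),
               74L + 49L)
})

test_that("oscillation extrema match brute-force enumeration on a toy curve", {
  # bumpy 40-point sine window decaying into a flat floor, left of a
  # dominant main peak at 200 bp
  sizes <- 74:439
  y <- rep(1e-4, 366)
  y[1:40] <- 0.002 + 0.0005 * sin((1:40) / 3) + 0.00002 * (1:40)
  y[41:60] <- seq(y[40], 1e-4, length.out = 20)  # smooth descent, no edge peak
  y[sizes == 200] <- 0.05
  d <- frag_distribution(y / sum(y))
  prof <- detect_oscillations(d, detection_params(smoothing_window_bp = 1,
                                                  min_prominence = 0,
                                                  expected_period_bp = 2))
  region <- 1:126  # sizes 74..199, strictly left of the main peak
  yy <- d$density[region]
  oracle <- brute_local_extrema(yy)
  expect_equal(prof$cycles$peak_bp, 73L + oracle$peaks)
  expect_equal(prof$cycles$peak_density, yy[oracle$peaks])
  # valleys: minimum strictly between successive peaks (or up to the main
  # peak for the last cycle)
  bounds <- c(oracle$peaks, 127L)
  for (j in seq_len(nrow(prof$cycles))) {
    seg <- (bounds[j] + 1):(bounds[j + 1] - 1)
    expect_equal(prof$cycles$valley_density[j], min(yy[seg]))
  }
  expect_true(all(diff(prof$cycles$peak_bp) > 0))
  expect_true(all(prof$cycles$peak_bp < prof$main_peak_bp))
  expect_equal(prof$cycles$diff,
               prof$cycles$peak_density - prof$cycles$valley_density)
})

test_that("monotone flank yields no cycles; close peaks are merged", {
  x <- dnorm(74:439, 250, 40)
  d <- frag_distribution(x / sum(x))
  expect_equal(nrow(detect_oscillations(d)$cycles), 0L)

  # two bumps 3 bp apart within half a 10.4 bp period collapse to one
  y <- dnorm(74:439, 250, 40)
  y <- y / sum(y)
  y[c(30, 33)] <- y[c(30, 33)] + c(0.002, 0.003)
  d2 <- frag_distribution(y / sum(y))
  prof <- detect_oscillations(d2, detection_params(smoothing_window_bp = 1))
  expect_equal(nrow(prof$cycles), 1L)
  expect_equal(prof$cycles$peak_bp, 73L + 33L)  # higher of the two kept
})

test_that("detected positions are invariant to positive rescaling", {
  d <- cohort_mean_distribution(
    cohort_summary(small_dists()[1:6], "normal"))
  p1 <- detect_oscillations(d)
  scaled <- d
  scaled$density <- d$density * 7.3  # bypass constructor: algorithm-level check
  p2 <- detect_oscillations(scaled)
  expect_equal(p1$cycles$peak_bp, p2$cycles$peak_bp)
  expect_equal(p1$cycles$valley_bp, p2$cycles$valley_bp)
  expect_equal(p1$main_peak_bp, p2$main_peak_bp)
})

test_that("published cycle-table worked examples are reproduced", {
  expect_equal(diff_statistic(0.0065, 0.0048), 0.0017)
  expect_equal(diff_statistic(0.0139, 0.0091), 0.0048)
  expect_equal(diff_statistic(0.004, 0.004), 0)

  rn <- reference_profile("normal")
  rt <- reference_profile("hemangiosarcoma")
  expect_equal(round(group_peak_mean(rn, c(5, 8)), 4), 0.0069)
  expect_equal(round(group_peak_mean(rt, c(5, 8)), 4), 0.0137)
  expect_equal(round(group_peak_mean(rn, c(1, 4)), 4), 0.0022)
  expect_error(group_peak_mean(rn, c(7, 9)), "not all present")

  # constant peak densities: mean is the constant
  cst <- rn
  cst$cycles$peak_density <- 0.004
  expect_equal(group_peak_mean(cst, c(1, 8)), 0.004)

  g <- diff_gap_ranking(rn, rt)
  expect_equal(unname(g$argmax), 6L)
  expect_equal(unname(g$argmin), 4L)

  # identical profiles: zero gaps, argmax 1 by tie-break
  g0 <- diff_gap_ranking(rn, rn)
  expect_true(all(g0$gaps == 0))
  expect_equal(unname(g0$argmax), 1L)
})

test_that("diff-gap ranking matches a brute-force scan on random profiles", {
  mk <- function(diffs) {
    p <- reference_profile("normal")
    p$cycles <- p$cycles[seq_along(diffs), ]
    p$cycles$diff <- diffs
    p
  }
  for (s in 1:10) {
    set.seed(s)
    a <- round(runif(8), 3); b <- round(runif(8), 3)
    g <- diff_gap_ranking(mk(a), mk(b))
    gaps <- abs(a - b)
    expect_equal(unname(g$gaps), gaps)
    expect_equal(unname(g$argmax), which(gaps == max(gaps))[1])
    expect_equal(unname(g$argmin), which(gaps == min(gaps))[1])
  }
  # unequal cycle counts: paired up to the shorter, with a warning
  expect_warning(g <- diff_gap_ranking(mk(runif(8)), mk(runif(5))), "differ")
  expect_length(g$gaps, 5L)
})

test_that("position matching is a greedy one-to-one count", {
  expect_equal(match_positions(c(81, 91, 102), c(81, 91, 102)), 3L)
  expect_equal(match_positions(c(81, 91), c(200, 300)), 0L)
  expect_equal(match_positions(c(81, 91, 100), c(81, 92, 100)), 2L)
  expect_equal(match_positions(c(81, 91, 100), c(81, 92, 100), tolerance_bp = 1), 3L)
  # one-to-one: a single b position cannot absorb two a positions
  expect_equal(match_positions(c(90, 91), 90, tolerance_bp = 1), 1L)
})
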