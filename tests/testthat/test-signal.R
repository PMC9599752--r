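test_that("normalization sets the in-window mean to exactly 1", {
  bait <- point_region(150)
  tr <- toy_track(c(2, 4, 6), stage = "raw", bait = bait)
  out <- normalize_local_mean(tr, signal_params(norm_halfwidth = 1000))
  expect_equal(out$score, c(0.5, 1.0, 1.5))
  expect_equal(mean(out$score), 1, tolerance = 1e-12)
  expect_equal(track_stage(out), "normalized")
  # constant scores normalize to exactly 1
  cst <- normalize_local_mean(toy_track(rep(7, 9), bait = bait),
                              signal_params(norm_halfwidth = 1000))
  expect_equal(cst$score, rep(1, 9))
})

test_that("only in-window fragments define the normalization mean", {
  bait <- point_region(150)
  tr <- toy_track(c(2, 4, 6, 1000, 1000), bait = bait)
  out <- normalize_local_mean(tr, signal_params(norm_halfwidth = 160))
  expect_equal(out$score[1:3], c(0.5, 1.0, 1.5))
})

test_that("all-zero and empty normalization windows are explicit errors", {
  bait <- point_region(150)
  expect_error(
    normalize_local_mean(toy_track(c(0, 0, 0), bait = bait),
                         signal_params(norm_halfwidth = 1000)),
    "cannot normalize")
  far_bait <- point_region(1e6)
  expect_error(
    normalize_local_mean(toy_track(1:3, bait = far_bait),
                         signal_params(norm_halfwidth = 100)),
    "no retained fragment")
})

test_that("running mean matches the edge-truncation arithmetic", {
  tr <- toy_track(1:5, stage = "normalized")
  out <- running_mean(tr, signal_params(smooth_window = 3))
  expect_equal(out$score, c(1.5, 2, 3, 4, 4.5))
  expect_equal(track_stage(out), "smoothed")
  # window wider than the chromosome collapses to the grand mean
  out11 <- running_mean(tr, signal_params(smooth_window = 11))
  expect_equal(out11$score, rep(3, 5))
  # constants are preserved under any window
  cst <- running_mean(toy_track(rep(2.5, 8), stage = "normalized"),
                      signal_params(smooth_window = 5))
  expect_equal(cst$score, rep(2.5, 8))
})

test_that("running mean is shift-equivariant and length-preserving", {
  set.seed(91)
  x <- rexp(40)
  tr <- toy_track(x, stage = "normalized")
  trs <- toy_track(x + 3, stage = "normalized")
  out <- running_mean(tr, signal_params(smooth_window = 7))
  outs <- running_mean(trs, signal_params(smooth_window = 7))
  expect_equal(outs$score, out$score + 3)
  expect_equal(nrow(out), 40L)
})

test_that("running mean smooths each chromosome independently", {
  df <- dplyr::bind_rows(tibble::as_tibble(toy_track(1:5)),
                         tibble::as_tibble(toy_track(101:105, chrom = "chrU")))
  tr <- new_track(df, stage = "normalized")
  out <- running_mean(tr, signal_params(smooth_window = 3))
  expect_equal(out$score[1:5], c(1.5, 2, 3, 4, 4.5))
  expect_equal(out$score[6:10], c(101.5, 102, 103, 104, 104.5))
})

test_that("exact power-law input recovers the closed-form intercept", {
    d <- c(10, 100, 1000)
  tr <- decay_track(d, 100 / d)
  prm <- signal_params(fit_min_distance = 10, fit_max_distance = 1000)
  fit <- fit_decay(tr, prm)
  expect_equal(fit$intercept, 2.0, tolerance = 1e-12)
  expect_equal(fit$slope, -1)
  expect_equal(fit$n_points, 3L)
  # any amplitude C gives intercept log10(C)
  trc <- decay_track(d, 37.5 / d)
  expect_equal(fit_decay(trc, prm)$intercept, log10(37.5), tolerance = 1e-12)
})

test_that("zero scores are excluded from the fit; too few points error", {
    prm <- signal_params(fit_min_distance = 10, fit_max_distance = 1000)
  tr <- decay_track(c(10, 100, 1000), c(10, 0, 0.01))
  expect_equal(fit_decay(tr, prm)$n_points, 2L)
  tr1 <- decay_track(c(10, 100, 1000), c(10, 0, 0))
  expect_error(fit_decay(tr1, prm), "at least 2")
})

test_that("intercept is recovered under multiplicative lognormal noise", {
  set.seed(92)
  d <- sort(runif(200, 10, 1000))
  s <- 100 / d * 10^rnorm(200, 0, 0.2)
  tr <- decay_track(d, s)
  fit <- fit_decay(tr, signal_params(fit_min_distance = 10,
                                     fit_max_distance = 1000))
  expect_lt(abs(fit$intercept - 2.0), 3 * fit$se)
})

test_that("profile correction flattens exact power-law decay to ones", {
    prm <- signal_params(fit_min_distance = 10, fit_max_distance = 1000)
  d <- 10^seq(1, 3, length.out = 50)
  tr <- decay_track(d, 100 / d)
  fit <- fit_decay(tr, prm)
  out <- profile_correct(tr, fit)
  expect_equal(out$score, rep(1, 50), tolerance = 1e-9)
  expect_equal(track_stage(out), "profile_corrected")
  # residual slope of log-corrected vs log-distance is zero
  resid_slope <- stats::coef(stats::lm(log10(out$score) ~ log10(d)))[2]
  expect_lt(abs(resid_slope), 1e-9)
  # doubling the observed scores doubles the corrected scores at fixed fit
  tr2 <- decay_track(d, 200 / d)
  out2 <- profile_correct(tr2, fit)
  expect_equal(out2$score, 2 * out$score, tolerance = 1e-12)
})

test_that("a planted peak stands out at the closed-form enrichment", {
    prm <- signal_params(fit_min_distance = 10, fit_max_distance = 1000)
  d <- 10^seq(1, 3, length.out = 60)
  peak <- d >= 400 & d <= 600
  s <- 100 / d * ifelse(peak, 3, 1)
  tr <- decay_track(d, s)
  fit <- fit_decay(tr, prm)
  a_expected <- 2 + mean(peak) * log10(3)  # refit absorbs part of the peak
  expect_equal(fit$intercept, a_expected, tolerance = 1e-12)
  expect_gt(fit$intercept, 2.0)
  out <- profile_correct(tr, fit)
  expect_equal(unique(round(out$score[!peak], 10)),
               round(10^(2 - a_expected), 10))
  expect_equal(unique(round(out$score[peak], 10)),
               round(3 * 10^(2 - a_expected), 10))
})

test_that("extrapolated and zero fragments are flagged through correction", {
    prm <- signal_params(fit_min_distance = 50, fit_max_distance = 1000)
  tr <- decay_track(c(20, 100, 300, 900), c(5, 1, 0, 100 / 900))
  fit <- fit_decay(tr, prm)
  out <- profile_correct(tr, fit)
  expect_equal(out$extrapolated, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$score[3], 0)
})

test_that("a surviving bait fragment aborts profile correction", {
  bait <- point_region(100, w = 2)
  tr <- track_at(c(100, 300, 500), c(5, 3, 1), w = 2, bait = bait)
  fit <- fit_decay(tr, signal_params(fit_min_distance = 100,
                                     fit_max_distance = 1000))
  expect_error(profile_correct(tr, fit), "exclusion")
})

test_that("stage transitions are enforced", {
  raw <- toy_track(1:5, bait = point_region(250))
  nrm <- normalize_local_mean(raw, signal_params(norm_halfwidth = 1e4))
  expect_error(normalize_local_mean(nrm), "expects a track at stage raw")
  expect_error(running_mean(raw), "expects a track at stage normalized")
  sm <- running_mean(nrm, signal_params(smooth_window = 3))
  expect_error(fit_decay(sm), "expects a track at stage normalized")
  expect_error(profile_correct(sm, structure(list(), class = "decay_fit")),
               "expects a track at stage normalized")
})

test_that("trans fragments pass normalization but are dropped by correction", {
  bait <- point_region(230)
  df <- dplyr::bind_rows(tibble::as_tibble(toy_track(c(4, 4, 4, 4))),
                         tibble::as_tibble(toy_track(c(8, 8), chrom = "chrU")))
  tr <- new_track(df, stage = "raw", bait = bait)
  nrm <- normalize_local_mean(tr, signal_params(norm_halfwidth = 1e4))
  expect_equal(nrow(nrm), 6L)          # trans carried through
  expect_equal(nrm$score[5:6], c(2, 2))  # divided by the cis window mean
  fit <- fit_decay(nrm, signal_params(fit_min_distance = 10,
                                      fit_max_distance = 1e4))
  out <- profile_correct(nrm, fit)
  expect_true(all(out$chrom == "chrT"))
})
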