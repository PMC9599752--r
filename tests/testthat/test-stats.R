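test_that("normality K2 matches independently computed reference values", {
  # frozen reference values from an independent implementation of the
  # D'Agostino / Anscombe-Glynn transforms on deterministic samples
  r <- dagostino_pearson(sin(1:50))
  expect_equal(r$statistic, 43.26765816707633, tolerance = 1e-9)
  expect_equal(r$p_value, 4.022975674741114e-10, tolerance = 1e-6)
  expect_equal(r$skew_z, 0.02924317897698248, tolerance = 1e-9)
  expect_equal(r$kurt_z, -6.577750603630366, tolerance = 1e-9)

  r2 <- dagostino_pearson((1:20)^2)
  expect_equal(r2$statistic, 2.514697432414396, tolerance = 1e-9)
  expect_equal(r2$p_value, 0.28440707165007806, tolerance = 1e-9)

  x3 <- c(1, 2, 2, 3, 3, 3, 4, 4, 4, 4, 5, 5, 5, 6, 6, 7, 8, 9, 10, 12,
          15, 20)
  r3 <- dagostino_pearson(x3)
  expect_equal(r3$statistic, 13.608051559819899, tolerance = 1e-9)
  expect_equal(r3$p_value, 0.0011093003475545163, tolerance = 1e-9)
})

test_that("strong skew is detected; small and degenerate samples handled", {
  set.seed(101)
  expect_lt(dagostino_pearson(rexp(200))$p_value, 0.01)
  expect_warning(r <- dagostino_pearson(1:5), "n >= 8")
  expect_false(r$applicable)
  expect_true(is.na(r$p_value))
  expect_error(dagostino_pearson(rep(3, 20)), "zero-variance")
})

test_that("normality gate holds its type-I error on normal data", {
  set.seed(102)
  rej <- mean(replicate(1000, dagostino_pearson(rnorm(1000))$p_value < 0.05))
  expect_gt(rej, 0.05 - 0.025)
  expect_lt(rej, 0.05 + 0.025)
})

test_that("Mann-Whitney worked examples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_two_tailed, 0.1)
  expect_equal(r$method, "exact")
  # identical singletons: a tie, no evidence
  expect_equal(mann_whitney_u(5, 5)$p_two_tailed, 1.0)
  # identical multisets
  r2 <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r2$U, 8)
  expect_gte(r2$p_two_tailed, 0.99)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact path equals brute-force enumeration for small groups", {
  set.seed(103)
  for (i in 1:60) {
    n1 <- sample(1:6, 1)
    n2 <- sample(1:6, 1)
    v <- sample(1:60, n1 + n2)  # tie-free
    x <- v[seq_len(n1)]
    y <- v[-seq_len(n1)]
    r <- mann_whitney_u(x, y)
    expect_equal(r$method, "exact")
    expect_equal(r$p_two_tailed, mw_enum_p(x, y))
  }
})

test_that("U statistics are symmetric and complementary", {
  set.seed(104)
  for (i in 1:20) {
    x <- rnorm(sample(3:40, 1))
    y <- rnorm(sample(3:40, 1))
    rx <- mann_whitney_u(x, y)
    ry <- mann_whitney_u(y, x)
    expect_equal(rx$p_two_tailed, ry$p_two_tailed)
    expect_equal(rx$U + ry$U, length(x) * length(y))
    expect_gte(rx$U, 0)
    expect_lte(rx$U, length(x) * length(y))
  }
})

test_that("normal approximation agrees with wilcox.test and permutation", {
  set.seed(105)
  x <- rnorm(50)
  y <- rnorm(50, 0.3)
  r <- mann_whitney_u(x, y)
  expect_equal(r$method, "normal_approx")
  w <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(r$p_two_tailed, w$p.value, tolerance = 1e-8)
  # permutation oracle
  pool <- c(x, y)
  m <- 50 * 50 / 2
  obs <- abs(r$U - m)
  set.seed(106)
  perm <- replicate(20000, {
    idx <- sample(100, 50)
    rr <- rank(pool)
    abs(sum(rr[idx]) - 50 * 51 / 2 - m)
  })
  expect_lt(abs(r$p_two_tailed - mean(perm >= obs - 1e-9)), 0.01)
})

test_that("tied data use the tie-corrected variance", {
  set.seed(107)
  x <- sample(1:5, 30, replace = TRUE)
  y <- sample(2:6, 30, replace = TRUE)
  r <- mann_whitney_u(x, y)
  w <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(r$p_two_tailed, w$p.value, tolerance = 1e-8)
  # fully tied groups carry no evidence
  expect_equal(mann_whitney_u(rep(1, 10), rep(1, 12))$p_two_tailed, 1)
})

test_that("star mapping is pure and monotone", {
  expect_equal(p_stars(c(0.2, 0.04, 0.009, 9e-4, 1e-4, 2e-4)),
               c("ns", "*", "**", "***", "****", "***"))
  p <- sort(10^runif(50, -6, 0))
  stars <- p_stars(p)
  width <- nchar(gsub("ns", "", stars))
  expect_true(all(diff(width) <= 0))
  expect_error(stats_params(star_thresholds = c(0.05, 0.01, 0.001, 0.01)))
})

test_that("region score extraction respects midpoints and order", {
  tr <- toy_track(c(5, 6, 7, 8))  # midpoints 50, 150, 250, 350
  expect_equal(extract_region_scores(tr, region("chrT", 0, 400)),
               c(5, 6, 7, 8))
  expect_equal(extract_region_scores(tr, region("chrT", 100, 300)),
               c(6, 7))
  # half-open: a midpoint at the region end is outside
  expect_equal(extract_region_scores(tr, region("chrT", 100, 250)), 6)
  expect_warning(v <- extract_region_scores(tr, region("chrT", 360, 390)),
                 "no retained fragment")
  expect_equal(v, numeric(0))
})

test_that("self-comparison of a condition is null at both stages", {
  sh <- shared_sim()
  sims <- simulate_scores(sh$map, sh$cfg)
  proc <- proc_conditions(sims, sh$cfg$excluded_region)
  res <- compare_conditions(proc$whisker_pad, proc$whisker_pad,
                            sh$cfg$peak_region)
  expect_equal(nrow(res), 2L)
  expect_setequal(res$stage, c("normalized", "profile_corrected"))
  expect_true(all(res$p_two_tailed >= 0.99))
  expect_true(all(res$stars == "ns"))
})

test_that("missing stages and undersized regions are errors", {
  sh <- shared_sim()
  sims <- simulate_scores(sh$map, sh$cfg)
  proc <- proc_conditions(sims, sh$cfg$excluded_region)
  broken <- proc$whisker_pad
  broken[[2]] <- broken[[2]]["normalized"]
  expect_error(
    compare_conditions(broken, proc$kidney, sh$cfg$peak_region),
    "stage 'profile_corrected' missing .* replicate 2")
  # a region squeezed between two fragment midpoints contains none of them
  mids <- (sh$map$start + sh$map$end) / 2
  m <- min(mids[mids > sh$cfg$bait_center + 500000])
  tiny <- region(sh$cfg$contig_name, m + 1, m + 2, "tiny")
  m_next <- min(mids[mids > m])
  stopifnot(m_next > m + 2)
  expect_error(
    suppressWarnings(
      compare_conditions(proc$whisker_pad, proc$kidney, tiny)),
    "fewer than 2")
})

test_that("differential contacts reach significance with a planted peak", {
  sh <- shared_sim()
  sims <- simulate_scores(sh$map, sh$cfg)  # default fold 3, seed 1
  proc <- proc_conditions(sims, sh$cfg$excluded_region)
  res <- compare_conditions(proc$whisker_pad, proc$kidney,
                            sh$cfg$peak_region,
                            condition_names = c("whisker_pad", "kidney"))
  pc <- res[res$stage == "profile_corrected", ]
  expect_lt(pc$p_two_tailed, 0.01)
  expect_gte(pc$U, 0)
  expect_lte(pc$U, pc$n1 * pc$n2)
  # enrichment is in the first condition: its ranks dominate
  expect_gt(pc$U, pc$n1 * pc$n2 / 2)
  expect_equal(pc$n1, pc$n2)  # same fragments pooled over equal replicates
  expect_true(all(res$normality_p_a >= 0 & res$normality_p_a <= 1,
                  na.rm = TRUE))
})

test_that("tidiers return broom-shaped tibbles", {
  sh <- shared_sim()
  sims <- simulate_scores(sh$map, sh$cfg)
  proc <- process_replicate(sims$kidney[[1]], sh$cfg$excluded_region)
  td <- tidy(proc$decay_fit)
  expect_equal(td$term, c("intercept", "slope"))
  expect_true(td$fixed[2])
  gl <- glance(proc$decay_fit)
  expect_equal(gl$slope, -1)
  res <- compare_conditions(list(proc), list(proc), sh$cfg$peak_region)
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res)$n_tests, 2L)
})
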