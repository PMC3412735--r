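test_that("MGET is exact for a boxcar retention (all mass leaves in one interval)", {
  t <- seq(0, 420, 10)
  r <- retention_curve(t, ifelse(t <= 100, 1, 0))
  expect_equal(gastric_emptying_time(r), 105)
})

test_that("MGET of sampled smooth curves matches the closed-form means", {
  t <- seq(0, 700, 10)
  r <- retention_curve(t, exp(-0.01 * t))
  expect_rel_error(gastric_emptying_time(r), 100, 0.01)

  t4 <- seq(0, 400, 10)
  pe <- retention_curve(t4, exp(-(0.01 * t4)^2))
  est <- gastric_emptying_time(pe)
  expect_rel_error(est, gamma(1.5) / 0.01, 0.01)
  # dense-grid oracle agrees with the analytic mean
  oracle <- dense_area(function(x) exp(-(0.01 * x)^2), 400)
  expect_equal(oracle, gamma(1.5) / 0.01, tolerance = 1e-4)
  expect_rel_error(est, oracle, 0.01)
})

test_that("MCAT is exact for a single-jump arrival and matches the exponential mean", {
  t <- seq(0, 420, 10)
  a <- arrival_curve(t, ifelse(t <= 200, 0, 1))
  expect_equal(cecum_arrival_time(a), 205)

  t7 <- seq(0, 700, 10)
  ae <- arrival_curve(t7, 1 - exp(-0.01 * t7))
  expect_rel_error(cecum_arrival_time(ae), 100, 0.01)
})

test_that("area form and rate-weighted form of MGET agree on complete curves", {
  set.seed(42)
  for (i in 1:25) {
    r <- random_monotone_retention(n = sample(5:40, 1))
    expect_equal(gastric_emptying_time(r),
                 acbtransit:::mget_rate_weighted(r), tolerance = 1e-9)
  }
})

test_that("MGET scales linearly under time rescaling", {
  t <- seq(0, 700, 10)
  r1 <- retention_curve(t, exp(-0.01 * t))
  r2 <- retention_curve(2 * t, exp(-0.01 * t))  # R(t/2) on a doubled grid
  expect_equal(gastric_emptying_time(r2), 2 * gastric_emptying_time(r1),
               tolerance = 1e-12)
})

test_that("halving the sampling interval moves MGET monotonically toward the dense oracle", {
  oracle <- dense_area(function(x) exp(-0.01 * x), 700, dt = 0.001)
  errs <- sapply(c(10, 5, 2.5), function(h) {
    t <- seq(0, 700, h)
    abs(gastric_emptying_time(retention_curve(t, exp(-0.01 * t))) - oracle)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("incomplete gastric decay warns under truncation and is repaired by tail extrapolation", {
  t <- seq(0, 200, 10)
  r <- retention_curve(t, exp(-0.01 * t))
  expect_warning(trunc <- gastric_emptying_time(r), "incomplete emptying")
  expect_lt(trunc, 90)  # truncation can only underestimate
  ext <- gastric_emptying_time(r, moment_config("exponential_extrapolate"))
  expect_rel_error(ext, 100, 0.01)
})

test_that("an unfinished arrival plateau is flagged and truncation only decreases MCAT", {
  t <- seq(0, 700, 10)
  cfull <- 1 - exp(-0.005 * t)
  full <- arrival_curve(t, cfull)
  expect_warning(mcat_full <- cecum_arrival_time(full), "plateau not reached")
  short <- arrival_curve(t[t <= 400], cfull[t <= 400])
  expect_warning(mcat_short <- cecum_arrival_time(short), "plateau not reached")
  expect_lt(mcat_short, mcat_full)
})

test_that("MSITT is the difference of the two moments", {
  expect_equal(small_intestinal_transit_time(119, 209), 90)
  expect_equal(small_intestinal_transit_time(203, 334), 131)
  expect_equal(small_intestinal_transit_time(123.4, 123.4), 0)
  expect_warning(neg <- small_intestinal_transit_time(200, 150), "negative MSITT")
  expect_equal(neg, -50)
})

test_that("t50 interpolates the first half-intensity crossing", {
  expect_equal(t50(retention_curve(c(0, 10, 20, 30, 40), c(1, 0.75, 0.5, 0.25, 0))), 20)
  expect_equal(t50(retention_curve(seq(0, 40, 10), c(1, 0.6, 0.4, 0.2, 0))), 15)
  t <- seq(0, 700, 10)
  expect_lt(abs(t50(retention_curve(t, exp(-0.01 * t))) - log(2) / 0.01), 1)
  expect_error(t50(retention_curve(c(0, 10, 20, 30), c(1, 0.9, 0.8, 0.7))),
               "incomplete emptying for t50")
})

test_that("analyze_recording composes normalization and moments with quality flags", {
  p <- solid_like(k = 0.01, beta = 2)
  rec <- simulate_recording(p, noise = noise_params(0))
  tt <- suppressWarnings(analyze_recording(rec$stomach, rec$cecum,
                                           gastric_baseline = "zero",
                                           cecal_baseline = "zero"))
  expect_rel_error(tt$mget, gamma(1.5) / 0.01, 0.01)
  expect_equal(tt$msitt, tt$mcat - tt$mget)

  flat <- signal_curve(rec$stomach$times, rep(1, length(rec$stomach$times)),
                       meal = "solid", animal_id = "sim")
  expect_error(analyze_recording(flat, rec$cecum), "degenerate recording")

  other <- rec$cecum
  other$animal_id <- "someone-else"
  expect_error(analyze_recording(rec$stomach, other), "same animal")
})
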