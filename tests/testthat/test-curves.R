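test_that("gastric normalization rescales affinely and anchors the first sample at 1", {
  sc <- signal_curve(seq(0, 50, 10), c(10, 5, 2.5, 0, 0, 0))
  r <- normalize_gastric(sc, "tail")
  expect_equal(r$fraction_remaining, c(1, 0.5, 0.25, 0, 0, 0))

  # invariance under positive affine transforms when the true tail is flat
  set.seed(11)
  base <- c(1, 0.7, 0.45, 0.2, 0.05, 0, 0, 0)
  for (i in 1:10) {
    a <- runif(1, 0.1, 50)
    b <- runif(1, -5, 5)
    sc2 <- signal_curve(seq(0, 70, 10), a * base + b)
    expect_equal(normalize_gastric(sc2, "tail")$fraction_remaining, base,
                 tolerance = 1e-12)
  }
})

test_that("degenerate and inverted gastric recordings are rejected", {
  flat <- signal_curve(seq(0, 40, 10), rep(3, 5))
  expect_error(normalize_gastric(flat), "degenerate recording")
  rising <- signal_curve(seq(0, 40, 10), c(1, 2, 5, 8, 9))
  expect_error(normalize_gastric(rising, "tail"), "inverted curve")
})

test_that("very negative retention flags a baseline problem and is floored", {
  sc <- signal_curve(seq(0, 50, 10), c(10, 6, 2, -3, 0.2, 0.1))
  expect_warning(r <- normalize_gastric(sc, "zero"), "baseline")
  expect_gte(min(r$fraction_remaining), -0.1)
})

test_that("cecal normalization scales by the maximal cumulative value", {
  cc <- signal_curve(seq(0, 50, 10), c(0, 0, 1, 3, 4, 4), site = "cecum")
  a <- normalize_cecal(cc)
  expect_equal(a$fraction_arrived, c(0, 0, 0.25, 0.75, 1, 1))
  expect_equal(max(a$fraction_arrived), 1)

  flat <- signal_curve(seq(0, 40, 10), rep(2, 5), site = "cecum")
  expect_error(normalize_cecal(flat), "no detectable arrival")
})

test_that("isotonic smoothing makes a noisy cecal curve monotone", {
  set.seed(3)
  t <- seq(0, 200, 10)
  s <- pmin(t / 120, 1) + rnorm(length(t), 0, 0.05)
  cc <- signal_curve(t, s, site = "cecum")
  sm <- normalize_cecal(cc, "zero", smooth = TRUE)
  expect_true(all(diff(sm$fraction_arrived) >= -1e-12))
  raw <- normalize_cecal(cc, "zero", smooth = FALSE)
  expect_true(all(raw$fraction_arrived >= 0 & raw$fraction_arrived <= 1))
})

test_that("site mismatches are caught", {
  sc <- signal_curve(seq(0, 40, 10), c(5, 4, 3, 2, 1))
  expect_error(normalize_cecal(sc), "cecum-site")
  cc <- signal_curve(seq(0, 40, 10), c(0, 1, 2, 3, 3), site = "cecum")
  expect_error(normalize_gastric(cc), "stomach-site")
})

test_that("noiseless liquid simulation normalizes to the closed-form exponential", {
  rec <- simulate_recording(liquid_like(duration_min = 700),
                            noise = noise_params(0))
  r <- normalize_gastric(rec$stomach, "zero")
  expect_lt(max(abs(r$fraction_remaining - exp(-0.01 * r$times))), 1e-6)
})

test_that("noiseless cecal normalization matches the simulated compartment masses", {
  p <- liquid_like(duration_min = 700)
  rec <- simulate_recording(p, noise = noise_params(0))
  a <- normalize_cecal(rec$cecum, "zero")
  tr <- simulate_compartments(p)
  cec <- tr$masses[, "cecum"]
  expect_true(all(diff(a$fraction_arrived) >= -1e-12))
  expect_equal(a$fraction_arrived, cec / max(cec), tolerance = 1e-9)
})

test_that("transit_times enforces the MSITT identity and flags inconsistency", {
  tt <- transit_times(100, 180)
  expect_equal(tt$msitt, 80)
  expect_warning(transit_times(200, 150), "negative MSITT")
  expect_error(transit_times(-5, 100), "positive")
})
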