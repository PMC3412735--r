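test_that("total tracer mass is conserved for liquid and solid regimes", {
  for (p in list(liquid_like(), solid_like(),
                 liquid_like(k_e = 0.03, n_compartments = 1, k_t = 0.2),
                 solid_like(beta = 3, n_compartments = 8, k_t = 0.1, m0 = 2.5))) {
    tr <- simulate_compartments(p)
    expect_lt(max(abs(rowSums(tr$masses) - p$m0)), 1e-6 * p$m0)
  }
})

test_that("liquid stomach mass follows the closed-form exponential", {
  p <- liquid_like(duration_min = 700)
  tr <- simulate_compartments(p)
  expect_lt(max(abs(tr$masses[, "stomach"] - exp(-0.01 * tr$times))), 1e-6)
})

test_that("a vanishing emptying rate keeps the meal gastric", {
  tr <- simulate_compartments(liquid_like(k_e = 1e-9))
  expect_true(all(tr$masses[, "stomach"] > 1 - 1e-5))
  expect_true(all(tr$masses[, "cecum"] < 1e-6))
})

test_that("mean cecal arrival time equals the sum of compartment residence times", {
  # chain of independent stages: 1/k_e + N/k_t = 100 + 80 = 180 min
  p <- liquid_like(duration_min = 1200)
  tr <- simulate_compartments(p, t_grid = seq(0, 1200, 1))
  arr_rate <- diff(tr$masses[, "cecum"])
  tmid <- (tr$times[-1] + tr$times[-length(tr$times)]) / 2
  mcat_quad <- sum(tmid * arr_rate) / sum(arr_rate)
  expect_rel_error(mcat_quad, 1 / p$k_e + p$n_compartments / p$k_t, 0.01)
})

test_that("analyzed noiseless simulation separates MGET and MCAT by N/k_t", {
  rec <- simulate_recording(liquid_like(duration_min = 700),
                            noise = noise_params(0))
  tt <- suppressWarnings(analyze_recording(rec$stomach, rec$cecum,
                                           gastric_baseline = "zero",
                                           cecal_baseline = "zero"))
  expect_rel_error(tt$msitt, 4 / 0.05, 0.02)
})

test_that("sensor response is the gradiometric two-term power law", {
  s <- sensor_params(exponent_p = 3, gain = 1)
  expect_equal(sensor_response(1, 3, s), 1 / 27 - 1 / 5832, tolerance = 1e-12)
  expect_equal(sensor_response(0, 3, s), 0)
  # linear in mass, strictly decreasing in distance
  expect_equal(sensor_response(3.7, 5, s), 3.7 * sensor_response(1, 5, s))
  d <- seq(1, 12, 0.5)
  expect_true(all(diff(sensor_response(1, d, sensor_params())) < 0))
  expect_error(sensor_response(1, 0, s), "positive")
  expect_error(sensor_response(1, -2, s), "positive")
})

test_that("noiseless recordings are proportional to the compartment masses", {
  p <- liquid_like()
  rec <- simulate_recording(p, noise = noise_params(0))
  tr <- simulate_compartments(p)
  ratio <- rec$stomach$intensities / tr$masses[, "stomach"]
  expect_lt(diff(range(ratio)), 1e-9 * ratio[1])
})

test_that("recordings are deterministic for a fixed seed and differ across seeds", {
  r1 <- simulate_recording(liquid_like(), noise = noise_params(seed = 99))
  r2 <- simulate_recording(liquid_like(), noise = noise_params(seed = 99))
  r3 <- simulate_recording(liquid_like(), noise = noise_params(seed = 100))
  expect_identical(r1$stomach$intensities, r2$stomach$intensities)
  expect_identical(r1$cecum$intensities, r2$cecum$intensities)
  expect_false(identical(r1$stomach$intensities, r3$stomach$intensities))
})

test_that("a crosstalk distance matrix lets distant compartments leak into a site", {
  p <- liquid_like(n_compartments = 2)
  # stomach sensor also sees both SI compartments at 6 cm
  ct <- matrix(Inf, nrow = 4, ncol = 2)
  ct[1, 1] <- 2; ct[4, 2] <- 2; ct[2, 1] <- 6; ct[3, 1] <- 6
  rec_ct <- simulate_recording(p, sensor_params(crosstalk = ct),
                               noise = noise_params(0))
  rec <- simulate_recording(p, noise = noise_params(0))
  expect_true(all(rec_ct$stomach$intensities >= rec$stomach$intensities))
  expect_gt(max(rec_ct$stomach$intensities - rec$stomach$intensities), 0)
  expect_equal(rec_ct$cecum$intensities, rec$cecum$intensities)
})

test_that("the validation study produces 18 records with the designed structure", {
  recs <- simulate_validation_study(noise = noise_params(0.01, seed = 5))
  expect_s3_class(recs, "validation_records")
  expect_equal(nrow(recs), 18)
  expect_equal(sort(unique(recs$kill_time_min)), seq(10, 60, 10))
  expect_true(all(table(recs$kill_time_min) == 3))
  expect_true(all(recs$distance_cm >= 0))
})

test_that("without noise or population spread the tracer front is non-decreasing in kill time", {
  recs <- simulate_validation_study(noise = noise_params(0),
                                    population_cv = 0, n_per_timepoint = 1)
  expect_true(all(diff(recs$distance_cm[order(recs$kill_time_min)]) >= 0))
})
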