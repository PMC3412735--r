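# dense-grid trapezoidal oracle for the first moment of a retention curve,
# independent of the package's sample-grid estimator
dense_area <- function(f, t_end, dt = 0.01) {
  t <- seq(0, t_end, by = dt)
  y <- f(t)
  sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
}

# random monotone non-increasing retention curve with R[1] = 1, R[end] = 0
random_monotone_retention <- function(n = 20, dt = 10) {
  drops <- runif(n - 1)
  r <- c(1, 1 - cumsum(drops) / sum(drops))
  retention_curve(seq(0, by = dt, length.out = n), pmax(r, 0))
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
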