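#' Construct a raw two-site signal curve
#'
#' A `signal_curve` holds one recording site's magnetic intensity time
#' series: signal in mV sampled at (nominally) regular 10-min intervals at
#' either the gastric or the cecal projection of the abdominal surface.
#'
#' @param times Sampling times in minutes since meal ingestion;
#'   non-negative, strictly increasing, length >= 4.
#' @param intensities Signal intensities in mV; finite, same length as
#'   `times`.
#' @param site `"stomach"` or `"cecum"`.
#' @param meal `"liquid"` or `"solid"`.
#' @param animal_id Opaque animal label.
#' @return An object of class `signal_curve`.
#' @examples
#' sc <- signal_curve(seq(0, 60, 10), c(10, 8, 6, 4, 3, 2, 1.5))
#' sc
#' @export
signal_curve <- function(times, intensities, site = c("stomach", "cecum"),
                         meal = c("liquid", "solid"), animal_id = "unknown") {
  site <- match.arg(site)
  meal <- match.arg(meal)
  times <- as.double(times)
  intensities <- as.double(intensities)
  if (length(times) != length(intensities))
    stop("times and intensities must have equal length")
  if (length(times) < 4)
    stop("a signal curve needs at least 4 samples")
  if (anyNA(times) || any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and non-negative")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (anyNA(intensities) || any(!is.finite(intensities)))
    stop("intensities must be finite")
  structure(
    list(times = times, intensities = intensities, site = site,
         meal = meal, animal_id = as.character(animal_id)),
    class = "signal_curve")
}

#' @export
print.signal_curve <- function(x, ...) {
  cat(sprintf("<signal_curve> site=%s meal=%s animal=%s  %d samples, t = %g..%g min, S = %.3g..%.3g mV\n",
              x$site, x$meal, x$animal_id, length(x$times),
              min(x$times), max(x$times), min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Construct a normalized gastric retention curve
#'
#' Fraction of the magnetic meal remaining in the stomach over time; the
#' first sample is 1 by construction.  Usually produced by
#' [normalize_gastric()]; direct construction is for curves already on the
#' retention scale.
#'
#' @param times Minutes, strictly increasing.
#' @param fraction_remaining Dimensionless retention fraction; first value
#'   must equal 1 (within 1e-9).  Values may stray slightly outside
#'   `[0, 1]` under noise; values are floored at -0.1.
#' @return An object of class `retention_curve`.
#' @export
retention_curve <- function(times, fraction_remaining) {
  times <- as.double(times)
  fr <- as.double(fraction_remaining)
  if (length(times) != length(fr) || length(times) < 2)
    stop("times and fraction_remaining must have equal length >= 2")
  if (any(diff(times) <= 0) || any(times < 0))
    stop("times must be non-negative and strictly increasing")
  if (anyNA(fr) || any(!is.finite(fr)))
    stop("fraction_remaining must be finite")
  if (abs(fr[1] - 1) > 1e-9)
    stop("retention curve not normalized: first value must be 1")
  if (min(fr) < -0.1)
    acb_warn("retention fraction below -0.1: baseline is likely wrong",
             "acb_quality_warning")
  fr <- pmax(fr, -0.1)
  structure(list(times = times, fraction_remaining = fr),
            class = "retention_curve")
}

#' Construct a normalized cumulative cecal arrival curve
#'
#' Cumulative fraction of the meal that has arrived at the cecum,
#' normalized by the plateau (maximal cumulative) value.  Usually produced
#' by [normalize_cecal()].
#'
#' @param times Minutes, strictly increasing.
#' @param fraction_arrived Cumulative arrival fraction in `[0, 1]`.
#' @return An object of class `arrival_curve`.
#' @export
arrival_curve <- function(times, fraction_arrived) {
  times <- as.double(times)
  fa <- as.double(fraction_arrived)
  if (length(times) != length(fa) || length(times) < 2)
    stop("times and fraction_arrived must have equal length >= 2")
  if (any(diff(times) <= 0) || any(times < 0))
    stop("times must be non-negative and strictly increasing")
  if (anyNA(fa) || any(!is.finite(fa)))
    stop("fraction_arrived must be finite")
  if (min(fa) < -1e-9 || max(fa) > 1 + 1e-9)
    stop("fraction_arrived must lie in [0, 1]")
  structure(list(times = times, fraction_arrived = pmin(pmax(fa, 0), 1)),
            class = "arrival_curve")
}

#' Normalize a gastric-site signal into a retention curve
#'
#' Estimates a baseline `b` and rescales the signal affinely so that the
#' first sample equals 1: `R(t) = (S(t) - b) / (S(t0) - b)`.  With
#' `baseline_mode = "tail"` (the default for field recordings) `b` is the
#' mean of the last 3 samples, which assumes the stomach has emptied
#' completely by the end of the >= 7 h record.  With `"zero"` no offset is
#' subtracted, appropriate when the sensor is known to be offset-free
#' (e.g. simulated recordings).
#'
#' @param curve A `signal_curve` with `site = "stomach"`.
#' @param baseline_mode `"tail"` or `"zero"`, or a single number giving an
#'   explicit baseline in mV.
#' @return A `retention_curve`.  Retention values below -0.1 trigger a
#'   quality warning (baseline likely wrong) and are floored at -0.1.
#' @examples
#' sc <- signal_curve(seq(0, 50, 10), c(10, 5, 2.5, 0, 0, 0))
#' normalize_gastric(sc)$fraction_remaining
#' @export
normalize_gastric <- function(curve, baseline_mode = c("tail", "zero")) {
  stopifnot(inherits(curve, "signal_curve"))
  if (curve$site != "stomach")
    stop("normalize_gastric expects a stomach-site curve")
  s <- curve$intensities
  if (diff(range(s)) == 0)
    stop("degenerate recording: zero dynamic range (all intensities equal)")
  b <- if (is.numeric(baseline_mode)) {
    as.double(baseline_mode[1])
  } else {
    switch(match.arg(baseline_mode),
           tail = mean(s[seq(length(s) - 2, length(s))]),
           zero = 0)
  }
  if (s[1] <= b)
    stop("inverted curve: first gastric sample does not exceed the baseline")
  retention_curve(curve$times, (s - b) / (s[1] - b))
}

#' Normalize a cecal-site signal into a cumulative arrival curve
#'
#' Subtracts a pre-arrival baseline (default: mean of the first 2 samples,
#' which assumes no tracer has reached the cecum in the first minutes of
#' the record) and divides by the maximal cumulative value `C_max`, so the
#' plateau equals 1.  Values are clipped to `[0, 1]`.
#'
#' @param curve A `signal_curve` with `site = "cecum"`.
#' @param baseline_mode `"head"` (mean of first 2 samples) or `"zero"`, or
#'   an explicit numeric baseline in mV.
#' @param smooth If `TRUE`, apply isotonic (pool-adjacent-violators)
#'   regression to the baseline-corrected signal before normalization,
#'   enforcing monotone non-decreasing arrival.  Off by default; moments
#'   integrate the raw clipped curve.
#' @return An `arrival_curve`.
#' @examples
#' cc <- signal_curve(seq(0, 50, 10), c(0, 0, 1, 3, 4, 4), site = "cecum")
#' normalize_cecal(cc)$fraction_arrived
#' @export
normalize_cecal <- function(curve, baseline_mode = c("head", "zero"),
                            smooth = FALSE) {
  stopifnot(inherits(curve, "signal_curve"))
  if (curve$site != "cecum")
    stop("normalize_cecal expects a cecum-site curve")
  s <- curve$intensities
  b <- if (is.numeric(baseline_mode)) {
    as.double(baseline_mode[1])
  } else {
    switch(match.arg(baseline_mode),
           head = mean(s[1:2]),
           zero = 0)
  }
  v <- s - b
  if (isTRUE(smooth)) v <- isoreg(curve$times, v)$yf
  cmax <- max(v)
  if (cmax <= 0)
    stop("no detectable arrival: cecal signal never rises above baseline")
  arrival_curve(curve$times, pmin(pmax(v / cmax, 0), 1))
}

#' Transit-time summary for one animal and meal
#'
#' Bundles the three moment-based transit times.  `msitt` is always
#' `mcat - mget` (the defining identity); a negative value signals
#' inconsistent curves and triggers a warning.
#'
#' @param mget Mean gastric emptying time, minutes.
#' @param mcat Mean cecum arrival time, minutes.
#' @param t50 Optional half-emptying time, minutes (`NA` if unavailable).
#' @param animal_id,meal Provenance labels.
#' @param warnings Character vector of quality flags accumulated during
#'   analysis.
#' @return An object of class `transit_times` with fields `mget`, `mcat`,
#'   `msitt`, `t50`.
#' @export
transit_times <- function(mget, mcat, t50 = NA_real_, animal_id = "unknown",
                          meal = "liquid", warnings = character()) {
  if (!is.finite(mget) || !is.finite(mcat))
    stop("mget and mcat must be finite")
  if (mget <= 0 || mcat <= 0)
    stop("transit times must be positive")
  msitt <- mcat - mget
  if (msitt < 0)
    acb_warn("negative MSITT (MCAT < MGET): curves are inconsistent",
             "acb_quality_warning")
  structure(
    list(mget = mget, mcat = mcat, msitt = msitt, t50 = as.double(t50),
         animal_id = animal_id, meal = meal, warnings = warnings),
    class = "transit_times")
}

#' @export
print.transit_times <- function(x, ...) {
  cat(sprintf("<transit_times> animal=%s meal=%s\n", x$animal_id, x$meal))
  cat(sprintf("  MGET  %8.2f min\n  MCAT  %8.2f min\n  MSITT %8.2f min\n",
              x$mget, x$mcat, x$msitt))
  if (is.finite(x$t50)) cat(sprintf("  t50   %8.2f min\n", x$t50))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
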