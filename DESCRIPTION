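Package: acbtransit
Title: Gastrointestinal Transit Analysis for AC Biosusceptometry Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical-moment analysis of gastrointestinal transit from
    two-site AC biosusceptometry (ACB) signal recordings in small animals.
    Normalizes gastric-projection and cecum-projection magnetic intensity
    time series into retention and cumulative-arrival curves, and estimates
    mean gastric emptying time (MGET), mean cecum arrival time (MCAT) and
    mean small-intestinal transit time (MSITT) by the first moment of the
    emptying- and arrival-rate distributions (area under the retention
    curve, area between the arrival curve and its plateau), plus the
    half-emptying time t50.  Includes a compartmental forward simulator of
    a magnetic test meal moving through the gut (first-order emptying for
    liquid meals, power-exponential lagged emptying for solid meals, a
    chain of small-intestinal compartments, and a gradiometric sensor
    response), a simulated kill-and-measure validation study, paired
    small-sample statistics with a self-contained Student t distribution,
    and a reproduction report for the reference transit-time table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
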