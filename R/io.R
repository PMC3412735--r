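# CSV dialect for recordings: optional '#'-prefixed metadata lines
# (animal_id, meal), then header time_min,stomach_mv,cecum_mv.
# Numbers are written with %.17g so write -> read -> write is
# byte-identical.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a two-site recording to CSV
#'
#' One file per animal/meal: `#`-prefixed metadata lines followed by the
#' header `time_min,stomach_mv,cecum_mv`.  Numbers are written with full
#' double precision so a write/read round trip is exact.
#'
#' @param stomach,cecum `signal_curve`s on the same time grid.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(stomach, cecum, path) {
  stopifnot(inherits(stomach, "signal_curve"), inherits(cecum, "signal_curve"))
  if (length(stomach$times) != length(cecum$times) ||
      any(abs(stomach$times - cecum$times) > 1e-9))
    stop("stomach and cecum curves must share the same time grid")
  lines <- c(
    sprintf("# animal_id: %s", stomach$animal_id),
    sprintf("# meal: %s", stomach$meal),
    "time_min,stomach_mv,cecum_mv",
    paste(fmt_num(stomach$times), fmt_num(stomach$intensities),
          fmt_num(cecum$intensities), sep = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a two-site recording from CSV
#'
#' Parses the recording dialect written by [write_recording()]:
#' optional `# key: value` metadata lines (`animal_id`, `meal`), the
#' header `time_min,stomach_mv,cecum_mv`, then one comma-separated row
#' per sample.  Malformed input (missing column, non-numeric cell,
#' non-increasing time) raises an error naming the offending line.
#'
#' @param path File path.
#' @return A list with `signal_curve`s `stomach` and `cecum`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- list(animal_id = "unknown", meal = "liquid")
  i <- 1
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    m <- regmatches(lines[i], regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)\\s*$", lines[i]))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
    i <- i + 1
  }
  if (i > length(lines) || trimws(lines[i]) != "time_min,stomach_mv,cecum_mv")
    stop(sprintf("parse error at line %d: expected header 'time_min,stomach_mv,cecum_mv'", i))
  header_line <- i
  if (i >= length(lines)) stop("recording has no data rows")
  body <- lines[seq(i + 1, length(lines))]
  body_idx <- which(nzchar(trimws(body)))
  if (length(body_idx) < 4)
    stop("recording has fewer than 4 data rows")
  parts <- strsplit(trimws(body[body_idx]), ",", fixed = TRUE)
  vals <- matrix(NA_real_, nrow = length(parts), ncol = 3)
  for (j in seq_along(parts)) {
    lineno <- header_line + body_idx[j]
    if (length(parts[[j]]) != 3)
      stop(sprintf("parse error at line %d: expected 3 comma-separated fields, found %d",
                   lineno, length(parts[[j]])))
    v <- suppressWarnings(as.double(parts[[j]]))
    if (anyNA(v))
      stop(sprintf("parse error at line %d: non-numeric cell '%s'",
                   lineno, parts[[j]][which(is.na(v))[1]]))
    vals[j, ] <- v
  }
  bad <- which(diff(vals[, 1]) <= 0)
  if (length(bad))
    stop(sprintf("parse error at line %d: time_min not strictly increasing",
                 header_line + body_idx[bad[1] + 1]))
  meal <- if (meta$meal %in% c("liquid", "solid")) meta$meal else "liquid"
  list(
    stomach = signal_curve(vals[, 1], vals[, 2], site = "stomach",
                           meal = meal, animal_id = meta$animal_id),
    cecum = signal_curve(vals[, 1], vals[, 3], site = "cecum",
                         meal = meal, animal_id = meta$animal_id))
}

#' Write validation-study records to CSV
#'
#' @param records A `validation_records` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_validation_records <- function(records, path) {
  stopifnot(inherits(records, "validation_records"))
  lines <- c(
    sprintf("# initial_intensity_mv: %s", fmt_num(attr(records, "initial_intensity_mv"))),
    "animal_id,kill_time_min,gastric_intensity_mv,distance_cm",
    paste(records$animal_id, fmt_num(records$kill_time_min),
          fmt_num(records$gastric_intensity_mv), fmt_num(records$distance_cm),
          sep = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a flat key-value run configuration
#'
#' One `key: value` pair per line (flat YAML); `#` comments allowed.
#' Unknown keys are rejected, as are non-positive rates.
#'
#' @param path Config file path.
#' @return A named list of configuration values merged over defaults.
#' @export
read_run_config <- function(path) {
  defaults <- list(
    n_animals = 6, seed = 1, sigma_fraction = 0.02, population_cv = 0.15,
    duration_min = 420, dt_sample_min = 10,
    liquid_k_e = 0.01, solid_k = gamma(1.5) / 140, solid_beta = 2,
    n_compartments = 4, k_t = 0.05,
    plateau_epsilon = 0.02, tail_policy = "truncate_warn",
    gastric_baseline = "tail", cecal_baseline = "head",
    out_dir = ".")
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(path)
  } else {
    lines <- grep("^\\s*(#|$)", readLines(path, warn = FALSE),
                  value = TRUE, invert = TRUE)
    kv <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*:\\s*(.*?)\\s*$", lines))
    if (any(lengths(kv) != 3)) stop("malformed config line: ", lines[lengths(kv) != 3][1])
    vals <- lapply(kv, function(m) {
      num <- suppressWarnings(as.double(m[3]))
      if (is.na(num)) m[3] else num
    })
    stats::setNames(vals, vapply(kv, `[`, "", 2))
  }
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, cfg)
  rates <- c("liquid_k_e", "solid_k", "k_t")
  if (any(unlist(out[rates]) <= 0))
    stop("all rates in the configuration must be positive")
  out
}
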