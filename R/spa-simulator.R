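#' Scan configuration for the SPA simulator
#'
#' @param step grid spacing of the line scan in mm (the source and detector
#'   advance this far between measuring points). Default 1 mm.
#' @param scan_width total scanned distance in mm; must span both bones plus
#'   off-bone flanks for baseline estimation.
#' @param noise_sd additive Gaussian noise per step, in areal-density
#'   equivalent units (mg/cm2).
#' @param calibration_gain dimensionless instrument gain.
#' @param scan_date ordinal day of the scan (drives the drift model).
#' @return an object of class `scan_config`.
#' @export
scan_config <- function(step = 1, scan_width = 40, noise_sd = 0,
                        calibration_gain = 1, scan_date = 0) {
  if (step <= 0) stop("step must be positive")
  if (scan_width <= 0) stop("scan_width must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (calibration_gain <= 0) stop("calibration_gain must be positive")
  structure(list(step = step, scan_width = scan_width, noise_sd = noise_sd,
                 calibration_gain = calibration_gain, scan_date = scan_date),
            class = "scan_config")
}

#' Instrument drift model
#'
#' The scanner's relative gain as a function of calendar date: a smooth
#' multiplicative annual drift plus an optional step discontinuity when the
#' radiation source is replaced.
#'
#' @param base_gain gain at `origin_date`.
#' @param annual_drift proportional gain change per year (0.001 = +0.1%/year).
#' @param source_change_date ordinal day of source replacement, or `NULL`.
#' @param change_factor multiplicative jump applied from
#'   `source_change_date` onward.
#' @param origin_date ordinal day at which the gain equals `base_gain`.
#' @return an object of class `drift_model` with element `relative_gain`,
#'   a vectorized function of ordinal date.
#' @export
drift_model <- function(base_gain = 1, annual_drift = 0,
                        source_change_date = NULL, change_factor = 1,
                        origin_date = 0) {
  if (base_gain <= 0 || change_factor <= 0) stop("gains must be positive")
  force(base_gain); force(annual_drift); force(source_change_date)
  force(change_factor); force(origin_date)
  fun <- function(date) {
    g <- base_gain * (1 + annual_drift)^((date - origin_date) / 365.25)
    if (!is.null(source_change_date)) {
      g <- g * ifelse(date >= source_change_date, change_factor, 1)
    }
    g
  }
  structure(list(relative_gain = fun, base_gain = base_gain,
                 annual_drift = annual_drift,
                 source_change_date = source_change_date,
                 change_factor = change_factor, origin_date = origin_date),
            class = "drift_model")
}

#' Drift model calibrated to known era-mean gain ratios
#'
#' Builds a piecewise-constant drift model for the two-cohort design in which
#' the ratio of the modern-era gain to the early-era gain equals the supplied
#' correction constants: `pre_constant` for early scans made before the source
#' replacement and `post_constant` for those made after. The modern era is
#' normalized to gain 1, so early-era values read low by exactly the factor a
#' later phantom-based correction must undo.
#'
#' @param pre_constant,post_constant target (modern mean) / (early mean)
#'   phantom ratios. Defaults 1.002 and 1.034.
#' @param source_change_date ordinal day of the source replacement within the
#'   early measurement era.
#' @param modern_date first ordinal day of the modern measurement era.
#' @return a `drift_model` whose `relative_gain(date)` is `1/pre_constant`
#'   before `source_change_date`, `1/post_constant` from there until
#'   `modern_date`, and 1 afterwards.
#' @export
calibrated_drift_model <- function(pre_constant = 1.002, post_constant = 1.034,
                                   source_change_date = 365,
                                   modern_date = 13500) {
  if (pre_constant <= 0 || post_constant <= 0) stop("constants must be positive")
  fun <- function(date) {
    ifelse(date >= modern_date, 1,
           ifelse(date >= source_change_date, 1 / post_constant, 1 / pre_constant))
  }
  structure(list(relative_gain = fun, base_gain = 1 / pre_constant,
                 annual_drift = 0, source_change_date = source_change_date,
                 change_factor = pre_constant / post_constant,
                 origin_date = 0, modern_date = modern_date,
                 pre_constant = pre_constant, post_constant = post_constant),
            class = c("calibrated_drift_model", "drift_model"))
}

# half-chord profile: length (mm) of the intersection of a vertical ray at x
# with a circle of diameter d centered at x0
chord_length <- function(x, center, diameter) {
  r <- diameter / 2
  dx2 <- r^2 - (x - center)^2
  out <- numeric(length(x))
  inside <- dx2 > 0
  out[inside] <- 2 * sqrt(dx2[inside])
  out
}

#' Simulate an SPA line scan across a forearm
#'
#' Forward model: at each grid position the signal is the constant water-cuff
#' baseline plus, for every bone, the gain times the bone's volumetric mineral
#' density times the mineral path length through its cortical shell --- the
#' chord through the outer circle minus the chord through the (water
#' equivalent) medullary cavity --- plus additive Gaussian noise. The signal
#' is expressed directly in areal-density-equivalent units (mg/cm2).
#'
#' @param bones a data frame with one row per bone: columns `center` (mm
#'   position of the bone axis along the scan), `periosteal`, `medullary`
#'   (diameters, mm) and `vol_density` (mg/cm3).
#' @param config a [scan_config()].
#' @param drift optional [drift_model()]; its `relative_gain(scan_date)`
#'   multiplies the calibration gain.
#' @param baseline constant soft-tissue baseline, mg/cm2.
#' @return an `spa_trace`: a tibble with columns `position` (mm) and `signal`
#'   (mg/cm2), with attributes `config`, `baseline_true` and `gain`.
#' @export
#' @examples
#' tr <- simulate_trace(
#'   tibble::tibble(center = 20, periosteal = 10, medullary = 0, vol_density = 1000),
#'   scan_config(step = 1, scan_width = 40)
#' )
#' max(tr$signal) - attr(tr, "baseline_true")  # ~ 1000 mg/cm3 * 1 cm
simulate_trace <- function(bones, config = scan_config(), drift = NULL,
                           baseline = 2) {
  stopifnot(all(c("center", "periosteal", "medullary", "vol_density") %in% names(bones)))
  check_geometry(bones$periosteal, bones$medullary, allow_equal = FALSE)
  if (any(bones$vol_density <= 0)) stop("vol_density must be positive")
  if (nrow(bones) > 1L) {
    ctr <- bones$center[order(bones$center)]
    rad <- bones$periosteal[order(bones$center)] / 2
    gaps <- diff(ctr) - (head(rad, -1) + tail(rad, -1))
    if (any(gaps <= 0)) stop("bones overlap along the scan line")
  }

  n_steps <- floor(config$scan_width / config$step + 1e-9)
  if (abs(n_steps * config$step - config$scan_width) > 1e-9) {
    warning("step does not divide scan_width; last partial step dropped")
  }
  positions <- seq(0, by = config$step, length.out = n_steps + 1L)

  # the *applied* gain includes instrument drift; downstream analysis only
  # knows the nominal calibration gain (drift is what phantom correction
  # later removes), so the two are recorded separately
  applied_gain <- config$calibration_gain
  if (!is.null(drift)) {
    applied_gain <- applied_gain * drift$relative_gain(config$scan_date)
  }

  mineral <- rep(0, length(positions))
  for (i in seq_len(nrow(bones))) {
    b <- bones[i, ]
    path_mm <- chord_length(positions, b$center, b$periosteal) -
      chord_length(positions, b$center, b$medullary)
    mineral <- mineral + b$vol_density * path_mm / 10  # mm -> cm path length
  }
  signal <- baseline + applied_gain * mineral
  if (config$noise_sd > 0) signal <- signal + rnorm(length(signal), 0, config$noise_sd)

  out <- tibble::tibble(position = positions, signal = signal)
  class(out) <- c("spa_trace", class(out))
  attr(out, "config") <- config
  attr(out, "baseline_true") <- baseline
  attr(out, "gain") <- config$calibration_gain
  attr(out, "applied_gain") <- applied_gain
  out
}

#' Simulate a phantom quality-assurance series
#'
#' The phantom is a stable object of known areal density scanned periodically;
#' its readout tracks instrument gain: measured BMD = true BMD x relative
#' gain x (1 + noise), with multiplicative Gaussian noise of the given
#' coefficient of variation.
#'
#' @param drift a [drift_model()].
#' @param dates ordinal days of the phantom scans (non-empty, non-decreasing).
#' @param noise_cv coefficient of variation of the readout, percent.
#' @param true_bmd reference areal density of the phantom, g/cm2 (default 1.25).
#' @return a tibble with columns `date` and `bmd` (g/cm2).
#' @export
simulate_phantom_series <- function(drift, dates, noise_cv = 0, true_bmd = 1.25) {
  if (length(dates) == 0L) stop("dates must be non-empty")
  if (is.unsorted(dates)) stop("dates must be non-decreasing")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  bmd <- true_bmd * drift$relative_gain(dates)
  if (noise_cv > 0) bmd <- bmd * (1 + rnorm(length(dates), 0, noise_cv / 100))
  tibble::tibble(date = dates, bmd = bmd)
}

#' Write / read a scan trace as two-column delimited text
#'
#' Metadata (step, width, gain, baseline, date) travel as `#`-prefixed header
#' lines above a `position_mm,signal` table.
#'
#' @param trace an `spa_trace`.
#' @param path file path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` an
#'   `spa_trace`.
#' @export
write_trace <- function(trace, path) {
  cfg <- attr(trace, "config")
  hdr <- c(
    sprintf("# step_mm: %.17g", cfg$step),
    sprintf("# scan_width_mm: %.17g", cfg$scan_width),
    sprintf("# noise_sd: %.17g", cfg$noise_sd),
    sprintf("# calibration_gain: %.17g", cfg$calibration_gain),
    sprintf("# scan_date: %.17g", cfg$scan_date),
    sprintf("# baseline_true: %.17g", attr(trace, "baseline_true")),
    sprintf("# gain: %.17g", attr(trace, "gain")),
    sprintf("# applied_gain: %.17g", attr(trace, "applied_gain") %||% attr(trace, "gain")),
    "position_mm,signal"
  )
  body <- sprintf("%.17g,%.17g", trace$position, trace$signal)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), ":\\s*")[[1]]
    meta[[kv[1]]] <- as.numeric(kv[2])
  }
  tab <- readr::read_csv(I(lines[!grepl("^#", lines)]), show_col_types = FALSE)
  out <- tibble::tibble(position = tab$position_mm, signal = tab$signal)
  class(out) <- c("spa_trace", class(out))
  attr(out, "config") <- scan_config(step = meta$step_mm,
                                     scan_width = meta$scan_width_mm,
                                     noise_sd = meta$noise_sd,
                                     calibration_gain = meta$calibration_gain,
                                     scan_date = meta$scan_date)
  attr(out, "baseline_true") <- meta$baseline_true
  attr(out, "gain") <- meta$gain
  attr(out, "applied_gain") <- meta$applied_gain %||% meta$gain
  out
}

#' @rdname write_trace
#' @param series phantom tibble (`date`, `bmd`).
#' @export
write_phantom_series <- function(series, path) {
  readr::write_csv(series, path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_phantom_series <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
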