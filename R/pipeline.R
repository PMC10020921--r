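#' Configuration for an end-to-end simulation run
#'
#' @param scale `"tiny"` (8 children, for fixtures and fast tests) or
#'   `"paper"` (55/61 + 238/204 children).
#' @param seed integer seed governing every random draw of the run.
#' @param params optional `spa_params` overriding the scale-derived defaults.
#' @param step scan step in mm.
#' @param scan_width scan width in mm.
#' @param trace_noise_sd additive trace noise, mg/cm2.
#' @param bone_separation minimum distance between the two bone centers, mm;
#'   for large bones the separation grows so that a soft-tissue gap of
#'   `min_gap` mm always remains between the periosteal surfaces.
#' @param min_gap minimum soft-tissue gap between the two bones, mm.
#' @param baseline soft-tissue baseline, mg/cm2.
#' @param correction apply phantom-derived drift correction to the
#'   reference-cohort panels.
#' @param drift drift model for instrument gain over calendar time; default
#'   [calibrated_drift_model()] (era gains matching correction constants
#'   1.002 and 1.034).
#' @param phantom_noise_cv phantom readout CV (%) used when estimating the
#'   correction constants within the run.
#' @param models which model specifications to fit (subset of `c(1, 2)`).
#' @param traits trait columns to fit, or `"all"`.
#' @param f_out,min_dip_prominence edge-detection thresholds, see
#'   [detect_edges()].
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(scale = c("paper", "tiny"), seed = 1,
                            params = NULL, step = 1, scan_width = 56,
                            trace_noise_sd = 5, bone_separation = 15,
                            min_gap = 3,
                            baseline = 2, correction = TRUE,
                            drift = calibrated_drift_model(),
                            phantom_noise_cv = 0.2,
                            models = 1L, traits = "all",
                            f_out = 0.1, min_dip_prominence = 0.05) {
  scale <- match.arg(scale)
  if (is.null(params)) {
    params <- if (scale == "tiny") {
      default_generative_params(n_boys = c(2L, 2L), n_girls = c(2L, 2L))
    } else {
      default_generative_params()
    }
  }
  structure(list(scale = scale, seed = seed, params = params, step = step,
                 scan_width = scan_width, trace_noise_sd = trace_noise_sd,
                 bone_separation = bone_separation, min_gap = min_gap,
                 baseline = baseline,
                 correction = correction, drift = drift,
                 phantom_noise_cv = phantom_noise_cv,
                 models = as.integer(models), traits = traits,
                 f_out = f_out, min_dip_prominence = min_dip_prominence),
            class = "pipeline_config")
}

panel_trait_names <- function() {
  c("bmc", "bmd", "bmad", "periosteal_diameter", "medullary_diameter",
    "cortical_thickness", "total_area", "csmi", "section_modulus",
    "strength_index")
}

#' Run the full simulate-scan-analyze-fit pipeline
#'
#' Orchestrates, deterministically under the configured seed:
#' generate the two cohorts and their latent bone geometry; simulate an SPA
#' line scan per arm under era-appropriate instrument gain (reference-cohort
#' children are split between scans made before and after the source
#' replacement); analyze every trace back into per-bone BMC and widths;
#' apply the exclusion and four-bone-averaging rules into per-child trait
#' panels; estimate phantom-derived correction constants and (optionally)
#' correct the reference-cohort mineral values; fit the requested log-linear
#' trajectory models; and tabulate slope contrasts and age-16 predictions.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `spa_run`: a list with `children`, `panels`,
#'   `measurements`, `constants`, `coefficients`, `contrasts`,
#'   `predictions_16`, `exclusions`, `config`.
#' @export
#' @examples
#' run <- run_pipeline(pipeline_config(scale = "tiny", seed = 1))
#' run$contrasts
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  params <- config$params

  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE)
    })
  }

  children <- stage("generate", generate_cohorts(params))
  bones <- stage("generate", generate_bone_geometry(children, params))

  # calendar placement: reference-era children split around the source
  # replacement; comparison-era children on the modern gain
  drift <- config$drift
  change_date <- drift$source_change_date %||% 365
  modern_date <- drift$modern_date %||% 13500
  is_ref <- children$cohort == params$cohort_labels[1]
  before <- is_ref & (runif(nrow(children)) < 0.5)
  scan_date <- ifelse(!is_ref, modern_date + 200,
                      ifelse(before, change_date - 180, change_date + 180))
  children$scan_date <- scan_date
  children$measured_before_change <- before

  # phantom QA series spanning both eras
  ref_dates <- seq(change_date - 300, change_date + 300, by = 20)
  mod_dates <- seq(modern_date, modern_date + 300, by = 20)
  phantom_ref <- stage("phantom", simulate_phantom_series(
    drift, ref_dates, noise_cv = config$phantom_noise_cv))
  phantom_mod <- stage("phantom", simulate_phantom_series(
    drift, mod_dates, noise_cv = config$phantom_noise_cv))
  constants <- stage("phantom", estimate_correction_constants(
    phantom_ref, phantom_mod, change_date))

  arm_tbl <- dplyr::distinct(bones, .data$child_id, .data$arm)
  measurements <- stage("scan/analyze", {
    purrr::map2(arm_tbl$child_id, arm_tbl$arm, function(id, arm) {
      b <- bones[bones$child_id == id & bones$arm == arm, ]
      sep <- max(config$bone_separation,
                 sum(b$periosteal) / 2 + config$min_gap)
      centers <- config$scan_width / 2 + c(-0.5, 0.5) * sep
      cfg <- scan_config(step = config$step, scan_width = config$scan_width,
                         noise_sd = config$trace_noise_sd,
                         scan_date = children$scan_date[children$child_id == id])
      tr <- simulate_trace(
        tibble::tibble(center = centers, periosteal = b$periosteal,
                       medullary = b$medullary, vol_density = b$vol_density),
        cfg, drift = drift, baseline = config$baseline
      )
      m <- analyze_trace(tr, f_out = config$f_out,
                         min_dip_prominence = config$min_dip_prominence)
      m$child_id <- id
      m$arm <- arm
      # a simulated per-arm technical-error flag also invalidates the scan
      if (any(b$technical_error)) m$quality <- "technical_error"
      m$bone_index <- (as.integer(arm == "right")) * 2L + seq_len(nrow(m))
      m
    }) |> dplyr::bind_rows()
  })

  panels <- stage("assemble", assemble_panels(measurements, children))
  if (config$correction) {
    ref_rows <- panels$cohort == params$cohort_labels[1]
    panels[ref_rows, ] <- apply_correction(
      panels[ref_rows, ], constants,
      before_change = panels$measured_before_change[ref_rows])
  }

  traits <- config$traits
  if (identical(traits, "all")) traits <- panel_trait_names()
  fits <- list()
  coefficients <- list()
  contrasts <- list()
  predictions <- list()
  for (m in config$models) {
    for (tr in traits) {
      fit <- stage("fit", fit_trend(panels, tr, model = m,
                                    sex_ref = params$sex_labels[1],
                                    cohort_ref = params$cohort_labels[1]))
      key <- sprintf("%s_model%d", tr, m)
      fits[[key]] <- fit
      coefficients[[key]] <- dplyr::mutate(tidy(fit), trait = tr, model = m,
                                           .before = 1)
      contrasts[[key]] <- dplyr::mutate(slope_contrast(fit), trait = tr,
                                        model = m, .before = 1)
      if (m == 1L) {
        predictions[[key]] <- dplyr::bind_rows(
          cohort_difference_at_age(fit, 16, sex = fit$sex_levels[1]),
          cohort_difference_at_age(fit, 16, sex = fit$sex_levels[2])
        ) |> dplyr::mutate(trait = tr, .before = 1)
      }
    }
  }

  structure(list(
    children = children,
    panels = panels,
    measurements = measurements,
    phantom = dplyr::bind_rows(reference = phantom_ref, comparison = phantom_mod,
                               .id = "era"),
    constants = constants,
    fits = fits,
    coefficients = dplyr::bind_rows(coefficients),
    contrasts = dplyr::bind_rows(contrasts),
    predictions_16 = dplyr::bind_rows(predictions),
    exclusions = attr(panels, "exclusion_summary"),
    config = config
  ), class = "spa_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.spa_run <- function(x, ...) {
  cat("<spa_run>\n")
  cat(sprintf("  %d children generated, %d panels retained (%d one-arm)\n",
              x$exclusions$n_children_in, x$exclusions$n_children_used,
              x$exclusions$n_one_arm))
  cat(sprintf("  correction constants: pre %.4f / post %.4f (%s)\n",
              x$constants$pre_change, x$constants$post_change,
              if (x$config$correction) "applied" else "not applied"))
  cat("  age-by-cohort slope contrasts (Model 1):\n")
  c1 <- dplyr::filter(x$contrasts, .data$model == 1)
  cat(sprintf("    %-20s %s\n", c1$trait,
              mapply(format_contrast, 1 + c1$percent_per_year / 100,
                     1 + c1$conf.low / 100, 1 + c1$conf.high / 100)),
      sep = "")
  invisible(x)
}

#' Write run artifacts as delimited text
#'
#' Emits the per-child trait table, the coefficient report, the contrast
#' summary, the age-16 prediction table and the exclusion counts as CSV
#' files under `dir`.
#'
#' @param run an `spa_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(run$panels, file.path(dir, "trait_panels.csv"))
  readr::write_csv(run$coefficients, file.path(dir, "coefficients.csv"))
  readr::write_csv(run$contrasts, file.path(dir, "contrasts.csv"))
  readr::write_csv(run$predictions_16, file.path(dir, "predictions_age16.csv"))
  readr::write_csv(run$exclusions, file.path(dir, "exclusions.csv"))
  readr::write_csv(tibble::as_tibble(run$constants),
                   file.path(dir, "correction_constants.csv"))
  invisible(dir)
}

#' Generate packaged fixture datasets
#'
#' `"tiny"` builds an 8-child dataset (2 boys + 2 girls per cohort) with
#' bone geometry; `"paper"` uses the default study sizes (558 children).
#' Regeneration is byte-identical under the same seed.
#'
#' @param size `"tiny"` or `"paper"`.
#' @param seed integer seed.
#' @param dir optional directory; when given, the children and bone tables
#'   are written there as CSV.
#' @return list with `children` and `bones` tibbles.
#' @export
make_fixtures <- function(size = c("tiny", "paper"), seed = 1, dir = NULL) {
  size <- match.arg(size)
  params <- if (size == "tiny") {
    default_generative_params(n_boys = c(2L, 2L), n_girls = c(2L, 2L))
  } else {
    default_generative_params()
  }
  set.seed(seed)
  children <- generate_cohorts(params)
  bones <- generate_bone_geometry(children, params)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(children, file.path(dir, sprintf("children_%s.csv", size)))
    readr::write_csv(bones, file.path(dir, sprintf("bones_%s.csv", size)))
  }
  list(children = children, bones = bones)
}
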