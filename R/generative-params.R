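#' Default generative parameters for the two-cohort forearm study
#'
#' Returns the parameter set that the synthetic-cohort generator treats as
#' ground truth. Each of the ten forearm traits follows a multiplicative
#' (log-linear) age trajectory
#' \deqn{\log y = \log b_0 + \log r_{sex} S + \log r_{coh} C +
#'   (\log r_{age} + \log r_{age:sex} S + \log r_{age:coh} C)(a - 7) + \epsilon,}
#' where \eqn{S} indicates girls, \eqn{C} indicates the comparison
#' (2017--2018) cohort, \eqn{a} is age in years, and
#' \eqn{\epsilon \sim N(0, \sigma_{\log}^2)}.
#'
#' Default intercepts and ratio multipliers are the age- and sex-adjusted
#' (Model 1) reference estimates for the distal forearm: e.g. bone mineral
#' content (BMC) intercept 345.930 mg/cm in 7-year-old boys of the reference
#' cohort, cohort ratio 0.909, age ratio 1.095 per year. Default cohort sizes
#' are 55/61 (boys/girls, reference 1979--1981 cohort) and 238/204
#' (comparison 2017--2018 cohort).
#'
#' Residual standard deviations on the natural-log scale (`sigma_log`) are not
#' reported quantities; defaults are 0.12 for mass/density traits, 0.08 for
#' diameters and cortical thickness, and proportionally larger values for the
#' derived mechanics traits whose scatter compounds diameter variability.
#'
#' @param n_boys,n_girls integer length-2 vectors: children per cohort
#'   (reference, comparison).
#' @param age_range numeric length 2; ages are drawn continuous-uniform on
#'   `[age_range[1], age_range[2])`. Default 7--16 years.
#' @param cohort_labels character length 2: labels for the reference and
#'   comparison cohorts.
#' @param bone_cor correlation between the four bones (radius/ulna, both arms)
#'   of one child on the log scale; the per-bone jitter SD is
#'   `sigma_log * sqrt(1/bone_cor - 1)`.
#' @param fracture_rate Bernoulli probability that a child had an upper
#'   extremity fracture in the preceding year (exercises the one-arm rule).
#' @param technical_error_rate per-arm-scan probability of a technical
#'   measurement error flag.
#' @param sigma_log optional named numeric vector overriding per-trait residual
#'   SDs, e.g. `c(bmc = 0)`; a single unnamed value applies to all traits.
#'
#' @return An object of class `spa_params`: a list with elements
#'   `traits` (tibble of per-trait generative coefficients), `growth`
#'   (per-sex quadratic log-age height/weight curves), `n` (cohort sizes),
#'   `age_range`, `cohort_labels`, `sex_labels`, `bone_cor`, `fracture_rate`,
#'   `technical_error_rate`.
#' @export
#' @examples
#' p <- default_generative_params()
#' dplyr::filter(p$traits, trait == "bmc")
default_generative_params <- function(n_boys = c(55L, 238L),
                                      n_girls = c(61L, 204L),
                                      age_range = c(7, 16),
                                      cohort_labels = c("1979-1981", "2017-2018"),
                                      bone_cor = 0.9,
                                      fracture_rate = 0.03,
                                      technical_error_rate = 0.005,
                                      sigma_log = NULL) {
  traits <- tibble::tribble(
    ~trait,                ~intercept, ~cohort_ratio, ~age_cohort_ratio, ~sex_ratio, ~age_ratio, ~age_sex_ratio, ~sigma_log,
    "bmc",                    345.930,         0.909,             1.000,      0.935,      1.095,          0.994,       0.12,
    "bmd",                    366.327,         0.975,             0.989,      0.963,      1.050,          1.000,       0.12,
    "bmad",                   590.672,         1.084,             0.980,      0.978,      1.022,          1.006,       0.12,
    "periosteal_diameter",      9.455,         0.931,             1.011,      0.971,      1.042,          0.993,       0.08,
    "medullary_diameter",       4.025,         0.970,             1.016,      0.985,      1.061,          0.989,       0.08,
    "cortical_thickness",       2.804,         0.889,             1.008,      0.979,      1.022,          0.996,       0.08,
    "total_area",               0.704,         0.867,             1.023,      0.942,      1.087,          0.987,       0.16,
    "csmi",                     0.042,         0.710,             1.052,      0.937,      1.162,          0.969,       0.30,
    "section_modulus",          0.087,         0.772,             1.039,      0.951,      1.118,          0.977,       0.22,
    "strength_index",          51.106,         0.838,             1.018,      0.930,      1.142,          0.983,       0.18
  )

  sigma_growth <- NULL
  if (!is.null(sigma_log)) {
    if (is.null(names(sigma_log))) {
      stopifnot(length(sigma_log) == 1L)
      traits$sigma_log <- sigma_log
      sigma_growth <- c(height = unname(sigma_log), weight = unname(sigma_log))
    } else {
      sigma_growth <- sigma_log[names(sigma_log) %in% c("height", "weight")]
      sigma_log <- sigma_log[!names(sigma_log) %in% c("height", "weight")]
      bad <- setdiff(names(sigma_log), traits$trait)
      if (length(bad)) stop("unknown trait(s) in sigma_log: ", paste(bad, collapse = ", "))
      idx <- match(names(sigma_log), traits$trait)
      traits$sigma_log[idx] <- unname(sigma_log)
    }
  }

  # Quadratic log-age growth curves; slopes chosen so age-16 means land at
  # realistic Swedish pediatric values and the comparison cohort is +1.4%
  # taller and +7.6% heavier at every age.
  growth <- tibble::tribble(
    ~outcome, ~sex,     ~intercept, ~slope1, ~slope2, ~cohort_ratio, ~sigma_log,
    "height", "male",        125.0, 0.04866, -0.0010,         1.014,       0.04,
    "height", "female",      124.0, 0.04478, -0.0015,         1.014,       0.04,
    "weight", "male",         25.0, 0.12770, -0.0020,         1.076,       0.15,
    "weight", "female",       24.5, 0.11842, -0.0020,         1.076,       0.15
  )
  if (length(sigma_growth)) {
    for (nm in names(sigma_growth)) {
      growth$sigma_log[growth$outcome == nm] <- sigma_growth[[nm]]
    }
  }

  params <- structure(list(
    traits = traits,
    growth = growth,
    n = tibble::tibble(
      cohort = rep(cohort_labels, each = 2L),
      sex = rep(c("male", "female"), 2L),
      n = as.integer(c(n_boys[1], n_girls[1], n_boys[2], n_girls[2]))
    ),
    age_range = age_range,
    cohort_labels = cohort_labels,
    sex_labels = c("male", "female"),
    bone_cor = bone_cor,
    fracture_rate = fracture_rate,
    technical_error_rate = technical_error_rate
  ), class = "spa_params")
  validate_params(params)
  params
}

validate_params <- function(params) {
  stopifnot(inherits(params, "spa_params"))
  tr <- params$traits
  ratio_cols <- c("intercept", "cohort_ratio", "age_cohort_ratio",
                  "sex_ratio", "age_ratio", "age_sex_ratio")
  if (any(as.matrix(tr[ratio_cols]) <= 0)) {
    stop("all trait intercepts and ratio multipliers must be strictly positive")
  }
  if (any(tr$sigma_log < 0)) stop("sigma_log must be >= 0")
  if (any(params$n$n < 0)) stop("cohort sample sizes must be >= 0")
  if (diff(params$age_range) <= 0) stop("age_range must be increasing")
  if (params$bone_cor <= 0 || params$bone_cor > 1) stop("bone_cor must be in (0, 1]")
  if (params$fracture_rate < 0 || params$fracture_rate > 1 ||
      params$technical_error_rate < 0 || params$technical_error_rate > 1) {
    stop("rates must be probabilities")
  }
  invisible(params)
}

#' @export
print.spa_params <- function(x, ...) {
  cat("<spa_params> two-cohort generative parameters\n")
  cat("  cohorts:", paste(x$cohort_labels, collapse = " vs "),
      sprintf(" (n = %s)\n", paste(x$n$n, collapse = "/")))
  cat("  ages: uniform on [", x$age_range[1], ",", x$age_range[2], ")\n")
  print(x$traits, n = Inf)
  invisible(x)
}

#' Look up a generative coefficient
#'
#' Convenience accessor for a single entry of `params$traits`.
#'
#' @param params an `spa_params` object.
#' @param trait trait name, e.g. `"bmc"`.
#' @param term one of `"intercept"`, `"cohort_ratio"`, `"age_cohort_ratio"`,
#'   `"sex_ratio"`, `"age_ratio"`, `"age_sex_ratio"`, `"sigma_log"`.
#' @return a single numeric value.
#' @export
generative_value <- function(params, trait, term) {
  row <- params$traits[params$traits$trait == trait, ]
  if (nrow(row) != 1L) stop("unknown trait: ", trait)
  if (!term %in% names(row)) stop("unknown term: ", term)
  row[[term]]
}

#' Serialize / read generative parameters
#'
#' Parameters are stored as a nested YAML mapping (one block per trait) so a
#' simulation run is reproducible from its config file plus a seed.
#'
#' @param params an `spa_params` object.
#' @param path file path.
#' @return `write_params()` returns `path` invisibly; `read_params()` returns
#'   an `spa_params` object.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  out <- list(
    traits = split(params$traits[-1], params$traits$trait) |>
      lapply(function(d) lapply(as.list(d), unname)),
    growth = apply(params$growth, 1, as.list, simplify = FALSE),
    n = apply(params$n, 1, as.list, simplify = FALSE),
    age_range = params$age_range,
    cohort_labels = params$cohort_labels,
    bone_cor = params$bone_cor,
    fracture_rate = params$fracture_rate,
    technical_error_rate = params$technical_error_rate
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- default_generative_params()
  traits <- dplyr::bind_rows(lapply(names(raw$traits), function(nm) {
    tibble::as_tibble(c(list(trait = nm), raw$traits[[nm]]))
  }))
  base$traits <- traits[match(base$traits$trait, traits$trait), ]
  base$growth <- dplyr::bind_rows(lapply(raw$growth, function(g) {
    tibble::as_tibble(lapply(g, type.convert, as.is = TRUE))
  }))
  base$n <- dplyr::bind_rows(lapply(raw$n, function(g) {
    tibble::tibble(cohort = g$cohort, sex = g$sex, n = as.integer(g$n))
  }))
  base$age_range <- as.numeric(raw$age_range)
  base$cohort_labels <- raw$cohort_labels
  base$bone_cor <- raw$bone_cor
  base$fracture_rate <- raw$fracture_rate
  base$technical_error_rate <- raw$technical_error_rate
  validate_params(base)
  base
}
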