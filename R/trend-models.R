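#' Fit a log-linear age-trajectory model comparing two cohorts
#'
#' Ordinary least squares on the natural log of the outcome with age centered
#' at 7 years, sex and cohort as factors (boys and the earlier cohort as
#' references), and age-by-sex and age-by-cohort interactions (Model 1).
#' Model 2 additionally adjusts for height and weight. Coefficients are
#' reported as antilogs (ratio multipliers) with Wald 95% confidence
#' intervals antilogged from the log scale, so the `cohort` term is the
#' relative difference at age 7 and the `age_cohort` term the relative
#' difference in annual change between cohorts.
#'
#' @param data data frame with one row per child: the outcome column plus
#'   `age`, `sex`, `cohort` (and `height`, `weight` for Model 2).
#' @param outcome name of the outcome column (string).
#' @param model 1 (age + sex) or 2 (adds height and weight).
#' @param squared_age add a squared centered-age term and its sex interaction
#'   (used for the height growth model, where the log-scale trajectory is
#'   visibly curved).
#' @param age_origin age at which the intercept is evaluated (default 7).
#' @param sex_ref,cohort_ref reference levels; defaults are the first level
#'   of each factor (alphabetical for character input, which puts `"male"`
#'   after `"female"` --- so pass `sex_ref = "male"` or use factors; cohort
#'   labels like `"1979-1981"` sort correctly).
#' @param log_covariates enter height and weight on the log scale instead of
#'   untransformed (Model 2 only).
#' @param conf.level confidence level for reported intervals.
#' @return an object of class `trend_fit`.
#' @export
#' @examples
#' kids <- generate_cohorts(seed = 1)
#' fit <- fit_trend(kids, "bmc", sex_ref = "male")
#' tidy(fit)
#' slope_contrast(fit)
fit_trend <- function(data, outcome, model = 1, squared_age = FALSE,
                      age_origin = 7, sex_ref = NULL, cohort_ref = NULL,
                      log_covariates = FALSE, conf.level = 0.95) {
  stopifnot(outcome %in% names(data))
  model <- match.arg(as.character(model), c("1", "2"))
  y <- data[[outcome]]
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("non-positive or missing outcome values in rows: ",
         paste(head(which(!is.finite(y) | y <= 0), 10), collapse = ", "))
  }
  sex_f <- as_ref_factor(data$sex, sex_ref, "sex")
  cohort_f <- as_ref_factor(data$cohort, cohort_ref, "cohort")
  if (nlevels(droplevels(sex_f)) < 2L) {
    stop("need both sexes present to estimate sex contrasts")
  }
  if (nlevels(droplevels(cohort_f)) < 2L) {
    stop("rank deficiency: need both cohorts present to estimate cohort contrasts")
  }

  df <- tibble::tibble(
    log_y = log(y),
    age_c = data$age - age_origin,
    sex_f = droplevels(sex_f),
    cohort_f = droplevels(cohort_f)
  )
  form <- log_y ~ age_c * sex_f + age_c * cohort_f
  if (squared_age) form <- stats::update(form, . ~ . + I(age_c^2) * sex_f)
  if (model == "2") {
    stopifnot(all(c("height", "weight") %in% names(data)))
    if (log_covariates) {
      df$height <- log(data$height); df$weight <- log(data$weight)
    } else {
      df$height <- data$height; df$weight <- data$weight
    }
    form <- stats::update(form, . ~ . + height + weight)
  }
  fit <- lm(form, data = df)
  if (fit$rank < length(coef(fit)) || anyNA(coef(fit))) {
    stop("rank-deficient design: some model terms are not estimable")
  }
  structure(list(
    fit = fit,
    outcome = outcome,
    model = as.integer(model),
    squared_age = squared_age,
    age_origin = age_origin,
    sex_levels = levels(df$sex_f),
    cohort_levels = levels(df$cohort_f),
    log_covariates = log_covariates,
    conf.level = conf.level,
    n = nrow(df),
    data = df
  ), class = "trend_fit")
}

as_ref_factor <- function(x, ref, what) {
  f <- if (is.factor(x)) x else factor(x)
  if (!is.null(ref)) {
    if (!ref %in% levels(f)) stop("reference level '", ref, "' not found in ", what)
    f <- stats::relevel(f, ref)
  }
  f
}

# canonical term names used throughout reporting
term_map <- function(object) {
  sx <- paste0("sex_f", object$sex_levels[2])
  ch <- paste0("cohort_f", object$cohort_levels[2])
  map <- c("(Intercept)" = "intercept",
           "age_c" = "age",
           setNames("sex", sx),
           setNames("cohort", ch),
           setNames("age_sex", paste0("age_c:", sx)),
           setNames("age_cohort", paste0("age_c:", ch)),
           "I(age_c^2)" = "age_sq",
           setNames("age_sq_sex", paste0("I(age_c^2):", sx)),
           "height" = "height",
           "weight" = "weight")
  map
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> log-linear trajectory model, outcome '%s' (Model %d%s)\n",
              x$outcome, x$model, if (x$squared_age) " + age^2" else ""))
  cat(sprintf("  n = %d; reference: %s, %s; age origin %g years\n",
              x$n, x$sex_levels[1], x$cohort_levels[1], x$age_origin))
  td <- tidy(x)
  stars <- dplyr::case_when(td$p.value < 0.001 ~ "***",
                            td$p.value < 0.01 ~ "**",
                            td$p.value < 0.05 ~ "*",
                            TRUE ~ "")
  lines <- sprintf("  %-12s %9.3f (%8.3f, %8.3f) %s",
                   td$term, td$estimate, td$conf.low, td$conf.high, stars)
  cat("  term          antilog (95% CI)\n")
  cat(lines, sep = "\n")
  invisible(x)
}

#' Tidy a fitted trend model
#'
#' One row per model term with the antilogged estimate and confidence bounds
#' (ratio scale), the log-scale standard error, the t statistic and two-sided
#' p-value.
#'
#' @param x a `trend_fit`.
#' @param conf.level confidence level (default taken from the fit).
#' @param ... unused.
#' @return a tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @method tidy trend_fit
#' @export
tidy.trend_fit <- function(x, conf.level = x$conf.level, ...) {
  sm <- summary(x$fit)$coefficients
  ci <- confint(x$fit, level = conf.level)
  map <- term_map(x)
  terms <- unname(map[rownames(sm)])
  terms[is.na(terms)] <- rownames(sm)[is.na(terms)]
  tibble::tibble(
    term = terms,
    estimate = unname(exp(sm[, "Estimate"])),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p.value = unname(sm[, "Pr(>|t|)"]),
    conf.low = unname(exp(ci[, 1])),
    conf.high = unname(exp(ci[, 2]))
  )
}

#' Model-level summary of a trend fit
#'
#' @param x a `trend_fit`.
#' @param ... unused.
#' @return one-row tibble: `n_used`, `sigma_log` (residual SD on the log
#'   scale), `r.squared`, `adj.r.squared`, `df.residual`, `outcome`, `model`.
#' @method glance trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(n_used = x$n, sigma_log = sm$sigma,
                 r.squared = sm$r.squared, adj.r.squared = sm$adj.r.squared,
                 df.residual = x$fit$df.residual,
                 outcome = x$outcome, model = x$model)
}

#' Express a ratio term as a percent-per-year slope contrast
#'
#' Antilogged interaction ratios are conventionally reported as percent
#' differences: `(ratio - 1) * 100`, with the CI endpoints transformed the
#' same way (for the `age_cohort` term this is the %/year difference in
#' trajectory between cohorts).
#'
#' @param fit a `trend_fit`.
#' @param term canonical term name (default `"age_cohort"`).
#' @param conf.level confidence level.
#' @return one-row tibble: `term`, `percent_per_year`, `conf.low`,
#'   `conf.high`, `p.value`.
#' @export
slope_contrast <- function(fit, term = "age_cohort", conf.level = fit$conf.level) {
  td <- tidy(fit, conf.level = conf.level)
  row <- td[td$term == term, ]
  if (nrow(row) != 1L) stop("term '", term, "' not present in fit")
  tibble::tibble(term = term,
                 percent_per_year = ratio_to_percent(row$estimate),
                 conf.low = ratio_to_percent(row$conf.low),
                 conf.high = ratio_to_percent(row$conf.high),
                 p.value = row$p.value)
}

#' Convert ratio multipliers to percent differences
#'
#' @param ratio positive ratio (antilogged coefficient).
#' @return `(ratio - 1) * 100`.
#' @export
ratio_to_percent <- function(ratio) (ratio - 1) * 100

#' Format a ratio and CI as a printed %/year contrast
#'
#' @param ratio,conf.low,conf.high antilogged estimate and CI bounds.
#' @param digits decimal places (default 1, the conventional presentation).
#' @return character, e.g. `"1.1%/year (0.3%, 2.0%)"`.
#' @export
#' @examples
#' format_contrast(1.011, 1.003, 1.020)
format_contrast <- function(ratio, conf.low, conf.high, digits = 1) {
  sprintf("%.*f%%/year (%.*f%%, %.*f%%)",
          digits, ratio_to_percent(ratio),
          digits, ratio_to_percent(conf.low),
          digits, ratio_to_percent(conf.high))
}

#' Coefficient set for the multiplicative trajectory model
#'
#' Bundles antilogged coefficients (e.g. printed reference estimates) so that
#' [predict_at_age()] and [cohort_difference_at_age()] can evaluate the
#' prediction equation without refitting.
#'
#' @param intercept trait value for a reference-cohort boy at the age origin.
#' @param cohort_ratio,sex_ratio,age_ratio,age_sex_ratio,age_cohort_ratio
#'   ratio multipliers (dimensionless; per year for the age terms).
#' @param age_origin age at which the intercept applies (default 7).
#' @return an object of class `trend_coefs`.
#' @export
#' @examples
#' # printed Model 1 BMC estimates
#' tc <- trend_coefficients(345.930, cohort_ratio = 0.909, age_ratio = 1.095)
#' cohort_difference_at_age(tc, age = 16, sex = "reference")
trend_coefficients <- function(intercept, cohort_ratio = 1, sex_ratio = 1,
                               age_ratio = 1, age_sex_ratio = 1,
                               age_cohort_ratio = 1, age_origin = 7) {
  stopifnot(intercept > 0, cohort_ratio > 0, sex_ratio > 0, age_ratio > 0,
            age_sex_ratio > 0, age_cohort_ratio > 0)
  structure(list(intercept = intercept, cohort_ratio = cohort_ratio,
                 sex_ratio = sex_ratio, age_ratio = age_ratio,
                 age_sex_ratio = age_sex_ratio,
                 age_cohort_ratio = age_cohort_ratio,
                 age_origin = age_origin),
            class = "trend_coefs")
}

coefs_from_fit <- function(fit) {
  td <- tidy(fit)
  if (any(c("height", "weight") %in% td$term)) {
    stop("predict_at_age() supports age- and sex-adjusted (Model 1) fits only")
  }
  if (fit$squared_age) {
    stop("predict_at_age() does not support squared-age fits; use fitted_curves()")
  }
  get <- function(term, default = 1) {
    v <- td$estimate[td$term == term]
    if (length(v)) v else default
  }
  trend_coefficients(get("intercept"), get("cohort"), get("sex"),
                     get("age"), get("age_sex"), get("age_cohort"),
                     age_origin = fit$age_origin)
}

sex_indicator <- function(sex, levels) {
  if (sex %in% c(levels[1], "reference", "male")) 0 else 1
}
cohort_indicator <- function(cohort, levels) {
  if (cohort %in% c(levels[1], "reference")) 0 else 1
}

#' Predict a trait value from the multiplicative trajectory model
#'
#' Evaluates
#' `intercept * sex_ratio^S * cohort_ratio^C *
#'  (age_ratio * age_sex_ratio^S * age_cohort_ratio^C)^(age - origin)`.
#'
#' @param object a `trend_fit` or [trend_coefficients()] object.
#' @param age age in years; must lie within `window` unless
#'   `extrapolate = TRUE`.
#' @param sex `"reference"` (boys) or the second factor level / `"other"`.
#' @param cohort `"reference"` or the comparison level.
#' @param window allowed prediction range, default `c(7, 16)`.
#' @param extrapolate allow ages outside the window.
#' @return predicted trait value (numeric).
#' @export
predict_at_age <- function(object, age, sex = "reference",
                           cohort = "reference", window = c(7, 16),
                           extrapolate = FALSE) {
  if (inherits(object, "trend_fit")) {
    cf <- coefs_from_fit(object)
    sexlev <- object$sex_levels; cohlev <- object$cohort_levels
  } else if (inherits(object, "trend_coefs")) {
    cf <- object
    sexlev <- c("reference", "female"); cohlev <- c("reference", "comparison")
  } else stop("object must be a trend_fit or trend_coefs")
  if (!extrapolate && (any(age < window[1]) || any(age > window[2]))) {
    stop("age outside the prediction window [", window[1], ", ", window[2],
         "]; set extrapolate = TRUE to override")
  }
  S <- sex_indicator(sex, sexlev)
  C <- cohort_indicator(cohort, cohlev)
  cf$intercept * cf$sex_ratio^S * cf$cohort_ratio^C *
    (cf$age_ratio * cf$age_sex_ratio^S * cf$age_cohort_ratio^C)^(age - cf$age_origin)
}

#' Predicted cohort difference at a given age
#'
#' @inheritParams predict_at_age
#' @return one-row tibble: `age`, `sex`, `reference`, `comparison`,
#'   `difference` (comparison minus reference, trait units) and `percent`
#'   (difference relative to the reference value, %).
#' @export
cohort_difference_at_age <- function(object, age, sex = "reference",
                                     window = c(7, 16), extrapolate = FALSE) {
  ref <- predict_at_age(object, age, sex, "reference", window, extrapolate)
  cmp <- predict_at_age(object, age, sex, "comparison", window, extrapolate)
  tibble::tibble(age = age, sex = sex, reference = ref, comparison = cmp,
                 difference = cmp - ref, percent = (cmp - ref) / ref * 100)
}

#' Fit the anthropometry growth model
#'
#' The height/weight counterpart of [fit_trend()]: log outcome on centered
#' age, sex, cohort and their age interactions, plus a squared centered-age
#' term with its sex interaction to absorb the curvature of log-scale growth.
#'
#' @inheritParams fit_trend
#' @param outcome `"height"` or `"weight"`.
#' @return a `trend_fit`.
#' @export
fit_growth_model <- function(data, outcome = c("height", "weight"),
                             age_origin = 7, sex_ref = NULL, cohort_ref = NULL,
                             conf.level = 0.95) {
  outcome <- match.arg(outcome)
  fit_trend(data, outcome, model = 1, squared_age = TRUE,
            age_origin = age_origin, sex_ref = sex_ref,
            cohort_ref = cohort_ref, conf.level = conf.level)
}

#' Fitted trajectory curves with pointwise confidence bands
#'
#' Evaluates the fitted model over an age grid for every sex-by-cohort
#' stratum, with pointwise Wald bands computed on the log scale and
#' antilogged. For Model 2 fits the covariates are held at their means.
#'
#' @param fit a `trend_fit`.
#' @param ages numeric grid of ages.
#' @param conf.level band level.
#' @return tibble: `age`, `sex`, `cohort`, `fit`, `conf.low`, `conf.high`
#'   (trait units).
#' @export
fitted_curves <- function(fit, ages = seq(7, 16, by = 0.25),
                          conf.level = fit$conf.level) {
  grid <- tidyr::expand_grid(age = ages, sex = fit$sex_levels,
                             cohort = fit$cohort_levels)
  nd <- tibble::tibble(
    age_c = grid$age - fit$age_origin,
    sex_f = factor(grid$sex, levels = fit$sex_levels),
    cohort_f = factor(grid$cohort, levels = fit$cohort_levels)
  )
  if (fit$model == 2L) {
    nd$height <- mean(fit$data$height)
    nd$weight <- mean(fit$data$weight)
  }
  pr <- predict(fit$fit, newdata = nd, se.fit = TRUE)
  z <- stats::qt(1 - (1 - conf.level) / 2, fit$fit$df.residual)
  dplyr::mutate(grid,
                fit = exp(pr$fit),
                conf.low = exp(pr$fit - z * pr$se.fit),
                conf.high = exp(pr$fit + z * pr$se.fit))
}
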