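noiseless_kids <- function(seed = 13) {
  generate_cohorts(default_generative_params(sigma_log = 0), seed = seed)
}

test_that("noiseless fits recover every generative ratio to machine precision", {
  kids <- noiseless_kids()
  p <- default_generative_params()
  for (tr in c("bmc", "periosteal_diameter", "strength_index")) {
    fit <- suppressWarnings(fit_trend(kids, tr, sex_ref = "male"))
    td <- suppressWarnings(tidy(fit))
    row <- p$traits[p$traits$trait == tr, ]
    truth <- c(intercept = row$intercept, age = row$age_ratio,
               sex = row$sex_ratio, cohort = row$cohort_ratio,
               age_sex = row$age_sex_ratio, age_cohort = row$age_cohort_ratio)
    expect_equal(td$estimate[match(names(truth), td$term)], unname(truth),
                 tolerance = 1e-8)
  }
})

test_that("single-cohort or single-sex data cannot identify the contrasts", {
  kids <- generate_cohorts(seed = 2)
  ref_only <- dplyr::filter(kids, cohort == "1979-1981")
  expect_error(fit_trend(ref_only, "bmc"), "cohort")
  boys_only <- dplyr::filter(kids, sex == "male")
  expect_error(fit_trend(boys_only, "bmc"), "sex")
  kids$bmc[3] <- -1
  expect_error(fit_trend(kids, "bmc"), "non-positive")
})

test_that("slope contrasts print as conventional percent-per-year strings", {
  expect_equal(format_contrast(1.011, 1.003, 1.020), "1.1%/year (0.3%, 2.0%)")
  expect_equal(format_contrast(0.989, 0.980, 0.998), "-1.1%/year (-2.0%, -0.2%)")
  expect_equal(ratio_to_percent(1.000), 0)
  # strictly increasing in the ratio
  expect_true(all(diff(ratio_to_percent(c(0.9, 0.99, 1, 1.05))) > 0))
})

test_that("predictions evaluate the multiplicative model", {
  tc <- trend_coefficients(345.930, cohort_ratio = 0.909, age_ratio = 1.095)
  # age origin: the intercept is returned exactly at age 7
  expect_equal(predict_at_age(tc, 7), 345.930)
  d16 <- cohort_difference_at_age(tc, 16)
  expect_equal(round(d16$reference, 1), 782.9)
  expect_equal(round(d16$difference, 1), -71.2)
  expect_equal(round(-d16$percent, 1), 9.1)

  # null cohort effects give zero difference at every age
  null_tc <- trend_coefficients(100, age_ratio = 1.05)
  for (a in c(7, 10, 16)) {
    expect_equal(cohort_difference_at_age(null_tc, a)$difference, 0)
  }

  expect_error(predict_at_age(tc, 20), "window")
  expect_equal(predict_at_age(tc, 7, extrapolate = TRUE, age = 20),
               predict_at_age(tc, 20, extrapolate = TRUE))

  # fitted-model predictions agree with the coefficient-set route
  kids <- noiseless_kids()
  fit <- suppressWarnings(fit_trend(kids, "bmc", sex_ref = "male"))
  expect_equal(suppressWarnings(predict_at_age(fit, 16, sex = "male", cohort = "1979-1981")),
               782.9, tolerance = 0.1)
})

test_that("predict_at_age at age 7 returns the intercept for any fit", {
  kids <- generate_cohorts(seed = 31)
  fit <- fit_trend(kids, "bmd", sex_ref = "male")
  td <- tidy(fit)
  expect_equal(predict_at_age(fit, 7),
               td$estimate[td$term == "intercept"], tolerance = 1e-10)
})

test_that("rescaling the outcome moves only the intercept", {
  kids <- generate_cohorts(seed = 17)
  f1 <- fit_trend(kids, "bmc", sex_ref = "male")
  kids$bmc_scaled <- kids$bmc * 2.5
  f2 <- fit_trend(kids, "bmc_scaled", sex_ref = "male")
  t1 <- tidy(f1); t2 <- tidy(f2)
  expect_equal(t2$estimate[t2$term == "intercept"],
               2.5 * t1$estimate[t1$term == "intercept"], tolerance = 1e-10)
  ratios <- setdiff(t1$term, "intercept")
  expect_equal(t2$estimate[match(ratios, t2$term)],
               t1$estimate[match(ratios, t1$term)], tolerance = 1e-10)
})

test_that("model 2 adjusts for anthropometry", {
  kids <- generate_cohorts(seed = 23)
  f2 <- fit_trend(kids, "bmc", model = 2, sex_ref = "male")
  td <- tidy(f2)
  expect_true(all(c("height", "weight") %in% td$term))
  f2l <- fit_trend(kids, "bmc", model = 2, sex_ref = "male",
                   log_covariates = TRUE)
  expect_false(isTRUE(all.equal(glance(f2)$sigma_log, glance(f2l)$sigma_log)))
})

test_that("the growth model captures quadratic log-age curvature", {
  p0 <- default_generative_params(sigma_log = 0)
  kids <- generate_cohorts(p0, seed = 41)
  fit <- suppressWarnings(fit_growth_model(kids, "height", sex_ref = "male"))

  # exact coefficient recovery on noiseless quadratic-log heights
  g <- p0$growth[p0$growth$outcome == "height" & p0$growth$sex == "male", ]
  lc <- coef(fit$fit)
  expect_equal(unname(exp(lc["(Intercept)"])), g$intercept, tolerance = 1e-8)
  expect_equal(unname(lc["age_c"]), g$slope1, tolerance = 1e-8)
  expect_equal(unname(lc["I(age_c^2)"]), g$slope2, tolerance = 1e-8)

  # omitting the squared term on curved data inflates the residual SD
  kids_n <- generate_cohorts(default_generative_params(), seed = 42)
  with_sq <- fit_growth_model(kids_n, "height", sex_ref = "male")
  without_sq <- fit_trend(kids_n, "height", sex_ref = "male")
  expect_lt(glance(with_sq)$sigma_log, glance(without_sq)$sigma_log)

  # residuals show no remaining quadratic age trend
  res <- stats::residuals(with_sq$fit)
  age_c <- with_sq$data$age_c
  quad <- coef(summary(lm(res ~ age_c + I(age_c^2))))["I(age_c^2)", ]
  expect_gt(quad["Pr(>|t|)"], 0.01)
})

test_that("fitted curves expose pointwise bands on the response scale", {
  kids <- generate_cohorts(seed = 55)
  fit <- fit_trend(kids, "bmc", sex_ref = "male")
  cv <- fitted_curves(fit, ages = c(7, 10, 16))
  expect_equal(nrow(cv), 3 * 2 * 2)
  expect_true(all(cv$conf.low < cv$fit & cv$fit < cv$conf.high))
  pl <- autoplot(fit)
  expect_s3_class(pl, "ggplot")
})
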