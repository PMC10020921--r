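#' Parameter-recovery simulation
#'
#' Repeatedly generates synthetic two-cohort datasets under the given
#' generative parameters, fits the Model 1 log-linear trajectory model to
#' each requested trait, and collects the tidied antilogged coefficients.
#' This is the stochastic-recovery machinery behind the headline checks:
#' with the model correctly specified, the mean fitted ratios converge to
#' the generative ratios and the 95% CIs cover them at the nominal rate.
#'
#' @param params an `spa_params` object (defaults define the two-cohort
#'   study conditions: 55/61 and 238/204 children).
#' @param traits character vector of trait columns to fit.
#' @param n_replicates number of simulated datasets.
#' @param seed optional integer seed for the whole simulation.
#' @param model passed to [fit_trend()].
#' @return tibble with one row per replicate x trait x term:
#'   `replicate`, `trait`, `term`, `estimate`, `conf.low`, `conf.high`,
#'   `p.value`.
#' @export
#' @examples
#' rec <- parameter_recovery(n_replicates = 5, traits = "bmc", seed = 1)
#' recovery_summary(rec)
parameter_recovery <- function(params = default_generative_params(),
                               traits = c("bmc", "bmd", "periosteal_diameter",
                                          "csmi", "section_modulus",
                                          "strength_index"),
                               n_replicates = 200, seed = NULL, model = 1) {
  stopifnot(all(traits %in% params$traits$trait))
  if (!is.null(seed)) set.seed(seed)
  reps <- purrr::map(seq_len(n_replicates), function(r) {
    kids <- generate_cohorts(params)
    purrr::map(traits, function(tr) {
      fit <- fit_trend(kids, tr, model = model, sex_ref = params$sex_labels[1],
                       cohort_ref = params$cohort_labels[1])
      td <- tidy(fit)
      td$trait <- tr
      td$replicate <- r
      td[, c("replicate", "trait", "term", "estimate",
             "conf.low", "conf.high", "p.value")]
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(reps)
  attr(out, "params") <- params
  out
}

#' Summarize a parameter-recovery simulation
#'
#' Joins the generative truth onto the recovered coefficients and reports,
#' per trait and term, the mean fitted ratio, its Monte-Carlo standard
#' error, the mean percent contrast, and the empirical coverage of the
#' confidence intervals.
#'
#' @param recovery output of [parameter_recovery()].
#' @param params generative parameters; defaults to those attached to
#'   `recovery`.
#' @return tibble: `trait`, `term`, `truth` (generative ratio),
#'   `mean_estimate`, `mc_se`, `mean_percent`, `coverage`, `n_replicates`.
#' @export
recovery_summary <- function(recovery, params = attr(recovery, "params")) {
  if (is.null(params)) params <- default_generative_params()
  truth <- tidyr::pivot_longer(
    params$traits,
    cols = c("intercept", "cohort_ratio", "sex_ratio", "age_ratio",
             "age_sex_ratio", "age_cohort_ratio"),
    names_to = "term", values_to = "truth"
  )
  truth$term <- sub("_ratio$", "", truth$term)
  truth <- dplyr::select(truth, "trait", "term", "truth")

  joined <- dplyr::inner_join(recovery, truth, by = c("trait", "term"))
  dplyr::summarise(
    dplyr::group_by(joined, .data$trait, .data$term),
    truth = .data$truth[1],
    mean_estimate = mean(.data$estimate),
    mc_se = stats::sd(.data$estimate) / sqrt(dplyr::n()),
    mean_percent = mean(ratio_to_percent(.data$estimate)),
    coverage = mean(.data$conf.low <= .data$truth &
                      .data$truth <= .data$conf.high),
    n_replicates = dplyr::n(),
    .groups = "drop"
  )
}
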