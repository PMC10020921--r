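#' Generate a synthetic two-cohort pediatric dataset
#'
#' Draws one row per child. Ages are continuous-uniform over the configured
#' range; every bone trait is drawn from its own multiplicative (log-linear)
#' age-trajectory model with independent Normal residuals on the natural-log
#' scale (see [default_generative_params()]); height and weight follow
#' per-sex quadratic log-age curves so that the squared-age growth model is
#' exercised. Fracture-in-the-preceding-year flags (with the injured arm) and
#' arm dominance are assigned to exercise the exclusion rules downstream.
#'
#' With `sigma_log = 0` the latent traits are exactly log-linear in age within
#' each sex-by-cohort stratum, and a 7-year-old boy in the reference cohort
#' carries each trait's intercept exactly.
#'
#' @param params an `spa_params` object, default [default_generative_params()].
#' @param seed optional integer; when supplied the draw is reproducible.
#' @return A tibble with one row per child: `child_id`, `cohort`, `sex`,
#'   `age`, `height`, `weight`, `fracture_last_year`, `injured_arm`,
#'   `dominant_arm`, and one column per latent trait (`bmc`, `bmd`, `bmad`,
#'   `periosteal_diameter`, `medullary_diameter`, `cortical_thickness`,
#'   `total_area`, `csmi`, `section_modulus`, `strength_index`). The
#'   generating `spa_params` are attached as attribute `"params"`.
#' @export
#' @examples
#' kids <- generate_cohorts(seed = 1)
#' dplyr::count(kids, cohort, sex)
generate_cohorts <- function(params = default_generative_params(), seed = NULL) {
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)

  strata <- params$n[params$n$n > 0, ]
  children <- tidyr::uncount(strata, weights = .data$n)
  n <- nrow(children)
  if (n == 0L) stop("all cohort sample sizes are zero")
  children <- dplyr::mutate(children,
    child_id = sprintf("child%04d", dplyr::row_number()),
    cohort = factor(.data$cohort, levels = params$cohort_labels),
    sex = factor(.data$sex, levels = params$sex_labels),
    age = runif(n, params$age_range[1], params$age_range[2])
  )

  S <- as.integer(children$sex == params$sex_labels[2])
  C <- as.integer(children$cohort == params$cohort_labels[2])
  t_c <- children$age - 7

  for (i in seq_len(nrow(params$traits))) {
    p <- params$traits[i, ]
    mu <- log(p$intercept) + log(p$sex_ratio) * S + log(p$cohort_ratio) * C +
      (log(p$age_ratio) + log(p$age_sex_ratio) * S + log(p$age_cohort_ratio) * C) * t_c
    children[[p$trait]] <- exp(mu + rnorm(n, 0, p$sigma_log))
  }

  for (out in unique(params$growth$outcome)) {
    g <- params$growth[params$growth$outcome == out, ]
    gi <- g[match(as.character(children$sex), g$sex), ]
    mu <- log(gi$intercept) + gi$slope1 * t_c + gi$slope2 * t_c^2 +
      log(gi$cohort_ratio) * C
    children[[out]] <- exp(mu + rnorm(n, 0, gi$sigma_log))
  }

  children$fracture_last_year <- rbinom(n, 1, params$fracture_rate) == 1
  children$injured_arm <- ifelse(children$fracture_last_year,
                                 sample(c("left", "right"), n, replace = TRUE),
                                 NA_character_)
  children$dominant_arm <- sample(c("right", "left", "unknown"), n,
                                  replace = TRUE, prob = c(0.85, 0.10, 0.05))

  out <- dplyr::relocate(tibble::as_tibble(children), "child_id")
  attr(out, "params") <- params
  out
}

#' Latent per-bone geometry for the scan simulator
#'
#' Expands a cohort table to one row per bone (two bones per arm, two arms per
#' child). Per-bone periosteal diameter, medullary diameter and volumetric
#' mineral density are jittered around the child's latent values on the log
#' scale, with jitter SD `sigma_log * sqrt(1/bone_cor - 1)` so that two bones
#' of the same child correlate at `bone_cor` (radius and ulna at this site
#' are near-identical in width). Draws violating `medullary < periosteal`
#' are resampled (up to 50 times, then the medullary value is clamped);
#' the number of resampled bones is recorded in attribute `"n_resampled"`.
#'
#' The bone's latent linear mineral content follows from the geometry:
#' BMC (mg/cm) = volumetric density (mg/cm3) x cortical area (cm2), so the
#' whole simulate-then-measure chain is self-consistent.
#'
#' @param children a cohort tibble from [generate_cohorts()].
#' @param params the generating `spa_params`; defaults to the ones attached to
#'   `children`.
#' @param seed optional integer seed.
#' @return A tibble with one row per bone: `child_id`, `arm`, `bone`,
#'   `bone_index` (1--4), `technical_error`, `injured`, `periosteal`,
#'   `medullary`, `vol_density`, `bmc_true`.
#' @export
generate_bone_geometry <- function(children, params = attr(children, "params"),
                                   seed = NULL) {
  if (is.null(params)) params <- default_generative_params()
  if (!is.null(seed)) set.seed(seed)

  jitter_sd <- function(trait) {
    generative_value(params, trait, "sigma_log") * sqrt(1 / params$bone_cor - 1)
  }
  u_pd <- jitter_sd("periosteal_diameter")
  u_md <- jitter_sd("medullary_diameter")
  u_vd <- jitter_sd("bmad")

  bones <- tidyr::expand_grid(
    child_id = children$child_id,
    arm = c("left", "right"),
    bone = 1:2
  )
  bones <- dplyr::left_join(
    bones,
    dplyr::select(children, "child_id", "fracture_last_year", "injured_arm",
                  pd_child = "periosteal_diameter",
                  md_child = "medullary_diameter", vd_child = "bmad"),
    by = "child_id"
  )
  nb <- nrow(bones)
  pd <- bones$pd_child * exp(rnorm(nb, 0, u_pd))
  md <- bones$md_child * exp(rnorm(nb, 0, u_md))

  n_resampled <- 0L
  bad <- which(md >= pd)
  tries <- 0L
  while (length(bad) && tries < 50L) {
    n_resampled <- max(n_resampled, length(bad))
    md[bad] <- bones$md_child[bad] * exp(rnorm(length(bad), 0, u_md))
    bad <- which(md >= pd)
    tries <- tries + 1L
  }
  if (length(bad)) md[bad] <- 0.95 * pd[bad]

  out <- dplyr::mutate(bones,
    bone_index = (as.integer(.data$arm == "right")) * 2L + .data$bone,
    technical_error = FALSE,
    injured = .data$fracture_last_year & !is.na(.data$injured_arm) &
      .data$arm == .data$injured_arm,
    periosteal = pd,
    medullary = md,
    vol_density = .data$vd_child * exp(rnorm(nb, 0, u_vd))
  )
  # technical errors are a per-arm-scan property: both bones of an arm share it
  arms <- dplyr::distinct(out, .data$child_id, .data$arm)
  arms$technical_error <- rbinom(nrow(arms), 1, params$technical_error_rate) == 1
  out$technical_error <- NULL
  out <- dplyr::left_join(out, arms, by = c("child_id", "arm"))
  out <- dplyr::mutate(out, bmc_true = .data$vol_density *
                         bone_areas(.data$periosteal, .data$medullary)$cortical)
  out <- dplyr::select(out, "child_id", "arm", "bone", "bone_index",
                       "technical_error", "injured",
                       "periosteal", "medullary", "vol_density", "bmc_true")
  attr(out, "n_resampled") <- n_resampled
  out
}

#' Write / read a cohort table as delimited text
#'
#' @param children cohort tibble.
#' @param path CSV path.
#' @return `write_cohorts()` returns `path` invisibly; `read_cohorts()` a tibble.
#' @export
write_cohorts <- function(children, path) {
  readr::write_csv(children, path)
  invisible(path)
}

#' @rdname write_cohorts
#' @export
read_cohorts <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
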