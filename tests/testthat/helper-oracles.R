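# Independent oracles used across tests.

# Second moment of the cortical annulus about a diameter axis, by brute-force
# midpoint quadrature of y^2 * chord_width(y): I = int y^2 [w_o(y) - w_i(y)] dy,
# diameters in mm, result in cm^4. Independent of the closed-form csmi().
oracle_csmi <- function(pd, md, n = 2e5) {
  ro <- pd / 20  # cm
  ri <- md / 20
  h <- 2 * ro / n
  y <- seq(-ro + h / 2, ro - h / 2, length.out = n)
  width <- function(y, r) ifelse(abs(y) < r, 2 * sqrt(pmax(r^2 - y^2, 0)), 0)
  sum(y^2 * (width(y, ro) - width(y, ri))) * h
}

# closed-form annulus cross-sectional area, cm^2
oracle_cortical_area <- function(pd, md) {
  pi / 4 * ((pd / 10)^2 - (md / 10)^2)
}

# evaluate the generative log-linear predictor for one trait
oracle_latent <- function(params, trait, age, female, comparison) {
  p <- params$traits[params$traits$trait == trait, ]
  exp(log(p$intercept) + log(p$sex_ratio) * female +
        log(p$cohort_ratio) * comparison +
        (log(p$age_ratio) + log(p$age_sex_ratio) * female +
           log(p$age_cohort_ratio) * comparison) * (age - 7))
}

# single-bone trace builder for round-trip tests
make_bone_trace <- function(pd, md, vol_density = 600, step = 0.1,
                            scan_width = 40, noise_sd = 0, baseline = 2) {
  simulate_trace(
    tibble::tibble(center = scan_width / 2, periosteal = pd,
                   medullary = md, vol_density = vol_density),
    scan_config(step = step, scan_width = scan_width, noise_sd = noise_sd),
    baseline = baseline
  )
}
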