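test_that("cylindrical areas and thickness follow the diameter formulas", {
  a <- bone_areas(9.455, 4.025)
  expect_equal(a$total, pi / 4 * 0.9455^2, tolerance = 1e-12)
  expect_equal(round(a$total, 3), 0.702)
  expect_equal(round(a$cortical, 3), 0.575)
  expect_equal(a$cortical, a$total - a$medullary, tolerance = 1e-15)

  solid <- bone_areas(10, 0)
  expect_equal(solid$medullary, 0)
  expect_equal(solid$cortical, solid$total)

  expect_equal(cortical_thickness(9.455, 4.025), 2.715)
  expect_equal(cortical_thickness(8, 8), 0)
  expect_equal(cortical_thickness(8, 0), 4)
  expect_error(bone_areas(8, 8), "non-physical")
  expect_error(cortical_thickness(8, 9), "non-physical")
})

test_that("csmi matches brute-force annulus integration to < 0.1%", {
  expect_equal(round(csmi(9.455, 4.025), 4), 0.0379)
  # solid cylinder closed form pi r^4 / 4 at d = 20 mm (r = 1 cm)
  expect_equal(csmi(20, 0), pi / 4)

  set.seed(77)
  for (i in 1:20) {
    pd <- runif(1, 5, 20)
    md <- runif(1, 0, 0.9) * pd
    expect_equal(csmi(pd, md), oracle_csmi(pd, md), tolerance = 1e-3)
  }

  # strictly increasing in periosteal diameter at fixed medullary diameter
  pds <- seq(6, 14, by = 0.5)
  expect_true(all(diff(csmi(pds, 4)) > 0))
})

test_that("section modulus, bmad and strength index compose correctly", {
  expect_equal(section_modulus(0.0379, 9.455), 0.0379 / 0.47275,
               tolerance = 1e-12)
  expect_equal(round(section_modulus(csmi(9.455, 4.025), 9.455), 4), 0.0803)
  expect_equal(section_modulus(csmi(20, 0), 20), pi / 4)  # Z = pi r^3 / 4

  # scaling both diameters by s scales Z by s^3
  s <- 1.3
  expect_equal(section_modulus(csmi(9.455 * s, 4.025 * s), 9.455 * s),
               s^3 * section_modulus(csmi(9.455, 4.025), 9.455),
               tolerance = 1e-12)

  expect_equal(bmad(345.930, 0.575), 345.930 / 0.575, tolerance = 1e-12)
  expect_equal(bmad(0, 0.575), 0)
  expect_equal(bmad(200, 0.5), bmad(400, 1.0))
  expect_error(bmad(100, 0), "positive")

  expect_equal(strength_index(0.087, 590.672), 51.388, tolerance = 1e-3)
  expect_equal(strength_index(0, 590.672), 0)
  chain <- strength_index(section_modulus(csmi(9.455, 4.025), 9.455),
                          bmad(345.930, bone_areas(9.455, 4.025)$cortical))
  expect_equal(chain, 48.3, tolerance = 0.01)
})

test_that("the derived chain at generative truth collapses to Z x density", {
  # strength index built from geometry-consistent BMC equals Z * vol_density
  set.seed(5)
  for (i in 1:10) {
    pd <- runif(1, 6, 15)
    md <- runif(1, 0.1, 0.8) * pd
    vd <- runif(1, 300, 900)
    area <- bone_areas(pd, md)$cortical
    z <- section_modulus(csmi(pd, md), pd)
    si <- strength_index(z, bmad(vd * area, area))
    expect_equal(si, z * vd, tolerance = 1e-12)
  }
})

test_that("derive_traits keeps the panel internally consistent", {
  panel <- derive_traits(tibble::tibble(
    bmc = c(345.93, 200), periosteal_diameter = c(9.455, 8),
    medullary_diameter = c(4.025, 3)))
  expect_equal(panel$cortical_area, panel$total_area - panel$medullary_area)
  expect_equal(panel$cortical_thickness,
               (panel$periosteal_diameter - panel$medullary_diameter) / 2)
  expect_equal(panel$strength_index, panel$section_modulus * panel$bmad)
  expect_equal(panel$bmd, panel$bmc / (panel$periosteal_diameter / 10))
})

test_that("correction constants are recovered from phantom segment means", {
  cal <- calibrated_drift_model(pre_constant = 1.002, post_constant = 1.034)
  ref <- simulate_phantom_series(cal, seq(100, 600, by = 25))
  cmp <- simulate_phantom_series(cal, seq(14000, 14300, by = 25))
  k <- estimate_correction_constants(ref, cmp, cal$source_change_date)
  expect_equal(k$pre_change, 1.002, tolerance = 1e-9)
  expect_equal(k$post_change, 1.034, tolerance = 1e-9)

  # identical phantom means imply unit constants
  flat <- simulate_phantom_series(drift_model(), seq(1, 400, by = 20))
  flat2 <- simulate_phantom_series(drift_model(), seq(1000, 1400, by = 20))
  k0 <- estimate_correction_constants(flat, flat2, 200)
  expect_equal(k0$pre_change, 1)
  expect_equal(k0$post_change, 1)

  # noisy recovery within standard-error tolerance
  set.seed(1002)
  refn <- simulate_phantom_series(cal, seq(100, 600, by = 5), noise_cv = 0.5)
  cmpn <- simulate_phantom_series(cal, seq(14000, 14500, by = 5), noise_cv = 0.5)
  kn <- estimate_correction_constants(refn, cmpn, cal$source_change_date)
  expect_equal(kn$pre_change, 1.002, tolerance = 0.005)
  expect_equal(kn$post_change, 1.034, tolerance = 0.005)

  expect_error(estimate_correction_constants(cmp, cmp, 100), "non-empty")
})

test_that("drift correction scales mineral traits only and is invertible", {
  panel <- derive_traits(tibble::tibble(
    bmc = 100, periosteal_diameter = 9, medullary_diameter = 4))
  k <- tibble::tibble(pre_change = 1.002, post_change = 1.034)
  corr <- apply_correction(panel, k, before_change = FALSE)
  expect_equal(corr$bmc, 103.4)
  expect_equal(corr$bmd, panel$bmd * 1.034)
  expect_equal(corr$periosteal_diameter, panel$periosteal_diameter)
  expect_equal(corr$csmi, panel$csmi)

  pre <- apply_correction(panel, k, before_change = TRUE)
  expect_equal(pre$bmc, 100.2)

  back <- apply_correction(corr, k, before_change = FALSE, invert = TRUE)
  expect_equal(back, panel)

  unit <- apply_correction(panel, tibble::tibble(pre_change = 1, post_change = 1),
                           before_change = FALSE)
  expect_equal(unit, panel)
})

test_that("rms precision CV matches hand arithmetic and recovers injected CV", {
  d <- data.frame(id = 1, y = c(95, 100, 105))
  expect_equal(precision_cv(d, id, y), 5.0)

  same <- data.frame(id = rep(1:3, each = 3), y = 100)
  expect_equal(precision_cv(same, id, y), 0)

  # 20 arms x 3 repositioned scans at 4.8% true CV
  set.seed(48)
  reps <- tidyr::expand_grid(id = 1:20, rep = 1:3)
  reps$y <- 100 * (1 + rnorm(nrow(reps), 0, 0.048))
  expect_equal(precision_cv(reps, id, y), 4.8, tolerance = 1.2)

  expect_error(precision_cv(data.frame(id = 1, y = 5), id, y), "replicates")
  expect_error(precision_cv(data.frame(id = c(1, 1), y = c(-2, 0)), id, y),
               "positive")
})
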