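test_that("baseline estimation recovers flat flanks and flags narrow windows", {
  tr <- make_bone_trace(10, 0, baseline = 2.0)
  expect_equal(estimate_baseline(tr), 2.0)

  # noisy baseline: SE = sd/sqrt(2k), estimate lands within a few SE
  set.seed(8)
  trn <- make_bone_trace(10, 0, step = 1, noise_sd = 0.1, baseline = 2.0)
  expect_lt(abs(estimate_baseline(trn) - 2.0), 0.1)

  # all-zero trace
  tr0 <- simulate_trace(
    tibble::tibble(center = 20, periosteal = 10, medullary = 0,
                   vol_density = 1e-12),
    scan_config(), baseline = 0)
  expect_equal(estimate_baseline(tr0), 0)

  trn2 <- simulate_trace(
    tibble::tibble(center = 7, periosteal = 12, medullary = 6,
                   vol_density = 800),
    scan_config(step = 1, scan_width = 14))
  expect_error(estimate_baseline(trn2), "too narrow")
})

test_that("edge detection recovers diameters within interpolation tolerance", {
  # solid cylinder at the default 1 mm step: within one step
  tr <- make_bone_trace(10, 0, step = 1)
  e <- detect_edges(tr, expected_bones = 1)
  expect_equal(e$quality, "ok")
  expect_lt(abs(e$periosteal - 10), 1)
  expect_equal(e$medullary, 0)

  # annulus at 0.1 mm step: periosteal within 0.15 mm (threshold bias +
  # interpolation), medullary within 0.3 mm
  tr2 <- make_bone_trace(12, 6, step = 0.1)
  e2 <- detect_edges(tr2, expected_bones = 1)
  expect_lt(abs(e2$periosteal - 12), 0.15)
  expect_lt(abs(e2$medullary - 6), 0.3)
})

test_that("a one-bone forearm scan is flagged as a technical error", {
  tr <- make_bone_trace(10, 4)
  m <- analyze_trace(tr)  # expects two bones
  expect_equal(m$quality, "technical_error")
  expect_true(is.na(m$bmc))
})

test_that("integrated BMC matches density x cortical area", {
  # annulus chosen so BMAD x cortical area ~ 345 mg/cm
  tr <- make_bone_trace(9.455, 4.025, vol_density = 600, step = 0.1)
  e <- detect_edges(tr, expected_bones = 1)
  bmc <- integrate_bmc(tr, attr(tr, "baseline_true"),
                       c(e$outer_left, e$outer_right))
  truth <- 600 * oracle_cortical_area(9.455, 4.025)
  expect_equal(bmc, truth, tolerance = 0.01)

  # linearity in density
  tr2 <- make_bone_trace(9.455, 4.025, vol_density = 1200, step = 0.1)
  bmc2 <- integrate_bmc(tr2, attr(tr2, "baseline_true"),
                        c(e$outer_left, e$outer_right))
  expect_equal(bmc2 / bmc, 2, tolerance = 1e-6)

  # zero-mineral trace integrates to ~0 (and noise floors at 0 with warning)
  tr0 <- simulate_trace(
    tibble::tibble(center = 20, periosteal = 10, medullary = 0,
                   vol_density = 1e-9), scan_config(step = 0.5))
  expect_equal(integrate_bmc(tr0, 2, c(15, 25)), 0, tolerance = 1e-8)
  set.seed(1)
  trneg <- simulate_trace(
    tibble::tibble(center = 20, periosteal = 10, medullary = 0,
                   vol_density = 1e-9),
    scan_config(step = 0.5, noise_sd = 5))
  expect_warning(v <- integrate_bmc(trneg, 10, c(15, 25)), "floored")
  expect_equal(v, 0)
})

test_that("noiseless generate-scan-analyze round trip over random geometries", {
  set.seed(42)
  for (i in 1:12) {
    pd <- runif(1, 7, 14)
    md <- runif(1, 0.25, 0.65) * pd
    vd <- runif(1, 400, 900)
    tr <- make_bone_trace(pd, md, vol_density = vd, step = 0.1,
                          scan_width = 44)
    m <- analyze_trace(tr, expected_bones = 1)
    expect_equal(m$quality, "ok")
    expect_lt(abs(m$periosteal - pd), 0.2)
    expect_lt(abs(m$medullary - md), 0.4)
    truth <- vd * oracle_cortical_area(pd, md)
    expect_lt(abs(m$bmc - truth) / truth, 0.01)
  }
})

test_that("bmd follows from bmc and scanned width", {
  expect_equal(compute_bmd(345.930, 9.455), 345.930 / 0.9455, tolerance = 1e-12)
  expect_equal(round(compute_bmd(345.930, 9.455), 1), 365.9)
  expect_equal(compute_bmd(0, 9.455), 0)
  expect_equal(compute_bmd(123.4, 10), 123.4)  # 10 mm width = 1 cm
  expect_error(compute_bmd(100, 0), "positive")
})

test_that("panel assembly applies exclusion and averaging rules", {
  four <- tibble::tibble(
    arm = c("left", "left", "right", "right"), bone_index = 1:4,
    bmc = c(300, 320, 340, 360), periosteal = c(9, 9.2, 9.4, 9.6),
    medullary = c(4, 4, 4, 4), quality = "ok")
  rec <- list(fracture_last_year = FALSE, injured_arm = NA_character_)
  p <- assemble_child_panel(four, rec)
  expect_equal(p$bmc, 330)
  expect_equal(p$periosteal_diameter, 9.3)
  expect_equal(p$n_bones, 4L)
  expect_false(p$one_arm)

  # four identical bones: panel equals single-bone values
  same <- dplyr::mutate(four, bmc = 320, periosteal = 9.2)
  p_same <- assemble_child_panel(same, rec)
  expect_equal(p_same$bmc, 320)
  expect_equal(p_same$csmi, csmi(9.2, 4))

  # fracture in the last year: only the uninjured arm's two bones count
  rec2 <- list(fracture_last_year = TRUE, injured_arm = "left")
  p2 <- assemble_child_panel(four, rec2)
  expect_equal(p2$n_bones, 2L)
  expect_true(p2$one_arm)
  expect_equal(p2$bmc, 350)

  # technical errors dropped; all-bad child yields an empty panel
  bad <- dplyr::mutate(four, quality = "technical_error")
  expect_equal(nrow(assemble_child_panel(bad, rec)), 0L)

  # derived traits come from averaged primitives, not averaged derivations
  expect_equal(p$csmi, csmi(9.3, 4))
  expect_false(isTRUE(all.equal(p$csmi, mean(csmi(four$periosteal, 4)))))
})

test_that("cohort-level assembly logs exclusions", {
  params <- default_generative_params(n_boys = c(4L, 4L), n_girls = c(4L, 4L),
                                      fracture_rate = 0.5,
                                      technical_error_rate = 0)
  kids <- generate_cohorts(params, seed = 10)
  bones <- generate_bone_geometry(kids, params, seed = 11)
  meas <- dplyr::transmute(bones, child_id, arm, bone_index,
                           bmc = bmc_true, periosteal, medullary,
                           quality = "ok")
  panels <- assemble_panels(meas, kids)
  expect_equal(nrow(panels), nrow(kids))
  expect_equal(sum(panels$one_arm), sum(kids$fracture_last_year))
  summ <- attr(panels, "exclusion_summary")
  expect_equal(summ$n_children_used, nrow(kids))
  expect_equal(summ$n_one_arm, sum(kids$fracture_last_year))
})
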