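#' Estimate the soft-tissue baseline of a scan trace
#'
#' The water cuff equalizes the soft-tissue path length, so off-bone steps
#' share a common baseline. The estimate is the mean of the outermost `k`
#' steps on each flank. If the flank regions are not flat --- i.e. the scan
#' window is so narrow that bone support reaches the flanks --- estimation
#' aborts.
#'
#' @param trace an `spa_trace`.
#' @param k steps per flank (default 5; the trace must have at least `2k + 1`
#'   points).
#' @return baseline estimate, mg/cm2.
#' @export
estimate_baseline <- function(trace, k = 5) {
  y <- trace$signal
  if (length(y) < 2 * k + 1) stop("trace too short for ", k, " flank steps per side")
  flank <- c(head(y, k), tail(y, k))
  est <- mean(flank)
  peak <- max(y) - est
  if (peak > 0 && (max(flank) - min(flank)) > 0.2 * peak) {
    stop("scan window too narrow: flank region overlaps bone support")
  }
  est
}

# parabolic vertex through (x0 +/- h) given three ordinates; falls back to the
# grid point when the curvature vanishes
refine_vertex <- function(x0, h, y_m, y_0, y_p) {
  denom <- y_m - 2 * y_0 + y_p
  if (!is.finite(denom) || abs(denom) < 1e-12) return(x0)
  x0 + h * (y_m - y_p) / (2 * denom)
}

# linear interpolation of the position where `net` crosses `tau` between
# indices j (>= tau) and j2 (< tau)
interp_crossing <- function(x, net, j, j2, tau) {
  if (net[j] == net[j2]) return(x[j])
  x[j] + (x[j2] - x[j]) * (net[j] - tau) / (net[j] - net[j2])
}

#' Detect bone edges in a scan trace
#'
#' Subtracts the baseline, segments the supra-threshold signal into bone
#' regions, and for each bone estimates:
#' \itemize{
#' \item outer (periosteal) edges: the outermost crossings of
#'   `f_out` x per-bone peak height, refined by linear interpolation between
#'   grid steps; the periosteal diameter is their distance;
#' \item inner (medullary) edges: under the chord model the profile of a
#'   cortical annulus peaks exactly above the medullary wall on each side of
#'   the central dip, so the medullary diameter is the separation of the two
#'   cortical peaks (parabolic sub-step refinement). A cavity is only scored
#'   when the central dip descends at least `min_dip_prominence` x peak below
#'   the lower cortical peak; otherwise the bone is treated as solid
#'   (medullary diameter 0).
#' }
#'
#' @param trace an `spa_trace`.
#' @param baseline baseline in mg/cm2; estimated with [estimate_baseline()]
#'   when `NULL`.
#' @param f_out outer-edge threshold as a fraction of the bone's peak height.
#' @param min_dip_prominence minimum central-dip depth, as a fraction of the
#'   peak, for a medullary cavity to be scored.
#' @param expected_bones number of bones the scan should cross (2 for a
#'   forearm). Any other count marks the scan as a technical error.
#' @return A tibble with one row per detected bone: `bone`, `outer_left`,
#'   `inner_left`, `inner_right`, `outer_right` (mm), `periosteal`,
#'   `medullary` (mm), `peak` (mg/cm2), `quality` (`"ok"` or
#'   `"technical_error"`). When segmentation does not find `expected_bones`
#'   regions every row is flagged `"technical_error"`.
#' @export
detect_edges <- function(trace, baseline = NULL, f_out = 0.1,
                         min_dip_prominence = 0.05, expected_bones = 2) {
  if (is.null(baseline)) baseline <- estimate_baseline(trace)
  x <- trace$position
  net <- trace$signal - baseline
  step <- x[2] - x[1]

  gmax <- max(net)
  if (gmax <= 0) {
    return(empty_edges("technical_error"))
  }
  above <- net > 0.05 * gmax
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 3L
  regions <- cbind(starts[keep], ends[keep])
  quality <- if (nrow(regions) == expected_bones) "ok" else "technical_error"
  if (nrow(regions) == 0L) return(empty_edges("technical_error"))

  rows <- lapply(seq_len(nrow(regions)), function(b) {
    i1 <- regions[b, 1]; i2 <- regions[b, 2]
    seg <- net[i1:i2]
    pk_rel <- which.max(seg)
    pk_idx <- i1 + pk_rel - 1L
    peak <- net[pk_idx]
    tau <- f_out * peak

    j <- pk_idx
    while (j > 1L && net[j - 1L] >= tau) j <- j - 1L
    outer_left <- if (j > 1L) interp_crossing(x, net, j, j - 1L, tau) else x[1]
    j <- pk_idx
    n <- length(net)
    while (j < n && net[j + 1L] >= tau) j <- j + 1L
    outer_right <- if (j < n) interp_crossing(x, net, j, j + 1L, tau) else x[n]

    # local maxima within the region (interior points of the segment)
    loc <- which(diff(sign(diff(seg))) < 0) + 1L
    inner <- c(NA_real_, NA_real_)
    medullary <- 0
    if (length(loc) >= 2L) {
      heights <- seg[loc]
      top2 <- loc[order(heights, decreasing = TRUE)[1:2]]
      lft <- min(top2); rgt <- max(top2)
      if (rgt - lft >= 2L) {
        dip <- min(seg[lft:rgt])
        prom <- (min(seg[lft], seg[rgt]) - dip) / peak
        if (prom >= min_dip_prominence) {
          il <- i1 + lft - 1L; ir <- i1 + rgt - 1L
          xl <- refine_vertex(x[il], step, net[il - 1L], net[il], net[il + 1L])
          xr <- refine_vertex(x[ir], step, net[ir - 1L], net[ir], net[ir + 1L])
          inner <- c(xl, xr)
          medullary <- xr - xl
        }
      }
    }
    tibble::tibble(bone = b,
                   outer_left = outer_left, inner_left = inner[1],
                   inner_right = inner[2], outer_right = outer_right,
                   periosteal = outer_right - outer_left,
                   medullary = medullary, peak = peak, quality = quality)
  })
  dplyr::bind_rows(rows)
}

empty_edges <- function(quality) {
  tibble::tibble(bone = integer(), outer_left = numeric(),
                 inner_left = numeric(), inner_right = numeric(),
                 outer_right = numeric(), periosteal = numeric(),
                 medullary = numeric(), peak = numeric(),
                 quality = character())[0, ] |>
    (\(d) {attr(d, "quality") <- quality; d})()
}

#' Integrate linear mineral content over a bone's support
#'
#' The trace integral over one bone is proportional to the amount of mineral
#' along the scanned axis: BMC (mg/cm) is the trapezoidal integral of
#' `(signal - baseline) / gain` across the bone's support, with positions
#' converted from mm to cm.
#'
#' @param trace an `spa_trace`.
#' @param baseline baseline, mg/cm2.
#' @param support numeric length 2: left and right position bounds (mm).
#' @param gain instrument gain; defaults to the trace's recorded gain.
#' @param pad extra margin (mm) added to both sides of the support to capture
#'   the thresholded-away edge tails. Default 2 steps.
#' @return BMC in mg/cm (floored at 0 with a warning if noise drives the
#'   integral negative).
#' @export
integrate_bmc <- function(trace, baseline, support, gain = attr(trace, "gain"),
                          pad = NULL) {
  if (is.null(gain)) gain <- 1
  x <- trace$position
  step <- x[2] - x[1]
  if (is.null(pad)) pad <- 2 * step
  lo <- max(min(x), support[1] - pad)
  hi <- min(max(x), support[2] + pad)
  if (lo >= hi) stop("bone support outside trace range")
  idx <- which(x >= lo - 1e-9 & x <= hi + 1e-9)
  val <- pracma::trapz(x[idx] / 10, (trace$signal[idx] - baseline) / gain)
  if (val < 0) {
    warning("negative integral floored at 0 (noise-dominated bone support)")
    val <- 0
  }
  val
}

#' Analyze one scan trace into per-bone measurements
#'
#' Runs baseline estimation, edge detection and BMC integration, returning
#' one row per bone. A scan in which segmentation does not find the expected
#' two bones is flagged as a technical error (and excluded downstream).
#'
#' @inheritParams detect_edges
#' @param ... passed to [detect_edges()].
#' @return A tibble with columns `bone`, `bmc` (mg/cm), `periosteal`,
#'   `medullary` (mm), `quality`.
#' @export
analyze_trace <- function(trace, baseline = NULL, ...) {
  if (is.null(baseline)) baseline <- estimate_baseline(trace)
  edges <- detect_edges(trace, baseline = baseline, ...)
  if (nrow(edges) == 0L || any(edges$quality != "ok")) {
    return(tibble::tibble(bone = NA_integer_, bmc = NA_real_,
                          periosteal = NA_real_, medullary = NA_real_,
                          quality = "technical_error"))
  }
  edges$bmc <- vapply(seq_len(nrow(edges)), function(i) {
    integrate_bmc(trace, baseline,
                  c(edges$outer_left[i], edges$outer_right[i]))
  }, numeric(1))
  dplyr::select(edges, "bone", "bmc", "periosteal", "medullary", "quality")
}

#' Assemble one child's trait panel from per-bone measurements
#'
#' Applies the exclusion rules --- drop bones flagged as technical errors;
#' for a child with an upper-extremity fracture in the preceding year use
#' only the uninjured arm --- then averages BMC and both diameters over the
#' remaining bones (four normally, two when one arm is excluded) and derives
#' the remaining traits from the averaged primitives via [derive_traits()].
#'
#' @param measurements tibble with one row per bone: `arm`, `bone_index`,
#'   `bmc`, `periosteal`, `medullary`, `quality`.
#' @param record one-row tibble (or list) for the child with at least
#'   `fracture_last_year` and `injured_arm`.
#' @return A one-row trait-panel tibble (`n_bones`, `one_arm`, `bmc`,
#'   `periosteal_diameter`, `medullary_diameter`, plus all derived traits),
#'   or a zero-row tibble when no usable bone remains.
#' @export
assemble_child_panel <- function(measurements, record) {
  m <- dplyr::filter(measurements, .data$quality == "ok")
  if (isTRUE(record$fracture_last_year) && !is.na(record$injured_arm)) {
    m <- dplyr::filter(m, .data$arm != record$injured_arm)
  }
  if (nrow(m) == 0L) {
    return(derive_traits(tibble::tibble(bmc = numeric(),
                                        periosteal_diameter = numeric(),
                                        medullary_diameter = numeric())) |>
             dplyr::mutate(n_bones = integer(), one_arm = logical(),
                           .before = 1))
  }
  prim <- tibble::tibble(
    bmc = mean(m$bmc),
    periosteal_diameter = mean(m$periosteal),
    medullary_diameter = mean(m$medullary)
  )
  out <- derive_traits(prim)
  dplyr::mutate(out,
                n_bones = nrow(m),
                one_arm = dplyr::n_distinct(m$arm) < 2L,
                .before = 1)
}

#' Assemble trait panels for a whole cohort
#'
#' Vectorized wrapper over [assemble_child_panel()]: joins per-bone
#' measurements to the cohort table, applies the exclusion rules per child,
#' and returns one panel row per usable child. Children whose every scan
#' failed are dropped, and an exclusion log is attached as attribute
#' `"exclusions"` (a tibble with `child_id` and `reason`) together with
#' counts in attribute `"exclusion_summary"`.
#'
#' @param measurements tibble with one row per bone: `child_id`, `arm`,
#'   `bone_index`, `bmc`, `periosteal`, `medullary`, `quality`.
#' @param children cohort tibble from [generate_cohorts()] (or a table with
#'   `child_id`, `fracture_last_year`, `injured_arm`).
#' @return tibble with one row per retained child: identifiers and covariates
#'   from `children` plus the measured/derived trait panel.
#' @export
assemble_panels <- function(measurements, children) {
  panels <- dplyr::group_split(measurements, measurements$child_id)
  ids <- vapply(panels, function(d) d$child_id[1], character(1))
  recs <- children[match(ids, children$child_id), ]
  rows <- purrr::map2(panels, seq_along(panels), function(d, i) {
    p <- assemble_child_panel(d, recs[i, ])
    if (nrow(p)) p$child_id <- ids[i]
    p
  })
  out <- dplyr::bind_rows(rows)
  dropped <- setdiff(children$child_id, c(out$child_id))
  exclusions <- tibble::tibble(child_id = dropped,
                               reason = "no usable bone measurements")
  covars <- dplyr::select(children, -dplyr::any_of(setdiff(
    names(out), c("child_id"))))
  res <- dplyr::left_join(covars, out, by = "child_id")
  res <- dplyr::filter(res, !is.na(.data$bmc))
  attr(res, "exclusions") <- exclusions
  attr(res, "exclusion_summary") <- tibble::tibble(
    n_children_in = nrow(children),
    n_children_used = nrow(res),
    n_children_dropped = length(dropped),
    n_one_arm = sum(res$one_arm)
  )
  res
}
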