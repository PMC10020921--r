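#' Estimate phantom-based drift correction constants
#'
#' The early measurement era is split at the radiation-source replacement.
#' Each constant is the mean phantom readout of the modern era divided by the
#' mean of the corresponding early-era segment; early-era study values are
#' later multiplied by the applicable constant to put both cohorts on the
#' modern calibration.
#'
#' @param reference phantom tibble (`date`, `bmd`) spanning the early era.
#' @param comparison phantom tibble for the modern era.
#' @param change_date ordinal day the source was replaced; splits `reference`
#'   into pre- and post-change segments.
#' @return an object of class `correction_constants`: a one-row tibble with
#'   columns `pre_change` and `post_change`.
#' @export
estimate_correction_constants <- function(reference, comparison, change_date) {
  pre <- reference$bmd[reference$date < change_date]
  post <- reference$bmd[reference$date >= change_date]
  if (length(pre) == 0L || length(post) == 0L || nrow(comparison) == 0L) {
    stop("each phantom segment must be non-empty")
  }
  out <- tibble::tibble(pre_change = mean(comparison$bmd) / mean(pre),
                        post_change = mean(comparison$bmd) / mean(post))
  if (any(unlist(out) <= 0)) stop("correction constants must be positive")
  class(out) <- c("correction_constants", class(out))
  out
}

#' Apply (or undo) drift correction to early-era trait panels
#'
#' Multiplies the mineral-derived quantities --- BMC and therefore BMD, BMAD
#' and the strength index --- by the applicable constant; bone widths and the
#' purely geometric traits are left untouched (the correction is derived from
#' mineral-readout phantoms).
#'
#' @param panel trait-panel tibble (any subset of the mineral columns may be
#'   present).
#' @param constants a `correction_constants` object (or list with
#'   `pre_change`/`post_change`).
#' @param before_change logical, length 1 or `nrow(panel)`: was the scan made
#'   before the source replacement?
#' @param invert undo a previously applied correction.
#' @return the panel with corrected mineral columns.
#' @export
apply_correction <- function(panel, constants, before_change, invert = FALSE) {
  if (any(c(constants$pre_change, constants$post_change) <= 0)) {
    stop("correction constants must be positive")
  }
  k <- ifelse(rep_len(before_change, nrow(panel)),
              constants$pre_change, constants$post_change)
  if (invert) k <- 1 / k
  cols <- intersect(c("bmc", "bmd", "bmad", "strength_index"), names(panel))
  for (cl in cols) panel[[cl]] <- panel[[cl]] * k
  panel
}

#' Root-mean-square precision coefficient of variation
#'
#' Standard densitometry QA summary of short-term precision from repeated
#' measurements after repositioning:
#' `CV = sqrt(mean_subjects((SD_subject / mean_subject)^2)) * 100`.
#'
#' @param data data frame of replicate measurements.
#' @param subject,value columns (tidy-eval) identifying the subject and the
#'   measured value.
#' @return RMS CV in percent.
#' @export
#' @examples
#' precision_cv(data.frame(id = 1, y = c(95, 100, 105)), id, y)
precision_cv <- function(data, subject, value) {
  per <- dplyr::summarise(
    dplyr::group_by(data, {{ subject }}),
    m = mean({{ value }}), s = stats::sd({{ value }}), k = dplyr::n(),
    .groups = "drop"
  )
  if (any(per$k < 2L)) stop("each subject needs >= 2 replicates")
  if (any(per$m <= 0)) stop("subject means must be positive")
  sqrt(mean((per$s / per$m)^2)) * 100
}
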