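#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a logistic labeling fit
#'
#' One row per parameter (`k`, `y0`, `T`, `T50`) with estimates.
#'
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k", "y0", "T", "T50"),
    estimate = c(x$k, x$y0, x$T, x$t50)
  )
}

#' One-row summary of a logistic labeling fit
#'
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, y0 = x$y0, T = x$T, t50 = x$t50, rss = x$rss,
    n = nrow(x$data), converged = x$converged, degenerate = x$degenerate
  )
}

#' Tidy a calibration curve
#'
#' One row per calibration level with back-calculation bias, RSD and the
#' +/-20% acceptance flag (after [validate_curve()]), or the raw points.
#'
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @export
tidy.calibration_curve <- function(x, ...) {
  if (!is.null(x$level_summary)) x$level_summary else x$points
}

#' One-row summary of a calibration curve
#'
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(
    compound = x$compound, slope = x$slope, intercept = x$intercept,
    r_squared = x$r_squared, lod_pmol = x$lod_pmol, loq_pmol = x$loq_pmol,
    linear_low = x$linear_range[1], linear_high = x$linear_range[2]
  )
}
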