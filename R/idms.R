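# Isotope dilution mass spectrometry: the 12C analyte is quantified against
# a co-analyzed fully 13C-labeled internal standard via the 12C/13C area
# ratio and an external calibration curve. Validation follows the +/-20%
# accuracy/precision rule for LOQ and linear range, and LOD = 3 sigma/slope.

#' Fit an IDMS calibration curve
#'
#' Least squares of the 12C/13C area ratio against the amount injected on
#' column, over the positive calibration levels (optionally restricted to
#' an accepted linear range). The default 1/x weighting keeps the top
#' levels of a range spanning three orders of magnitude from leaking their
#' absolute noise into the intercept and low-end accuracy; unweighted OLS
#' is available.
#'
#' @param df Tibble with columns `level_pmol` and `ratio` (and optionally
#'   `compound`, `replicate`); blank rows (`level_pmol == 0`) are kept
#'   aside for LOD estimation but excluded from the fit.
#' @param range Optional `c(low, high)` pmol window to fit within.
#' @param weighting `"1/x"` (default) or `"none"`.
#' @return A `calibration_curve` object: `slope`, `intercept`, `r_squared`,
#'   `points`, `blanks`, and (after [validate_curve()]) `lod_pmol`,
#'   `loq_pmol`, `linear_range`.
#' @export
fit_calibration <- function(df, range = NULL, weighting = c("1/x", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("level_pmol", "ratio") %in% names(df)))
  blanks <- dplyr::filter(df, .data$level_pmol == 0)
  pts <- dplyr::filter(df, .data$level_pmol > 0)
  if (!is.null(range)) {
    pts <- dplyr::filter(pts, .data$level_pmol >= range[1],
                         .data$level_pmol <= range[2])
  }
  amounts <- unique(pts$level_pmol)
  if (length(amounts) < 2) stop("need at least 2 distinct positive amounts")
  if (length(amounts) < 5) stop("need at least 5 calibration levels")
  if (stats::sd(pts$ratio) == 0) stop("zero-variance ratios")
  w <- if (weighting == "1/x") 1 / pts$level_pmol else rep(1, nrow(pts))
  fit <- stats::lm(ratio ~ level_pmol, data = pts, weights = w)
  structure(
    list(
      compound = if ("compound" %in% names(pts)) pts$compound[1] else NA_character_,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = suppressWarnings(summary(fit)$r.squared),
      weighting = weighting,
      points = pts,
      blanks = blanks,
      lod_pmol = NA_real_,
      loq_pmol = NA_real_,
      linear_range = c(NA_real_, NA_real_)
    ),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: ratio = %.4g + %.4g * pmol, R^2 = %.4f\n",
              x$compound %||% "?", x$intercept, x$slope, x$r_squared))
  if (!is.na(x$loq_pmol) || !is.na(x$linear_range[1])) {
    cat(sprintf("  LOD %.3g pmol, LOQ %.3g pmol, linear range %.3g-%.3g pmol\n",
                x$lod_pmol, x$loq_pmol, x$linear_range[1], x$linear_range[2]))
  }
  invisible(x)
}

back_calculate <- function(curve, ratio) (ratio - curve$intercept) / curve$slope

ols_over_range <- function(points, range, weighting) {
  pts <- dplyr::filter(points, .data$level_pmol >= range[1],
                       .data$level_pmol <= range[2])
  w <- if (weighting == "1/x") 1 / pts$level_pmol else rep(1, nrow(pts))
  fit <- stats::lm(ratio ~ level_pmol, data = pts, weights = w)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit)$r.squared))
}

# per-level back-calculation diagnostics against a given line
level_diagnostics <- function(points, line, threshold) {
  points |>
    dplyr::mutate(back = (.data$ratio - line$intercept) / line$slope) |>
    dplyr::group_by(.data$level_pmol) |>
    dplyr::summarise(
      mean_back = mean(.data$back),
      rsd = stats::sd(.data$back) / abs(mean(.data$back)),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      bias = (.data$mean_back - .data$level_pmol) / .data$level_pmol,
      accepted = abs(.data$bias) <= threshold &
        (is.na(.data$rsd) | .data$rsd <= threshold)
    ) |>
    dplyr::arrange(.data$level_pmol)
}

#' Validate a calibration curve: LOD, LOQ and linear range
#'
#' Applies the +/-20% rule: a calibration level is acceptable when the mean
#' back-calculated amount is within `accuracy_threshold` of the nominal
#' amount (bias) and its replicate RSD is at most the same threshold. The
#' linear range is the maximal contiguous span of levels that all pass the
#' rule against the line fitted over that same span (searched widest
#' first, preferring the span reaching lower amounts on ties), so a
#' saturated top level can neither join the range nor drag the working
#' curve. LOQ is the lowest accepted level. LOD is 3 sigma / slope with
#' sigma from blank replicates when present, else from the lowest level's
#' replicates.
#'
#' @param curve A `calibration_curve` with replicate ratios per level.
#' @param accuracy_threshold Bias/RSD threshold (default 0.20).
#' @return The curve with `lod_pmol`, `loq_pmol`, `linear_range` filled,
#'   the line refitted over the linear range, and a `level_summary` tibble
#'   (per-level bias, RSD, acceptance against the final line). When no
#'   span passes, `loq_pmol` and `linear_range` are NA.
#' @export
validate_curve <- function(curve, accuracy_threshold = 0.20) {
  stopifnot(inherits(curve, "calibration_curve"))
  levels <- sort(unique(curve$points$level_pmol))
  nl <- length(levels)

  best <- NULL
  for (width in nl:2) {
    for (start in 1:(nl - width + 1)) {
      span <- c(levels[start], levels[start + width - 1])
      line <- ols_over_range(curve$points, span, curve$weighting)
      lv <- level_diagnostics(
        dplyr::filter(curve$points, .data$level_pmol >= span[1],
                      .data$level_pmol <= span[2]),
        line, accuracy_threshold
      )
      if (all(lv$accepted)) {
        # ties at equal level count: prefer the span covering more orders
        # of magnitude
        if (is.null(best) ||
            span[2] / span[1] > best$span[2] / best$span[1]) {
          best <- list(span = span, line = line)
        }
      }
    }
    if (!is.null(best)) break
  }

  sigma <- if (nrow(curve$blanks) >= 2) {
    stats::sd(curve$blanks$ratio)
  } else {
    low <- min(curve$points$level_pmol)
    stats::sd(curve$points$ratio[curve$points$level_pmol == low])
  }

  if (is.null(best)) {
    curve$loq_pmol <- NA_real_
    curve$linear_range <- c(NA_real_, NA_real_)
  } else {
    curve$linear_range <- best$span
    curve$loq_pmol <- best$span[1]
    curve$slope <- best$line$slope
    curve$intercept <- best$line$intercept
    curve$r_squared <- best$line$r_squared
  }
  curve$lod_pmol <- if (is.na(sigma)) NA_real_ else 3 * sigma / curve$slope
  curve$level_summary <- level_diagnostics(curve$points,
                                           curve[c("slope", "intercept")],
                                           accuracy_threshold)
  curve
}

#' Absolute quantification of samples by IDMS
#'
#' Inverts the calibration line to the amount on column, scales by the
#' resuspension/injection volume ratio and divides by the sample biomass to
#' give intracellular concentration in nmol/gDCW. Replicates are aggregated
#' to mean +/- SD per compound (and strain if present). Ratios falling
#' outside the curve's validated linear range are flagged, not dropped.
#'
#' @param df Tibble with columns `compound` (or `metabolite`), `ratio`,
#'   `biomass_gdcw`, and optionally `strain`, `replicate`.
#' @param curves A single `calibration_curve` or a named list per compound.
#' @param volumes See [default_volumes()].
#' @param aggregate Return per-group mean/SD (default) or per-replicate rows.
#' @return Tibble with `compound`, `concentration` (nmol/gDCW), `sd`,
#'   `n_replicates`, `out_of_range` (any replicate outside linear range).
#' @export
quantify <- function(df, curves, volumes = default_volumes(),
                     aggregate = TRUE) {
  if ("metabolite" %in% names(df) && !"compound" %in% names(df)) {
    df <- dplyr::rename(df, compound = "metabolite")
  }
  stopifnot(all(c("compound", "ratio", "biomass_gdcw") %in% names(df)),
            all(df$ratio >= 0), all(df$biomass_gdcw > 0))
  get_curve <- function(cmp) {
    if (inherits(curves, "calibration_curve")) return(curves)
    cv <- curves[[cmp]]
    if (is.null(cv)) stop("no calibration curve for ", cmp)
    cv
  }
  per_rep <- df |>
    dplyr::mutate(
      amount_pmol = purrr::map2_dbl(.data$compound, .data$ratio,
                                    function(cmp, r) back_calculate(get_curve(cmp), r)),
      concentration = .data$amount_pmol *
        (volumes$resuspension_ul / volumes$injection_ul) / 1000 /
        .data$biomass_gdcw,
      out_of_range = purrr::map2_lgl(.data$compound, .data$amount_pmol,
        function(cmp, a) {
          rng <- get_curve(cmp)$linear_range
          !is.na(rng[1]) && (a < rng[1] || a > rng[2])
        })
    )
  if (!aggregate) return(per_rep)
  keys <- intersect(c("strain", "compound"), names(per_rep))
  per_rep |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      sd = stats::sd(.data$concentration),
      concentration = mean(.data$concentration),
      n_replicates = dplyr::n(),
      out_of_range = any(.data$out_of_range),
      .groups = "drop"
    ) |>
    dplyr::relocate("concentration", .before = "sd")
}
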