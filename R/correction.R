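# Correction of measured mass fractions for naturally occurring isotopes and
# tracer purity. High-resolution regime: at R = 70,000 with a 5 ppm
# extraction window, non-carbon isotope peaks (18O, 2H; the compounds carry
# no N or S) are resolved away from the 13C isotopologues, so only carbon
# natural abundance and tracer purity need correcting.

#' Build a carbon isotopologue correction model
#'
#' Constructs the lower-triangular operator mapping the "nominal" (corrected)
#' distribution to the observed one. Column j (the nominal species with j
#' tracer-derived labels) is the convolution of `binomial(j, purity)` over
#' the j tracer positions with `binomial(n - j, abundance)` over the n - j
#' non-tracer carbons. Every column sums to 1, so correction conserves total
#' signal. `correct_spectrum()` inverts this model.
#'
#' @param n Carbon count.
#' @param abundance Natural 13C abundance (default 0.0107).
#' @param purity Isotopic purity of the tracer (default 0.99).
#' @return A `correction_model` object with the (n+1) x (n+1) `matrix`.
#' @export
build_correction_model <- function(n, abundance = 0.0107, purity = 0.99) {
  stopifnot(n >= 0, abundance > 0, abundance < 1, purity > 0, purity <= 1)
  A <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    col <- convolve_distributions(
      binomial_distribution(j, purity),
      binomial_distribution(n - j, abundance)
    )
    A[, j + 1L] <- col
  }
  structure(
    list(n = as.integer(n), abundance = abundance, purity = purity, matrix = A),
    class = "correction_model"
  )
}

#' @export
print.correction_model <- function(x, ...) {
  cat("<correction_model> n =", x$n, " abundance =", x$abundance,
      " purity =", x$purity, "\n")
  invisible(x)
}

#' Correct a measured spectrum to an isotopologue distribution
#'
#' Solves `observed = matrix %*% true` for the nominal isotopologue
#' distribution by non-negative least squares and renormalizes to unit sum.
#' A large relative residual (mass fractions inconsistent with the model,
#' e.g. an interfering peak) triggers a warning, not a failure.
#'
#' @param raw Measured intensity vector of length n+1 (any scale).
#' @param model A `correction_model` for the same carbon count.
#' @param residual_warn Relative residual (`||Ax - b|| / ||b||`) above which
#'   a warning is issued.
#' @return Numeric distribution M0..Mn with attribute `"residual"`.
#' @export
correct_spectrum <- function(raw, model, residual_warn = 0.05) {
  stopifnot(inherits(model, "correction_model"))
  if (length(raw) != model$n + 1L) {
    stop("raw spectrum has length ", length(raw), ", expected ", model$n + 1L)
  }
  if (any(!is.finite(raw)) || any(raw < 0)) stop("raw intensities must be finite and >= 0")
  if (sum(raw) == 0) stop("all-zero spectrum cannot be corrected")
  b <- raw / sum(raw)
  fit <- pracma::lsqnonneg(model$matrix, b)
  x <- fit$x
  resid <- sqrt(sum((model$matrix %*% x - b)^2)) / sqrt(sum(b^2))
  if (resid > residual_warn) {
    warning(sprintf("correction residual %.3g exceeds %.3g", resid, residual_warn))
  }
  if (sum(x) == 0) stop("degenerate correction (zero solution)")
  out <- x / sum(x)
  attr(out, "residual") <- resid
  out
}

#' Correct a table of measured mass fractions
#'
#' Data-frame front end to [correct_spectrum()]: groups rows by sample keys,
#' corrects each (n+1)-row spectrum, and appends the corrected fractions and
#' the per-spectrum mean 13C enrichment.
#'
#' @param df Tibble with at least `metabolite`, `m_index` (0..n) and an
#'   intensity column; any other columns (`strain`, `replicate`, `time_min`,
#'   ...) are treated as grouping keys.
#' @param pathway A `pathway_spec` supplying carbon counts per metabolite
#'   (or pool) name.
#' @param abundance,purity Passed to [build_correction_model()].
#' @param intensity Name of the intensity column.
#' @return The input grouped keys with `m_index`, `fraction_corrected` and
#'   `mean_enrichment` (repeated within a spectrum), one row per
#'   isotopologue.
#' @export
correct_measurements <- function(df, pathway = read_pathway(),
                                 abundance = 0.0107, purity = 0.99,
                                 intensity = "intensity") {
  stopifnot(all(c("metabolite", "m_index", intensity) %in% names(df)))
  carbons <- lookup_carbons(pathway, unique(df$metabolite))
  models <- lapply(unique(carbons), build_correction_model,
                   abundance = abundance, purity = purity)
  names(models) <- as.character(unique(carbons))

  keys <- setdiff(names(df), c("m_index", intensity, "fraction_corrected",
                               "mean_enrichment"))
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(g, key) {
      n <- carbons[[as.character(key$metabolite)]]
      g <- dplyr::arrange(g, .data$m_index)
      if (!identical(as.integer(g$m_index), 0:n)) {
        stop("metabolite ", key$metabolite,
             ": expected isotopologue indices 0..", n)
      }
      M <- correct_spectrum(g[[intensity]], models[[as.character(n)]])
      g$fraction_corrected <- as.numeric(M)
      g$mean_enrichment <- mean_enrichment(as.numeric(M))
      g
    }) |>
    dplyr::ungroup()
}

# carbon counts for measurement names that may be compound or pool labels
lookup_carbons <- function(pathway, names) {
  met <- pathway$metabolites
  pl <- pathway$pools
  out <- stats::setNames(integer(length(names)), names)
  for (nm in names) {
    i <- match(nm, met$name)
    j <- match(nm, pl$pool)
    if (!is.na(i)) out[nm] <- met$n_carbons[i]
    else if (!is.na(j)) out[nm] <- pl$n_carbons[j]
    else stop("unknown metabolite: ", nm)
  }
  out
}
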