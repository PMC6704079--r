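# Strain comparisons: Welch's t test from replicate summaries and
# turnover-based relative flux inference. The labeling dynamics of a pool
# reflect its turnover (flux / pool size); when turnover is unchanged
# between strains, the flux ratio equals the pool-size ratio.

#' Welch's two-sided t test from group summaries
#'
#' Standard Welch statistic with Satterthwaite fractional degrees of
#' freedom, computed from (mean, sd, n) summaries as reported for
#' biological replicates.
#'
#' @param mean_a,sd_a,n_a Summary of group A.
#' @param mean_b,sd_b,n_b Summary of group B.
#' @return Tibble with `t`, `df`, `p_value`.
#' @examples
#' welch_test(1.4, 0.1, 3, 12.8, 2.0, 3) # p ~ 0.010
#' @export
welch_test <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0)
  if (sd_a == 0 && sd_b == 0) stop("both groups have zero variance")
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  t <- (mean_a - mean_b) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  p <- 2 * stats::pt(-abs(t), df = df)
  tibble::tibble(t = t, df = df, p_value = p)
}

#' Relative flux between strains under constant turnover
#'
#' In the constant-turnover mode (default) the biosynthetic flux ratio
#' between strains equals the ratio of their pool sizes; the SD is
#' propagated to first order (delta method) assuming independent groups:
#' \deqn{sd = \frac{m_a}{m_b}\sqrt{(s_a/m_a)^2 + (s_b/m_b)^2}.}
#' When half-times are supplied, the turnover-adjusted ratio
#' `(m_a/T50_a) / (m_b/T50_b)` is used instead (T50s enter as point values).
#' A bootstrap SD over normal resamples of the group means is available as
#' a cross-check on the delta method.
#'
#' @param mean_a,sd_a,n_a Pool summary, strain A (numerator).
#' @param mean_b,sd_b,n_b Pool summary, strain B (denominator).
#' @param t50_a,t50_b Optional half-times (minutes) for turnover adjustment.
#' @param boot Number of bootstrap draws for the alternative SD (0 = skip).
#' @param seed Seed for the bootstrap.
#' @return Tibble with `ratio`, `sd`, and `sd_boot` when requested.
#' @examples
#' flux_ratio(12.8, 2.0, 3, 1.4, 0.1, 3) # ratio ~ 9.1
#' @export
flux_ratio <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                       t50_a = NULL, t50_b = NULL, boot = 0, seed = 1L) {
  stopifnot(mean_a > 0, mean_b > 0, sd_a >= 0, sd_b >= 0)
  adj <- !is.null(t50_a) && !is.null(t50_b)
  if (adj) stopifnot(t50_a > 0, t50_b > 0)
  ratio <- if (adj) (mean_a / t50_a) / (mean_b / t50_b) else mean_a / mean_b
  sd_delta <- ratio * sqrt((sd_a / mean_a)^2 + (sd_b / mean_b)^2)
  out <- tibble::tibble(ratio = ratio, sd = sd_delta)
  if (boot > 0) {
    set.seed(seed)
    a <- stats::rnorm(boot, mean_a, sd_a / sqrt(n_a))
    b <- stats::rnorm(boot, mean_b, sd_b / sqrt(n_b))
    keep <- a > 0 & b > 0
    r <- if (adj) (a / t50_a) / (b / t50_b) else a / b
    out$sd_boot <- stats::sd(r[keep])
  }
  out
}

#' Compare pool sizes between two strains
#'
#' Joins two quantification tables (output of [quantify()]) by compound and
#' reports Welch statistics and the constant-turnover flux ratio per
#' compound. No multiple-testing adjustment is applied; raw per-compound
#' p-values are reported.
#'
#' @param quant_a,quant_b Tibbles with `compound`, `concentration`, `sd`,
#'   `n_replicates` (strain A = numerator of the ratio).
#' @return Tibble with per-compound `t`, `df`, `p_value`, `flux_ratio`,
#'   `flux_ratio_sd`.
#' @export
compare_strains <- function(quant_a, quant_b) {
  need <- c("compound", "concentration", "sd", "n_replicates")
  stopifnot(all(need %in% names(quant_a)), all(need %in% names(quant_b)))
  joined <- dplyr::inner_join(quant_a, quant_b, by = "compound",
                              suffix = c("_a", "_b"))
  purrr::pmap_dfr(joined, function(compound, concentration_a, sd_a,
                                   n_replicates_a, concentration_b, sd_b,
                                   n_replicates_b, ...) {
    w <- welch_test(concentration_a, sd_a, n_replicates_a,
                    concentration_b, sd_b, n_replicates_b)
    fr <- flux_ratio(concentration_a, sd_a, n_replicates_a,
                     concentration_b, sd_b, n_replicates_b)
    tibble::tibble(compound = compound,
                   mean_a = concentration_a, sd_a = sd_a,
                   mean_b = concentration_b, sd_b = sd_b,
                   t = w$t, df = w$df, p_value = w$p_value,
                   flux_ratio = fr$ratio, flux_ratio_sd = fr$sd)
  })
}

#' Compare labeling dynamics (T50) between strains
#'
#' Welch test on replicate-level half-times per metabolite; used to ask
#' whether label-incorporation dynamics differ between strains despite
#' pool-size changes (they do not when flux scales with the pools).
#'
#' @param fits_a,fits_b Tibbles from [fit_enrichment_kinetics()] run on
#'   replicate-level series: columns `metabolite`, `replicate`, `t50`.
#' @return Tibble with per-metabolite `t50_mean_a`, `t50_mean_b`, `t`,
#'   `df`, `p_value`.
#' @export
compare_labeling_dynamics <- function(fits_a, fits_b) {
  summarize_t50 <- function(df) {
    stopifnot(all(c("metabolite", "t50") %in% names(df)))
    df |>
      dplyr::filter(is.finite(.data$t50)) |>
      dplyr::group_by(.data$metabolite) |>
      dplyr::summarise(mean = mean(.data$t50), sd = stats::sd(.data$t50),
                       n = dplyr::n(), .groups = "drop")
  }
  a <- summarize_t50(fits_a)
  b <- summarize_t50(fits_b)
  joined <- dplyr::inner_join(a, b, by = "metabolite", suffix = c("_a", "_b"))
  if (any(joined$n_a < 2 | joined$n_b < 2)) {
    stop("need >= 2 replicate T50 values per strain and metabolite")
  }
  purrr::pmap_dfr(joined, function(metabolite, mean_a, sd_a, n_a,
                                   mean_b, sd_b, n_b) {
    w <- welch_test(mean_a, sd_a, n_a, mean_b, sd_b, n_b)
    tibble::tibble(metabolite = metabolite,
                   t50_mean_a = mean_a, t50_mean_b = mean_b,
                   t = w$t, df = w$df, p_value = w$p_value)
  })
}
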