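# Labeling kinetics: time-course 13C enrichments are fitted with a logistic
# model and summarized by the half-time T50, the time needed to exchange
# half of a pool's 12C atoms for 13C.

#' Logistic enrichment model
#'
#' \deqn{E(t) = \frac{k\, y_0\, e^{tT}}{k + y_0 e^{tT} - y_0}}
#' with plateau enrichment `k`, initial enrichment `y0` and rate parameter
#' `T` (1/min). Undefined at `y0 = 0`, which is why fits floor the initial
#' value.
#'
#' @param t Time (minutes).
#' @param k,y0,T Model parameters.
#' @export
logistic_enrichment <- function(t, k, y0, T) {
  e <- exp(t * T)
  k * y0 * e / (k + y0 * e - y0)
}

#' Closed-form half-time of the logistic model
#'
#' \deqn{T_{50} = \frac{1}{T}\,\ln\frac{k - y_0}{y_0}}
#' at which the model passes exactly through `k/2`. When `y0 >= k/2` the
#' pool was already half-exchanged at t = 0 and T50 <= 0 is returned with a
#' warning rather than clamped.
#'
#' @param k,y0,T Logistic parameters with `0 < y0 < k` and `T > 0`.
#' @return T50 in minutes.
#' @export
t50_logistic <- function(k, y0, T) {
  stopifnot(y0 > 0, k > y0, T > 0)
  out <- log((k - y0) / y0) / T
  if (out <= 0) warning("T50 <= 0: pool already half-exchanged at t = 0")
  out
}

#' Fit the logistic labeling model to an enrichment time course
#'
#' Least-squares fit of [logistic_enrichment()] with a deterministic
#' initialization: `y0` from the first observation (floored at 1e-4), `k`
#' from the maximum observation (capped at 1), and `T` from the early-phase
#' log-linear slope. Series whose total enrichment change is below
#' `min_change` are flagged degenerate (mirroring the exclusion of pools
#' with low, flat signals) and carry no T50.
#'
#' @param times Time points (minutes), >= 4, strictly increasing.
#' @param enrichment Enrichment values in \[0, 1\].
#' @param weights Optional per-point weights (e.g. 1/SD^2 for replicate
#'   means); default unweighted.
#' @param min_change Enrichment change below which the series is degenerate.
#' @return A `logistic_fit` object with elements `k`, `y0`, `T`, `t50`,
#'   `rss`, `converged`, `degenerate` and the data.
#' @export
fit_logistic <- function(times, enrichment, weights = NULL,
                         min_change = 0.05) {
  stopifnot(length(times) == length(enrichment), length(times) >= 4,
            !is.unsorted(times, strictly = TRUE),
            all(enrichment >= -1e-9), all(enrichment <= 1 + 1e-9))
  E <- pmin(pmax(enrichment, 0), 1)
  if (is.null(weights)) weights <- rep(1, length(E))

  new_fit <- function(k = NA_real_, y0 = NA_real_, T = NA_real_,
                      t50 = NA_real_, rss = NA_real_, converged = FALSE,
                      degenerate = FALSE) {
    structure(list(k = k, y0 = y0, T = T, t50 = t50, rss = rss,
                   converged = converged, degenerate = degenerate,
                   data = tibble::tibble(time_min = times, enrichment = E)),
              class = "logistic_fit")
  }

  if (diff(range(E)) < min_change) {
    return(new_fit(degenerate = TRUE))
  }

  y0_init <- max(E[1], 1e-4)
  k_init <- min(max(E), 1)
  # early phase (below half-plateau): E ~ y0 * exp(t*T), so log E is linear
  early <- which(E < k_init / 2 & E > 0)
  T_init <- if (length(early) >= 2) {
    max(min(unname(stats::coef(stats::lm(log(E[early]) ~ times[early]))[2]),
            10), 1e-3)
  } else 0.1

  fit <- tryCatch(
    minpack.lm::nlsLM(
      E ~ logistic_enrichment(time, k, y0, T),
      data = data.frame(time = times, E = E),
      start = list(k = k_init, y0 = min(y0_init, 0.9 * k_init), T = T_init),
      lower = c(k = 1e-3, y0 = 1e-6, T = 1e-6),
      upper = c(k = 1, y0 = 1, T = 10),
      weights = weights,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(new_fit(converged = FALSE))
  }
  p <- stats::coef(fit)
  if (p[["y0"]] >= p[["k"]]) {
    # plateau not above start: treat as degenerate (no exchange signal)
    return(new_fit(k = p[["k"]], y0 = p[["y0"]], T = p[["T"]],
                   degenerate = TRUE))
  }
  t50 <- t50_logistic(p[["k"]], p[["y0"]], p[["T"]])
  new_fit(k = p[["k"]], y0 = p[["y0"]], T = p[["T"]], t50 = t50,
          rss = sum(weights * stats::residuals(fit)^2), converged = TRUE)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit>")
  if (x$degenerate) {
    cat(" degenerate (flat series, no T50)\n")
  } else if (!x$converged) {
    cat(" NOT converged\n")
  } else {
    cat(sprintf(" k = %.4f, y0 = %.4g, T = %.4f /min, T50 = %.2f min\n",
                x$k, x$y0, x$T, x$t50))
  }
  invisible(x)
}

#' Half-time of a fitted logistic model
#'
#' @param fit A converged `logistic_fit`.
#' @return T50 in minutes (NA for degenerate/unconverged fits).
#' @export
t50 <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  fit$t50
}

#' Fit labeling kinetics for every metabolite/strain series in a table
#'
#' Groups an enrichment table by metabolite (and strain and any other key
#' columns), fits [fit_logistic()] per group, and returns one row per
#' series with the parameters, T50 and fit diagnostics. The fitted objects
#' are kept in a list-column for plotting.
#'
#' @param df Tibble with columns `time_min`, `mean_enrichment` (or
#'   `enrichment`) and key columns such as `metabolite`, `strain`.
#' @param min_change Passed to [fit_logistic()].
#' @return Tibble with key columns, `k`, `y0`, `T`, `t50`, `rss`,
#'   `converged`, `degenerate` and list-column `fit`.
#' @export
fit_enrichment_kinetics <- function(df, min_change = 0.05) {
  ecol <- if ("mean_enrichment" %in% names(df)) "mean_enrichment" else "enrichment"
  stopifnot("time_min" %in% names(df), ecol %in% names(df))
  keys <- intersect(c("strain", "metabolite", "replicate"), names(df))
  if (!"metabolite" %in% keys) stop("df must have a metabolite column")
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      fit = list(fit_logistic(.data$time_min, .data[[ecol]],
                              min_change = min_change)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      k = purrr::map_dbl(fit, "k"),
      y0 = purrr::map_dbl(fit, "y0"),
      T = purrr::map_dbl(fit, "T"),
      t50 = purrr::map_dbl(fit, "t50"),
      rss = purrr::map_dbl(fit, "rss"),
      converged = purrr::map_lgl(fit, "converged"),
      degenerate = purrr::map_lgl(fit, "degenerate")
    )
}

#' Collapse corrected isotopologue tables to enrichment series
#'
#' One row per (keys, time): the per-spectrum mean enrichment, averaged over
#' replicates when present (with SD).
#'
#' @param df Output of [correct_measurements()].
#' @param average_replicates Average biological replicates per time point.
#' @return Tibble with `strain`/`metabolite`/`time_min`,
#'   `mean_enrichment` and (when averaging) `enrichment_sd`, `n`.
#' @export
enrichment_series <- function(df, average_replicates = TRUE) {
  stopifnot(all(c("metabolite", "time_min", "mean_enrichment") %in% names(df)))
  keys <- intersect(c("strain", "metabolite", "replicate", "time_min"),
                    names(df))
  out <- df |>
    dplyr::distinct(dplyr::across(dplyr::all_of(c(keys, "mean_enrichment"))))
  if (average_replicates && "replicate" %in% keys) {
    out <- out |>
      dplyr::group_by(dplyr::across(dplyr::all_of(setdiff(keys, "replicate")))) |>
      dplyr::summarise(
        enrichment_sd = stats::sd(.data$mean_enrichment),
        n = dplyr::n(),
        mean_enrichment = mean(.data$mean_enrichment),
        .groups = "drop"
      )
  }
  dplyr::arrange(out, dplyr::across(dplyr::any_of(c("strain", "metabolite",
                                                    "time_min"))))
}
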