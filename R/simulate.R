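# Ground-truth-known simulator of instationary 13C labeling: cells at
# metabolic steady state (constant pools and fluxes) are switched at t = 0
# from unlabeled to uniformly 13C-labeled glucose, and label propagates
# through the pathway with per-pool first-order exchange at rate flux/pool.

#' Simulation configuration
#'
#' Bundles the pathway, pool sizes, pathway flux and measurement parameters
#' for the labeling simulator. The shipped presets are study-like fixtures:
#' pool sizes in the nmol/gDCW range with GGPP at 1.4 (wild type) or 12.8
#' (overexpression strain, all pools and the flux scaled by 12.8/1.4), and a
#' single pathway flux of 0.3 nmol/gDCW/min chosen so that noise-free
#' half-times span roughly 5 min (M5P) to 20 min (GGPP) across the pathway.
#'
#' @param strain Preset name: `"WT"` or `"S037"`; ignored when `pool_sizes`
#'   and `flux` are both supplied.
#' @param pathway A `pathway_spec`.
#' @param pool_sizes Named vector, nmol/gDCW per kinetic pool; must cover
#'   every pool of the pathway and be positive.
#' @param flux Pathway flux, nmol/gDCW/min (> 0).
#' @param tracer_purity Isotopic purity of the tracer (fraction, default 0.99).
#' @param natural_abundance Natural 13C abundance (default 0.0107).
#' @param timepoints Sampling times in minutes, strictly increasing from 0.
#' @param noise_cv Total multiplicative (lognormal) CV of a measured peak
#'   area. It decomposes into a per-injection common-mode factor (source
#'   and injection fluctuations, shared by every peak of an injection
#'   including the 13C internal standard, hence cancelling in IDMS ratios)
#'   and an independent per-peak residual of CV `peak_cv`.
#' @param peak_cv Uncorrelated per-peak CV (default 0.04); the common-mode
#'   CV is `sqrt(noise_cv^2 - peak_cv^2)`. When `noise_cv < peak_cv` all
#'   noise is per-peak.
#' @param replicates Biological replicates per strain.
#' @param seed RNG seed for the measurement layer.
#' @param source_lag Optional first-order lag (min) of source-unit labeling
#'   after the medium switch; 0 means an instantaneous switch.
#' @param biomass_gdcw Biomass collected per sample (g dry cell weight).
#' @param volumes List with `resuspension_ul` and `injection_ul` (and
#'   `extraction_ml`, bookkeeping only), mirroring the sampling protocol.
#' @param response_slope IDMS response: 12C/13C area ratio per pmol on
#'   column (calibration-curve slope used by the generator).
#' @param istd_area Nominal fully 13C-labeled internal-standard area
#'   (arbitrary units) emitted per metabolite signal.
#' @return A `sim_config` list.
#' @export
sim_config <- function(strain = c("WT", "S037"),
                       pathway = read_pathway(),
                       pool_sizes = NULL,
                       flux = NULL,
                       tracer_purity = 0.99,
                       natural_abundance = 0.0107,
                       timepoints = default_timepoints(),
                       noise_cv = 0.1,
                       peak_cv = 0.04,
                       replicates = 3L,
                       seed = 1L,
                       source_lag = 0,
                       biomass_gdcw = 0.01,
                       volumes = default_volumes(),
                       response_slope = 0.2,
                       istd_area = 1e6) {
  strain <- match.arg(strain)
  base_pools <- c(MEV = 1.0, M5P = 0.5, M5PP = 0.4, IPP_DMAPP = 1.0,
                  GPP = 0.8, FPP = 1.0, GGPP = 1.4)
  base_flux <- 0.3
  scale <- if (strain == "S037") 12.8 / 1.4 else 1
  if (is.null(pool_sizes)) pool_sizes <- base_pools * scale
  if (is.null(flux)) flux <- base_flux * scale

  missing_pools <- setdiff(pathway$pools$pool, names(pool_sizes))
  if (length(missing_pools) > 0) {
    stop("pool_sizes missing for: ", paste(missing_pools, collapse = ", "))
  }
  stopifnot(all(pool_sizes > 0), flux > 0,
            tracer_purity > 0, tracer_purity <= 1,
            natural_abundance >= 0, natural_abundance < 1,
            length(timepoints) >= 1, timepoints[1] == 0,
            !is.unsorted(timepoints, strictly = TRUE),
            noise_cv >= 0, peak_cv >= 0, replicates >= 1, source_lag >= 0,
            biomass_gdcw > 0)
  structure(
    list(strain = strain, pathway = pathway,
         pool_sizes = pool_sizes[pathway$pools$pool], flux = flux,
         tracer_purity = tracer_purity,
         natural_abundance = natural_abundance,
         timepoints = timepoints, noise_cv = noise_cv, peak_cv = peak_cv,
         replicates = as.integer(replicates), seed = as.integer(seed),
         source_lag = source_lag, biomass_gdcw = biomass_gdcw,
         volumes = volumes, response_slope = response_slope,
         istd_area = istd_area),
    class = "sim_config"
  )
}

#' Default sample-processing volumes
#'
#' Extraction in 5 mL, resuspension in 200 uL, injection of 10 uL.
#' @export
default_volumes <- function() {
  list(extraction_ml = 5, resuspension_ul = 200, injection_ul = 10)
}

#' Turnover times of the configured pools
#'
#' Turnover time (min) of pool i is pool_size_i / flux; its inverse is the
#' exchange rate of the labeling dynamics.
#' @param config A `sim_config`.
#' @export
turnover_times <- function(config) config$pool_sizes / config$flux

# source-unit distribution at simulation time t (t < 0: pre-switch)
source_distribution <- function(config, t) {
  nc <- config$pathway$source_unit_carbons
  if (t < 0) return(binomial_distribution(nc, config$natural_abundance))
  p <- if (config$source_lag > 0) {
    config$natural_abundance +
      (config$tracer_purity - config$natural_abundance) *
        (1 - exp(-t / config$source_lag))
  } else {
    config$tracer_purity
  }
  binomial_distribution(nc, p)
}

# one inflow rule per pool, compiled from the reaction list
pool_inflows <- function(pathway) {
  inflows <- list()
  for (r in pathway$reactions) {
    if (!is.null(inflows[[r$product]])) {
      stop("pool ", r$product, " has more than one producing reaction")
    }
    inflows[[r$product]] <- r
  }
  missing <- setdiff(pathway$pools$pool, names(inflows))
  if (length(missing) > 0) stop("no producing reaction for: ",
                                paste(missing, collapse = ", "))
  inflows
}

#' Simulate instationary labeling dynamics
#'
#' Integrates, for every pool i with exchange rate flux/pool_i, the balance
#' d(M_i)/dt = (flux/pool_i) (M_inflow - M_i) over isotopologue
#' distributions, where the inflow distribution is the threefold
#' convolution of the source-unit distribution for the entry pool, the
#' upstream pool's distribution for linear steps, the random carbon-loss
#' operator for the decarboxylation, and the convolution of the substrate
#' distributions for condensations. At t = 0 every pool is at the
#' natural-abundance steady state and the source units switch to the tracer
#' purity.
#'
#' @param config A `sim_config`.
#' @param times Output times (minutes, starting at 0); defaults to the
#'   configured sampling scheme.
#' @param atol,rtol Integrator tolerances (`deSolve::lsoda`).
#' @return Tibble with `time_min`, `metabolite` (pool name), `m_index`,
#'   `fraction`; each (time, pool) spectrum is a valid distribution.
#' @export
simulate_labeling <- function(config, times = config$timepoints,
                              atol = 1e-9, rtol = 1e-8) {
  stopifnot(inherits(config, "sim_config"))
  pw <- config$pathway
  pools <- pw$pools$pool
  ncarb <- stats::setNames(pw$pools$n_carbons, pools)
  len <- ncarb + 1L
  offset <- stats::setNames(c(0L, cumsum(len))[seq_along(pools)], pools)
  inflows <- pool_inflows(pw)
  rates <- config$flux / config$pool_sizes

  y0 <- unlist(lapply(pools, function(p) {
    binomial_distribution(ncarb[[p]], config$natural_abundance)
  }))

  get_dist <- function(y, p) y[(offset[[p]] + 1L):(offset[[p]] + len[[p]])]

  rhs <- function(t, y, parms) {
    src <- source_distribution(config, t)
    dy <- numeric(length(y))
    for (p in pools) {
      r <- inflows[[p]]
      inflow <- switch(r$type,
        source_feed = {
          d <- src
          if (r$units > 1) for (i in 2:r$units) d <- convolve_distributions(d, src)
          d
        },
        linear_step = get_dist(y, r$substrate),
        carbon_loss = carbon_loss_operator(get_dist(y, r$substrate)),
        condensation = Reduce(convolve_distributions,
                              lapply(r$substrates, get_dist, y = y))
      )
      idx <- (offset[[p]] + 1L):(offset[[p]] + len[[p]])
      dy[idx] <- rates[[p]] * (inflow - y[idx])
    }
    list(dy)
  }

  if (times[1] != 0) times <- c(0, times)
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", atol = atol, rtol = rtol)
  if (any(!is.finite(sol))) stop("integration produced non-finite state")

  out <- purrr::map_dfr(pools, function(p) {
    idx <- (offset[[p]] + 1L):(offset[[p]] + len[[p]]) + 1L # +1: time column
    block <- sol[, idx, drop = FALSE]
    block[block < 0] <- 0
    block <- block / rowSums(block)
    tibble::tibble(
      time_min = rep(sol[, 1], each = len[[p]]),
      metabolite = p,
      m_index = rep(0:ncarb[[p]], times = nrow(sol)),
      fraction = as.numeric(t(block))
    )
  })
  dplyr::arrange(out, .data$time_min,
                 factor(.data$metabolite, levels = pools), .data$m_index)
}

#' Simulate labeling to isotopic steady state
#'
#' Runs the simulator to ten times the slowest pool turnover time, where
#' every pool's distribution has converged to the source composition.
#'
#' @param config A `sim_config`.
#' @return Tibble as [simulate_labeling()], at the final time only.
#' @export
simulate_to_steady_state <- function(config) {
  t_end <- 10 * max(cumsum(turnover_times(config)))
  traj <- simulate_labeling(config, times = c(0, t_end))
  dplyr::filter(traj, .data$time_min == max(.data$time_min))
}

# pmol of a pool loaded on column for one sample
amount_on_column_pmol <- function(pool_nmol_gdcw, biomass_gdcw, volumes) {
  pool_nmol_gdcw * biomass_gdcw * 1000 *
    volumes$injection_ul / volumes$resuspension_ul
}

lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# split a total per-peak CV into a common-mode (per-injection) component and
# an uncorrelated per-peak residual
noise_components <- function(noise_cv, peak_cv) {
  peak <- min(noise_cv, peak_cv)
  list(peak = peak, common = sqrt(max(noise_cv^2 - peak^2, 0)))
}

#' Apply the measurement layer to a simulated trajectory
#'
#' Produces a vendor-export-shaped raw table: each true isotopologue
#' distribution is pushed through the forward model of the correction step
#' (natural abundance on non-tracer carbons and tracer purity on labeled
#' positions), scaled to an absolute response from the pool size, the
#' biomass and the calibration slope, and multiplied by per-peak lognormal
#' noise. A fully 13C-labeled internal-standard area is emitted per
#' (sample, metabolite). Noise follows the configured IDMS structure: one
#' common-mode factor per injection multiplies every peak of that sample
#' (analyte and internal standard alike), and each peak additionally
#' carries an independent residual of CV `peak_cv`.
#'
#' @param trajectory Output of [simulate_labeling()].
#' @param config The `sim_config` used to generate it.
#' @return Tibble with columns `strain`, `replicate`, `time_min`,
#'   `metabolite`, `m_index`, `intensity`, `istd_area`, `biomass_gdcw`.
#' @export
apply_measurement_layer <- function(trajectory, config) {
  stopifnot(inherits(config, "sim_config"))
  pw <- config$pathway
  ncarb <- stats::setNames(pw$pools$n_carbons, pw$pools$pool)
  models <- lapply(unique(ncarb), build_correction_model,
                   abundance = max(config$natural_abundance, 1e-12),
                   purity = config$tracer_purity)
  names(models) <- as.character(unique(ncarb))

  nc <- noise_components(config$noise_cv, config$peak_cv)
  set.seed(config$seed)
  reps <- purrr::map_dfr(seq_len(config$replicates), function(rep_i) {
    injections <- tibble::tibble(
      time_min = sort(unique(trajectory$time_min)),
      common = lognormal_noise(dplyr::n_distinct(trajectory$time_min),
                               nc$common)
    )
    trajectory |>
      dplyr::group_by(.data$time_min, .data$metabolite) |>
      dplyr::group_modify(function(g, key) {
        n <- ncarb[[key$metabolite]]
        g <- dplyr::arrange(g, .data$m_index)
        observed <- as.numeric(models[[as.character(n)]]$matrix %*% g$fraction)
        amount <- amount_on_column_pmol(config$pool_sizes[[key$metabolite]],
                                        config$biomass_gdcw, config$volumes)
        scale <- config$istd_area * config$response_slope * amount
        common <- injections$common[injections$time_min == key$time_min]
        g$intensity <- observed * scale * common *
          lognormal_noise(n + 1L, nc$peak)
        g$istd_area <- config$istd_area * common * lognormal_noise(1L, nc$peak)
        g$biomass_gdcw <- config$biomass_gdcw
        g
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(strain = config$strain, replicate = rep_i)
  })
  dplyr::select(reps, "strain", "replicate", "time_min", "metabolite",
                "m_index", "intensity", "istd_area", "biomass_gdcw")
}

#' Generate an IDMS calibration series
#'
#' Emits (amount on column, 12C/13C area ratio) pairs from a linear true
#' response with multiplicative lognormal noise, an additive blank noise
#' floor, and response saturation above the linear-range ceiling of
#' 50 pmol on column. Blank injections (`level_pmol = 0`) carry the blank
#' noise only. Per-injection common-mode variation (CV
#' `sqrt(noise_cv^2 - peak_cv^2)`) cancels in the 12C/13C ratio, so the
#' ratio carries only the two independent per-peak residuals of CV
#' `peak_cv` plus the blank floor.
#'
#' @param compound Compound label.
#' @param levels Amounts injected on column (pmol); at least 5 positive
#'   levels. The defaults span 0.02-100 pmol, i.e. the 0.08 nM-10 uM
#'   calibration mixtures at a 10 uL injection.
#' @param slope True response (ratio per pmol).
#' @param noise_cv Total multiplicative CV of a peak area.
#' @param peak_cv Uncorrelated per-peak CV (see [sim_config()]).
#' @param blank_sd Additive blank noise floor (ratio units).
#' @param replicates Injections per level.
#' @param n_blanks Blank injections.
#' @param saturate_above Amount (pmol) above which response rolls off.
#' @param seed RNG seed.
#' @return Tibble with `compound`, `level_pmol`, `replicate`, `ratio`.
#' @export
make_calibration_series <- function(compound = "GGPP",
                                    levels = c(0.02, 0.05, 0.1, 0.2, 0.5, 1,
                                               2, 5, 10, 20, 50, 100),
                                    slope = 0.2,
                                    noise_cv = 0.1,
                                    peak_cv = 0.04,
                                    blank_sd = 0.002,
                                    replicates = 3L,
                                    n_blanks = 5L,
                                    saturate_above = 50,
                                    seed = 1L) {
  if (length(levels) < 2) stop("at least 2 levels required")
  if (sum(levels > 0) < 5) stop("at least 5 positive levels required")
  stopifnot(all(levels >= 0), slope > 0, noise_cv >= 0, blank_sd >= 0)
  nc <- noise_components(noise_cv, peak_cv)
  set.seed(seed)
  grid <- tidyr::expand_grid(level_pmol = sort(unique(levels)),
                             replicate = seq_len(replicates))
  eff <- ifelse(grid$level_pmol <= saturate_above, grid$level_pmol,
                saturate_above + 0.3 * (grid$level_pmol - saturate_above))
  ratio <- slope * eff *
    lognormal_noise(nrow(grid), nc$peak) /
    lognormal_noise(nrow(grid), nc$peak) +
    stats::rnorm(nrow(grid), 0, blank_sd)
  out <- tibble::tibble(compound = compound, level_pmol = grid$level_pmol,
                        replicate = grid$replicate, ratio = ratio)
  if (n_blanks > 0) {
    out <- dplyr::bind_rows(
      tibble::tibble(compound = compound, level_pmol = 0,
                     replicate = seq_len(n_blanks),
                     ratio = stats::rnorm(n_blanks, 0, blank_sd)),
      out
    )
  }
  out
}

#' Simulate an absolute-quantification experiment
#'
#' Generates per-replicate 12C/13C ratios for unlabeled extracts of all
#' measured compounds with known true intracellular pools, using the same
#' response and noise model as the calibration generator: common-mode
#' injection variation cancels in the ratio, and the analyte and
#' internal-standard areas each carry an independent per-peak residual of
#' CV `peak_cv`, so the ratio CV is about `sqrt(2) * peak_cv`.
#'
#' @param true_pools Named vector of true concentrations (nmol/gDCW) per
#'   compound.
#' @param noise_cv Total per-area lognormal CV.
#' @param peak_cv Uncorrelated per-peak CV (see [sim_config()]).
#' @param replicates Biological replicates.
#' @param biomass_gdcw Biomass per sample (gDCW).
#' @param volumes See [default_volumes()].
#' @param slope True response slope(s), ratio per pmol; scalar or named.
#' @param seed RNG seed.
#' @return Tibble with `compound`, `replicate`, `ratio`, `biomass_gdcw`.
#' @export
simulate_quant_experiment <- function(true_pools = default_compound_pools(),
                                      noise_cv = 0.1,
                                      peak_cv = 0.04,
                                      replicates = 3L,
                                      biomass_gdcw = 0.01,
                                      volumes = default_volumes(),
                                      slope = 0.2,
                                      seed = 1L) {
  stopifnot(all(true_pools > 0), !is.null(names(true_pools)))
  slopes <- if (length(slope) == 1) {
    stats::setNames(rep(slope, length(true_pools)), names(true_pools))
  } else slope
  nc <- noise_components(noise_cv, peak_cv)
  set.seed(seed)
  grid <- tidyr::expand_grid(compound = names(true_pools),
                             replicate = seq_len(replicates))
  amount <- amount_on_column_pmol(true_pools[grid$compound], biomass_gdcw,
                                  volumes)
  ratio <- slopes[grid$compound] * amount *
    lognormal_noise(nrow(grid), nc$peak) / lognormal_noise(nrow(grid), nc$peak)
  tibble::tibble(compound = grid$compound, replicate = grid$replicate,
                 ratio = as.numeric(ratio), biomass_gdcw = biomass_gdcw)
}

#' Study-like true pools for the eight measured compounds (nmol/gDCW)
#'
#' Wild-type-like fixture values; GGPP at the printed 1.4 nmol/gDCW, the
#' isobaric IPP/DMAPP pool split 60/40.
#' @export
default_compound_pools <- function() {
  c(MEV = 1.0, M5P = 0.5, M5PP = 0.4, IPP = 0.6, DMAPP = 0.4,
    GPP = 0.8, FPP = 1.0, GGPP = 1.4)
}
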