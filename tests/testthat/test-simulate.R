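test_that("pre-switch state is the natural-abundance binomial for every pool", {
  cfg <- noise_free_config()
  traj <- simulate_labeling(cfg, times = c(0, 1))
  t0 <- dplyr::filter(traj, time_min == 0)
  for (p in pathway$pools$pool) {
    n <- pathway$pools$n_carbons[pathway$pools$pool == p]
    M <- dplyr::filter(t0, metabolite == p) |> dplyr::pull(fraction)
    expect_equal(M, binomial_distribution(n, cfg$natural_abundance),
                 tolerance = 1e-12, info = p)
  }
})

test_that("all pools converge to the tracer purity at isotopic steady state", {
  cfg <- noise_free_config()
  ss <- simulate_to_steady_state(cfg)
  enr <- ss |>
    dplyr::group_by(metabolite) |>
    dplyr::summarise(E = mean_enrichment(fraction))
  expect_true(all(abs(enr$E - cfg$tracer_purity) < 1e-3))
})

test_that("simulated distributions stay normalized at every time", {
  cfg <- noise_free_config()
  traj <- simulate_labeling(cfg)
  sums <- traj |>
    dplyr::group_by(time_min, metabolite) |>
    dplyr::summarise(s = sum(fraction), lo = min(fraction), .groups = "drop")
  expect_true(all(abs(sums$s - 1) <= 1e-9))
  expect_true(all(sums$lo >= 0))
})

test_that("a single pool follows the closed-form first-order solution", {
  pw1 <- single_pool_pathway()
  tau <- 4
  cfg <- sim_config("WT", pathway = pw1, pool_sizes = c(X = tau), flux = 1,
                    natural_abundance = 0, tracer_purity = 0.99,
                    noise_cv = 0, replicates = 1)
  times <- c(0, 1, 2, 5, 10, 20, 40)
  traj <- simulate_labeling(cfg, times = times, atol = 1e-12, rtol = 1e-10)
  E <- traj |>
    dplyr::group_by(time_min) |>
    dplyr::summarise(E = mean_enrichment(fraction)) |>
    dplyr::pull(E)
  expect_equal(E, 0.99 * (1 - exp(-times / tau)), tolerance = 1e-6)
})

test_that("T50 is non-decreasing along the pathway on noise-free output", {
  enr <- noise_free_enrichment(noise_free_config())
  fits <- fit_enrichment_kinetics(enr)
  t50s <- fits$t50[match(c("M5P", "IPP_DMAPP", "GPP", "FPP", "GGPP"),
                         fits$metabolite)]
  expect_true(all(is.finite(t50s)))
  expect_true(all(diff(t50s) >= 0))
})

test_that("scaling pools and flux together leaves enrichment unchanged", {
  cfg1 <- noise_free_config()
  lam <- 3.7
  cfg2 <- sim_config("WT", pathway = pathway,
                     pool_sizes = cfg1$pool_sizes * lam,
                     flux = cfg1$flux * lam, noise_cv = 0, replicates = 1)
  tr1 <- simulate_labeling(cfg1)
  tr2 <- simulate_labeling(cfg2)
  expect_equal(tr2$fraction, tr1$fraction, tolerance = 1e-6)
})

test_that("larger pools at fixed flux slow labeling down", {
  cfg1 <- noise_free_config()
  cfg2 <- sim_config("WT", pathway = pathway,
                     pool_sizes = cfg1$pool_sizes * 9, flux = cfg1$flux,
                     noise_cv = 0, replicates = 1)
  f1 <- fit_enrichment_kinetics(noise_free_enrichment(cfg1))
  f2 <- fit_enrichment_kinetics(noise_free_enrichment(cfg2))
  j <- dplyr::inner_join(f1, f2, by = "metabolite", suffix = c("_1", "_9"))
  expect_true(all(j$t50_9 > j$t50_1))
})

test_that("the measurement layer is deterministic in the seed", {
  cfg <- sim_config("WT", pathway = pathway, noise_cv = 0.1, replicates = 2,
                    seed = 99)
  traj <- simulate_labeling(cfg, times = c(0, 5, 15))
  m1 <- apply_measurement_layer(traj, cfg)
  m2 <- apply_measurement_layer(traj, cfg)
  expect_identical(m1, m2)
  cfg2 <- sim_config("WT", pathway = pathway, noise_cv = 0.1, replicates = 2,
                     seed = 100)
  m3 <- apply_measurement_layer(traj, cfg2)
  expect_false(identical(m1$intensity, m3$intensity))
})

test_that("sim_config validates its inputs", {
  expect_error(sim_config("WT", pathway = pathway, flux = -1), "flux")
  expect_error(sim_config("WT", pathway = pathway,
                          pool_sizes = c(MEV = 1)), "missing")
  expect_error(sim_config("WT", pathway = pathway,
                          timepoints = c(1, 2)), "timepoints")
  expect_error(sim_config("WT", pathway = pathway, tracer_purity = 0),
               "tracer_purity")
})

test_that("calibration generator: exact line at zero noise, saturation above 50 pmol", {
  cal <- make_calibration_series("GGPP", noise_cv = 0, blank_sd = 0,
                                 n_blanks = 0, slope = 0.2)
  pts <- dplyr::filter(cal, level_pmol > 0, level_pmol <= 50)
  fit <- stats::lm(ratio ~ level_pmol, data = pts)
  expect_equal(unname(stats::coef(fit)), c(0, 0.2), tolerance = 1e-12)
  # beyond the linear-range ceiling the response rolls off
  top <- dplyr::filter(cal, level_pmol == 100)
  expect_lt(unique(top$ratio), 0.2 * 100 * 0.8)
  expect_error(make_calibration_series(levels = c(1, 2)), "5 positive")
})

test_that("levels below the LOD are blank-dominated", {
  # with blank floor sigma_b, signal at the lowest level sinks below 3 sigma_b
  set.seed(5)
  lod_true <- 3 * 0.002 / 0.2 # = 0.03 pmol
  cal <- make_calibration_series("GGPP", levels = c(0.005, 0.1, 1, 5, 10, 50),
                                 slope = 0.2, blank_sd = 0.002,
                                 noise_cv = 0.1, replicates = 50, seed = 5)
  low <- dplyr::filter(cal, level_pmol == 0.005)  # well below 0.03
  hi <- dplyr::filter(cal, level_pmol == 0.1)     # above 0.03
  expect_lt(mean(low$ratio) / 0.002, 3)   # S/N < 3 below LOD
  expect_gt(mean(hi$ratio) / 0.002, 3)    # S/N > 3 above LOD
})
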