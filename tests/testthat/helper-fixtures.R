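# Shared fixtures: pathway object (load once), small configs, and a
# single-pool pathway config for analytic checks.

pathway <- read_pathway()

noise_free_config <- function(strain = "WT", ...) {
  sim_config(strain, pathway = pathway, noise_cv = 0, replicates = 1, ...)
}

# one-carbon pool fed directly by a one-carbon source unit: the labeling
# balance has the closed-form solution E(t) = E0 + (p - E0)(1 - exp(-t/tau))
single_pool_pathway <- function() {
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  writeLines(c(
    "name: single_pool",
    "source_unit_carbons: 1",
    "metabolites:",
    "  - {name: X, formula: CH4O, pool: X, quantifiable_ile: true}",
    "reactions:",
    "  - {type: source_feed, product: X, units: 1}"
  ), path)
  read_pathway(path)
}

# enrichment table for the quantifiable pools of a noise-free run
noise_free_enrichment <- function(config) {
  traj <- simulate_labeling(config)
  quantifiable <- config$pathway$pools$pool[config$pathway$pools$quantifiable_ile]
  traj |>
    dplyr::filter(metabolite %in% quantifiable) |>
    dplyr::group_by(metabolite, time_min) |>
    dplyr::summarise(mean_enrichment = mean_enrichment(fraction),
                     .groups = "drop")
}

# independent of the package-internal noise generator
lognormal_noise_for_test <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

expect_distribution <- function(M, tol = 1e-9) {
  expect_gte(min(M), -tol)
  expect_equal(sum(M), 1, tolerance = tol)
}
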