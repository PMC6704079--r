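# End-to-end orchestration: CSV I/O with provenance headers, schema
# validation of vendor-export-shaped measurement tables, and the staged
# run simulate -> correct -> enrich -> fit -> quantify -> compare.

MEASUREMENT_COLUMNS <- c("strain", "replicate", "time_min", "metabolite",
                         "m_index", "intensity", "istd_area", "biomass_gdcw")

#' Read a raw measurement table
#'
#' Reads and validates the vendor-export-shaped CSV written by
#' [write_stage_csv()] / the simulator: required columns, non-negative
#' intensities, known metabolites, no duplicate (sample, metabolite,
#' m_index) keys, and a complete 0..n isotopologue ladder per spectrum.
#' Lines starting with `#` (provenance headers) are skipped.
#'
#' @param path CSV path.
#' @param pathway A `pathway_spec` used to validate metabolite names and
#'   carbon counts.
#' @return Validated tibble of measurements.
#' @export
read_measurements <- function(path, pathway = read_pathway()) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  missing <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("missing columns: ", paste(missing, collapse = ", "))
  }
  known <- c(pathway$metabolites$name, pathway$pools$pool)
  bad <- which(!df$metabolite %in% known)
  if (length(bad) > 0) {
    stop("unknown metabolite(s) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), ": ",
         paste(unique(df$metabolite[bad]), collapse = ", "))
  }
  if (any(df$intensity < 0)) stop("negative intensities")
  keys <- paste(df$strain, df$replicate, df$time_min, df$metabolite,
                df$m_index)
  if (anyDuplicated(keys)) {
    stop("duplicate (sample, metabolite, m_index) keys at row ",
         anyDuplicated(keys))
  }
  carbons <- lookup_carbons(pathway, unique(df$metabolite))
  check <- df |>
    dplyr::group_by(.data$strain, .data$replicate, .data$time_min,
                    .data$metabolite) |>
    dplyr::summarise(idx = list(sort(.data$m_index)), .groups = "drop")
  for (i in seq_len(nrow(check))) {
    n <- carbons[[check$metabolite[i]]]
    if (!identical(as.integer(check$idx[[i]]), 0:n)) {
      stop("incomplete isotopologue ladder for ", check$metabolite[i],
           " (", check$strain[i], ", replicate ", check$replicate[i],
           ", t = ", check$time_min[i], "): expected m_index 0..", n)
    }
  }
  df
}

#' Write a stage output CSV with a provenance header
#'
#' Prepends `#`-comment lines recording the package version, seed and a
#' content hash of the configuration, then the data as plain CSV
#' (UTF-8, comma, `.` decimal). Readable with [read_measurements()] or any
#' CSV reader that skips `#` comments.
#'
#' @param df Tibble to write.
#' @param path Output path.
#' @param seed Seed recorded in the header.
#' @param config_hash Provenance hash (e.g. from [config_hash()]).
#' @export
write_stage_csv <- function(df, path, seed = NA, config_hash = NA) {
  header <- c(
    sprintf("# prenylflux %s", as.character(utils::packageVersion("prenylflux"))),
    sprintf("# seed: %s", seed),
    sprintf("# config_hash: %s", config_hash)
  )
  writeLines(header, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Content hash of a configuration object
#'
#' MD5 of the deparsed configuration, recorded in output headers so a
#' result file can be traced to the exact configuration that produced it.
#'
#' @param config Any R object.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "pathway")]), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full workflow on a configuration
#'
#' Orchestrates the computational workflow end to end on simulated or
#' supplied data: measurement generation (or loading), isotopologue
#' correction, enrichment series, logistic kinetics with T50, IDMS
#' calibration + quantification, and strain comparison when two strains are
#' present. Stage outputs are returned as tibbles and, when `out_dir` is
#' given, written as provenance-stamped CSVs. Deterministic given the
#' configuration and seed.
#'
#' @param config A `sim_config` (the generated-data path) — or a list of
#'   two, e.g. `list(WT = ..., S037 = ...)`, to compare strains.
#' @param measurements Optional pre-loaded measurement table; skips
#'   simulation.
#' @param quant_samples Optional tibble for absolute quantification (see
#'   [simulate_quant_experiment()]); when NULL one is generated per strain
#'   from the configured pools. Set to `FALSE` to skip quantification.
#' @param calibration Optional calibration table per compound; generated
#'   with [make_calibration_series()] defaults when NULL.
#' @param out_dir Optional output directory for stage CSVs.
#' @return List with `measurements`, `corrected`, `enrichment`, `fits`,
#'   `quant`, `comparison` (NULL when single-strain), `config_hash`.
#' @export
run_pipeline <- function(config, measurements = NULL, quant_samples = NULL,
                         calibration = NULL, out_dir = NULL) {
  configs <- if (inherits(config, "sim_config")) list(config) else config
  stopifnot(length(configs) >= 1,
            all(vapply(configs, inherits, logical(1), "sim_config")))
  pw <- configs[[1]]$pathway
  hash <- config_hash(configs[[1]])
  seed <- configs[[1]]$seed

  if (is.null(measurements)) {
    measurements <- purrr::map_dfr(configs, function(cf) {
      traj <- simulate_labeling(cf)
      apply_measurement_layer(traj, cf)
    })
  }

  corrected <- correct_measurements(
    measurements, pathway = pw,
    abundance = max(configs[[1]]$natural_abundance, 1e-12),
    purity = configs[[1]]$tracer_purity
  )
  quantifiable <- pw$pools$pool[pw$pools$quantifiable_ile]
  enr <- enrichment_series(
    dplyr::filter(corrected, .data$metabolite %in% quantifiable),
    average_replicates = FALSE
  )
  fits <- fit_enrichment_kinetics(enr)

  quant <- NULL
  if (!isFALSE(quant_samples)) {
    if (is.null(calibration)) {
      cmps <- names(default_compound_pools())
      calibration <- purrr::map_dfr(seq_along(cmps), function(i) {
        make_calibration_series(cmps[i], seed = seed + i)
      })
    }
    curves <- calibration |>
      dplyr::group_split(.data$compound) |>
      purrr::map(~ validate_curve(fit_calibration(.x)))
    names(curves) <- purrr::map_chr(curves, "compound")
    if (is.null(quant_samples)) {
      quant_samples <- purrr::imap_dfr(configs, function(cf, i) {
        pools <- default_compound_pools() *
          cf$pool_sizes[["GGPP"]] / default_compound_pools()[["GGPP"]]
        simulate_quant_experiment(pools, noise_cv = cf$noise_cv,
                                  replicates = cf$replicates,
                                  biomass_gdcw = cf$biomass_gdcw,
                                  volumes = cf$volumes,
                                  slope = cf$response_slope,
                                  seed = cf$seed + 1000L) |>
          dplyr::mutate(strain = cf$strain)
      })
    }
    quant <- quantify(quant_samples, curves,
                      volumes = configs[[1]]$volumes)
  }

  comparison <- NULL
  strain_order <- vapply(configs, function(cf) cf$strain, character(1))
  if (!is.null(quant) && "strain" %in% names(quant) &&
      length(strain_order) == 2 && strain_order[1] != strain_order[2]) {
    # second configured strain (the perturbed one) over the first (reference)
    comparison <- compare_strains(
      dplyr::filter(quant, .data$strain == strain_order[2]),
      dplyr::filter(quant, .data$strain == strain_order[1])
    )
  }

  result <- list(measurements = measurements, corrected = corrected,
                 enrichment = enr, fits = fits, quant = quant,
                 comparison = comparison, config_hash = hash)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("measurements", "corrected", "enrichment", "quant",
                 "comparison")) {
      if (!is.null(result[[nm]])) {
        write_stage_csv(result[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                        seed = seed, config_hash = hash)
      }
    }
    write_stage_csv(dplyr::select(fits, -"fit"),
                    file.path(out_dir, "fits.csv"),
                    seed = seed, config_hash = hash)
  }
  result
}
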