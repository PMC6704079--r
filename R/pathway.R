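#' Read a pathway specification from a YAML config
#'
#' A pathway config defines the measured compounds (name, formula, CAS,
#' retention time, kinetic pool, ILE-quantifiability) and the reaction
#' topology from the two-carbon source units to the terminal prenyl
#' pyrophosphate. Reaction types are `source_feed` (the entry pool is built
#' from `units` source units), `linear_step` (carbon-conserving conversion),
#' `carbon_loss` (decarboxylation losing one carbon) and `condensation`
#' (carbons of the two substrates add up). Carbon conservation of every
#' reaction and acyclicity of the topology are validated on load.
#'
#' @param path Path to the YAML file. The default is the shipped
#'   mevalonate/prenyl-pyrophosphate config.
#' @return A `pathway_spec` object: list with `name`, `source_unit_carbons`,
#'   `metabolites` (tibble, one row per compound, with computed `n_carbons`
#'   and `mz`), `pools` (tibble, one row per kinetic pool in topological
#'   order) and `reactions` (list).
#' @export
read_pathway <- function(path = prenylflux_example("pathway_mevalonate.yaml")) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$metabolites), !is.null(cfg$reactions))

  mets <- purrr::map_dfr(cfg$metabolites, function(m) {
    counts <- parse_formula(m$formula)
    tibble::tibble(
      name = m$name,
      formula = m$formula,
      n_carbons = if ("C" %in% names(counts)) as.integer(counts[["C"]]) else 0L,
      cas = m$cas %||% NA_character_,
      retention_time = as.numeric(m$retention_time %||% NA_real_),
      pool = m$pool %||% m$name,
      quantifiable_ile = isTRUE(m$quantifiable_ile),
      mz = exact_mz(m$formula)
    )
  })
  if (anyDuplicated(mets$name)) stop("duplicate metabolite names in config")

  pools <- mets |>
    dplyr::group_by(.data$pool) |>
    dplyr::summarise(
      n_carbons = unique(.data$n_carbons)[1],
      quantifiable_ile = any(.data$quantifiable_ile),
      n_compounds = dplyr::n(),
      .groups = "drop"
    )
  bad <- mets |>
    dplyr::group_by(.data$pool) |>
    dplyr::filter(dplyr::n_distinct(.data$n_carbons) > 1)
  if (nrow(bad) > 0) stop("compounds sharing a pool must share a carbon count")

  pw <- structure(
    list(
      name = cfg$name %||% "pathway",
      source_unit_carbons = as.integer(cfg$source_unit_carbons %||% 2L),
      metabolites = mets,
      pools = pools,
      reactions = cfg$reactions
    ),
    class = "pathway_spec"
  )
  validate_pathway(pw)
  # topological order of pools, source first
  order <- pathway_topo_order(pw)
  pw$pools <- pools[match(order, pools$pool), ]
  pw
}

#' @export
print.pathway_spec <- function(x, ...) {
  cat("<pathway_spec> ", x$name, "\n", sep = "")
  cat("  ", nrow(x$metabolites), " compounds in ", nrow(x$pools),
      " kinetic pools; source unit: C", x$source_unit_carbons, "\n", sep = "")
  print(x$metabolites[, c("name", "formula", "n_carbons", "pool",
                          "quantifiable_ile", "mz")])
  invisible(x)
}

pool_carbons <- function(pathway, pool) {
  i <- match(pool, pathway$pools$pool)
  if (is.na(i)) stop("unknown pool: ", pool)
  pathway$pools$n_carbons[i]
}

validate_pathway <- function(pw) {
  for (r in pw$reactions) {
    n_prod <- pool_carbons(pw, r$product)
    ok <- switch(r$type,
      source_feed = n_prod == r$units * pw$source_unit_carbons,
      linear_step = n_prod == pool_carbons(pw, r$substrate),
      carbon_loss = n_prod == pool_carbons(pw, r$substrate) - 1L,
      condensation = n_prod == sum(vapply(r$substrates, pool_carbons,
                                          integer(1), pathway = pw)),
      stop("unknown reaction type: ", r$type)
    )
    if (!ok) {
      stop("carbon balance violated in ", r$type, " -> ", r$product)
    }
  }
  invisible(pw)
}

# Kahn topological sort over pools; errors on cycles (isomerizations within a
# merged pool, e.g. IPP<->DMAPP, never appear as reactions).
pathway_topo_order <- function(pw) {
  pools <- pw$pools$pool
  deps <- stats::setNames(vector("list", length(pools)), pools)
  for (r in pw$reactions) {
    subs <- switch(r$type,
      source_feed = character(0),
      linear_step = ,
      carbon_loss = r$substrate,
      condensation = unlist(r$substrates)
    )
    deps[[r$product]] <- union(deps[[r$product]], setdiff(subs, r$product))
  }
  order <- character(0)
  remaining <- pools
  while (length(remaining) > 0) {
    ready <- remaining[vapply(remaining, function(p) {
      all(deps[[p]] %in% order)
    }, logical(1))]
    if (length(ready) == 0) stop("pathway topology contains a cycle")
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  order
}

#' Count measured isotopologues
#'
#' A pool with n carbons contributes n+1 mass isotopologues (M0..Mn) per
#' measured signal and timepoint. Only pools flagged quantifiable in the ILE
#' are counted; the isobaric IPP/DMAPP pair is one signal (6 isotopologues)
#' but two metabolic pools. With the default pathway and the 11-timepoint
#' sampling scheme this yields 61 isotopologues per timepoint and 671 over
#' the time course.
#'
#' @param pathway A `pathway_spec`.
#' @param timepoints Sampling times (minutes); only their number matters.
#' @return List with `per_signal` (tibble: signal, n_carbons,
#'   n_isotopologues), `n_pools` (metabolic pools behind the signals),
#'   `per_timepoint_total` and `total`.
#' @export
count_isotopologues <- function(pathway,
                                timepoints = default_timepoints()) {
  if (length(timepoints) == 0) stop("empty timepoint list")
  signals <- pathway$pools |>
    dplyr::filter(.data$quantifiable_ile) |>
    dplyr::transmute(
      signal = .data$pool,
      n_carbons = .data$n_carbons,
      n_isotopologues = .data$n_carbons + 1L,
      n_compounds = .data$n_compounds
    )
  per_tp <- sum(signals$n_isotopologues)
  list(
    per_signal = signals,
    n_pools = sum(signals$n_compounds),
    per_timepoint_total = per_tp,
    total = per_tp * length(timepoints)
  )
}

#' Sampling times of the labeling experiment (minutes)
#' @export
default_timepoints <- function() c(0, 1, 2, 5, 10, 15, 30, 45, 60, 90, 120)

#' Path to a file shipped with prenylflux
#'
#' @param file File name under `inst/extdata`; with no argument, lists them.
#' @export
prenylflux_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "prenylflux")))
  }
  p <- system.file("extdata", file, package = "prenylflux", mustWork = TRUE)
  p
}
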