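# Monoisotopic atomic masses (NIST), >= 6 decimals. Only elements occurring in
# the mevalonate/prenyl-pyrophosphate intermediates (plus common organics).
MONOISOTOPIC_MASS <- c(
  H = 1.0078250319,
  C = 12,
  N = 14.0030740052,
  O = 15.9949146221,
  P = 30.97376151,
  S = 31.97207069
)

# Mass of a proton (Da); subtracting it from the neutral monoisotopic mass
# gives the [M-H]- ion m/z with the electron mass accounted for.
PROTON_MASS <- 1.0072765

#' Parse an elemental formula
#'
#' Parses a Hill-style molecular formula such as `"C20H36O7P2"` into named
#' element counts. Only elements with tabulated monoisotopic masses (C, H, N,
#' O, P, S) are accepted; anything else is an error, as is a formula with no
#' atoms.
#'
#' @param formula A single formula string, e.g. `"C6H12O4"`.
#' @return A named integer vector of element counts.
#' @examples
#' parse_formula("C6H12O4")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  x <- gsub("\\s", "", formula)
  if (!nzchar(x)) stop("empty formula")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", x)[[1]]
  tokens <- regmatches(x, gregexpr("[A-Z][a-z]?[0-9]*", x))[[1]]
  if (sum(nchar(tokens)) != nchar(x)) {
    stop("malformed formula: ", formula)
  }
  elems <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(elems, names(MONOISOTOPIC_MASS))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  out <- tapply(counts, factor(elems, levels = unique(elems)), sum)
  out <- stats::setNames(as.integer(out), names(out))
  if (any(out < 0) || sum(out) == 0L) stop("formula must contain at least one atom")
  out
}

#' Monoisotopic neutral mass of a formula
#'
#' @param formula Formula string or named count vector from [parse_formula()].
#' @return Monoisotopic mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  sum(MONOISOTOPIC_MASS[names(counts)] * counts)
}

#' Theoretical ion m/z for targeted acquisition
#'
#' Computes the exact m/z of the deprotonated ion, the only species required
#' for negative-mode tSIM acquisition of the isoprenoid precursors (all are
#' acids/phosphates and ionize as \eqn{[M-H]^-}).
#'
#' @param formula Formula string or named count vector.
#' @param adduct Ion species; only `"[M-H]-"` is supported.
#' @return m/z in Da (neutral monoisotopic mass minus the proton mass).
#' @examples
#' exact_mz("C20H36O7P2") # GGPP, 449.18635
#' @export
exact_mz <- function(formula, adduct = "[M-H]-") {
  if (!identical(adduct, "[M-H]-")) {
    stop("unsupported adduct: ", adduct, " (only [M-H]- is implemented)")
  }
  monoisotopic_mass(formula) - PROTON_MASS
}
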