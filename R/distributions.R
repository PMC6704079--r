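# Vector primitives on carbon isotopologue distributions: a compound with n
# carbons is represented by the length-(n+1) vector M0..Mn of fractions.

#' Validate an isotopologue distribution
#'
#' @param M Numeric vector M0..Mn.
#' @param tol Tolerance on the unit sum.
#' @return `M`, invisibly, after checking non-negativity and normalization.
#' @export
check_distribution <- function(M, tol = 1e-9) {
  stopifnot(is.numeric(M), length(M) >= 1)
  if (any(M < -tol)) stop("negative isotopologue fraction")
  if (abs(sum(M) - 1) > tol) stop("distribution does not sum to 1")
  invisible(M)
}

#' Natural-abundance isotopologue distribution
#'
#' Binomial pattern of 13C over `n` carbons at per-carbon probability `p`
#' (0.0107 for natural 13C abundance).
#'
#' @param n Carbon count.
#' @param p Per-carbon 13C probability.
#' @export
binomial_distribution <- function(n, p) {
  stopifnot(n >= 0, p >= 0, p <= 1)
  stats::dbinom(0:n, size = n, prob = p)
}

#' Convolve two isotopologue distributions
#'
#' The mass isotopologue distribution of a condensation product is the
#' convolution of its substrates' distributions (labels add).
#'
#' @param a,b Distributions over n_a and n_b carbons.
#' @return Distribution over n_a + n_b carbons.
#' @export
convolve_distributions <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

#' Random single-carbon loss operator
#'
#' Models decarboxylation (M5PP -> IPP/DMAPP) on mass isotopologues: one of
#' the n carbons is removed uniformly at random, so a species with j labels
#' keeps them with probability (n-j)/n and drops to j-1 with probability j/n.
#' Positional isotopomer information is not tracked.
#'
#' @param M Distribution over n >= 1 carbons (length n+1).
#' @return Distribution over n-1 carbons (length n).
#' @export
carbon_loss_operator <- function(M) {
  n <- length(M) - 1L
  if (n < 1) stop("carbon_loss_operator requires at least one carbon")
  j <- 0:(n - 1L)
  out <- M[j + 1L] * (n - j) / n + M[j + 2L] * (j + 1L) / n
  s <- sum(out)
  if (s > 0) out / s else out
}

#' Mean 13C enrichment of an isotopologue distribution
#'
#' The average fraction of carbon positions carrying 13C:
#' \deqn{E = \frac{\sum_{i=1}^{n} i \cdot M_i}{n}}
#' where \eqn{M_i} is the proportion of the isotopologue with i 13C atoms of
#' a compound with n carbon atoms.
#'
#' @param M Distribution M0..Mn (length n+1, n >= 1).
#' @return E, a fraction in \[0, 1\].
#' @examples
#' mean_enrichment(c(0.1, 0.2, 0.3, 0.4)) # 2/3
#' @export
mean_enrichment <- function(M) {
  n <- length(M) - 1L
  if (n < 1) stop("mean enrichment is undefined for a 0-carbon compound")
  check_distribution(M, tol = 1e-6)
  sum((0:n) * M) / n
}
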