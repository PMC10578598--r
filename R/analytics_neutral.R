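# Equilibrium analytics of the neutral (Hubbell-type, infinite-allele)
# metacommunity model.

#' Fundamental biodiversity number
#'
#' Concentration parameter of the equilibrium species partition,
#' `theta = (M - 1) * nu / (1 - nu)`.
#'
#' @param M Integer number of patches (>= 2).
#' @param nu Innovation rate, `0 <= nu < 1`.
#' @return Numeric `theta >= 0`.
#' @examples
#' ewens_theta(10000, 0.01)
#' @export
ewens_theta <- function(M, nu) {
  if (M < 2) stop("`M` must be >= 2", call. = FALSE)
  if (nu < 0 || nu >= 1) stop("`nu` must lie in [0, 1)", call. = FALSE)
  (M - 1) * nu / (1 - nu)
}

#' Expected equilibrium diversity (exact sum)
#'
#' Expected number of species coexisting at the neutral-model
#' equilibrium: `sum_{i=0}^{M-1} theta / (theta + i)`, the mean number of
#' occupied tables in a Chinese-restaurant process with `M` customers.
#'
#' @inheritParams ewens_theta
#' @return Numeric in `(1, M]`.
#' @examples
#' expected_diversity_exact(1000, 0.01)
#' @export
expected_diversity_exact <- function(M, nu) {
  if (nu <= 0 || nu >= 1) stop("`nu` must lie in (0, 1)", call. = FALSE)
  theta <- ewens_theta(M, nu)
  sum(theta / (theta + 0:(M - 1)))
}

#' Expected equilibrium diversity (large-M, small-nu closed form)
#'
#' `-M * nu * log(nu)` (natural log), the integral approximation of the
#' exact sum valid for `M >> 1` and `nu << 1`.
#'
#' @inheritParams ewens_theta
#' @return Numeric > 0.
#' @examples
#' expected_diversity_approx(10000, 0.01)
#' @export
expected_diversity_approx <- function(M, nu) {
  if (M < 2) stop("`M` must be >= 2", call. = FALSE)
  if (nu <= 0 || nu >= 1) stop("`nu` must lie in (0, 1)", call. = FALSE)
  -M * nu * log(nu)
}

#' Ewens expected species-abundance spectrum
#'
#' Expected number of species occupying exactly `n` of the `M` patches at
#' the neutral equilibrium:
#' `(theta / n) * Gamma(M + 1) * Gamma(M + theta - n) /
#'  (Gamma(M + 1 - n) * Gamma(M + theta))`,
#' evaluated stably via log-gamma differences. Summing the spectrum over
#' `n` recovers [expected_diversity_exact()]; weighting by `n` recovers
#' `M` (patch conservation).
#'
#' @inheritParams ewens_theta
#' @param n Occupancy class, integer (vectorized), `1 <= n <= M`.
#' @return Expected count of species in class `n`.
#' @examples
#' ewens_expected_abundance(100, 0.02, 1:5)
#' @export
ewens_expected_abundance <- function(M, nu, n) {
  if (nu <= 0 || nu >= 1) stop("`nu` must lie in (0, 1)", call. = FALSE)
  if (any(n < 1 | n > M)) stop("`n` must lie in 1..M", call. = FALSE)
  theta <- ewens_theta(M, nu)
  exp(log(theta) - log(n) +
        lgamma(M + 1) + lgamma(M + theta - n) -
        lgamma(M + 1 - n) - lgamma(M + theta))
}

#' Equilibration time of the neutral diversity dynamics
#'
#' `tau_eq ~ M / nu` steps (`1 / nu` meta-generations): the relaxation
#' time over which diversity reaches its stationary plateau.
#'
#' @inheritParams ewens_theta
#' @return Time in elementary steps.
#' @examples
#' tau_eq(10000, 0.01)  # 1e6 steps = 100 generations
#' @export
tau_eq <- function(M, nu) {
  if (nu <= 0) stop("`nu` must be > 0 (equilibration time diverges)", call. = FALSE)
  M / nu
}
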