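# Closed-form description of the spread of a single beneficial gene and
# of the residual diversity it leaves behind.

#' Deterministic carrier count during a sweep (logistic growth)
#'
#' Continuous-limit solution of
#' `dB/dt = (p_m + p_h) * (B/M) * (1 - B/M)` with `B(0) = 1`:
#' `B(t) = M * exp(r t) / (exp(r t) + M - 1)`, `r = (p_m + p_h) / M`.
#' `B(tau_fix) = M - 1` defines the fixation time [tau_fix()].
#'
#' @param t Time in elementary steps since gene introduction (vectorized).
#' @param M Number of patches.
#' @param p_m,p_h Sweep probabilities per step.
#' @return Expected carrier count, increasing from 1 towards `M`.
#' @examples
#' carriers_logistic(c(0, 1e4, 1e5), M = 1000, p_m = 0.9, p_h = 0.1)
#' @export
carriers_logistic <- function(t, M, p_m, p_h) {
  stopifnot(all(t >= 0))
  r <- (p_m + p_h) / M
  # M / (1 + (M - 1) exp(-r t)): overflow-safe form of M e^{rt}/(e^{rt}+M-1)
  M / (1 + (M - 1) * exp(-r * t))
}

#' Expected fixation time of a beneficial gene
#'
#' `tau_fix = 2 M log(M - 1) / (p_m + p_h)` steps
#' (`~ 2 log(M) / (p_m + p_h)` meta-generations), the time at which the
#' logistic carrier curve reaches `M - 1`.
#'
#' @param M Number of patches.
#' @param p_m,p_h Sweep probabilities per step, `p_m + p_h > 0`.
#' @return Time in elementary steps.
#' @examples
#' tau_fix(10000, 0.9, 0.1)
#' @export
tau_fix <- function(M, p_m, p_h) {
  if (p_m + p_h <= 0)
    stop("p_m + p_h must be > 0 (fixation time diverges)", call. = FALSE)
  2 * M * log(M - 1) / (p_m + p_h)
}

#' Decay of a non-carrier species during a sweep
#'
#' Number of patches still occupied by a focal species that does not
#' carry the gene, under `dD/dt = -p_m * (B(t)/M) * (D/M)` with
#' `D(0) = m0` and the logistic `B(t)`:
#' `D(t) = m0 * (M / (exp(r t) + M - 1))^(p_m / (p_m + p_h))`,
#' `r = (p_m + p_h) / M`.
#'
#' @param t Time in steps (vectorized).
#' @param M Number of patches.
#' @param m0 Initial occupancy of the focal species, `1 <= m0 <= M`.
#' @param p_m,p_h Sweep probabilities per step.
#' @return Expected non-carrier occupancy, non-increasing from `m0` to 0.
#' @examples
#' noncarrier_species_decay(c(0, 1e4), M = 1000, m0 = 10, p_m = 0.9, p_h = 0.1)
#' @export
noncarrier_species_decay <- function(t, M, m0, p_m, p_h) {
  stopifnot(all(t >= 0), m0 >= 1, m0 <= M)
  if (p_m == 0) return(rep(m0, length(t)))
  r <- (p_m + p_h) / M
  expo <- p_m / (p_m + p_h)
  # (M/(e^{rt}+M-1))^expo computed in log space for large r t
  m0 * exp(expo * (log(M) - .log_exp_plus(r * t, M - 1)))
}

# log(exp(x) + c) without overflow
.log_exp_plus <- function(x, c) {
  pmax(x, log(c)) + log1p(exp(-abs(x - log(c))))
}

#' Expected number of gene gains for a focal species
#'
#' Expected number of times a species initially on `m0` non-carrier
#' patches acquires the beneficial gene by HGT over the whole sweep:
#' `G_tot = m0 * p_h / p_m` (the time-integral of the HGT gain rate
#' `p_h * (B/M) * (D/M)`).
#'
#' @param m0 Initial occupancy of the focal species.
#' @param p_m,p_h Sweep probabilities per step, `p_m > 0`.
#' @return Expected total gains.
#' @examples
#' expected_total_gains(5, 0.8, 0.2)
#' @export
expected_total_gains <- function(m0, p_m, p_h) {
  if (p_m <= 0)
    stop("p_m must be > 0 (expected gains diverge: the species always survives)",
         call. = FALSE)
  m0 * p_h / p_m
}

#' Extinction probability of a non-carrier species during a sweep
#'
#' Assuming the number of HGT gains is Poisson with mean
#' [expected_total_gains()], the species goes extinct (never acquires the
#' gene before being displaced) with probability
#' `P_ext = exp(-m0 * p_h / p_m)`.
#'
#' @param m0 Initial occupancy (vectorized), `m0 >= 0`.
#' @param p_m,p_h Sweep probabilities per step, `p_m > 0`.
#' @return Probability in `(0, 1]`, decreasing in `m0`.
#' @examples
#' extinction_probability(10, 0.9, 0.1)
#' @export
extinction_probability <- function(m0, p_m, p_h) {
  if (p_m <= 0) stop("p_m must be > 0", call. = FALSE)
  stopifnot(all(m0 >= 0))
  exp(-m0 * p_h / p_m)
}

#' Fisher log-series occupancy distribution
#'
#' Large-`M`, small-`nu` approximation of the normalized equilibrium
#' occupancy distribution of a species:
#' `P(m0) = -(1 / log(nu)) * (1 - nu)^m0 / m0`, which sums to one over
#' `m0 >= 1`.
#'
#' @param m0 Occupancy (vectorized), integer >= 1.
#' @param nu Innovation rate, `0 < nu < 1`.
#' @return Probability mass at `m0`.
#' @examples
#' fisher_logseries_pmf(1:5, 0.01)
#' @export
fisher_logseries_pmf <- function(m0, nu) {
  if (nu <= 0 || nu >= 1) stop("`nu` must lie in (0, 1)", call. = FALSE)
  stopifnot(all(m0 >= 1))
  -(1 / log(nu)) * (1 - nu)^m0 / m0
}

#' Sweep parameter: expected residual diversity fraction
#'
#' Expected ratio of post-fixation to initial diversity when a single
#' beneficial gene fixes with no diversity restoration, obtained by
#' averaging the per-species survival probability
#' `1 - exp(-m0 * p_h / p_m)` over the Fisher log-series occupancy
#' distribution:
#' `Q0 = 1 - log(1 - (1 - nu) * exp(-p_h / p_m)) / log(nu)`.
#' `Q0 = 0` is a full genome-wide sweep (only reached as
#' `p_h / p_m -> 0`); `Q0 = 1` preserves all diversity.
#'
#' @param nu Innovation rate that generated the initial diversity,
#'   `0 < nu < 1`.
#' @param p_m,p_h Sweep probabilities per step (`p_m = 0` returns the
#'   limit `Q0 = 1`). Only the ratio `p_h / p_m` matters.
#' @return Value in `[0, 1]`.
#' @examples
#' sweep_parameter_Q0(0.01, p_m = 1, p_h = 0.1)  # ~ 0.51
#' @export
sweep_parameter_Q0 <- function(nu, p_m, p_h) {
  if (nu <= 0 || nu >= 1) stop("`nu` must lie in (0, 1)", call. = FALSE)
  if (p_h < 0 || p_m < 0) stop("rates must be >= 0", call. = FALSE)
  if (p_m == 0) return(1)  # pure gene-specific sweeps: no diversity lost
  1 - log(1 - (1 - nu) * exp(-p_h / p_m)) / log(nu)
}

#' Critical arrival frequency of beneficial genes
#'
#' `omega0 = 1 / (tau_fix + tau_eq)`: for arrival frequencies above
#' `omega0` the neutral dynamics cannot restore diversity between
#' successive sweeps.
#'
#' @param M Number of patches.
#' @param nu Innovation rate (> 0).
#' @param p_m,p_h Sweep probabilities per step, `p_m + p_h > 0`.
#' @return Frequency per elementary step.
#' @examples
#' omega0(10000, 0.01, 0.9, 0.1)
#' @export
omega0 <- function(M, nu, p_m, p_h) {
  1 / (tau_fix(M, p_m, p_h) + tau_eq(M, nu))
}

#' Classify the dynamical regime of recurrent gene sweeps
#'
#' Two dimensionless numbers organize the long-run behaviour of diversity
#' under recurrent beneficial-gene arrivals:
#' `x1 = omega * (tau_fix + tau_eq)` (arrival intensity relative to one
#' full sweep-plus-recovery cycle) and `x2 = tau_fix / tau_eq` (which of
#' the two phases dominates). `x1 < 1`: full recovery between arrivals,
#' maximum diversity reaches the neutral value `S0`; `x1 >= 1`: recovery
#' is cut short and `S_max < S0`. `x2 < 1`: fixation outruns restoration
#' and the minimum approaches `Q0 * S0`; `x2 >= 1`: restoration acts
#' during the sweep and the minimum stays above `Q0 * S0`.
#'
#' @param omega Arrival frequency per step (0 for a single arrival).
#' @param tau_fix_steps,tau_eq_steps The two time scales in steps.
#' @return A list of class `"regime_report"`: `omega0`, `x1`, `x2`,
#'   `label`, and qualitative predictions `S_max_pred`, `S_min_pred`.
#' @examples
#' classify_regime(2e-6, tau_fix(1e4, 0.9, 0.1), tau_eq(1e4, 0.01))
#' @export
classify_regime <- function(omega, tau_fix_steps, tau_eq_steps) {
  stopifnot(omega >= 0, tau_fix_steps > 0, tau_eq_steps > 0)
  x1 <- omega * (tau_fix_steps + tau_eq_steps)
  x2 <- tau_fix_steps / tau_eq_steps
  label <- paste0(
    if (x1 < 1) "sparse arrivals, full recovery" else "frequent arrivals, suppressed recovery",
    "; ",
    if (x2 < 1) "fast fixation, deep minima" else "slow fixation, shallow minima")
  structure(
    list(omega = omega,
         omega0 = 1 / (tau_fix_steps + tau_eq_steps),
         x1 = x1, x2 = x2, label = label,
         S_max_pred = if (x1 < 1) "S0" else "< S0",
         S_min_pred = if (x2 < 1) "~ Q0 * S0" else "> Q0 * S0"),
    class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  cat("<regime_report>\n")
  cat(sprintf("  omega = %g, omega0 = %g\n", x$omega, x$omega0))
  cat(sprintf("  x1 = omega*(tau_fix+tau_eq) = %.3g; x2 = tau_fix/tau_eq = %.3g\n",
              x$x1, x$x2))
  cat(sprintf("  regime: %s\n  S_max ~ %s; S_min ~ %s\n",
              x$label, x$S_max_pred, x$S_min_pred))
  invisible(x)
}
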