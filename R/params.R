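#' Parameter set for a metacommunity run
#'
#' Bundles the macroscopic per-step probabilities and run controls that
#' determine one simulation. All rates are per patch, per elementary time
#' step (dimensionless probabilities, as in a discrete-clock Gillespie
#' scheme where exactly one candidate move is drawn per step).
#'
#' @param M Integer number of patches (>= 2).
#' @param nu Innovation probability per step, in `[0, 1)`. Each step is an
#'   innovation (a brand-new species label) with probability `nu`.
#' @param p_m Migration-sweep probability: given a carrier/non-carrier
#'   ordered patch pair, the carrier's species invades and replaces the
#'   resident with probability `p_m` (genome-wide sweep).
#' @param p_h HGT-sweep probability: with probability `p_h` the gene alone
#'   transfers and the resident species keeps its identity (gene-specific
#'   sweep). Requires `p_m + p_h <= 1`; any remainder is a per-step no-op.
#' @param omega Arrival frequency of new beneficial genes per step (>= 0).
#' @param arrival_mode One of `"none"`, `"single"`, `"periodic"`,
#'   `"poisson"`.
#' @param n_steps Integer run horizon in elementary steps.
#' @param record_every Trajectory sampling stride in steps (default `M`,
#'   i.e. one record per meta-generation).
#' @param seed Optional integer seed; when non-`NULL`, run functions call
#'   `set.seed(seed)` on entry so a run is fully determined by
#'   `(params, seed)`.
#'
#' @return An object of class `"model_params"` (a validated list).
#' @examples
#' p <- model_params(M = 1000, nu = 0.01, n_steps = 1e4)
#' @export
model_params <- function(M, nu = 0, p_m = 0, p_h = 0, omega = 0,
                         arrival_mode = c("none", "single", "periodic", "poisson"),
                         n_steps, record_every = M, seed = NULL) {
  arrival_mode <- match.arg(arrival_mode)
  M <- as.integer(M)
  if (is.na(M) || M < 2L) stop("`M` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(nu) || nu < 0 || nu >= 1) stop("`nu` must lie in [0, 1)", call. = FALSE)
  if (p_m < 0 || p_h < 0 || p_m + p_h > 1 + 1e-12)
    stop("need p_m >= 0, p_h >= 0 and p_m + p_h <= 1", call. = FALSE)
  if (omega < 0) stop("`omega` must be >= 0", call. = FALSE)
  if (arrival_mode %in% c("periodic", "poisson") && omega <= 0)
    stop("`omega` must be > 0 for periodic or poisson arrivals", call. = FALSE)
  n_steps <- floor(n_steps)
  if (n_steps < 1) stop("`n_steps` must be >= 1", call. = FALSE)
  record_every <- floor(record_every)
  if (record_every < 1) stop("`record_every` must be >= 1", call. = FALSE)
  structure(
    list(M = M, nu = nu, p_m = p_m, p_h = p_h, omega = omega,
         arrival_mode = arrival_mode, n_steps = n_steps,
         record_every = record_every, seed = seed),
    class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  M = %d patches; nu = %g; p_m = %g; p_h = %g\n",
              x$M, x$nu, x$p_m, x$p_h))
  cat(sprintf("  arrivals: %s (omega = %g); horizon %g steps (%.1f gen), stride %d\n",
              x$arrival_mode, x$omega, x$n_steps, x$n_steps / x$M, x$record_every))
  invisible(x)
}

#' Microscopic within-patch rates
#'
#' The per-step sweep probabilities of the patch-level model arise from
#' microscopic within-patch dynamics: a beneficial mutation with selective
#' advantage `s` in a patch of `N` individuals fixes with probability
#' about `s`, so basal migration and HGT attempt rates `mu_m`, `mu_h`
#' (per generation) yield effective sweep rates `p_m = s * mu_m` and
#' `p_h = s * mu_h`. `mu_I` is the basal arrival rate of new species.
#'
#' @param N Within-patch population size (>= 2).
#' @param s Selection coefficient, `0 < s < 1`.
#' @param mu_m,mu_h,mu_I Basal migration, HGT and innovation rates per
#'   generation (all >= 0).
#' @return An object of class `"micro_rates"`.
#' @seealso [effective_rates()], [validate_timescale_separation()]
#' @export
micro_rates <- function(N, s, mu_m, mu_h, mu_I) {
  if (N < 2) stop("`N` must be >= 2", call. = FALSE)
  if (s <= 0 || s >= 1) stop("`s` must lie in (0, 1)", call. = FALSE)
  if (any(c(mu_m, mu_h, mu_I) < 0)) stop("rates must be >= 0", call. = FALSE)
  structure(list(N = N, s = s, mu_m = mu_m, mu_h = mu_h, mu_I = mu_I),
            class = "micro_rates")
}

#' Effective patch-level sweep probabilities from microscopic rates
#'
#' Maps basal migration/HGT rates and the within-patch fixation
#' probability `s` onto the per-step probabilities of the patch model:
#' `p_m = s * mu_m`, `p_h = s * mu_h`.
#'
#' @param micro A [micro_rates()] object.
#' @return Named numeric vector `c(p_m = , p_h = )`.
#' @examples
#' effective_rates(micro_rates(1e6, 0.1, 0.5, 0.1, 0.1))
#' @export
effective_rates <- function(micro) {
  stopifnot(inherits(micro, "micro_rates"))
  p_m <- micro$s * micro$mu_m
  p_h <- micro$s * micro$mu_h
  if (p_m + p_h > 1)
    stop("s * mu_m + s * mu_h exceeds 1; cannot be treated as per-step probabilities",
         call. = FALSE)
  c(p_m = p_m, p_h = p_h)
}

#' Check the time-scale separation behind the patch-level model
#'
#' The patch-level description assumes three well-separated processes:
#' within-patch fixation of beneficial mutations (rate ~ `s / log(N s)`),
#' migration/HGT sweeps across patches (rates `s * mu_m`, `s * mu_h`), and
#' neutral turnover / innovation (rates `mu_m / N`, `mu_I / N`), together
#' with `1/N << s << 1` and `mu_I, mu_m, mu_h << 1 / log(N s)`.
#'
#' Strict inequalities are operationalized as a ratio of at least
#' `separation_factor` (default 10); "approximately equal" as a ratio
#' within `[1/separation_factor, separation_factor]`.
#'
#' @param micro A [micro_rates()] object.
#' @param separation_factor Ratio (> 1) required for `<<` / `>>`.
#' @return Character vector of violated inequalities (empty when the
#'   separation holds at the given factor).
#' @examples
#' validate_timescale_separation(micro_rates(1e6, 1e-2, 1e-4, 1e-4, 1e-4))
#' @export
validate_timescale_separation <- function(micro, separation_factor = 10) {
  stopifnot(inherits(micro, "micro_rates"))
  if (separation_factor <= 1) stop("`separation_factor` must be > 1", call. = FALSE)
  N <- micro$N; s <- micro$s
  mu_m <- micro$mu_m; mu_h <- micro$mu_h; mu_I <- micro$mu_I
  if (N * s <= 1)
    stop("N * s <= 1: log(N s) is not positive, the sweep regime is undefined",
         call. = FALSE)
  f <- separation_factor
  lNs <- log(N * s)
  out <- character(0)
  much_less <- function(a, b) {
    if (a == 0) return(b > 0)
    r <- b / a
    is.finite(r) && r >= f
  }
  approx_eq <- function(a, b) {
    if (a == 0 && b == 0) return(TRUE)
    r <- a / b
    is.finite(r) && r >= 1 / f && r <= f
  }
  if (!much_less(1 / N, s)) out <- c(out, "1/N << s")
  if (!much_less(s, 1)) out <- c(out, "s << 1")
  if (mu_m > 0 && !much_less(s * mu_m, s / lNs))
    out <- c(out, "s*mu_m << s/log(Ns)")
  if (mu_h > 0 && !much_less(s * mu_h, s / lNs))
    out <- c(out, "s*mu_h << s/log(Ns)")
  if (!approx_eq(s * mu_m, s * mu_h)) out <- c(out, "s*mu_m ~ s*mu_h")
  if (mu_m > 0 && !much_less(mu_m / N, s * mu_m))
    out <- c(out, "mu_m/N << s*mu_m")
  if (mu_I > 0 && mu_h > 0 && !much_less(mu_I / N, s * mu_h))
    out <- c(out, "mu_I/N << s*mu_h")
  if (!approx_eq(mu_m / N, mu_I / N)) out <- c(out, "mu_m/N ~ mu_I/N")
  for (nm in c("mu_I", "mu_m", "mu_h")) {
    v <- micro[[nm]]
    if (v > 0 && !much_less(v, 1 / lNs)) out <- c(out, paste0(nm, " << 1/log(Ns)"))
  }
  out
}
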