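# Long-horizon runners backed by the compiled engine.

.mode_code <- c(neutral = 0L, sweep = 1L, full = 2L)

# Low-level wrapper around the compiled event loop. Returns the raw engine
# output plus a reconstructed metacommunity_state.
.engine_run <- function(state, mode, nu = 0, p_m = 0, p_h = 0, n_steps,
                        record_every = 1, arrival_steps = numeric(0),
                        stop_at_fixation = FALSE) {
  res <- cpp_run(state$patch_species, state$patch_carrier, state$next_label,
                 as.numeric(state$step), state$arrivals_seen,
                 .mode_code[[mode]], nu, p_m, p_h,
                 as.numeric(n_steps), as.numeric(record_every),
                 as.numeric(arrival_steps), isTRUE(stop_at_fixation))
  new_state <- .new_state(res$species, res$carrier, res$next_label,
                          step = res$step, arrivals_seen = res$arrivals_seen)
  list(records = res$records, episodes = res$episodes, state = new_state,
       steps_done = res$steps_done, start_step = state$step)
}

.as_trajectory <- function(records, start_step, M, arrivals_offset = 0L) {
  step <- records$step + start_step
  tibble::tibble(
    step = step,
    generation = step / M,
    S = records$S,
    B = records$B,
    arrivals_seen = records$arrivals_seen + arrivals_offset)
}

.as_episodes <- function(episodes, start_step, M) {
  tibble::tibble(
    start_step = episodes$start_step + start_step,
    end_step = episodes$end_step + start_step,
    S_start = episodes$S_start,
    S_min = episodes$S_min,
    S_min_all = episodes$S_min_all,
    S_max = episodes$S_max,
    S_mean = episodes$S_mean,
    S_end = episodes$S_end,
    S_fix = episodes$S_fix,
    fixation_step = episodes$fixation_step + start_step,
    fixation_gen = (episodes$fixation_step + start_step) / M,
    truncated = episodes$truncated == 1L)
}

.msweep_run <- function(model, params, trajectory, episodes, state) {
  structure(list(model = model, params = params, trajectory = trajectory,
                 episodes = episodes, state = state),
            class = "msweep_run")
}

#' @export
print.msweep_run <- function(x, ...) {
  cat(sprintf("<msweep_run: %s model> %d trajectory records, %d episode(s)\n",
              x$model, nrow(x$trajectory),
              if (is.null(x$episodes)) 0L else nrow(x$episodes)))
  print(x$state)
  invisible(x)
}

#' Simulate the neutral diversity-maintenance model
#'
#' Runs the infinite-allele neutral model (innovation at rate `nu`,
#' neutral migration-sweeps otherwise) for `params$n_steps` steps from a
#' monomorphic metacommunity (`S(0) = 1`), sampling the trajectory every
#' `params$record_every` steps. Diversity relaxes to a plateau with mean
#' [expected_diversity_exact()] on the time scale [tau_eq()].
#'
#' @param params A [model_params()] object with `arrival_mode = "none"`.
#' @param init_state Optional starting `metacommunity_state` (default
#'   monomorphic).
#' @return An object of class `"msweep_run"` with elements `trajectory`
#'   (a tibble: `step`, `generation`, `S`, `B`, `arrivals_seen`) and
#'   `state` (the final state).
#' @examples
#' p <- model_params(M = 200, nu = 0.05, n_steps = 2e4, seed = 1)
#' run <- run_neutral(p)
#' tail(run$trajectory)
#' @export
run_neutral <- function(params, init_state = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (params$arrival_mode != "none")
    stop("the neutral model has no gene arrivals; use run_full()", call. = FALSE)
  if (!is.null(params$seed)) set.seed(params$seed)
  state <- if (is.null(init_state)) new_monomorphic_state(params$M) else init_state
  res <- .engine_run(state, "neutral", nu = params$nu,
                     n_steps = params$n_steps,
                     record_every = params$record_every)
  .msweep_run("neutral", params,
              .as_trajectory(res$records, res$start_step, params$M),
              NULL, res$state)
}

#' Run the pure gene-sweep model until fixation
#'
#' Iterates [sweep_step()] dynamics from a state carrying the gene on one
#' patch until every patch carries it (`B = M`, the absorbing state) or
#' `max_steps` elapse. No innovation acts, so `S(t)` is non-increasing and
#' `B(t)` non-decreasing; the residual diversity at fixation is `S_f`.
#'
#' @param state A `metacommunity_state` with `B >= 1` (see
#'   [introduce_gene()]).
#' @param p_m,p_h Sweep probabilities, `p_m + p_h <= 1`, with
#'   `p_m + p_h > 0` unless `max_steps` is finite.
#' @param record_every Trajectory stride in steps (default `M`).
#' @param max_steps Step budget; default `50 * tau_fix(M, p_m, p_h)`.
#' @return A list with `trajectory`, `summary` (a tibble row: `S_i`,
#'   `S_f`, `S_min`, `fixation_step` counted from entry, `truncated`) and
#'   the final `state`.
#' @examples
#' set.seed(2)
#' st <- introduce_gene(sample_equilibrium_state(200, 0.02))
#' run_until_fixation(st, p_m = 0.9, p_h = 0.1)$summary
#' @export
run_until_fixation <- function(state, p_m, p_h,
                               record_every = length(state$patch_species),
                               max_steps = NULL) {
  stopifnot(inherits(state, "metacommunity_state"))
  if (carrier_count(state) < 1)
    stop("no beneficial gene present; call introduce_gene() first", call. = FALSE)
  M <- length(state$patch_species)
  if (is.null(max_steps)) {
    if (p_m + p_h <= 0)
      stop("p_m + p_h = 0: fixation never occurs; give `max_steps`", call. = FALSE)
    max_steps <- ceiling(50 * tau_fix(M, p_m, p_h))
  }
  res <- .engine_run(state, "sweep", p_m = p_m, p_h = p_h,
                     n_steps = max_steps, record_every = record_every,
                     stop_at_fixation = TRUE)
  ep <- res$episodes
  fixed <- !is.na(ep$fixation_step[1])
  summary <- tibble::tibble(
    S_i = ep$S_start[1],
    S_f = if (fixed) ep$S_fix[1] else ep$S_end[1],
    S_min = ep$S_min[1],
    fixation_step = ep$fixation_step[1],
    truncated = !fixed)
  list(trajectory = .as_trajectory(res$records, res$start_step, M),
       summary = summary, state = res$state)
}

#' Schedule beneficial-gene arrival times
#'
#' @param omega Arrival frequency per step (> 0 for periodic/poisson).
#' @param mode `"none"`, `"single"`, `"periodic"` or `"poisson"`.
#' @param horizon Run length in steps.
#' @return Sorted numeric vector of 0-based arrival steps within
#'   `[0, horizon]`: `single` is `0`; `periodic` is multiples of
#'   `round(1/omega)`; `poisson` accumulates geometric gaps with mean
#'   `1/omega` (drawn from the current RNG stream).
#' @export
schedule_arrivals <- function(omega, mode = c("none", "single", "periodic", "poisson"),
                              horizon, ...) {
  mode <- match.arg(mode)
  if (mode == "none") return(numeric(0))
  if (mode == "single") return(0)
  if (!is.numeric(omega) || omega <= 0)
    stop("`omega` must be > 0 for periodic or poisson arrivals", call. = FALSE)
  if (mode == "periodic") {
    gap <- max(1, round(1 / omega))
    return(seq(0, horizon, by = gap))
  }
  # poisson: geometric inter-arrival gaps with mean 1/omega
  expected <- horizon * omega
  out <- numeric(0)
  t <- 0
  repeat {
    n_draw <- max(16L, ceiling(2 * expected))
    gaps <- rgeom(n_draw, prob = min(omega, 1)) + 1
    times <- t + cumsum(gaps)
    out <- c(out, times[times <= horizon])
    if (length(times) == 0 || times[length(times)] > horizon) break
    t <- times[length(times)]
  }
  out
}

#' Simulate the full competing-time-scales model
#'
#' Interleaves [full_step()] dynamics (innovation, neutral migration,
#' selective migration-sweep, HGT-sweep) with scheduled beneficial-gene
#' arrivals. Each arrival clears all carrier flags (the newest gene
#' carries the highest benefit) and seeds one random patch. One episode
#' summary is produced per inter-arrival window, reporting the diversity
#' drop (`S_min`, taken up to fixation when the gene fixes within the
#' window), the recovery peak (`S_max`), the time-averaged `S_mean` and
#' the fixation step if any.
#'
#' @param params A [model_params()] object.
#' @param init_state Optional starting state; by default the neutral
#'   equilibrium at `params$nu` drawn by [sample_equilibrium_state()]
#'   (required explicitly when `nu = 0`).
#' @return An `"msweep_run"` with `trajectory`, `episodes` (a tibble) and
#'   the final `state`.
#' @examples
#' p <- model_params(M = 200, nu = 0.02, p_m = 0.9, p_h = 0.1,
#'                   arrival_mode = "single", n_steps = 3e4, seed = 3)
#' run <- run_full(p)
#' run$episodes
#' @export
run_full <- function(params, init_state = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  if (is.null(init_state)) {
    if (params$nu <= 0)
      stop("with nu = 0 an explicit `init_state` is required", call. = FALSE)
    init_state <- sample_equilibrium_state(params$M, params$nu)
  }
  arrivals <- schedule_arrivals(params$omega, params$arrival_mode, params$n_steps)
  res <- .engine_run(init_state, "full", nu = params$nu,
                     p_m = params$p_m, p_h = params$p_h,
                     n_steps = params$n_steps,
                     record_every = params$record_every,
                     arrival_steps = arrivals)
  .msweep_run("full", params,
              .as_trajectory(res$records, res$start_step, params$M),
              .as_episodes(res$episodes, res$start_step, params$M),
              res$state)
}
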