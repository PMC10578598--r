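# Single-step updates in pure R.
#
# These consume exactly the same uniform draws, in the same order, as the
# compiled engine in src/engine.cpp, so that an R-level loop and cpp_run()
# produce identical states from the same seed. The long-horizon run_*()
# functions use the engine; these are the reference semantics.

#' One step of the neutral (diversity-maintenance) model
#'
#' With probability `nu` a uniformly chosen focal patch is swept by a
#' brand-new species (innovation); otherwise the focal patch's species
#' migrates and neutrally sweeps a uniformly chosen *other* patch,
#' replacing its resident.
#'
#' @param state A `metacommunity_state`.
#' @param nu Innovation probability per step, in `[0, 1)`.
#' @return The updated state; the event is attached as attribute
#'   `"event"` (a list with `type` and patch indices).
#' @export
neutral_step <- function(state, nu) {
  M <- length(state$patch_species)
  if (runif(1) < nu) {
    i <- .pick(M) + 1L
    state <- .innovate(state, i, FALSE)
    ev <- list(type = "innovation", i = i)
  } else {
    i <- .pick(M) + 1L
    j <- .pick_other(i - 1L, M) + 1L
    state <- .replace_species(state, j, state$patch_species[i])
    ev <- list(type = "neutral_migration", i = i, j = j)
  }
  state$step <- state$step + 1
  attr(state, "event") <- ev
  state
}

#' One step of the pure gene-sweep model
#'
#' An ordered patch pair `(i, j)`, `i != j`, is drawn uniformly. Only
#' carrier -> non-carrier pairs trigger events: with probability `p_m` the
#' carrier's species invades patch `j` (migration-sweep, diversity may
#' drop); otherwise with probability `p_h` the gene alone transfers
#' (HGT-sweep, diversity preserved). All other configurations are no-ops,
#' so carriers are never displaced.
#'
#' @param state A `metacommunity_state`.
#' @param p_m,p_h Sweep probabilities, `p_m + p_h <= 1`.
#' @return The updated state with the `"event"` attribute.
#' @export
sweep_step <- function(state, p_m, p_h) {
  if (p_m + p_h > 1 + 1e-12) stop("p_m + p_h must be <= 1", call. = FALSE)
  M <- length(state$patch_species)
  i <- .pick(M) + 1L
  j <- .pick_other(i - 1L, M) + 1L
  ev <- list(type = "noop", i = i, j = j)
  if (state$patch_carrier[i] && !state$patch_carrier[j]) {
    u <- runif(1)
    if (u < p_m) {
      state <- .replace_species(state, j, state$patch_species[i])
      state$patch_carrier[j] <- TRUE
      ev$type <- "migration_sweep"
    } else if (u < p_m + p_h) {
      state$patch_carrier[j] <- TRUE
      ev$type <- "hgt_sweep"
    }
  }
  state$step <- state$step + 1
  attr(state, "event") <- ev
  state
}

#' One step of the full competing-time-scales model
#'
#' With probability `nu`, innovation: a uniform focal patch receives a
#' brand-new species whose carrier status is Bernoulli with success
#' probability `B/M` (the current carrier fraction). Otherwise an ordered
#' pair `(i, j)` is drawn: same carrier status -> neutral migration-sweep
#' (patch `j` adopts `i`'s species, gene status unchanged);
#' carrier -> non-carrier -> selective migration-sweep with probability
#' `p_m` or HGT-sweep with probability `p_h`; non-carrier -> carrier is a
#' no-op.
#'
#' @param state A `metacommunity_state`.
#' @param nu Innovation probability per step.
#' @param p_m,p_h Sweep probabilities, `p_m + p_h <= 1`.
#' @return The updated state with the `"event"` attribute.
#' @export
full_step <- function(state, nu, p_m, p_h) {
  if (p_m + p_h > 1 + 1e-12) stop("p_m + p_h must be <= 1", call. = FALSE)
  M <- length(state$patch_species)
  B <- carrier_count(state)
  if (runif(1) < nu) {
    i <- .pick(M) + 1L
    flag <- FALSE
    if (B > 0) flag <- if (B == M) TRUE else runif(1) < B / M
    state <- .innovate(state, i, flag)
    ev <- list(type = "innovation", i = i, carrier = flag)
  } else {
    i <- .pick(M) + 1L
    j <- .pick_other(i - 1L, M) + 1L
    ci <- state$patch_carrier[i]; cj <- state$patch_carrier[j]
    if (ci == cj) {
      state <- .replace_species(state, j, state$patch_species[i])
      ev <- list(type = "neutral_migration", i = i, j = j)
    } else if (ci && !cj) {
      u <- runif(1)
      ev <- list(type = "noop", i = i, j = j)
      if (u < p_m) {
        state <- .replace_species(state, j, state$patch_species[i])
        state$patch_carrier[j] <- TRUE
        ev$type <- "migration_sweep"
      } else if (u < p_m + p_h) {
        state$patch_carrier[j] <- TRUE
        ev$type <- "hgt_sweep"
      }
    } else {
      ev <- list(type = "noop", i = i, j = j)
    }
  }
  state$step <- state$step + 1
  attr(state, "event") <- ev
  state
}
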