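#' Metacommunity state
#'
#' A metacommunity state records, for each of the `M` patches, the integer
#' label of its resident species and whether that resident carries the
#' (newest) beneficial gene, plus incremental bookkeeping: a species
#' occupancy table (`species_counts`, label -> number of patches), a fresh
#' label counter for the infinite-allele species supply, the elapsed step
#' count and the number of beneficial-gene arrivals seen.
#'
#' @name metacommunity_state
#' @keywords internal
NULL

# build a state from raw vectors (labels 0-based integers)
.new_state <- function(patch_species, patch_carrier, next_label,
                       step = 0, arrivals_seen = 0L) {
  patch_species <- as.integer(patch_species)
  tab <- table(patch_species)
  counts <- stats::setNames(as.integer(tab), names(tab))
  structure(
    list(patch_species = patch_species,
         patch_carrier = as.logical(patch_carrier),
         species_counts = counts,
         next_label = as.integer(next_label),
         step = step,
         arrivals_seen = as.integer(arrivals_seen)),
    class = "metacommunity_state")
}

#' Monomorphic initial state
#'
#' All `M` patches share a single species (label 0) and no patch carries a
#' beneficial gene: `S = 1`, `B = 0`.
#'
#' @param M Integer number of patches (>= 2).
#' @return A `metacommunity_state`.
#' @examples
#' st <- new_monomorphic_state(10)
#' diversity(st)
#' @export
new_monomorphic_state <- function(M) {
  M <- as.integer(M)
  if (is.na(M) || M < 2L) stop("`M` must be an integer >= 2", call. = FALSE)
  .new_state(rep(0L, M), rep(FALSE, M), next_label = 1L)
}

#' Sample the neutral-model equilibrium state
#'
#' Draws a species partition of the `M` patches from the stationary
#' distribution of the infinite-allele neutral model with innovation rate
#' `nu`, whose abundance spectrum is the Ewens sampling formula with
#' concentration `theta = (M - 1) * nu / (1 - nu)`. The default method is
#' the sequential Chinese-restaurant construction (exact and O(M)); a
#' burn-in alternative runs the neutral dynamics from a monomorphic state
#' for `burnin_factor * M / nu` steps.
#'
#' @param M Integer number of patches (>= 2).
#' @param nu Innovation rate, `0 < nu < 1`.
#' @param method `"crp"` (default) or `"burnin"`.
#' @param burnin_factor Burn-in length in units of the equilibration time
#'   `M / nu` steps (default 5).
#' @return A `metacommunity_state` with no carriers.
#' @examples
#' set.seed(1)
#' diversity(sample_equilibrium_state(1000, 0.01))
#' @export
sample_equilibrium_state <- function(M, nu, method = c("crp", "burnin"),
                                     burnin_factor = 5) {
  method <- match.arg(method)
  M <- as.integer(M)
  if (is.na(M) || M < 2L) stop("`M` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(nu) || nu <= 0 || nu >= 1)
    stop("`nu` must lie in (0, 1)", call. = FALSE)
  if (method == "burnin") {
    st <- new_monomorphic_state(M)
    res <- .engine_run(st, mode = "neutral", nu = nu,
                       n_steps = ceiling(burnin_factor * M / nu),
                       record_every = 0)
    st <- res$state
    st$step <- 0
    return(st)
  }
  theta <- ewens_theta(M, nu)
  labels <- integer(M)
  labels[1] <- 0L
  next_label <- 1L
  for (k in 2:M) {
    if (runif(1) < theta / (theta + k - 1)) {
      labels[k] <- next_label
      next_label <- next_label + 1L
    } else {
      labels[k] <- labels[.pick(k - 1L) + 1L]
    }
  }
  labels <- labels[sample.int(M)]  # patches are exchangeable
  .new_state(labels, rep(FALSE, M), next_label = next_label)
}

#' Number of distinct species in a state
#'
#' O(1) via the incremental occupancy table.
#'
#' @param state A `metacommunity_state`.
#' @return Integer diversity `S`, `1 <= S <= M`.
#' @export
diversity <- function(state) {
  stopifnot(inherits(state, "metacommunity_state"))
  length(state$species_counts)
}

#' Number of patches carrying the beneficial gene
#'
#' @param state A `metacommunity_state`.
#' @return Integer carrier count `B`, `0 <= B <= M`.
#' @export
carrier_count <- function(state) {
  stopifnot(inherits(state, "metacommunity_state"))
  sum(state$patch_carrier)
}

#' Introduce a single beneficial gene
#'
#' Marks exactly one patch (given, or uniformly random) as carrying the
#' beneficial gene. Requires a gene-free state (`B = 0`).
#'
#' @param state A `metacommunity_state` with no carriers.
#' @param patch Optional 1-based patch index; default uniform random.
#' @return The updated state with `B = 1`.
#' @export
introduce_gene <- function(state, patch = NULL) {
  stopifnot(inherits(state, "metacommunity_state"))
  if (carrier_count(state) > 0)
    stop("beneficial gene already present (B > 0)", call. = FALSE)
  M <- length(state$patch_species)
  if (is.null(patch)) patch <- .pick(M) + 1L
  if (patch < 1 || patch > M) stop("`patch` out of range", call. = FALSE)
  state$patch_carrier[patch] <- TRUE
  state
}

#' Arrival of a new (fitter) beneficial gene
#'
#' The newest gene always carries the highest beneficial effect, so older
#' genes become dynamically inert: all carrier flags are cleared and one
#' uniformly random patch seeds the new gene. Species labels are untouched
#' (`S` unchanged); the arrival counter is incremented.
#'
#' @param state A `metacommunity_state`.
#' @return The updated state with `B = 1`.
#' @export
apply_gene_arrival <- function(state) {
  stopifnot(inherits(state, "metacommunity_state"))
  M <- length(state$patch_species)
  state$patch_carrier[] <- FALSE
  state$patch_carrier[.pick(M) + 1L] <- TRUE
  state$arrivals_seen <- state$arrivals_seen + 1L
  state
}

#' @export
print.metacommunity_state <- function(x, ...) {
  M <- length(x$patch_species)
  cat(sprintf("<metacommunity_state> M = %d, S = %d, B = %d, step = %g, arrivals = %d\n",
              M, diversity(x), carrier_count(x), x$step, x$arrivals_seen))
  invisible(x)
}

# ---- internal sampling primitives (mirrored exactly in the C++ engine) ----

# uniform 0-based index in 0..(M-1)
.pick <- function(M) {
  k <- as.integer(floor(runif(1) * M))
  if (k >= M) M - 1L else k
}

# uniform 0-based index over the M-1 values != i0 (i0 0-based)
.pick_other <- function(i0, M) {
  k <- as.integer(floor(runif(1) * (M - 1)))
  if (k >= M - 1L) k <- M - 2L
  k + (k >= i0)
}

# patch j (1-based) adopts species label `lab`, updating the occupancy table
.replace_species <- function(state, j, lab) {
  old <- state$patch_species[j]
  if (old == lab) return(state)
  cnt <- state$species_counts
  ko <- as.character(old); kn <- as.character(lab)
  cnt[[ko]] <- cnt[[ko]] - 1L
  if (cnt[[ko]] == 0L) cnt <- cnt[names(cnt) != ko]
  if (kn %in% names(cnt)) cnt[[kn]] <- cnt[[kn]] + 1L else cnt[kn] <- 1L
  state$species_counts <- cnt
  state$patch_species[j] <- lab
  state
}

# innovation at patch i (1-based): fresh label, carrier flag set to `flag`
.innovate <- function(state, i, flag) {
  lab <- state$next_label
  state <- .replace_species(state, i, lab)
  state$next_label <- lab + 1L
  state$patch_carrier[i] <- flag
  state
}
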