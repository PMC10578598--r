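# shared helpers: independent recount oracle, ad-hoc state builder, SE

recount_diversity <- function(state) length(unique(state$patch_species))

# state from explicit label/carrier vectors (labels non-negative integers)
mk_state <- function(species, carrier = rep(FALSE, length(species))) {
  metasweep:::.new_state(as.integer(species), carrier,
                         next_label = max(species) + 1L)
}

se <- function(x) stats::sd(x) / sqrt(length(x))

# mean S_f/S_i of the pure sweep model over replicates with CRP initial
# conditions; seeds are base + 1..n
sweep_ratio_ensemble <- function(n, M, nu, p_m, p_h, base_seed) {
  vapply(seq_len(n), function(r) {
    set.seed(base_seed + r)
    st <- introduce_gene(sample_equilibrium_state(M, nu))
    s <- run_until_fixation(st, p_m, p_h, record_every = 0)$summary
    s$S_f / s$S_i
  }, numeric(1))
}
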