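test_that("fundamental biodiversity number and time scales evaluate correctly", {
  expect_equal(ewens_theta(10000, 0.01), 9999 * 0.01 / 0.99)
  expect_equal(ewens_theta(100, 0), 0)
  expect_equal(ewens_theta(2, 0.5), 1)
  expect_error(ewens_theta(100, 1), "nu")

  expect_equal(tau_eq(10000, 0.01), 1e6)
  expect_equal(tau_eq(1000, 0.01), 1e5)
  expect_equal(tau_eq(1000, 0.02), tau_eq(1000, 0.01) / 2)
  expect_error(tau_eq(1000, 0), "nu")
})

test_that("exact, integral and small-nu diversity formulas are consistent", {
  # two-term sum with theta = 1: 1 + 1/2
  expect_equal(expected_diversity_exact(2, 0.5), 1.5)
  # integral approximation theta * log((M - 1 + theta)/theta) within 2%
  th <- ewens_theta(1e4, 0.01)
  integral <- th * log((1e4 - 1 + th) / th)
  expect_lt(abs(expected_diversity_exact(1e4, 0.01) - integral) / integral, 0.02)
  # closed form -M nu log(nu)
  expect_equal(expected_diversity_approx(1e4, 0.01), -1e4 * 0.01 * log(0.01))
  expect_equal(expected_diversity_approx(2722, exp(-1)), 2722 * exp(-1))
  # approximation error below 5% deep in the M >> 1, nu << 1 regime
  ex <- expected_diversity_exact(1e4, 1e-3)
  ap <- expected_diversity_approx(1e4, 1e-3)
  expect_lt(abs(ap - ex) / ex, 0.05)
})

test_that("Ewens abundance spectrum obeys its summation identities", {
  M <- 500; nu <- 0.02
  spec <- ewens_expected_abundance(M, nu, 1:M)
  expect_true(all(spec >= 0))
  expect_lt(abs(sum((1:M) * spec) - M) / M, 1e-8)          # patch conservation
  expect_lt(abs(sum(spec) - expected_diversity_exact(M, nu)) /
              expected_diversity_exact(M, nu), 1e-8)
  # decreasing beyond the mode
  mode_n <- which.max(spec)
  expect_true(all(diff(spec[mode_n:M]) <= 1e-12))
  # two-patch enumeration: <S(2)> = 1/2, <S(1)> = 1 at theta = 1
  expect_equal(ewens_expected_abundance(2, 0.5, 2), 0.5)
  expect_equal(ewens_expected_abundance(2, 0.5, 1), 1)
  expect_error(ewens_expected_abundance(10, 0.1, 11), "n")
})

test_that("single neutral steps innovate or copy as specified", {
  set.seed(21)
  st <- new_monomorphic_state(10)
  s1 <- neutral_step(st, 1 - 1e-12)      # innovation forced
  expect_equal(diversity(s1), 2)
  expect_equal(attr(s1, "event")$type, "innovation")

  s0 <- neutral_step(st, 0)              # copy within a monomorphic state
  expect_equal(s0$patch_species, st$patch_species)
  expect_equal(s0$step, 1)

  # M = 2 with distinct species and nu = 0: either ordered pair merges them
  two <- mk_state(c(0, 1))
  s2 <- neutral_step(two, 0)
  expect_equal(diversity(s2), 1)
})

test_that("nu = 0 makes the monomorphic state absorbing", {
  set.seed(22)
  st <- sample_equilibrium_state(100, 0.05)
  res <- metasweep:::.engine_run(st, "neutral", nu = 0, n_steps = 5e4,
                                 record_every = 500)
  S <- res$records$S
  expect_true(all(diff(S) <= 0))
  expect_equal(S[length(S)], 1)
})

test_that("compiled engine reproduces the R reference dynamics draw-for-draw", {
  st <- new_monomorphic_state(40)
  # neutral
  set.seed(23); a <- st; for (k in 1:300) a <- neutral_step(a, 0.08)
  set.seed(23); b <- metasweep:::.engine_run(st, "neutral", nu = 0.08,
                                             n_steps = 300, record_every = 0)$state
  expect_identical(a$patch_species, b$patch_species)
  expect_identical(a$next_label, b$next_label)
  ord <- function(cnt) cnt[order(as.integer(names(cnt)))]
  expect_equal(ord(a$species_counts), ord(b$species_counts))
  # sweep
  set.seed(24); g0 <- introduce_gene(sample_equilibrium_state(40, 0.1), patch = 5)
  a <- g0; for (k in 1:300) a <- sweep_step(a, 0.7, 0.2)
  set.seed(24); g1 <- introduce_gene(sample_equilibrium_state(40, 0.1), patch = 5)
  b <- metasweep:::.engine_run(g1, "sweep", p_m = 0.7, p_h = 0.2,
                               n_steps = 300, record_every = 0)$state
  expect_identical(a$patch_species, b$patch_species)
  expect_identical(a$patch_carrier, b$patch_carrier)
  # full
  set.seed(25); g0 <- introduce_gene(sample_equilibrium_state(40, 0.1), patch = 2)
  a <- g0; for (k in 1:300) a <- full_step(a, 0.05, 0.6, 0.2)
  set.seed(25); g1 <- introduce_gene(sample_equilibrium_state(40, 0.1), patch = 2)
  b <- metasweep:::.engine_run(g1, "full", nu = 0.05, p_m = 0.6, p_h = 0.2,
                               n_steps = 300, record_every = 0)$state
  expect_identical(a$patch_species, b$patch_species)
  expect_identical(a$patch_carrier, b$patch_carrier)
  expect_identical(a$next_label, b$next_label)
})

test_that("diversity relaxes to the Ewens stationary mean across innovation rates", {
  M <- 1000
  for (nu in c(0.005, 0.01, 0.02)) {
    n_steps <- ceiling(3 * M / nu)
    late <- vapply(1:40, function(r) {
      p <- model_params(M, nu = nu, n_steps = n_steps, record_every = M,
                        seed = 3100 + r)
      tr <- run_neutral(p)$trajectory
      mean(tr$S[tr$step >= 2 / 3 * n_steps])
    }, numeric(1))
    expect_lt(abs(mean(late) - expected_diversity_exact(M, nu)), 3 * se(late))
  }
})

test_that("equilibration completes on the M/nu time scale for every nu", {
  # by tau = t * nu / M of order one the rescaled mean curves coincide
  M <- 1000
  taus <- seq(1.2, 3, by = 0.2)
  curves <- lapply(c(0.005, 0.01, 0.02), function(nv) {
    stride <- round(0.05 * M / nv)
    S0 <- expected_diversity_exact(M, nv)
    mat <- vapply(1:60, function(r) {
      p <- model_params(M, nu = nv, n_steps = 60 * stride, record_every = stride,
                        seed = 3200 + r)
      tr <- run_neutral(p)$trajectory
      idx <- match(round(taus / 0.05), round(tr$step / stride))
      tr$S[idx] / S0
    }, numeric(length(taus)))
    list(mean = rowMeans(mat), se = apply(mat, 1, stats::sd) / sqrt(60))
  })
  for (a in 1:2) for (b in (a + 1):3) {
    gap <- abs(curves[[a]]$mean - curves[[b]]$mean)
    pooled <- sqrt(curves[[a]]$se^2 + curves[[b]]$se^2)
    expect_true(all(gap < 3 * pooled))
  }
})

test_that("late-time simulated diversity is distributed like the partition sampler", {
  M <- 200; nu <- 0.05
  late <- vapply(1:300, function(r) {
    p <- model_params(M, nu = nu, n_steps = 2e4, record_every = 2e4, seed = 3300 + r)
    tail(run_neutral(p)$trajectory$S, 1)
  }, numeric(1))
  set.seed(33)
  crp <- replicate(300, diversity(sample_equilibrium_state(M, nu)))
  expect_gt(suppressWarnings(stats::ks.test(late, crp)$p.value), 0.01)
})
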