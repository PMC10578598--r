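test_that("pair events sweep genomes or genes exactly as specified", {
  # forced migration-sweep: once the carrier -> non-carrier pair is drawn,
  # the resident of the target patch is displaced and diversity collapses
  set.seed(41)
  s <- mk_state(c(0, 1), carrier = c(TRUE, FALSE))
  while (carrier_count(s) < 2) s <- sweep_step(s, 1, 0)
  expect_equal(diversity(s), 1)
  expect_equal(carrier_count(s), 2)

  # forced HGT-sweep preserves both species
  s <- mk_state(c(0, 1), carrier = c(TRUE, FALSE))
  while (carrier_count(s) < 2) s <- sweep_step(s, 0, 1)
  expect_equal(diversity(s), 2)
  expect_equal(carrier_count(s), 2)

  # ordered pairs with the carrier second are no-ops: the carrier patch is
  # never displaced, and nothing changes until the (carrier, non-carrier)
  # ordering comes up
  s <- mk_state(c(0, 1), carrier = c(FALSE, TRUE))
  for (k in 1:30) {
    s2 <- sweep_step(s, 1, 0)
    ev <- attr(s2, "event")
    if (ev$type == "noop")
      expect_identical(s2$patch_species, s$patch_species)
    expect_true(s2$patch_carrier[2])
    expect_equal(s2$patch_species[2], 1L)
    s <- s2
  }
})

test_that("fixation is absorbing and the residual diversity obeys the limits", {
  # pure genome-wide sweeps erase all but the carrier lineage
  for (r in 1:15) {
    set.seed(4100 + r)
    st <- introduce_gene(sample_equilibrium_state(150, 0.05))
    out <- run_until_fixation(st, p_m = 1, p_h = 0, record_every = 0)
    expect_false(out$summary$truncated)
    expect_equal(out$summary$S_f, 1L)
    expect_equal(carrier_count(out$state), 150)
  }
  # pure gene-specific sweeps preserve every species
  for (r in 1:15) {
    set.seed(4200 + r)
    st <- introduce_gene(sample_equilibrium_state(150, 0.05))
    out <- run_until_fixation(st, p_m = 0, p_h = 0.5, record_every = 0,
                              max_steps = 1e6)
    expect_equal(out$summary$S_f, out$summary$S_i)
  }
})

test_that("empirical fixation times scale like the logistic prediction", {
  M <- 1000
  steps <- vapply(1:100, function(r) {
    set.seed(4300 + r)
    st <- introduce_gene(sample_equilibrium_state(M, 0.02))
    run_until_fixation(st, 0.8, 0.2, record_every = 0)$summary$fixation_step
  }, numeric(1))
  ratio <- mean(steps) / tau_fix(M, 0.8, 0.2)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
  # a starved step budget reports truncation instead of failing
  set.seed(43)
  st <- introduce_gene(sample_equilibrium_state(100, 0.05))
  out <- run_until_fixation(st, 0.5, 0.1, record_every = 0, max_steps = 10)
  expect_true(out$summary$truncated)
})

test_that("monotonicity during a sweep: B never falls, S never rises", {
  set.seed(44)
  st <- introduce_gene(sample_equilibrium_state(300, 0.02))
  out <- run_until_fixation(st, 0.7, 0.3, record_every = 300)
  expect_true(all(diff(out$trajectory$B) >= 0))
  expect_true(all(diff(out$trajectory$S) <= 0))
  expect_equal(tail(out$trajectory$B, 1), 300L)
})

test_that("logistic carrier curve satisfies its defining ODE and boundaries", {
  M <- 1000; p_m <- 0.9; p_h <- 0.1
  expect_equal(carriers_logistic(0, M, p_m, p_h), 1)
  tf <- tau_fix(M, p_m, p_h)
  expect_equal(carriers_logistic(tf, M, p_m, p_h), M - 1, tolerance = 1e-9)
  expect_equal(tau_fix(M, 0.45, 0.05), 2 * tau_fix(M, 0.9, 0.1))
  # central-difference residual against dB/dt = (pm+ph)(B/M)(1-B/M)
  tt <- seq(0.05, 1.2, by = 0.05) * tf
  h <- tf / 1e4
  num <- (carriers_logistic(tt + h, M, p_m, p_h) -
            carriers_logistic(tt - h, M, p_m, p_h)) / (2 * h)
  B <- carriers_logistic(tt, M, p_m, p_h)
  rhs <- (p_m + p_h) * (B / M) * (1 - B / M)
  expect_lt(max(abs(num - rhs) / rhs), 1e-4)
})

test_that("non-carrier decay matches adaptive ODE integration", {
  skip_if_not_installed("deSolve")
  M <- 1000; m0 <- 10; p_m <- 0.9; p_h <- 0.1
  expect_equal(noncarrier_species_decay(0, M, m0, p_m, p_h), m0)
  expect_equal(noncarrier_species_decay(c(0, 5e3, 1e7), M, m0, 0, 0.5),
               rep(m0, 3))
  tf <- tau_fix(M, p_m, p_h)
  sol <- deSolve::ode(
    y = c(D = m0), times = c(0, tf / 4, tf / 2, tf),
    func = function(t, y, parms) {
      list(-p_m * (carriers_logistic(t, M, p_m, p_h) / M) * y / M)
    }, parms = NULL, rtol = 1e-10, atol = 1e-12)
  ours <- noncarrier_species_decay(sol[, "time"], M, m0, p_m, p_h)
  expect_lt(max(abs(ours - sol[, "D"]) / pmax(sol[, "D"], 1e-12)), 1e-3)
  # decays to zero
  expect_lt(noncarrier_species_decay(50 * tf, M, m0, p_m, p_h), 1e-6)
})

test_that("expected HGT gains equal the quadrature of the gain rate", {
  expect_equal(expected_total_gains(5, 0.8, 0.2), 1.25)
  expect_equal(expected_total_gains(7, 0.4, 0), 0)
  expect_error(expected_total_gains(5, 0, 0.2), "p_m")
  M <- 1000; m0 <- 10; p_m <- 0.9; p_h <- 0.1
  quad <- stats::integrate(function(t) {
    p_h * (carriers_logistic(t, M, p_m, p_h) / M) *
      (noncarrier_species_decay(t, M, m0, p_m, p_h) / M)
  }, 0, 60 * tau_fix(M, p_m, p_h), rel.tol = 1e-9)$value
  expect_lt(abs(quad - expected_total_gains(m0, p_m, p_h)) /
              expected_total_gains(m0, p_m, p_h), 1e-3)
})

test_that("extinction probability follows the Poisson-gains closed form", {
  expect_equal(extinction_probability(10, 0.9, 0.1), exp(-10 / 9))
  expect_equal(extinction_probability(10, 0.5, 0), 1)
  expect_true(all(diff(extinction_probability(1:20, 0.9, 0.1)) < 0))
})

test_that("Fisher log series is a normalized occupancy distribution", {
  expect_equal(fisher_logseries_pmf(1, 0.01), 0.99 / log(100))
  m <- 1:1e6
  expect_lt(abs(sum(fisher_logseries_pmf(m, 0.01)) - 1), 1e-10)
  # agreement with the normalized Ewens spectrum at small occupancy
  M <- 1e4; nu <- 0.01
  ew <- ewens_expected_abundance(M, nu, 1:20)
  ew_norm <- ew / expected_diversity_exact(M, nu)
  fi <- fisher_logseries_pmf(1:20, nu)
  expect_lt(max(abs(fi - ew_norm) / ew_norm), 0.05)
})

test_that("sweep parameter Q0: worked values, limits, oracle and monotonicity", {
  expect_equal(sweep_parameter_Q0(0.01, 1, 0.1), 0.509, tolerance = 2e-3)
  expect_equal(sweep_parameter_Q0(0.02, 0.8, 0.2), 0.6317, tolerance = 1e-4)
  expect_equal(sweep_parameter_Q0(0.3, 0.5, 0), 0)     # no HGT: full genome sweep
  expect_equal(sweep_parameter_Q0(0.01, 0, 0.2), 1)    # no migration: none lost
  # direct mixture over the log-series occupancy distribution
  m <- 1:1e6
  for (prm in list(c(0.01, 0.9, 0.1), c(0.02, 0.8, 0.2))) {
    mix <- 1 - sum(fisher_logseries_pmf(m, prm[1]) *
                     extinction_probability(m, prm[2], prm[3]))
    expect_lt(abs(mix - sweep_parameter_Q0(prm[1], prm[2], prm[3])), 1e-6)
  }
  # increasing in p_h/p_m at fixed nu; decreasing in nu at fixed ratio
  ratios <- seq(0.02, 2, length.out = 25)
  q_r <- vapply(ratios, function(x) sweep_parameter_Q0(0.01, 1, x), numeric(1))
  expect_true(all(diff(q_r) > 0))
  nus <- seq(0.001, 0.2, length.out = 25)
  q_n <- vapply(nus, function(x) sweep_parameter_Q0(x, 1, 0.1), numeric(1))
  expect_true(all(diff(q_n) < 0))
  expect_true(all(q_r >= 0 & q_r <= 1))
})
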