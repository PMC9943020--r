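test_that("delta_energy equals the brute-force Hamiltonian difference", {
  m2 <- ising_model(c(0, 0), matrix(c(0, 1, 1, 0), 2))
  expect_equal(delta_energy(c(1, 1), m2, 1), 2)
  iso <- ising_model(0.5, matrix(0, 1, 1), pairing = NULL)
  expect_equal(delta_energy(-1, iso, 1), -1)
  for (s in 1:5) {
    m <- random_model(7, seed = s)
    set.seed(s)
    sg <- sample(c(-1, 1), 7, replace = TRUE)
    k <- sample(7, 1)
    flipped <- sg; flipped[k] <- -flipped[k]
    expect_equal(delta_energy(sg, m, k),
                 hamiltonian(flipped, m) - hamiltonian(sg, m),
                 tolerance = 1e-12)
  }
})

test_that("chains are reproducible and track energy exactly", {
  m <- random_model(8, seed = 2)
  cfg <- metropolis_config(n_flip_attempts = 2e4, burn_in = 100,
                           thinning = 7, seed = 11)
  c1 <- metropolis_run(m, 0.9, cfg)
  c2 <- metropolis_run(m, 0.9, cfg)
  expect_identical(c1$states, c2$states)
  expect_identical(c1$energy, c2$energy)
  expect_equal(length(c1$energy), floor((2e4 - 100) / 7))
  # spot-check stored energies against the Hamiltonian
  for (i in c(1, 50, length(c1$energy))) {
    expect_equal(c1$energy[i], hamiltonian(c1$states[i, ], m),
                 tolerance = 1e-8)
  }
  # per-sample magnetization is the spin sum
  expect_equal(c1$magnetization, rowSums(c1$states))
})

test_that("all proposals are accepted in the infinite-temperature limit", {
  m <- random_model(6, seed = 4)
  cfg <- metropolis_config(n_flip_attempts = 5e3, burn_in = 0,
                           thinning = 1, seed = 3)
  ch <- metropolis_run(m, 1e9, cfg)
  expect_equal(ch$acceptance_rate, 1)
})

test_that("long-run state frequencies match the Boltzmann distribution", {
  # detailed-balance check on a 4-spin model at 1e6 attempts
  m <- random_model(4, j_sd = 0.4, h_sd = 0.3, seed = 6)
  cfg <- metropolis_config(n_flip_attempts = 1e6, burn_in = 1e4,
                           thinning = 1, seed = 21)
  ch <- metropolis_run(m, 1, cfg)
  idx <- as.integer((ch$states + 1) %*% (2^(3:0)) / 2) + 1L
  emp <- tabulate(idx, 16) / length(idx)
  d <- exact_distribution(m)
  sidx <- as.integer((d$states + 1) %*% (2^(3:0)) / 2) + 1L
  ex <- numeric(16); ex[sidx] <- d$prob
  expect_lt(0.5 * sum(abs(emp - ex)), 0.02)
})

test_that("estimated observables match enumeration within Monte-Carlo error", {
  m <- random_model(6, j_sd = 0.3, h_sd = 0.2, seed = 31)
  cfg <- metropolis_config(n_flip_attempts = 5e5, burn_in = 1e4,
                           thinning = 1, seed = 31)
  ch <- metropolis_run(m, 1, cfg)
  for (conv in c("raw", "branch_flipped")) {
    o <- estimate_observables(ch, m, convention = conv)
    e <- exact_observables(m, convention = conv)
    se <- o$standard_errors
    expect_lt(abs(o$mean_magnetization - e$mean_magnetization),
              4 * se$mean_magnetization)
    expect_lt(abs(o$susceptibility - e$susceptibility),
              4 * se$susceptibility)
    expect_lt(abs(o$heat_capacity - e$heat_capacity), 4 * se$heat_capacity)
    expect_lt(abs(o$mean_energy - e$mean_energy), 4 * se$mean_energy)
  }
})

test_that("independent spins give chi = N / T", {
  m <- ising_model(numeric(10), matrix(0, 10, 10))
  for (Tt in c(0.5, 2)) {
    cfg <- metropolis_config(n_flip_attempts = 3e5, burn_in = 1e4,
                             thinning = 1, seed = 8)
    ch <- metropolis_run(m, Tt, cfg)
    o <- estimate_observables(ch, m, convention = "raw",
                              include_links = FALSE)
    expect_lt(abs(o$susceptibility - 10 / Tt),
              3 * o$standard_errors$susceptibility)
  }
})

test_that("a cold ferromagnet saturates branch-flipped magnetization", {
  J <- matrix(0.5, 8, 8); diag(J) <- 0
  m <- ising_model(numeric(8), J)
  ch <- metropolis_run(m, 0.3, sweep_config(8, 2000, seed = 14))
  o <- estimate_observables(ch, m, convention = "branch_flipped",
                            include_links = FALSE)
  expect_gt(o$mean_magnetization, 7.9)
})

test_that("sweeps are deterministic given the base seed and locate the peak", {
  m <- complete_graph_model(30)
  grid <- seq(0.5, 1.6, by = 0.1)
  cfg <- sweep_config(30, 5e3, sweeps_burn = 500, seed = 9)
  sw1 <- temperature_sweep(m, grid, cfg, complexity = FALSE)
  sw2 <- temperature_sweep(m, grid, cfg, complexity = FALSE)
  expect_identical(sw1$table, sw2$table)
  tc <- find_critical_temperature(sw1)
  expect_gt(tc, 0.6); expect_lt(tc, 1.3)
  # boundary maximum is refused
  low <- temperature_sweep(m, seq(1.3, 1.8, 0.1), cfg, complexity = FALSE)
  expect_error(find_critical_temperature(low), "boundary")
})

test_that("link perturbation scales exactly the selected couplings", {
  arch <- make_archetype(archetype_spec(), seed = 11)
  expect_identical(perturb_links(arch, "homotopic", 1)$J, arch$J)
  ph <- perturb_links(arch, "homotopic", 0.8)
  n <- 16
  hom <- cbind(seq_len(n), mirror_pairing(n))
  expect_equal(ph$J[hom], 0.8 * arch$J[hom])
  others <- ph$J; others[hom] <- arch$J[hom]
  expect_identical(others, arch$J)
  # random_matched scales the same count of non-homotopic links
  pr <- perturb_links(arch, "random_matched", 0.8, seed = 3)
  changed <- which(pr$J != arch$J & upper.tri(arch$J), arr.ind = TRUE)
  expect_equal(nrow(changed), n / 2)
  expect_true(all(mirror_pairing(n)[changed[, 1]] != changed[, 2]))
  expect_symmetric(pr$J)
})
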