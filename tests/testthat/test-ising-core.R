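test_that("hamiltonian matches hand-computed energies and flip symmetry", {
  m2 <- ising_model(c(0, 0), matrix(c(0, 1, 1, 0), 2))
  expect_equal(hamiltonian(c(1, 1), m2), -1)
  m3 <- ising_model(c(1, 1, 1), matrix(0, 3, 3), pairing = NULL)
  expect_equal(hamiltonian(c(1, 1, 1), m3), -3)
  # global flip symmetry at h = 0
  m <- random_model(6, h_sd = 0, seed = 3)
  for (s in 1:5) {
    set.seed(s)
    sg <- sample(c(-1, 1), 6, replace = TRUE)
    expect_equal(hamiltonian(sg, m), hamiltonian(-sg, m))
  }
  expect_error(hamiltonian(c(1, 1), m3), "length")
})

test_that("model constructor enforces its invariants", {
  J <- matrix(c(0, 1, 2, 0), 2)
  expect_error(ising_model(c(0, 0), J), "symmetric")
  J2 <- matrix(c(1, 0.5, 0.5, 0), 2)
  expect_error(ising_model(c(0, 0), J2), "diagonal")
  expect_error(ising_model(c(0, 0), matrix(0, 2, 2), beta = -1), "beta")
  expect_error(ising_model(numeric(4), matrix(0, 4, 4),
                           pairing = c(2, 1, 3, 4)),
               "fixed-point free")
  expect_error(ising_model(numeric(4), matrix(0, 4, 4),
                           pairing = c(2, 3, 4, 1)),
               "involution")
})

test_that("conditional probability is the logistic of twice the local field", {
  # h_i + sum J s = 1  ->  1 / (1 + e^-2)
  mm <- ising_model(c(1, 0), matrix(0, 2, 2))
  expect_equal(conditional_prob(c(1, 1), mm, 1), 0.880797, tolerance = 1e-6)
  m0 <- ising_model(c(0, 0), matrix(0, 2, 2))
  expect_equal(conditional_prob(c(1, -1), m0, 1), 0.5)
  # normalization P(+1) + P(-1) = 1 on random inputs
  m <- random_model(5, seed = 9)
  for (i in 1:5) {
    set.seed(i)
    sg <- sample(c(-1, 1), 5, replace = TRUE)
    p_plus <- conditional_prob(sg, m, i)
    sg_i <- sg; sg_i[i] <- 1
    f <- m$h[i] + sum(m$J[i, -i] * sg[-i])
    p_minus <- 1 / (1 + exp(2 * f))
    expect_equal(p_plus + p_minus, 1)
  }
})

test_that("exact distribution reproduces closed forms and normalizes", {
  m2 <- ising_model(c(0, 0), matrix(c(0, 1, 1, 0), 2))
  d <- exact_distribution(m2)
  # P(++) = e / (2e + 2/e)
  expect_equal(d$prob[4], exp(1) / (2 * exp(1) + 2 * exp(-1)),
               tolerance = 1e-12)
  expect_equal(d$prob[4], 0.44040, tolerance = 1e-4)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  # beta -> 0 limit approaches uniform
  d0 <- exact_distribution(random_model(4, seed = 2), beta = 1e-9)
  expect_equal(d0$prob, rep(1 / 16, 16), tolerance = 1e-6)
  expect_error(exact_distribution(random_model(3, seed = 1), beta = -1),
               "positive")
})

test_that("exact observables reduce to independent-spin closed forms", {
  m <- ising_model(numeric(8), matrix(0, 8, 8))
  o <- exact_observables(m, convention = "raw")
  expect_equal(o$mean_magnetization, 0)
  expect_equal(o$susceptibility, 8)       # Var(M) = N at J = 0, h = 0
  expect_equal(o$heat_capacity, 0)        # H identically 0
  expect_equal(o$local_susceptibility, rep(1, 8))
})

test_that("chi_n sums to chi and link susceptibility is symmetric", {
  for (s in 1:3) {
    m <- random_model(6, seed = s)
    o <- exact_observables(m, convention = "raw")
    expect_equal(sum(o$local_susceptibility), o$susceptibility,
                 tolerance = 1e-10)
    expect_symmetric(o$link_susceptibility)
    expect_gte(o$susceptibility, 0)
    expect_gte(o$heat_capacity, 0)
  }
})

test_that("fluctuation-dissipation: chi equals the field derivative of <M>", {
  eps <- 1e-3
  for (s in 1:4) {
    m <- random_model(sample(4:8, 1), j_sd = 0.3, h_sd = 0.2, seed = 40 + s)
    o <- exact_observables(m, convention = "raw")
    shift <- function(dh) {
      exact_observables(ising_model(m$h + dh, m$J, pairing = m$pairing),
                        convention = "raw")$mean_magnetization
    }
    dMdh <- (shift(eps) - shift(-eps)) / (2 * eps)
    expect_equal(o$susceptibility, dMdh, tolerance = 1e-3)
  }
})

test_that("heat capacity equals the temperature derivative of <H>", {
  eps <- 1e-3
  for (s in 1:3) {
    m <- random_model(6, seed = 50 + s)
    Tt <- 1.3
    o <- exact_observables(m, beta = 1 / Tt, convention = "raw")
    meanE <- function(Tq) exact_observables(m, beta = 1 / Tq,
                                            convention = "raw")$mean_energy
    dHdT <- (meanE(Tt + eps) - meanE(Tt - eps)) / (2 * eps)
    expect_equal(o$heat_capacity, dHdT, tolerance = 1e-3)
  }
})

test_that("branch-flipped enumeration gives |M| statistics", {
  # strong ferromagnet: branch-flipped <M> is near N, raw <M> is 0 by symmetry
  J <- matrix(0.8, 6, 6); diag(J) <- 0
  m <- ising_model(numeric(6), J)
  raw <- exact_observables(m, convention = "raw")
  bf <- exact_observables(m, convention = "branch_flipped")
  expect_equal(raw$mean_magnetization, 0, tolerance = 1e-10)
  expect_gt(bf$mean_magnetization, 5.5)
})

test_that("exact sampling matches the enumerated moments", {
  m <- random_model(6, seed = 77)
  set.seed(123)
  dat <- exact_sample(m, 2e4)
  emp <- empirical_moments(dat)
  d <- exact_distribution(m)
  exp_m1 <- as.numeric(t(d$states) %*% d$prob)
  # 3 sigma binomial-scale tolerance
  expect_true(all(abs(emp$m1 - exp_m1) < 3 / sqrt(2e4) * 2))
})
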