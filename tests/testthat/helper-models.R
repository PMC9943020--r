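# model factories shared across tests

random_model <- function(n, j_sd = 0.3, h_sd = 0.3, seed = 1) {
  set.seed(seed)
  J <- matrix(rnorm(n * n, 0, j_sd), n, n)
  J <- (J + t(J)) / 2
  diag(J) <- 0
  ising_model(rnorm(n, 0, h_sd), J,
              pairing = if (n %% 2 == 0) mirror_pairing(n) else NULL)
}

# L x L periodic nearest-neighbour ferromagnet (J = 1, h = 0)
lattice_model <- function(L) {
  N <- L * L
  J <- matrix(0, N, N)
  id <- function(i, j) ((i - 1) %% L) * L + ((j - 1) %% L) + 1
  for (i in 1:L) {
    for (j in 1:L) {
      a <- id(i, j)
      for (nb in list(c(i + 1, j), c(i, j + 1))) {
        b <- id(nb[1], nb[2])
        J[a, b] <- J[b, a] <- 1
      }
    }
  }
  ising_model(numeric(N), J, pairing = NULL)
}

# complete graph with J0 / N couplings (mean-field Tc = J0)
complete_graph_model <- function(N, J0 = 1) {
  J <- matrix(J0 / N, N, N)
  diag(J) <- 0
  ising_model(numeric(N), J, pairing = NULL)
}

# short Metropolis config: burn-in of `sweeps_burn` sweeps, one retained
# sample per sweep
sweep_config <- function(n, n_samples, sweeps_burn = 1000, seed = 1,
                         branch_flip = TRUE) {
  metropolis_config(n_flip_attempts = sweeps_burn * n + n_samples * n,
                    burn_in = sweeps_burn * n, thinning = n, seed = seed,
                    branch_flip = branch_flip)
}

# tiny synthetic cohort for pipeline-level tests
small_cohort <- function(seed = 1, n_subjects = 6, n_parcels = 8,
                         t_max = 80, shift = 0.07) {
  arch <- make_archetype(archetype_spec(n_parcels = n_parcels), seed = 11)
  simulate_cohort(arch, cohort_config(n_subjects = n_subjects, t_max = t_max,
                                      temperature_shift = shift, seed = seed))
}

expect_symmetric <- function(J, tol = 1e-12) {
  expect_lt(max(abs(J - t(J))), tol)
}
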