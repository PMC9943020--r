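test_that("empirical moments match a brute-force averaging loop", {
  d <- binary_series(matrix(1, 3, 5), pairing = NULL)
  em <- empirical_moments(d)
  expect_equal(em$m1, rep(1, 3))
  expect_true(all(em$m2 == 1))
  anti <- rbind(c(1, -1, 1, -1), c(-1, 1, -1, 1))
  expect_equal(empirical_moments(anti)$m2[1, 2], -1)
  set.seed(12)
  S <- matrix(sample(c(-1, 1), 4 * 30, replace = TRUE), 4, 30)
  em <- empirical_moments(S)
  # direct loops as the oracle
  for (i in 1:4) {
    expect_equal(em$m1[i], sum(S[i, ]) / 30)
    for (j in 1:4) {
      if (i != j) expect_equal(em$m2[i, j], sum(S[i, ] * S[j, ]) / 30)
    }
  }
})

test_that("pseudo-moments collapse to tanh(beta h) at J = 0 and stay bounded", {
  h <- c(0.5, -0.3, 0)
  m <- ising_model(h, matrix(0, 3, 3), pairing = NULL)
  set.seed(3)
  S <- matrix(sample(c(-1, 1), 3 * 40, replace = TRUE), 3, 40)
  for (b in c(0.5, 1, 2)) {
    pm <- pseudo_moments(S, m, beta = b)
    expect_equal(pm$m1, tanh(b * h))
    expect_true(all(abs(pm$m1) <= 1) && all(abs(pm$m2) <= 1))
  }
})

test_that("pseudo-moments equal a hand evaluation on a single-ish case", {
  # 2 spins, J12 = 0.4, h = (0.1, -0.2), two time points
  m <- ising_model(c(0.1, -0.2), matrix(c(0, 0.4, 0.4, 0), 2))
  S <- cbind(c(1, -1), c(1, 1))
  pm <- pseudo_moments(S, m, beta = 1)
  f1 <- c(0.1 + 0.4 * -1, 0.1 + 0.4 * 1)   # local field of spin 1 at t=1,2
  f2 <- c(-0.2 + 0.4 * 1, -0.2 + 0.4 * 1)
  expect_equal(pm$m1, c(mean(tanh(f1)), mean(tanh(f2))))
  hand12 <- mean(S[2, ] * tanh(f1))
  hand21 <- mean(S[1, ] * tanh(f2))
  expect_equal(pm$m2[1, 2], (hand12 + hand21) / 2)
  expect_equal(pm$m2[1, 2], pm$m2[2, 1])
})

test_that("independent-spin data recovers fields via the atanh closed form", {
  set.seed(42)
  h <- c(0.5, -0.5, 0)
  probs <- (1 + tanh(h)) / 2
  S <- t(vapply(probs, function(p)
    ifelse(runif(2e4) < p, 1, -1), numeric(2e4)))
  fit <- fit_archetype(S, fit_config())
  expect_true(fit$converged)
  em <- empirical_moments(S)
  expect_true(all(abs(fit$model$J) < 0.05))
  expect_true(all(abs(fit$model$h - atanh(em$m1)) < 0.05))
})

test_that("converged fits satisfy the moment-matching fixed point", {
  coh <- small_cohort(seed = 51, n_subjects = 2, t_max = 100)
  dat <- assemble_condition_data(coh, "global")
  cfg <- fit_config(tolerance = 1e-3)
  fit <- fit_archetype(dat, cfg)
  expect_true(fit$converged)
  em <- empirical_moments(dat)
  pm <- pseudo_moments(dat, fit$model, beta = 1)
  expect_lt(max(abs(em$m1 - pm$m1)), cfg$tolerance)
  expect_lt(max(abs(em$m2 - pm$m2)), cfg$tolerance)
})

test_that("recovery error shrinks with sample size", {
  m <- random_model(6, j_sd = 0.25, h_sd = 0.1, seed = 7)
  rmse_at <- function(tlen, seed) {
    set.seed(seed)
    fit <- fit_archetype(exact_sample(m, tlen), fit_config(tolerance = 1e-3))
    ut <- upper.tri(m$J)
    sqrt(mean((fit$model$J[ut] - m$J[ut])^2))
  }
  for (s in 1:3) {
    expect_lt(rmse_at(3e4, s), rmse_at(500, s))
  }
})

test_that("fitting is equivariant under parcel permutation", {
  coh <- small_cohort(seed = 61, n_subjects = 2, t_max = 80)
  dat <- assemble_condition_data(coh, "global")
  cfg <- fit_config(tolerance = 1e-3)
  fit <- fit_archetype(dat$states, cfg)
  perm <- c(3, 1, 4, 2, 7, 8, 5, 6)
  fit_p <- fit_archetype(dat$states[perm, ], cfg)
  expect_equal(fit_p$model$h, fit$model$h[perm], tolerance = 1e-10)
  expect_equal(fit_p$model$J, fit$model$J[perm, perm], tolerance = 1e-10)
})

test_that("temperature fit recovers beta and satisfies its fixed point", {
  arch <- make_archetype(archetype_spec(n_parcels = 8), seed = 19)
  set.seed(73)
  cfg <- sweep_config(8, 5e3, seed = 73)
  chain <- metropolis_run(arch, 1 / 1.1, cfg)
  ft <- fit_temperature(t(chain$states), arch, fit_config())
  expect_true(ft$converged)
  expect_equal(ft$beta, 1.1, tolerance = 0.05)
  # fixed point: empirical energy equals pseudo-model energy at beta-hat
  pm <- pseudo_moments(t(chain$states), arch, beta = ft$beta)
  h_model <- -sum(arch$h * pm$m1) -
    sum(arch$J[upper.tri(arch$J)] * pm$m2[upper.tri(pm$m2)])
  expect_lt(abs(ft$empirical_energy - h_model), 1e-4 + 1e-8)
})

test_that("temperature fit errors on dimension mismatch and beta <= 0", {
  arch <- make_archetype(archetype_spec(n_parcels = 8), seed = 19)
  expect_error(fit_temperature(matrix(1, 4, 10), arch, fit_config()),
               "dimensions")
})

test_that("goodness of fit separates self-fit from a mismatched model", {
  coh <- small_cohort(seed = 81, n_subjects = 3, t_max = 150)
  dat <- assemble_condition_data(coh, "global")
  fit <- fit_archetype(dat, fit_config(tolerance = 1e-3))
  cfg <- sweep_config(8, 1e4, seed = 5)
  gof_self <- goodness_of_fit(dat, fit$model, T = 1, config = cfg)
  wrong <- random_model(8, j_sd = 0.6, h_sd = 0.5, seed = 1)
  gof_wrong <- goodness_of_fit(dat, wrong, T = 1, config = cfg)
  expect_gt(gof_self$fc_r, 0.9)
  expect_gt(gof_self$fc_r, gof_wrong$fc_r + 0.1)
})
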