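test_that("archetype construction places couplings block by block", {
  spec <- archetype_spec(n_parcels = 4, intra_strength = 0.5,
                         homotopic_strength = 0.3, inter_strength = -0.05,
                         coupling_noise_sd = 0, field_sd = 0, density = 1)
  m <- make_archetype(spec, seed = 1)
  # mirror pairing on 4 parcels: 1<->4, 2<->3
  expect_equal(m$J[1, 4], 0.3)
  expect_equal(m$J[2, 3], 0.3)
  expect_equal(sum(m$J == 0.3), 4)          # 2 homotopic links, symmetric
  expect_equal(m$J[1, 2], 0.5)              # intra (hemisphere 1)
  expect_equal(m$J[3, 4], 0.5)              # intra (hemisphere 2)
  expect_equal(m$J[1, 3], -0.05)            # non-homotopic inter
  expect_equal(m$h, rep(0, 4))
  expect_error(make_archetype(archetype_spec(n_parcels = 5)), "even")
})

test_that("archetypes are symmetric, zero-diagonal, and seed-deterministic", {
  for (s in 1:3) {
    m <- make_archetype(archetype_spec(), seed = s)
    expect_symmetric(m$J)
    expect_true(all(diag(m$J) == 0))
    m2 <- make_archetype(archetype_spec(), seed = s)
    expect_identical(m$J, m2$J)
    expect_identical(m$h, m2$h)
  }
  expect_false(identical(make_archetype(archetype_spec(), seed = 1)$J,
                         make_archetype(archetype_spec(), seed = 2)$J))
})

test_that("cohorts have the configured shape and stored ground truth", {
  coh <- small_cohort(seed = 31, n_subjects = 3, n_parcels = 8, t_max = 12)
  expect_length(coh$series, 3 * 2 * 2)
  for (s in coh$series) expect_equal(dim(s$states), c(8, 12))
  expect_equal(dim(coh$ground_truth$temperatures), c(3, 2))
  expect_true(all(coh$ground_truth$temperatures > 0))
})

test_that("zero shift and zero sd give identical condition temperatures", {
  arch <- make_archetype(archetype_spec(n_parcels = 8), seed = 11)
  coh <- simulate_cohort(arch, cohort_config(n_subjects = 3, t_max = 10,
                                             temperature_shift = 0,
                                             subject_temperature_sd = 0,
                                             shift_sd = 0, seed = 5))
  temps <- coh$ground_truth$temperatures
  expect_equal(temps[, 1], temps[, 2])
  expect_equal(unname(temps[, 1]), rep(1, 3))
})

test_that("a temperature shift lowers session magnetization below Tc", {
  # ferromagnetic archetype sampled below its critical temperature: the
  # hotter condition must show smaller mean |M| across >= 10 subjects
  arch <- make_archetype(archetype_spec(n_parcels = 8,
                                        intra_strength = 0.4), seed = 3)
  coh <- simulate_cohort(arch, cohort_config(n_subjects = 10, t_max = 60,
                                             base_temperature = 0.45,
                                             temperature_shift = 0.2,
                                             subject_temperature_sd = 0,
                                             shift_sd = 0, seed = 17))
  mean_absM <- function(co) {
    mean(vapply(coh$series[grepl(paste0("\\|", co, "\\|"),
                                 names(coh$series))],
                function(s) mean(abs(colSums(s$states))), numeric(1)))
  }
  expect_gt(mean_absM("A"), mean_absM("B"))
})

test_that("simulated moments converge to enumeration moments", {
  m <- random_model(6, j_sd = 0.25, h_sd = 0.1, seed = 13)
  Tt <- 1.1
  set.seed(99)
  cfg <- sweep_config(6, 3e4, seed = 99)
  chain <- metropolis_run(m, Tt, cfg)
  emp <- empirical_moments(t(chain$states))
  d <- exact_distribution(m, beta = 1 / Tt)
  exp_m1 <- as.numeric(t(d$states) %*% d$prob)
  exp_m2 <- t(d$states) %*% (d$states * d$prob)
  # 3 Monte-Carlo standard errors with a generous autocorrelation factor
  se <- 3 * sqrt(1 / 3e4) * 3
  expect_true(all(abs(emp$m1 - exp_m1) < se))
  expect_true(all(abs(emp$m2[upper.tri(exp_m2)] -
                      exp_m2[upper.tri(exp_m2)]) < se))
})

test_that("pseudo-BOLD rendering is reproducible and invertible", {
  b <- binary_series(matrix(rep(c(1, -1), 40), 8, 10, byrow = TRUE))
  ts1 <- render_pseudo_bold(b, amplitude = 2, noise_sd = 0.3, seed = 4)
  ts2 <- render_pseudo_bold(b, amplitude = 2, noise_sd = 0.3, seed = 4)
  expect_identical(ts1$values, ts2$values)
  # noiseless rendering with balanced rows binarizes back exactly
  ts0 <- render_pseudo_bold(b, amplitude = 1, noise_sd = 0, seed = 1)
  expect_identical(binarize_median(ts0)$states, b$states)
  # an all-(+1) row is flagged as constant downstream
  b1 <- binary_series(rbind(rep(1, 10), rep(c(1, -1), 5)))
  expect_warning(binarize_median(render_pseudo_bold(b1, 1, 0, 1)), "constant")
})
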