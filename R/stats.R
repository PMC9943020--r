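#' Paired condition contrast test
#'
#' Paired test on `b - a` (condition B minus condition A per subject).
#' The Wilcoxon signed-rank variant uses the exact null distribution for
#' n <= 25 (no ties) and the normal approximation with continuity correction
#' otherwise; the t variant reports Cohen's d of the paired differences.
#'
#' @param a,b equal-length per-subject metric vectors for the two conditions.
#' @param method `"wilcoxon"` or `"t"`.
#' @param alternative `"greater"` (B exceeds A), `"less"`, or `"two.sided"`.
#' @return A list of class `test_result` with `statistic`, `p_value`,
#'   `sidedness`, `n`, `effect_size` (t only), and `method`.
#' @export
paired_condition_test <- function(a, b, method = c("wilcoxon", "t"),
                                  alternative = c("greater", "less",
                                                  "two.sided")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (length(a) != length(b)) stop("conditions have different lengths")
  n <- length(a)
  if (n < 5) stop("need at least 5 paired observations")
  d <- b - a
  if (method == "wilcoxon") {
    if (all(d == 0))
      stop("all paired differences are zero; signed-rank test is degenerate")
    ht <- suppressWarnings(
      wilcox.test(b, a, paired = TRUE, alternative = alternative,
                  exact = n <= 25, correct = TRUE))
    eff <- NULL
  } else if (all(d == 0)) {
    # identical conditions: no evidence either way
    ht <- list(statistic = c(t = 0), p.value = 1, method = "Paired t-test")
    eff <- 0
  } else {
    ht <- t.test(b, a, paired = TRUE, alternative = alternative)
    eff <- if (sd(d) > 0) mean(d) / sd(d) else 0
  }
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 sidedness = alternative, n = n, effect_size = eff,
                 method = ht$method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s, n = %d)\n",
              x$method, x$statistic, x$p_value, x$sidedness, x$n))
  invisible(x)
}

#' Parcel-label permutation test for the temperature contrast
#'
#' Tests whether the observed between-condition temperature difference
#' depends on the fitted archetype architecture. Each permutation applies
#' one random parcel relabeling jointly to the archetype's fields (entries
#' of `h`) and couplings (rows and columns of `J`), refits the inverse
#' temperature of every subject and condition against the permuted
#' archetype, and recomputes the one-sample t statistic of the paired
#' per-subject temperature differences (condition B minus A, on `T = 1/beta`).
#' The p-value uses the add-one estimator
#' `p = (1 + #\{t_perm >= t_obs\}) / (1 + n_perm)`.
#'
#' @param cohort an `ising_cohort` with two conditions.
#' @param archetype the fitted archetype [ising_model()].
#' @param config a [fit_config()] for the temperature refits.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed for the permutation draws.
#' @param add_one use the add-one p-value estimator (the raw fraction is
#'   reported alongside either way).
#' @return A list of class `permutation_result` with `observed_t`,
#'   `permuted_t`, `p_value`, `p_raw`, `n_perm`, `seed`, and the observed
#'   per-subject temperatures.
#' @export
permutation_test_temperature <- function(cohort, archetype,
                                         config = fit_config(),
                                         n_perm = 1000, seed = 1,
                                         add_one = TRUE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  validate_ising_model(archetype)
  man <- cohort$manifest
  if (length(man$conditions) != 2) stop("cohort must have two conditions")
  n <- length(archetype$h)

  # assemble each subject/condition series once; the permutation loop then
  # bypasses the per-call validation of fit_temperature() and drives the
  # compiled fitter directly on the cached matrices
  data_grid <- lapply(man$subjects, function(s)
    lapply(man$conditions, function(co)
      assemble_condition_data(cohort, "subject_condition",
                              condition = co, subject = s)$states))
  # beta may legitimately cross zero against a permuted (anti-matched)
  # architecture; the same unconstrained fit is applied to the observed
  # archetype so observed and permuted statistics stay exchangeable
  subject_T <- function(h, J) {
    vapply(data_grid, function(per_cond) {
      vapply(per_cond, function(S) {
        ft <- fit_beta_cpp(S, h, J, config$beta_learning_rate,
                           as.integer(config$max_iterations),
                           config$tolerance, config$beta_init,
                           allow_negative = TRUE)
        1 / ft$beta
      }, numeric(1))
    }, numeric(2))            # 2 x n_subjects (conditions in rows)
  }
  t_of <- function(temps) {
    d <- temps[2, ] - temps[1, ]
    unname(t.test(d)$statistic)
  }
  obs_T <- subject_T(archetype$h, archetype$J)
  t_obs <- t_of(obs_T)

  set.seed(seed)
  t_perm <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    perm <- sample.int(n)
    t_perm[p] <- t_of(subject_T(archetype$h[perm],
                                archetype$J[perm, perm]))
  }
  exceed <- sum(t_perm >= t_obs)
  p_raw <- exceed / n_perm
  p_val <- if (add_one) (1 + exceed) / (1 + n_perm) else p_raw
  structure(list(observed_t = t_obs, permuted_t = t_perm, p_value = p_val,
                 p_raw = p_raw, n_perm = n_perm, seed = seed,
                 observed_temperatures = obs_T),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test: t_obs = %.3f, p = %.4g (%d permutations)\n",
              x$observed_t, x$p_value, x$n_perm))
  invisible(x)
}

#' Correlations between per-subject condition differences
#'
#' Pearson correlation (with two-sided p) between pairs of per-subject
#' metric deltas, e.g. the temperature shift against the complexity shift.
#'
#' @param deltas data frame or named list of per-subject difference vectors.
#' @param pairs optional list of 2-element character vectors naming the
#'   pairs to correlate; defaults to all distinct pairs.
#' @return Data frame with columns `metric_a`, `metric_b`, `r`, `p_value`, `n`.
#' @export
correlate_metrics <- function(deltas, pairs = NULL) {
  deltas <- as.data.frame(deltas)
  if (nrow(deltas) < 3) stop("need at least 3 subjects")
  nm <- names(deltas)
  if (is.null(pairs)) {
    pairs <- list()
    for (i in seq_along(nm))
      for (j in seq_along(nm))
        if (i < j) pairs[[length(pairs) + 1]] <- c(nm[i], nm[j])
  }
  rows <- lapply(pairs, function(p) {
    ct <- cor.test(deltas[[p[1]]], deltas[[p[2]]])
    data.frame(metric_a = p[1], metric_b = p[2],
               r = unname(ct$estimate), p_value = ct$p.value,
               n = nrow(deltas))
  })
  do.call(rbind, rows)
}
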