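#' Fit settings for pseudo-likelihood estimation
#'
#' @param learning_rate gradient step for the (h, J) archetype fit.
#' @param beta_learning_rate gradient step for the temperature fit (damped
#'   adaptively when the energy mismatch grows).
#' @param max_iterations iteration cap.
#' @param tolerance convergence threshold on the maximum absolute moment
#'   mismatch (archetype fit) or on the absolute energy mismatch
#'   (temperature fit).
#' @param init `"zeros"` or a list with `h` and `J` starting values.
#' @param beta_init starting inverse temperature for [fit_temperature()].
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(learning_rate = 0.2, beta_learning_rate = 0.05,
                       max_iterations = 5000, tolerance = 1e-4,
                       init = "zeros", beta_init = 1) {
  if (learning_rate <= 0 || beta_learning_rate <= 0)
    stop("learning rates must be > 0")
  if (tolerance <= 0) stop("tolerance must be > 0")
  structure(list(learning_rate = learning_rate,
                 beta_learning_rate = beta_learning_rate,
                 max_iterations = max_iterations, tolerance = tolerance,
                 init = init, beta_init = beta_init),
            class = "fit_config")
}

#' Empirical 1- and 2-point moments of binary data
#'
#' @param data a [binary_series()] or -1/+1 matrix (parcels x time).
#' @return List with `m1` (time-averaged spins) and `m2` (pair correlation
#'   matrix, symmetric with unit diagonal).
#' @export
empirical_moments <- function(data) {
  S <- series_matrix(data)
  m2 <- tcrossprod(S) / ncol(S)
  diag(m2) <- 1
  list(m1 = rowMeans(S), m2 = m2)
}

series_matrix <- function(data) {
  S <- if (inherits(data, "binary_series")) data$states else as.matrix(data)
  if (!all(S %in% c(-1, 1))) stop("data must be -1/+1")
  if (ncol(S) < 2) stop("need at least 2 time points")
  S
}

#' Model moments under the pseudo-likelihood conditionals
#'
#' The 1-point moment replaces each observed spin by the conditional mean of
#' its spin given the others, `tanh(beta * (h_i + sum_j J_ij s_j(t)))`,
#' averaged over time; the 2-point moment averages
#' `s_j(t) * tanh(beta * f_i(t))`, symmetrized over the (i|j) and (j|i)
#' conditionals so the result is a symmetric matrix.
#'
#' @param data a [binary_series()] or -1/+1 matrix.
#' @param model an [ising_model()].
#' @param beta inverse temperature at which the conditionals are evaluated.
#' @return List with `m1` and `m2` (unit diagonal).
#' @export
pseudo_moments <- function(data, model, beta = 1) {
  S <- series_matrix(data)
  if (nrow(S) != length(model$h)) stop("dimension mismatch with the model")
  res <- pseudo_moments_cpp(S, model$h, model$J, beta)
  list(m1 = as.numeric(res$m1), m2 = res$m2)
}

#' Fit an archetype Ising model by maximum pseudo-likelihood
#'
#' Gradient ascent on the log pseudo-likelihood at beta = 1:
#' `h_i <- h_i + eta * (<s_i>_emp - <s_i>_model)` and
#' `J_ij <- J_ij + eta * (<s_i s_j>_emp - <s_i s_j>_model)`, with `J` kept
#' symmetric and zero-diagonal at every step. Converged means the maximum
#' absolute moment mismatch dropped below the tolerance, the fixed point of
#' the update rule.
#'
#' @param data a [binary_series()] or -1/+1 matrix (parcels x time).
#' @param config a [fit_config()].
#' @return A list of class `fit_result` with `model`, `iterations`,
#'   `mismatch`, and `converged`.
#' @export
fit_archetype <- function(data, config = fit_config()) {
  S <- series_matrix(data)
  n <- nrow(S)
  if (ncol(S) < 10 * n)
    warning(sprintf("only %d time points for %d parcels; estimates are noisy",
                    ncol(S), n))
  if (identical(config$init, "zeros")) {
    h0 <- numeric(n)
    J0 <- matrix(0, n, n)
  } else {
    h0 <- config$init$h
    J0 <- config$init$J
  }
  res <- fit_archetype_cpp(S, config$learning_rate,
                           as.integer(config$max_iterations),
                           config$tolerance, h0, J0)
  labels <- if (inherits(data, "binary_series")) data$parcel_labels else NULL
  pairing <- if (inherits(data, "binary_series")) data$pairing else NULL
  model <- ising_model(as.numeric(res$h), res$J,
                       parcel_labels = labels, pairing = pairing)
  structure(list(model = model, iterations = res$iterations,
                 mismatch = res$mismatch, converged = res$converged),
            class = "fit_result")
}

#' Personalize a frozen archetype by fitting its temperature
#'
#' Keeps `(h, J)` fixed and adjusts the single inverse temperature by the
#' energy-matching rule `beta <- beta - eta * (<H>_emp - <H>_model)`, whose
#' fixed point equates the empirical mean energy of the data with the model
#' mean energy assembled from the pseudo-moments (pairs counted once on both
#' sides).
#'
#' @param data a [binary_series()] or -1/+1 matrix.
#' @param archetype an [ising_model()] with matching dimensions.
#' @param config a [fit_config()].
#' @param allow_negative permit the fit to cross beta = 0 instead of
#'   erroring. A negative fixed point means the architecture is anti-matched
#'   to the data; it arises routinely for permuted archetypes and is needed
#'   there so the permutation null is well defined.
#' @return A list of class `fit_result` with `beta`, `temperature` (1/beta),
#'   `trajectory`, `iterations`, `mismatch`, and `converged`.
#' @export
fit_temperature <- function(data, archetype, config = fit_config(),
                            allow_negative = FALSE) {
  S <- series_matrix(data)
  validate_ising_model(archetype)
  if (nrow(S) != length(archetype$h))
    stop("archetype dimensions do not match the data")
  res <- fit_beta_cpp(S, archetype$h, archetype$J,
                      config$beta_learning_rate,
                      as.integer(config$max_iterations),
                      config$tolerance, config$beta_init,
                      allow_negative = allow_negative)
  structure(list(beta = res$beta, temperature = 1 / res$beta,
                 trajectory = as.numeric(res$trajectory),
                 iterations = res$iterations, mismatch = res$mismatch,
                 converged = res$converged,
                 empirical_energy = res$empirical_energy),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (!is.null(x$model)) {
    cat(sprintf("Archetype fit: %d parcels, %d iterations, mismatch %.2e%s\n",
                length(x$model$h), x$iterations, x$mismatch,
                if (x$converged) "" else " (NOT converged)"))
  } else {
    cat(sprintf("Temperature fit: beta = %.4f (T = %.4f), %d iterations%s\n",
                x$beta, x$temperature, x$iterations,
                if (x$converged) "" else " (NOT converged)"))
  }
  invisible(x)
}

#' Goodness of fit of a model against binary data
#'
#' Simulates the model with the Metropolis sampler and compares simulated
#' against empirical pairwise correlation matrices (Pearson r over the
#' off-diagonal upper triangle, the functional-connectivity fit the
#' archetype construction aims for) together with RMSEs of the 1- and
#' 2-point moments.
#'
#' @param data a [binary_series()] or -1/+1 matrix.
#' @param model an [ising_model()].
#' @param T simulation temperature (default the model's `1/beta`, or 1).
#' @param config a [metropolis_config()].
#' @return List with `fc_r`, `rmse_m1`, `rmse_m2`, and the simulated moments.
#' @export
goodness_of_fit <- function(data, model, T = NULL,
                            config = metropolis_config()) {
  S <- series_matrix(data)
  validate_ising_model(model)
  T <- T %||% (1 / (model$beta %||% 1))
  emp <- empirical_moments(S)
  chain <- metropolis_run(model, T, config)
  sim <- empirical_moments(t(chain$states))
  ut <- upper.tri(emp$m2)
  list(fc_r = cor(emp$m2[ut], sim$m2[ut]),
       rmse_m1 = sqrt(mean((emp$m1 - sim$m1)^2)),
       rmse_m2 = sqrt(mean((emp$m2[ut] - sim$m2[ut])^2)),
       simulated_moments = sim, empirical_moments = emp)
}
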