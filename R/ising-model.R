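#' Construct an Ising (pairwise maximum-entropy) model
#'
#' The model is a Sherrington-Kirkpatrick-type spin glass with arbitrary-sign
#' couplings and external fields. Its energy for a spin configuration
#' \eqn{\sigma \in \{-1,+1\}^N} is
#' \deqn{H(\sigma) = -\sum_{i<j} J_{ij}\sigma_i\sigma_j - \sum_i h_i\sigma_i,}
#' with pairs counted once. The optional inverse temperature \eqn{\beta}
#' scales the whole Hamiltonian in the Boltzmann weight
#' \eqn{P(\sigma) \propto e^{-\beta H(\sigma)}}; when absent the model is
#' understood at its nominal temperature \eqn{\beta = 1}.
#'
#' @param h numeric vector of external fields, length `N`.
#' @param J symmetric numeric `N x N` coupling matrix with zero diagonal.
#' @param beta optional positive inverse temperature.
#' @param parcel_labels optional character vector of parcel names.
#' @param pairing optional integer vector: `pairing[i]` is the index of the
#'   parcel homotopic to `i` (a fixed-point-free involution). Defaults to the
#'   mirror pairing `i <-> N + 1 - i` when `N` is even, otherwise `NULL`.
#' @return An object of class `ising_model`.
#' @export
ising_model <- function(h, J, beta = NULL, parcel_labels = NULL, pairing = NULL) {
  h <- as.numeric(h)
  J <- as.matrix(J)
  n <- length(h)
  if (is.null(pairing) && n %% 2 == 0) pairing <- mirror_pairing(n)
  if (is.null(parcel_labels)) parcel_labels <- default_parcel_labels(n)
  m <- structure(list(h = h, J = unname(J), beta = beta,
                      parcel_labels = parcel_labels, pairing = pairing),
                 class = "ising_model")
  validate_ising_model(m)
  m
}

default_parcel_labels <- function(n) sprintf("P%02d", seq_len(n))

#' Mirror homotopic pairing
#'
#' Pairs parcel `i` with parcel `N + 1 - i`, the convention used when parcels
#' are ordered with one hemisphere first and the other mirrored after it.
#'
#' @param n even number of parcels.
#' @return Integer vector of length `n` giving each parcel's homotopic partner.
#' @export
mirror_pairing <- function(n) {
  if (n %% 2 != 0) stop("mirror pairing requires an even number of parcels")
  rev(seq_len(n))
}

#' Hemisphere assignment for mirrored parcel orderings
#'
#' First half of the parcels is one hemisphere, second half the other.
#'
#' @param n even number of parcels.
#' @return Integer vector of 1s and 2s.
#' @export
hemisphere_split <- function(n) {
  if (n %% 2 != 0) stop("hemisphere split requires an even number of parcels")
  rep(1:2, each = n / 2)
}

validate_pairing <- function(pairing, n) {
  pairing <- as.integer(pairing)
  if (length(pairing) != n) stop("pairing must have one entry per parcel")
  if (any(pairing < 1L | pairing > n)) stop("pairing indices out of range")
  if (any(pairing == seq_len(n))) stop("pairing must be fixed-point free")
  if (any(pairing[pairing] != seq_len(n))) stop("pairing must be an involution")
  pairing
}

#' Validate an Ising model object
#'
#' Checks symmetry and zero diagonal of `J`, positivity of `beta`, and that
#' any homotopic pairing is a fixed-point-free involution.
#'
#' @param m an [ising_model()].
#' @return `m`, invisibly; errors describe the violated invariant.
#' @export
validate_ising_model <- function(m) {
  stopifnot(inherits(m, "ising_model"))
  n <- length(m$h)
  if (!is.numeric(m$h) || anyNA(m$h)) stop("h must be finite numeric")
  if (!is.matrix(m$J) || nrow(m$J) != n || ncol(m$J) != n)
    stop("J must be a square matrix matching length(h)")
  if (anyNA(m$J) || any(!is.finite(m$J))) stop("J must be finite")
  if (max(abs(m$J - t(m$J))) > 1e-10) stop("J must be symmetric")
  if (any(diag(m$J) != 0)) stop("J must have a zero diagonal")
  if (!is.null(m$beta) && (!is.numeric(m$beta) || m$beta <= 0))
    stop("beta must be positive when present")
  if (!is.null(m$pairing)) validate_pairing(m$pairing, n)
  if (length(m$parcel_labels) != n) stop("parcel_labels length mismatch")
  invisible(m)
}

n_parcels <- function(x) {
  if (inherits(x, "ising_model")) return(length(x$h))
  if (inherits(x, "binary_series") || inherits(x, "parcel_ts"))
    return(nrow(x$values %||% x$states))
  stop("unsupported object")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ising_model <- function(x, ...) {
  n <- length(x$h)
  cat(sprintf("Ising model: %d parcels, %d nonzero couplings%s\n",
              n, sum(x$J[upper.tri(x$J)] != 0),
              if (is.null(x$beta)) "" else sprintf(", beta = %.4g", x$beta)))
  invisible(x)
}

#' Energy of a spin configuration
#'
#' @param state vector in `{-1, +1}^N` (a single spin configuration).
#' @param model an [ising_model()].
#' @return The energy `H(state)` with pairs counted once. The model's `beta`
#'   is not applied here; it only enters the Boltzmann weight.
#' @export
hamiltonian <- function(state, model) {
  state <- check_spin_state(state, length(model$h))
  -0.5 * sum(state * (model$J %*% state)) - sum(model$h * state)
}

check_spin_state <- function(state, n) {
  state <- as.numeric(state)
  if (length(state) != n) stop("state length does not match the model")
  if (!all(state %in% c(-1, 1))) stop("state entries must be -1 or +1")
  state
}

#' Conditional probability of one spin given all the others
#'
#' Under the pseudo-likelihood factorization, the probability that spin `i`
#' is +1 given the remaining spins is a logistic function of its local field:
#' \eqn{P(\sigma_i = +1 \mid \sigma_{/i}) =
#'   1 / (1 + e^{-2\beta(h_i + \sum_{j \ne i} J_{ij}\sigma_j)})}.
#'
#' @param state spin configuration (the value of `state[i]` is ignored).
#' @param model an [ising_model()].
#' @param i spin index.
#' @param beta inverse temperature; defaults to the model's `beta` or 1.
#' @return Probability in (0, 1) that spin `i` is +1.
#' @export
conditional_prob <- function(state, model, i, beta = NULL) {
  state <- check_spin_state(state, length(model$h))
  if (i < 1 || i > length(model$h)) stop("spin index out of range")
  beta <- beta %||% model$beta %||% 1
  f <- model$h[i] + sum(model$J[i, -i] * state[-i])
  1 / (1 + exp(-2 * beta * f))
}

#' Enumerate all spin configurations of a small system
#'
#' @param n number of spins (at most 20).
#' @return A `2^n x n` matrix of -1/+1 rows.
#' @keywords internal
enumerate_states <- function(n) {
  if (n > 20) stop("exact enumeration is limited to 20 spins")
  states <- matrix(0L, 2^n, n)
  for (j in seq_len(n))
    states[, j] <- rep(rep(c(-1L, 1L), each = 2^(n - j)), times = 2^(j - 1))
  states
}

#' Exact Boltzmann distribution by enumeration
#'
#' Enumerates all `2^N` configurations and returns their Boltzmann
#' probabilities \eqn{P(\sigma) = e^{-\beta H(\sigma)} / Z}. Intended as an
#' oracle for validating the sampler and the fitters on small systems.
#'
#' @param model an [ising_model()] with at most 20 spins.
#' @param beta positive inverse temperature (defaults to the model's, or 1).
#' @return A list of class `state_distribution` with elements `states`
#'   (matrix of configurations), `prob`, `log_weight`, `partition` (Z, scaled
#'   by `exp(max log-weight)` shift for stability: `partition` is reported on
#'   the original scale), `energy`, and `beta`.
#' @export
exact_distribution <- function(model, beta = NULL) {
  validate_ising_model(model)
  beta <- beta %||% model$beta %||% 1
  if (beta <= 0) stop("beta must be positive")
  n <- length(model$h)
  if (n > 20) stop("exact enumeration is limited to 20 spins")
  S <- enumerate_states(n)
  E <- state_energies(S, model)
  lw <- -beta * E
  mx <- max(lw)
  w <- exp(lw - mx)
  Z <- sum(w)
  structure(list(states = S, prob = w / Z, energy = E,
                 partition = Z * exp(mx), beta = beta),
            class = "state_distribution")
}

state_energies <- function(S, model) {
  # S: m x n matrix of configurations (rows)
  -0.5 * rowSums((S %*% model$J) * S) - as.numeric(S %*% model$h)
}

#' Exact ensemble observables by enumeration
#'
#' Computes magnetization, energy, susceptibility, heat capacity, and local
#' and link susceptibilities as exact sums over all `2^N` states:
#' \eqn{\chi = \mathrm{Var}(M)/T}, \eqn{C_v = \mathrm{Var}(H)/T^2},
#' \eqn{\chi_n = \beta(\langle M\sigma_n\rangle - \langle M\rangle\langle\sigma_n\rangle)},
#' \eqn{l_{ij} = \beta(\langle M\sigma_i\sigma_j\rangle - \langle M\rangle\langle\sigma_i\sigma_j\rangle)},
#' and \eqn{L_{ij} = l_{ij} J_{ij}}. `M` is the un-normalized sum of spins.
#'
#' With `convention = "branch_flipped"` every configuration is reflected by
#' the sign of its magnetization (\eqn{\sigma \to \sigma\,\mathrm{sign}(M)},
#' with sign(0) taken as +1) before averaging, the smoothing used to tame
#' finite-size bistability below the critical point.
#'
#' @param model an [ising_model()] with at most 20 spins.
#' @param beta inverse temperature (defaults to the model's, or 1).
#' @param convention `"raw"` or `"branch_flipped"`.
#' @return An object of class `observable_estimates`.
#' @export
exact_observables <- function(model, beta = NULL,
                              convention = c("raw", "branch_flipped")) {
  convention <- match.arg(convention)
  dist <- exact_distribution(model, beta)
  S <- dist$states
  p <- dist$prob
  E <- dist$energy
  beta <- dist$beta
  M <- rowSums(S)
  if (convention == "branch_flipped") {
    flip <- ifelse(M < 0, -1, 1)
    S <- S * flip
    M <- M * flip
    E <- state_energies(S, model)
  }
  Tt <- 1 / beta
  mean_M <- sum(p * M)
  var_M <- sum(p * M^2) - mean_M^2
  mean_E <- sum(p * E)
  var_E <- sum(p * E^2) - mean_E^2
  mean_s <- as.numeric(t(S) %*% p)
  mean_Ms <- as.numeric(t(S) %*% (p * M))
  chi_n <- beta * (mean_Ms - mean_M * mean_s)
  C2 <- t(S) %*% (S * p)             # <s_i s_j>
  CM <- t(S) %*% (S * (p * M))       # <M s_i s_j>
  l <- beta * (CM - mean_M * C2)
  diag(l) <- 0
  l <- (l + t(l)) / 2
  new_observable_estimates(
    mean_magnetization = mean_M, mean_energy = mean_E,
    susceptibility = var_M / Tt, heat_capacity = var_E / Tt^2,
    local_susceptibility = chi_n, link_susceptibility = l,
    scaled_link_susceptibility = l * model$J,
    pair_correlations = C2, mean_spins = mean_s,
    standard_errors = NULL, convention = convention, temperature = Tt)
}

new_observable_estimates <- function(...) {
  structure(list(...), class = "observable_estimates")
}

#' @export
print.observable_estimates <- function(x, ...) {
  cat(sprintf(
    "Observables (%s, T = %.4g): <M> = %.4g, chi = %.4g, <H> = %.4g, Cv = %.4g\n",
    x$convention, x$temperature, x$mean_magnetization, x$susceptibility,
    x$mean_energy, x$heat_capacity))
  invisible(x)
}

#' Draw exact samples from a small model by enumeration
#'
#' @param model an [ising_model()] with at most 20 spins.
#' @param n_samples number of independent configurations to draw.
#' @param beta inverse temperature.
#' @return A `binary_series` whose columns are independent exact samples.
#' @export
exact_sample <- function(model, n_samples, beta = NULL) {
  dist <- exact_distribution(model, beta)
  idx <- sample.int(nrow(dist$states), n_samples, replace = TRUE,
                    prob = dist$prob)
  binary_series(t(dist$states[idx, , drop = FALSE]),
                parcel_labels = model$parcel_labels,
                pairing = model$pairing,
                provenance = list(source = "exact_sample",
                                  beta = dist$beta))
}
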