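#' Metropolis sampler settings
#'
#' @param n_flip_attempts total single-spin flip attempts (including burn-in).
#' @param burn_in attempts discarded before sampling starts.
#' @param thinning attempts between retained samples (one sweep = N attempts).
#' @param seed integer seed, or `NULL` to continue the current RNG stream.
#' @param branch_flip default convention for observable estimation: reflect
#'   each retained sample by the sign of its magnetization.
#' @return An object of class `metropolis_config`.
#' @export
metropolis_config <- function(n_flip_attempts = 1e6, burn_in = 1e4,
                              thinning = 1, seed = 1, branch_flip = TRUE) {
  if (n_flip_attempts <= burn_in) stop("n_flip_attempts must exceed burn_in")
  if (burn_in < 0) stop("burn_in must be >= 0")
  if (thinning < 1) stop("thinning must be >= 1")
  structure(list(n_flip_attempts = n_flip_attempts, burn_in = burn_in,
                 thinning = thinning, seed = seed, branch_flip = branch_flip),
            class = "metropolis_config")
}

#' Energy change of a single spin flip
#'
#' Returns `2 * s_k * (sum_j J_jk s_j + h_k)`, the exact difference
#' `H(flipped) - H(state)` used in the Metropolis acceptance rule.
#'
#' @param state spin configuration in `{-1, +1}^N`.
#' @param model an [ising_model()].
#' @param k index of the spin to flip.
#' @return Numeric energy difference.
#' @export
delta_energy <- function(state, model, k) {
  state <- check_spin_state(state, length(model$h))
  if (k < 1 || k > length(state)) stop("spin index out of range")
  2 * state[k] * (sum(model$J[, k] * state) + model$h[k])
}

#' Run a Metropolis chain at a given temperature
#'
#' Random-site single-flip Metropolis with acceptance probability
#' `min(1, exp(-dH / T))`. Energy is tracked incrementally and re-verified
#' against a from-scratch Hamiltonian evaluation at the end of the chain.
#'
#' @param model an [ising_model()].
#' @param T positive system temperature.
#' @param config a [metropolis_config()].
#' @param init_state optional starting configuration; random by default.
#' @param store_states keep the retained spin configurations (needed for
#'   local/link susceptibilities and complexity; scalar observables only need
#'   the energy and magnetization traces).
#' @return An object of class `sample_chain` with elements `states`
#'   (samples x N or `NULL`), `energy`, `magnetization`, `acceptance_rate`,
#'   `temperature`, and `config`.
#' @export
metropolis_run <- function(model, T, config = metropolis_config(),
                           init_state = NULL, store_states = TRUE) {
  validate_ising_model(model)
  stopifnot(inherits(config, "metropolis_config"))
  if (T <= 0) stop("temperature must be positive")
  n <- length(model$h)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(init_state)) {
    init_state <- sample(c(-1L, 1L), n, replace = TRUE)
  } else {
    init_state <- as.integer(check_spin_state(init_state, n))
  }
  res <- metropolis_run_cpp(model$h, model$J, T, config$n_flip_attempts,
                            config$burn_in, as.integer(config$thinning),
                            store_states, init_state)
  if (abs(res$final_energy - res$final_energy_recomputed) > 1e-6)
    stop("incremental energy bookkeeping drifted; this is a bug")
  structure(list(states = res$states, energy = as.numeric(res$energy),
                 magnetization = as.numeric(res$magnetization),
                 acceptance_rate = res$acceptance_rate,
                 final_state = res$final_state,
                 temperature = T, config = config),
            class = "sample_chain")
}

#' @export
print.sample_chain <- function(x, ...) {
  cat(sprintf("Metropolis chain: %d samples at T = %.4g (acceptance %.1f%%)\n",
              length(x$energy), x$temperature, 100 * x$acceptance_rate))
  invisible(x)
}

#' Estimate ensemble observables from a Metropolis chain
#'
#' Sample-average estimators of mean magnetization, mean energy,
#' susceptibility `Var(M)/T`, heat capacity `Var(H)/T^2`, local
#' susceptibility `chi_n`, and link susceptibility `l_ij` (with its scaled
#' form `L_ij = l_ij J_ij`). Standard errors come from a moving-block
#' bootstrap over contiguous blocks of retained samples, which absorbs the
#' chain's autocorrelation.
#'
#' With `convention = "branch_flipped"` each retained sample is reflected by
#' the sign of its magnetization before averaging (sign(0) treated as +1),
#' removing the finite-size bistability of the ordered phase.
#'
#' @param chain a [sample_chain()] from [metropolis_run()].
#' @param model the sampled [ising_model()].
#' @param T temperature the chain was run at (defaults to the chain's).
#' @param convention `"raw"` or `"branch_flipped"`.
#' @param include_links also estimate the `N x N` link susceptibilities
#'   (quadratic in N; switch off for large lattices).
#' @param n_blocks number of bootstrap blocks.
#' @param n_boot bootstrap replicates.
#' @return An `observable_estimates` object with a `standard_errors` list.
#' @export
estimate_observables <- function(chain, model, T = NULL,
                                 convention = c("raw", "branch_flipped"),
                                 include_links = TRUE, n_blocks = 50,
                                 n_boot = 200) {
  convention <- match.arg(convention)
  stopifnot(inherits(chain, "sample_chain"))
  T <- T %||% chain$temperature
  n_s <- length(chain$energy)
  if (n_s < 100) stop("too few samples (< 100) for observable estimation")
  if (is.null(chain$states))
    stop("chain was run with store_states = FALSE; states are required")
  S <- chain$states                     # samples x N, integer
  M <- chain$magnetization
  E <- chain$energy
  if (convention == "branch_flipped") {
    flip <- ifelse(M < 0, -1, 1)
    f <- as.numeric(S %*% model$h)      # field part of the energy
    S <- S * flip
    M <- M * flip
    E <- E + f - flip * f               # pair term is flip-invariant
  }
  beta <- 1 / T
  est <- observables_from_stats(S, M, E, model, T, include_links)
  se <- block_bootstrap_se(S, M, E, model, T, include_links,
                           n_blocks, n_boot)
  new_observable_estimates(
    mean_magnetization = est$mean_M, mean_energy = est$mean_E,
    susceptibility = est$chi, heat_capacity = est$Cv,
    local_susceptibility = est$chi_n,
    link_susceptibility = est$l,
    scaled_link_susceptibility = if (include_links) est$l * model$J else NULL,
    pair_correlations = est$C2, mean_spins = est$mean_s,
    standard_errors = se, convention = convention, temperature = T,
    n_samples = n_s)
}

observables_from_stats <- function(S, M, E, model, T, include_links) {
  beta <- 1 / T
  n_s <- nrow(S)
  mean_M <- mean(M); mean_E <- mean(E)
  chi <- (mean(M^2) - mean_M^2) / T
  Cv <- (mean(E^2) - mean_E^2) / T^2
  mean_s <- colMeans(S)
  mean_Ms <- as.numeric(crossprod(S, M)) / n_s
  chi_n <- beta * (mean_Ms - mean_M * mean_s)
  l <- C2 <- NULL
  if (include_links) {
    C2 <- crossprod(S) / n_s
    CM <- crossprod(S, S * M) / n_s
    l <- beta * (CM - mean_M * C2)
    diag(l) <- 0
    l <- (l + t(l)) / 2
  }
  list(mean_M = mean_M, mean_E = mean_E, chi = chi, Cv = Cv,
       mean_s = mean_s, chi_n = chi_n, l = l, C2 = C2)
}

block_bootstrap_se <- function(S, M, E, model, T, include_links,
                               n_blocks, n_boot) {
  n_s <- nrow(S)
  n_blocks <- min(n_blocks, n_s %/% 2)
  idx <- split(seq_len(n_s), cut(seq_len(n_s), n_blocks, labels = FALSE))
  # per-block sufficient statistics
  bs <- lapply(idx, function(ii) {
    Si <- S[ii, , drop = FALSE]
    Mi <- M[ii]; Ei <- E[ii]
    st <- list(M = mean(Mi), M2 = mean(Mi^2), E = mean(Ei), E2 = mean(Ei^2),
               s = colMeans(Si), Ms = as.numeric(crossprod(Si, Mi)) / length(ii))
    if (include_links) {
      st$C2 <- crossprod(Si) / length(ii)
      st$CM <- crossprod(Si, Si * Mi) / length(ii)
    }
    st
  })
  beta <- 1 / T
  draw <- function() {
    pick <- sample.int(n_blocks, n_blocks, replace = TRUE)
    avg <- function(name) Reduce(`+`, lapply(bs[pick], `[[`, name)) / n_blocks
    mM <- avg("M"); mE <- avg("E")
    out <- list(mean_M = mM, mean_E = mE,
                chi = (avg("M2") - mM^2) / T,
                Cv = (avg("E2") - mE^2) / T^2,
                chi_n = beta * (avg("Ms") - mM * avg("s")))
    if (include_links) {
      l <- beta * (avg("CM") - mM * avg("C2"))
      diag(l) <- 0
      out$l <- (l + t(l)) / 2
    }
    out
  }
  reps <- replicate(n_boot, draw(), simplify = FALSE)
  se_of <- function(name) {
    vals <- lapply(reps, `[[`, name)
    if (is.matrix(vals[[1]])) {
      apply(simplify2array(vals), c(1, 2), sd)
    } else if (length(vals[[1]]) > 1) {
      apply(do.call(rbind, vals), 2, sd)
    } else {
      sd(unlist(vals))
    }
  }
  out <- list(mean_magnetization = se_of("mean_M"),
              mean_energy = se_of("mean_E"),
              susceptibility = se_of("chi"),
              heat_capacity = se_of("Cv"),
              local_susceptibility = se_of("chi_n"))
  if (include_links) out$link_susceptibility <- se_of("l")
  out
}

#' Sweep observables and complexity across a temperature grid
#'
#' Runs an independent Metropolis chain per temperature (chain `i` is seeded
#' deterministically as `config$seed + i`) and estimates the scalar
#' observables at the requested convention. When `complexity = TRUE`, each
#' retained lattice sample contributes its N-spin configuration: the samples
#' are concatenated in chain order into one binary string per temperature for
#' the aggregate LZW rate `rho0`, per-sample strings give the rho0 spread,
#' and the sample matrix is scored with the Block Decomposition Method both
#' whole and in contiguous segments for a spread estimate.
#'
#' @param model an [ising_model()].
#' @param T_grid strictly increasing temperature grid.
#' @param config a [metropolis_config()]; `config$branch_flip` selects the
#'   estimation convention.
#' @param complexity compute LZW/BDM summaries per temperature.
#' @param ctm a [ctm_table()] or `NULL` for the entropy fallback.
#' @param block_shape BDM block shape.
#' @param include_links keep link susceptibilities per temperature.
#' @param n_segments number of chain segments for the BDM spread.
#' @return An object of class `observable_sweep`: a list with `table` (one
#'   row per temperature) and `observables` (per-T `observable_estimates`).
#' @export
temperature_sweep <- function(model, T_grid, config = metropolis_config(),
                              complexity = TRUE, ctm = NULL,
                              block_shape = c(4, 4), include_links = FALSE,
                              n_segments = 20) {
  validate_ising_model(model)
  if (length(T_grid) < 1) stop("temperature grid is empty")
  if (is.unsorted(T_grid, strictly = TRUE))
    stop("temperature grid must be strictly increasing")
  convention <- if (isTRUE(config$branch_flip)) "branch_flipped" else "raw"
  base_seed <- config$seed %||% 0
  rows <- vector("list", length(T_grid))
  obs_list <- vector("list", length(T_grid))
  for (i in seq_along(T_grid)) {
    cfg_i <- config
    cfg_i$seed <- base_seed + i
    chain <- metropolis_run(model, T_grid[i], cfg_i)
    obs <- estimate_observables(chain, model, T_grid[i],
                                convention = convention,
                                include_links = include_links)
    row <- data.frame(
      T = T_grid[i],
      mean_M = obs$mean_magnetization,
      chi = obs$susceptibility,
      Cv = obs$heat_capacity,
      mean_E = obs$mean_energy,
      se_M = obs$standard_errors$mean_magnetization,
      se_chi = obs$standard_errors$susceptibility,
      se_Cv = obs$standard_errors$heat_capacity,
      acceptance = chain$acceptance_rate)
    if (complexity) {
      cx <- sweep_complexity(chain, model, ctm, block_shape, n_segments)
      row <- cbind(row, cx)
    }
    rows[[i]] <- row
    obs_list[[i]] <- obs
  }
  structure(list(table = do.call(rbind, rows), observables = obs_list,
                 convention = convention, model = model),
            class = "observable_sweep")
}

sweep_complexity <- function(chain, model, ctm, block_shape, n_segments) {
  # samples in chain order as time frames of a binary series
  bs <- binary_series(t(chain$states),
                      parcel_labels = model$parcel_labels,
                      pairing = model$pairing)
  s_all <- flatten_binary(bs)
  concat <- lzw_compress(s_all)
  per <- apply(chain$states, 1, function(r) {
    s <- spins_to_string(r)
    c_n <- lzw_compress_cpp(s, character(0))$n_codes
    (if (c_n > 1) c_n * log2(c_n) else 1) / nchar(s)
  })
  b_all <- bdm(bs$states, table = ctm, block_shape = block_shape)
  n_s <- ncol(bs$states)
  seg <- cut(seq_len(n_s), n_segments, labels = FALSE)
  b_seg <- vapply(split(seq_len(n_s), seg), function(ii)
    bdm(bs$states[, ii, drop = FALSE], table = ctm,
        block_shape = block_shape)$bdm, numeric(1))
  data.frame(rho0_concat = concat$rho0,
             rho0_sample_mean = mean(per), rho0_sample_sd = sd(per),
             bdm = b_all$bdm,
             bdm_segment_mean = mean(b_seg), bdm_segment_sd = sd(b_seg))
}

#' Locate the critical temperature from a sweep
#'
#' Takes the grid argmax of the susceptibility and refines it by quadratic
#' interpolation through the three points around the maximum.
#'
#' @param sweep an `observable_sweep` (or its `table`).
#' @return The refined peak temperature. Errors if the maximum sits on the
#'   grid boundary, where the peak cannot be bracketed.
#' @export
find_critical_temperature <- function(sweep) {
  tab <- if (inherits(sweep, "observable_sweep")) sweep$table else sweep
  k <- which.max(tab$chi)
  if (k == 1 || k == nrow(tab))
    stop("susceptibility maximum lies on the grid boundary; widen the grid")
  x <- tab$T[(k - 1):(k + 1)]
  y <- tab$chi[(k - 1):(k + 1)]
  d1 <- (y[3] - y[1]) / 2
  d2 <- y[3] - 2 * y[2] + y[1]
  if (d2 >= 0) return(x[2])  # degenerate curvature: keep the grid argmax
  # vertex of the parabola through the three points (uniform grid assumed
  # locally; non-uniform grids fall back to an exact 3-point fit)
  if (abs((x[3] - x[2]) - (x[2] - x[1])) < 1e-12) {
    x[2] - (x[2] - x[1]) * d1 / d2
  } else {
    fit <- lm(y ~ poly(x, 2, raw = TRUE))
    b <- coef(fit)
    -b[2] / (2 * b[3])
  }
}

#' Scale homotopic or matched random links of a model
#'
#' `selector = "homotopic"` multiplies every homotopic coupling
#' `J[i, pair(i)]` by `factor` (symmetrically). `selector = "random_matched"`
#' instead scales an equal count of randomly chosen nonzero non-homotopic
#' links, the control used to show that homotopic links carry a
#' disproportionate share of the ordering interaction.
#'
#' @param model an [ising_model()] with a pairing.
#' @param selector `"homotopic"` or `"random_matched"`.
#' @param factor non-negative scale factor.
#' @param seed seed for the random link choice.
#' @return A new [ising_model()].
#' @export
perturb_links <- function(model, selector = c("homotopic", "random_matched"),
                          factor = 0.8, seed = 1) {
  selector <- match.arg(selector)
  validate_ising_model(model)
  if (factor < 0) stop("factor must be >= 0")
  if (is.null(model$pairing)) stop("model has no homotopic pairing")
  n <- length(model$h)
  J <- model$J
  pair_idx <- which(model$pairing > seq_len(n))  # each pair once
  if (selector == "homotopic") {
    for (i in pair_idx) {
      j <- model$pairing[i]
      J[i, j] <- J[j, i] <- factor * J[i, j]
    }
  } else {
    set.seed(seed)
    ut <- which(upper.tri(J), arr.ind = TRUE)
    is_homotopic <- model$pairing[ut[, 1]] == ut[, 2]
    candidates <- which(!is_homotopic & J[ut] != 0)
    need <- length(pair_idx)
    if (length(candidates) < need)
      stop("not enough nonzero non-homotopic links to match")
    chosen <- ut[sample(candidates, need), , drop = FALSE]
    for (r in seq_len(nrow(chosen))) {
      i <- chosen[r, 1]; j <- chosen[r, 2]
      J[i, j] <- J[j, i] <- factor * J[i, j]
    }
  }
  ising_model(model$h, J, beta = model$beta,
              parcel_labels = model$parcel_labels, pairing = model$pairing)
}
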