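#' Specification of a synthetic archetype coupling structure
#'
#' Describes a two-hemisphere Ising connectome of the kind recovered from
#' resting-state data: two mostly-positive intra-hemispheric blocks, strong
#' positive homotopic (mirror-pair) interhemispheric links, and weak,
#' typically negative, remaining interhemispheric links. The defaults give an
#' archetype whose critical temperature sits below 1, so that a cohort
#' sampled at nominal temperature 1 lives in the paramagnetic phase.
#'
#' @param n_parcels even number of parcels (default 16).
#' @param intra_strength mean positive intra-hemispheric coupling.
#' @param homotopic_strength mean homotopic coupling (positive, strong).
#' @param inter_strength mean non-homotopic interhemispheric coupling
#'   (small, typically negative).
#' @param coupling_noise_sd Gaussian jitter applied to every drawn coupling.
#' @param field_sd standard deviation of the external fields `h`.
#' @param density fraction of intra-hemispheric pairs that receive a nonzero
#'   coupling, in (0, 1].
#' @return An object of class `archetype_spec`.
#' @export
archetype_spec <- function(n_parcels = 16, intra_strength = 0.1,
                           homotopic_strength = 0.6, inter_strength = -0.02,
                           coupling_noise_sd = 0.05, field_sd = 0.05,
                           density = 1) {
  if (n_parcels %% 2 != 0) stop("n_parcels must be even")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  if (coupling_noise_sd < 0 || field_sd < 0) stop("sds must be >= 0")
  structure(list(n_parcels = n_parcels, intra_strength = intra_strength,
                 homotopic_strength = homotopic_strength,
                 inter_strength = inter_strength,
                 coupling_noise_sd = coupling_noise_sd,
                 field_sd = field_sd, density = density),
            class = "archetype_spec")
}

#' Draw a ground-truth archetype model
#'
#' Builds a symmetric zero-diagonal coupling matrix with the block structure
#' described by the spec: homotopic entries `J[i, pair(i)]` drawn around
#' `homotopic_strength`, intra-hemispheric entries around `intra_strength`
#' at the given density, remaining interhemispheric entries around
#' `inter_strength`, and fields `h ~ Normal(0, field_sd^2)`.
#'
#' @param spec an [archetype_spec()].
#' @param seed integer seed; the same spec and seed give the same model.
#' @return An [ising_model()] with mirror pairing.
#' @export
make_archetype <- function(spec = archetype_spec(), seed = 1) {
  stopifnot(inherits(spec, "archetype_spec"))
  n <- spec$n_parcels
  set.seed(seed)
  hemi <- hemisphere_split(n)
  pairing <- mirror_pairing(n)
  J <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (pairing[i] == j) {
        v <- spec$homotopic_strength + rnorm(1, 0, spec$coupling_noise_sd)
      } else if (hemi[i] == hemi[j]) {
        if (runif(1) > spec$density) next
        v <- spec$intra_strength + rnorm(1, 0, spec$coupling_noise_sd)
      } else {
        v <- spec$inter_strength + rnorm(1, 0, spec$coupling_noise_sd)
      }
      J[i, j] <- J[j, i] <- v
    }
  }
  h <- rnorm(n, 0, spec$field_sd)
  ising_model(h, J, pairing = pairing)
}

#' Cohort simulation settings
#'
#' The defaults mirror the study design the pipeline targets: 15 subjects,
#' two conditions with two sessions each, 217 time points per session, and a
#' +7% relative temperature shift of condition B over condition A with
#' subject-level variability of about 5 percentage points.
#'
#' @param n_subjects number of subjects.
#' @param conditions two condition labels; the first is the reference.
#' @param base_temperature mean condition-A temperature (> 0).
#' @param temperature_shift mean relative shift of condition B vs A.
#' @param subject_temperature_sd log-scale sd of the subject baseline
#'   temperatures (log-normal draws keep temperatures positive).
#' @param shift_sd sd of the per-subject additive noise on the shift.
#' @param t_max time points per session.
#' @param sessions sessions per subject and condition.
#' @param seed integer seed.
#' @param burn_in_per_spin Metropolis burn-in attempts per spin before each
#'   session chain (sessions are sampled as independent chains).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 15, conditions = c("A", "B"),
                          base_temperature = 1, temperature_shift = 0.07,
                          subject_temperature_sd = 0.05, shift_sd = 0.05,
                          t_max = 217, sessions = 2, seed = 1,
                          burn_in_per_spin = 1000) {
  if (base_temperature <= 0) stop("base_temperature must be > 0")
  if (t_max < 2) stop("t_max must be >= 2")
  if (length(conditions) != 2) stop("exactly two conditions are supported")
  structure(list(n_subjects = n_subjects, conditions = conditions,
                 base_temperature = base_temperature,
                 temperature_shift = temperature_shift,
                 subject_temperature_sd = subject_temperature_sd,
                 shift_sd = shift_sd, t_max = t_max, sessions = sessions,
                 seed = seed, burn_in_per_spin = burn_in_per_spin),
            class = "cohort_config")
}

#' Simulate a synthetic cohort from an archetype
#'
#' For each subject `s` a baseline temperature `T_s(A)` is drawn log-normally
#' around `base_temperature`, and the second condition gets
#' `T_s(B) = T_s(A) * (1 + temperature_shift + noise)`. Every session is an
#' independent Metropolis chain at the subject/condition temperature, burned
#' in and thinned to one retained lattice per sweep, giving a
#' `n_parcels x t_max` binary series. The programmed temperatures are stored
#' as ground truth.
#'
#' @param archetype an [ising_model()].
#' @param config a [cohort_config()].
#' @return A list of class `ising_cohort` with `manifest`, `series` (keyed
#'   `subject|condition|session`), and `ground_truth`.
#' @export
simulate_cohort <- function(archetype, config = cohort_config()) {
  validate_ising_model(archetype)
  stopifnot(inherits(config, "cohort_config"))
  n <- length(archetype$h)
  set.seed(config$seed)
  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  temps <- matrix(NA_real_, config$n_subjects, 2,
                  dimnames = list(subjects, config$conditions))
  for (s in seq_len(config$n_subjects)) {
    tA <- config$base_temperature *
      exp(rnorm(1, 0, config$subject_temperature_sd))
    tB <- tA * (1 + config$temperature_shift + rnorm(1, 0, config$shift_sd))
    tries <- 0
    while (tB <= 0 && tries < 100) {
      tB <- tA * (1 + config$temperature_shift + rnorm(1, 0, config$shift_sd))
      tries <- tries + 1
    }
    if (tB <= 0) stop("could not draw a positive condition-B temperature")
    temps[s, ] <- c(tA, tB)
  }
  series <- list()
  mcfg_base <- list(burn_in = config$burn_in_per_spin * n, thinning = n)
  for (s in seq_len(config$n_subjects)) {
    for (ci in 1:2) {
      for (se in seq_len(config$sessions)) {
        cfg <- metropolis_config(
          n_flip_attempts = mcfg_base$burn_in + config$t_max * n,
          burn_in = mcfg_base$burn_in, thinning = n,
          seed = NULL)  # RNG stream already positioned by config$seed
        chain <- metropolis_run(archetype, temps[s, ci], cfg)
        key <- series_key(subjects[s], config$conditions[ci], se)
        series[[key]] <- binary_series(
          t(chain$states), parcel_labels = archetype$parcel_labels,
          pairing = archetype$pairing,
          provenance = list(subject = subjects[s],
                            condition = config$conditions[ci],
                            session = se, temperature = temps[s, ci]))
      }
    }
  }
  manifest <- cohort_manifest(subjects = subjects,
                              conditions = config$conditions,
                              sessions_per_condition = config$sessions,
                              parcel_labels = archetype$parcel_labels,
                              pairing = archetype$pairing)
  structure(list(manifest = manifest, series = series,
                 ground_truth = list(archetype = archetype,
                                     temperatures = temps,
                                     config = config)),
            class = "ising_cohort")
}

#' @export
print.ising_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Cohort: %d subjects x %d conditions x %d sessions, %d parcels\n",
              length(m$subjects), length(m$conditions),
              m$sessions_per_condition, length(m$parcel_labels)))
  invisible(x)
}

#' Render a pseudo-continuous series from binary states
#'
#' Produces `x[p, t] = amplitude * s[p, t] + Normal(0, noise_sd^2)` so the
#' median-binarization stage can be exercised on continuous input with known
#' ground truth.
#'
#' @param binary a [binary_series()].
#' @param amplitude positive scale of the two levels.
#' @param noise_sd additive Gaussian noise sd (>= 0).
#' @param seed integer seed.
#' @return A [parcel_ts()].
#' @export
render_pseudo_bold <- function(binary, amplitude = 1, noise_sd = 0.1,
                               seed = 1) {
  stopifnot(inherits(binary, "binary_series"))
  if (amplitude <= 0) stop("amplitude must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  v <- amplitude * binary$states +
    matrix(rnorm(length(binary$states), 0, noise_sd),
           nrow(binary$states), ncol(binary$states))
  parcel_ts(v, parcel_labels = binary$parcel_labels)
}
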