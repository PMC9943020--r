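#' Analysis configuration for the end-to-end pipeline
#'
#' Gathers every tunable of the full analysis; all randomness is derived
#' deterministically from `seed`, so identical configurations reproduce
#' identical reports.
#'
#' @param seed master integer seed.
#' @param fit a [fit_config()] for archetype and temperature fits.
#' @param sampler a [metropolis_config()] used when generating model-side
#'   synthetic data for the complexity comparison (its `seed` is ignored;
#'   chain seeds derive from `seed`).
#' @param n_perm permutations for the parcel-label test.
#' @param bdm_block_shape BDM block shape.
#' @param ctm optional [ctm_table()].
#' @param flatten_order flattening order for LZW input.
#' @param condition_order condition order for the archetype dictionary
#'   (default: manifest order).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(seed = 1, fit = fit_config(),
                            sampler = metropolis_config(),
                            n_perm = 1000, bdm_block_shape = c(4, 4),
                            ctm = NULL, flatten_order = "space_then_time",
                            condition_order = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  structure(list(seed = seed, fit = fit, sampler = sampler, n_perm = n_perm,
                 bdm_block_shape = bdm_block_shape, ctm = ctm,
                 flatten_order = flatten_order,
                 condition_order = condition_order),
            class = "analysis_config")
}

#' Run the full condition-contrast analysis on a cohort
#'
#' Orchestrates the whole pipeline: (1) fit the global archetype to the
#' concatenated data of all subjects and conditions; (2) fit per-condition
#' archetypes and compare their connectivity; (3) personalize the global
#' archetype per subject and condition by fitting the temperature; (4) score
#' LZW and BDM complexity of each subject's data (LZW seeded with the
#' cohort-wide archetype dictionary) and of model-generated synthetic data
#' at the fitted temperature; (5) run the paired condition tests, the
#' parcel-label permutation test, and the between-metric correlations.
#'
#' @param cohort an `ising_cohort` (binary series).
#' @param config an [analysis_config()].
#' @return A list of class `analysis_report`.
#' @export
run_pipeline <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(cohort, "ising_cohort"))
  man <- cohort$manifest
  if (length(man$conditions) != 2)
    stop("pipeline expects exactly two conditions")
  cond <- man$conditions
  subjects <- man$subjects
  n <- length(man$parcel_labels)

  # -- archetypes ----------------------------------------------------------
  global_data <- assemble_condition_data(cohort, "global")
  global_fit <- with_stage("global archetype fit",
                           fit_archetype(global_data, config$fit))
  archetype <- global_fit$model
  cond_fits <- lapply(cond, function(co)
    with_stage(paste("archetype fit, condition", co),
               fit_archetype(assemble_condition_data(cohort, "condition",
                                                     condition = co),
                             config$fit)))
  names(cond_fits) <- cond
  comparison <- compare_archetypes(cond_fits[[1]]$model, cond_fits[[2]]$model)

  # -- personalization -----------------------------------------------------
  per <- expand.grid(subject = subjects, condition = cond,
                     stringsAsFactors = FALSE)
  per$beta <- NA_real_
  per$temperature <- NA_real_
  subj_data <- list()
  for (r in seq_len(nrow(per))) {
    key <- paste(per$subject[r], per$condition[r], sep = "|")
    dat <- assemble_condition_data(cohort, "subject_condition",
                                   condition = per$condition[r],
                                   subject = per$subject[r])
    subj_data[[key]] <- dat
    ft <- with_stage(paste("temperature fit", key),
                     fit_temperature(dat, archetype, config$fit))
    per$beta[r] <- ft$beta
    per$temperature[r] <- ft$temperature
  }

  # -- complexity ----------------------------------------------------------
  dict <- build_archetype_dictionary(cohort,
                                     condition_order = config$condition_order,
                                     order = config$flatten_order)
  per$rho0_data <- NA_real_
  per$bdm_data <- NA_real_
  per$rho0_synth <- NA_real_
  per$bdm_synth <- NA_real_
  for (r in seq_len(nrow(per))) {
    key <- paste(per$subject[r], per$condition[r], sep = "|")
    dat <- subj_data[[key]]
    s <- flatten_binary(dat, order = config$flatten_order)
    per$rho0_data[r] <- lzw_compress(s, seed_dictionary = dict)$rho0
    per$bdm_data[r] <- bdm(dat$states, table = config$ctm,
                           block_shape = config$bdm_block_shape)$bdm
    scfg <- config$sampler
    scfg$seed <- config$seed + 1000 + r
    scfg$thinning <- n
    scfg$burn_in <- 1000 * n
    scfg$n_flip_attempts <- scfg$burn_in + ncol(dat$states) * n
    chain <- metropolis_run(archetype, per$temperature[r], scfg)
    synth <- binary_series(t(chain$states), parcel_labels = man$parcel_labels,
                           pairing = man$pairing)
    ss <- flatten_binary(synth, order = config$flatten_order)
    per$rho0_synth[r] <- lzw_compress(ss, seed_dictionary = dict)$rho0
    per$bdm_synth[r] <- bdm(synth$states, table = config$ctm,
                            block_shape = config$bdm_block_shape)$bdm
  }

  # -- condition contrasts -------------------------------------------------
  split_metric <- function(col) {
    a <- per[per$condition == cond[1], col]
    b <- per[per$condition == cond[2], col]
    list(a = a[order(per$subject[per$condition == cond[1]])],
         b = b[order(per$subject[per$condition == cond[2]])])
  }
  contrast <- function(col) {
    v <- split_metric(col)
    list(wilcoxon_one_tailed = paired_condition_test(v$a, v$b, "wilcoxon",
                                                     "greater"),
         t_two_sided = paired_condition_test(v$a, v$b, "t", "two.sided"))
  }
  contrasts <- list(temperature = contrast("temperature"),
                    rho0_data = contrast("rho0_data"),
                    bdm_data = contrast("bdm_data"),
                    rho0_synth = contrast("rho0_synth"),
                    bdm_synth = contrast("bdm_synth"))

  perm <- with_stage("permutation test",
                     permutation_test_temperature(cohort, archetype,
                                                  config$fit,
                                                  n_perm = config$n_perm,
                                                  seed = config$seed + 500))

  deltas <- data.frame(
    dT = split_metric("temperature")$b - split_metric("temperature")$a,
    d_rho0_data = split_metric("rho0_data")$b - split_metric("rho0_data")$a,
    d_rho0_synth = split_metric("rho0_synth")$b - split_metric("rho0_synth")$a,
    d_bdm_data = split_metric("bdm_data")$b - split_metric("bdm_data")$a,
    d_bdm_synth = split_metric("bdm_synth")$b - split_metric("bdm_synth")$a)
  correlations <- correlate_metrics(deltas)

  structure(list(
    archetype = archetype, archetype_fit = global_fit,
    condition_archetypes = lapply(cond_fits, `[[`, "model"),
    archetype_comparison = comparison,
    connectivity = connectivity_metrics(archetype),
    per_subject = per, contrasts = contrasts, permutation = perm,
    deltas = deltas, correlations = correlations,
    provenance = list(seed = config$seed, n_perm = config$n_perm,
                      conditions = cond,
                      n_parcels = n, n_subjects = length(subjects),
                      package_version = as.character(
                        utils::packageVersion("spinglassfc")))),
    class = "analysis_report")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' @export
print.analysis_report <- function(x, ...) {
  cond <- x$provenance$conditions
  tmp <- x$contrasts$temperature
  cat(sprintf("Analysis report: %d subjects, %d parcels\n",
              x$provenance$n_subjects, x$provenance$n_parcels))
  dT <- x$deltas$dT
  a <- x$per_subject$temperature[x$per_subject$condition == cond[1]]
  cat(sprintf("  temperature shift %s vs %s: %.2f%% (Wilcoxon one-tailed p = %.3g)\n",
              cond[2], cond[1], 100 * mean(dT / a),
              tmp$wilcoxon_one_tailed$p_value))
  cat(sprintf("  permutation test p = %.3g (%d permutations)\n",
              x$permutation$p_value, x$permutation$n_perm))
  invisible(x)
}

#' Write an analysis report as structured JSON
#'
#' Serializes the scalar and tabular content of the report (fitted archetype
#' parameters are written alongside with [write_model()] when `model_path`
#' is given). Identical configurations and seeds produce byte-identical
#' files.
#'
#' @param report an `analysis_report`.
#' @param path output JSON path.
#' @param model_path optional path for the fitted archetype model.
#' @export
write_report <- function(report, path, model_path = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  strip <- function(x) {
    if (inherits(x, c("test_result", "permutation_result"))) unclass(x)
    else x
  }
  obj <- list(
    provenance = report$provenance,
    per_subject = report$per_subject,
    contrasts = lapply(report$contrasts, function(cc) lapply(cc, strip)),
    permutation = list(observed_t = report$permutation$observed_t,
                       p_value = report$permutation$p_value,
                       p_raw = report$permutation$p_raw,
                       n_perm = report$permutation$n_perm,
                       seed = report$permutation$seed),
    correlations = report$correlations,
    note = "all p-values are uncorrected")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  if (!is.null(model_path)) write_model(report$archetype, model_path)
  invisible(path)
}
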