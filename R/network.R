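#' Connectivity metrics of an Ising coupling matrix
#'
#' Global connectivity is the unsigned row sum `GC_i = sum_j |J_ij|`, split
#' exactly into its intra-hemispheric and interhemispheric parts, and
#' homotopic connectivity is the unsigned coupling to the mirror parcel,
#' `HC_i = |J[i, pair(i)]|`.
#'
#' @param model an [ising_model()] with a pairing.
#' @param hemisphere optional integer vector of 1s and 2s assigning parcels
#'   to hemispheres; defaults to [hemisphere_split()] (first half vs second).
#' @return A list of class `connectivity_metrics` with `GC`, `GC_intra`,
#'   `GC_inter`, and `HC` (all length-N, non-negative,
#'   `GC = GC_intra + GC_inter` exactly).
#' @export
connectivity_metrics <- function(model, hemisphere = NULL) {
  validate_ising_model(model)
  n <- length(model$h)
  if (is.null(model$pairing)) stop("model has no homotopic pairing")
  hemisphere <- hemisphere %||% hemisphere_split(n)
  if (length(hemisphere) != n || !all(hemisphere %in% 1:2))
    stop("hemisphere must assign each parcel to 1 or 2")
  if (any(hemisphere[model$pairing] == hemisphere))
    stop("homotopic pairing must cross hemispheres")
  A <- abs(model$J)
  same <- outer(hemisphere, hemisphere, `==`)
  GC_intra <- rowSums(A * same)
  GC_inter <- rowSums(A * !same)
  HC <- A[cbind(seq_len(n), model$pairing)]
  structure(list(GC = GC_intra + GC_inter, GC_intra = GC_intra,
                 GC_inter = GC_inter, HC = HC,
                 hemisphere = hemisphere, pairing = model$pairing),
            class = "connectivity_metrics")
}

#' Compare two archetype models
#'
#' Pairs the two models' unsigned link strengths, global-connectivity and
#' homotopic-connectivity vectors, and fields, and runs paired t and Wilcoxon
#' signed-rank tests on each (treating links, parcels, and fields as the
#' paired samples; link-level p-values carry the caveat that links are not
#' independent). Also reports `hc_scaling`, the Pearson correlation of the
#' signed homotopic change `HC_B - HC_A` with the baseline `HC_A`: a
#' reduction in B that scales with the baseline strength shows up as a
#' negative correlation.
#'
#' @param A,B two [ising_model()]s with identical dimensions and pairing.
#' @param hemisphere optional hemisphere assignment (see
#'   [connectivity_metrics()]).
#' @return A list of class `archetype_comparison` with the signed difference
#'   matrix `dJ = J_A - J_B`, unsigned difference `d_absJ = |J_A| - |J_B|`,
#'   per-metric test results, and `hc_scaling` (correlation of HC decrease
#'   with baseline HC).
#' @export
compare_archetypes <- function(A, B, hemisphere = NULL) {
  validate_ising_model(A)
  validate_ising_model(B)
  if (length(A$h) != length(B$h)) stop("models have different dimensions")
  if (!identical(A$pairing, B$pairing)) stop("models have different pairings")
  cmA <- connectivity_metrics(A, hemisphere)
  cmB <- connectivity_metrics(B, hemisphere)
  ut <- upper.tri(A$J)
  links_A <- abs(A$J)[ut]
  links_B <- abs(B$J)[ut]
  tests <- list(
    links = paired_metric_tests(links_A, links_B),
    GC = paired_metric_tests(cmA$GC, cmB$GC),
    GC_intra = paired_metric_tests(cmA$GC_intra, cmB$GC_intra),
    GC_inter = paired_metric_tests(cmA$GC_inter, cmB$GC_inter),
    HC = paired_metric_tests(cmA$HC, cmB$HC),
    h = paired_metric_tests(A$h, B$h))
  dHC <- cmB$HC - cmA$HC        # signed change of B relative to baseline A
  hc_scaling <- if (sd(dHC) > 0 && sd(cmA$HC) > 0) {
    ct <- cor.test(dHC, cmA$HC)
    list(r = unname(ct$estimate), p_value = ct$p.value, n = length(dHC))
  } else {
    list(r = NA_real_, p_value = NA_real_, n = length(dHC))
  }
  structure(list(dJ = A$J - B$J, d_absJ = abs(A$J) - abs(B$J),
                 dh = A$h - B$h, metrics_A = cmA, metrics_B = cmB,
                 tests = tests, hc_scaling = hc_scaling,
                 caveat = "link-level tests treat links as independent"),
            class = "archetype_comparison")
}

# paired tests on d = a - b, so positive differences mean "larger in A"
paired_metric_tests <- function(a, b) {
  d <- a - b
  if (all(d == 0)) {
    return(list(t = list(statistic = 0, p_value = 1, effect_size = 0),
                wilcoxon = list(statistic = NA_real_, p_value = NA_real_),
                mean_difference = 0, n = length(d)))
  }
  tt <- t.test(a, b, paired = TRUE)
  wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE))
  list(t = list(statistic = unname(tt$statistic), p_value = tt$p.value,
                effect_size = mean(d) / sd(d)),
       wilcoxon = list(statistic = unname(wt$statistic),
                       p_value = wt$p.value),
       mean_difference = mean(d), n = length(d))
}

#' Correlate a connectivity metric with a parcel covariate or matrix
#'
#' Pearson correlation between a model-derived metric and an external
#' covariate: either two parcel-aligned vectors (e.g. GC against a receptor
#' density map) or two symmetric matrices (e.g. unsigned Ising couplings
#' against a structural connectome), which are vectorized over the
#' off-diagonal upper triangle. The homotopic entries can be masked out to
#' measure how much of a matrix correlation the homotopic diagonal accounts
#' for.
#'
#' @param metric numeric vector or symmetric matrix.
#' @param covariate numeric vector or matrix of matching shape.
#' @param exclude_homotopic drop entries `(i, pair(i))` (matrix input only).
#' @param pairing homotopic pairing, required when `exclude_homotopic`.
#' @return List with `r`, `p_value`, and `n` (pairs used).
#' @export
correlate_with_covariate <- function(metric, covariate,
                                     exclude_homotopic = FALSE,
                                     pairing = NULL) {
  if (is.matrix(metric) != is.matrix(covariate))
    stop("metric and covariate must both be vectors or both matrices")
  if (is.matrix(metric)) {
    if (!all(dim(metric) == dim(covariate))) stop("matrix dimensions differ")
    keep <- upper.tri(metric)
    if (exclude_homotopic) {
      if (is.null(pairing)) stop("pairing required to exclude homotopic links")
      pairing <- validate_pairing(pairing, nrow(metric))
      hom <- matrix(FALSE, nrow(metric), ncol(metric))
      hom[cbind(seq_len(nrow(metric)), pairing)] <- TRUE
      keep <- keep & !(hom | t(hom))
    }
    x <- metric[keep]
    y <- covariate[keep]
  } else {
    if (length(metric) != length(covariate)) stop("vector lengths differ")
    x <- as.numeric(metric)
    y <- as.numeric(covariate)
  }
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: an input has zero variance")
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
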