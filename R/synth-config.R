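#' Default baseline phenotype mix for an unperturbed well
#'
#' In an unperturbed well almost all cells show the reporter in the cytoplasm
#' where mature subunits accumulate; small fractions are nucleoplasmic or
#' nucleolar by chance, not expressing the reporter, mitotic, or debris.
#'
#' @inheritParams readout_classes
#' @return named probability vector over the readout's classes
#' @export
default_baseline_mix <- function(readout = "rps2") {
  mix <- switch(readout,
    rps2  = c(cytoplasmic = 0.90, nucleoplasmic = 0.02, nucleolar = 0.02,
              no_reporter = 0.03, mitotic = 0.02, debris = 0.01),
    enp1  = c(nucleolus = 0.90, nucleoplasm = 0.03, cytoplasm = 0.04,
              mitotic = 0.02, debris = 0.01),
    rpl29 = c(cytoplasm = 0.92, nucleus = 0.02, no_reporter = 0.03,
              mitotic = 0.02, debris = 0.01)
  )
  check_mix(mix, readout)
}

#' Default positive-control phenotype mix
#'
#' Positive-control wells carry a Crm1 (exportin-1) knockdown, which blocks
#' nuclear export of the reporter and drives a strong nucleoplasmic
#' accumulation with a moderate growth defect.
#'
#' @inheritParams readout_classes
#' @return named probability vector over the readout's classes
#' @export
default_positive_mix <- function(readout = "rps2") {
  mix <- switch(readout,
    rps2  = c(cytoplasmic = 0.22, nucleoplasmic = 0.55, nucleolar = 0.12,
              no_reporter = 0.05, mitotic = 0.04, debris = 0.02),
    enp1  = c(nucleolus = 0.30, nucleoplasm = 0.58, cytoplasm = 0.07,
              mitotic = 0.03, debris = 0.02),
    rpl29 = c(cytoplasm = 0.30, nucleus = 0.58, no_reporter = 0.05,
              mitotic = 0.05, debris = 0.02)
  )
  check_mix(mix, readout)
}

#' Gaussian feature model for feature-level simulation
#'
#' Places each phenotype class at its own mean in 30-dimensional feature
#' space with a shared covariance. Class k sits at
#' `separation * sigma / sqrt(2)` along its own coordinate axis, so with the
#' isotropic covariance every pair of class means is exactly `separation`
#' Mahalanobis units apart.
#'
#' @param readout readout id (fixes the class set)
#' @param separation pairwise Mahalanobis distance between class means
#' @param sigma marginal feature standard deviation (isotropic covariance)
#' @return list with `means` (class x 30 matrix) and `cov` (30 x 30)
#' @export
default_feature_model <- function(readout = "rps2", separation = 4, sigma = 1) {
  cls <- readout_classes(readout)
  p <- length(feature_names())
  means <- matrix(0, nrow = length(cls), ncol = p,
                  dimnames = list(cls, feature_names()))
  # class k sits at d/sqrt(2) on axis k: ||mu_i - mu_j|| = d for all i != j
  for (k in seq_along(cls)) means[k, k] <- separation * sigma / sqrt(2)
  list(means = means, cov = diag(sigma^2, p))
}

#' Assemble and validate a synthetic-screen configuration
#'
#' The configuration is the complete ground-truth model of a simulated
#' screen: plate layout, baseline phenotype mix, per-target knockdown
#' effects (phenotype-mix overrides plus a growth multiplier shrinking the
#' expected cell count), the negative-binomial cell-count model, and the
#' per-class Gaussian feature model used on the feature-level path.
#'
#' @param layout plate layout data.frame from [plate_layout()]
#' @param readout readout id
#' @param baseline_mix phenotype mix of unperturbed wells (sums to 1)
#' @param positive_mix phenotype mix applied to positive-control wells
#' @param effect_map named list: target -> list(mix = named numeric
#'   (full mix or partial override of the baseline; renormalized classes must
#'   sum to 1), growth = multiplier in (0, 1]). Optionally per-siRNA:
#'   list(sirnas = list(sirna_id = list(mix=, growth=))).
#' @param cells_per_well_mean expected cells imaged per unperturbed well
#' @param cells_per_well_dispersion negative-binomial size parameter
#'   (larger = closer to Poisson)
#' @param feature_model list(means, cov) as from [default_feature_model()]
#' @param render logical; TRUE selects the image-rendering path
#' @param seed integer master seed; every simulation draw derives from it
#' @return object of class `synth_config`
#' @export
synth_config <- function(layout,
                         readout = "rps2",
                         baseline_mix = default_baseline_mix(readout),
                         positive_mix = default_positive_mix(readout),
                         effect_map = list(),
                         cells_per_well_mean = 1500,
                         cells_per_well_dispersion = 10,
                         feature_model = default_feature_model(readout),
                         render = FALSE,
                         seed = 1L) {
  stopifnot(is.data.frame(layout), cells_per_well_mean > 0,
            cells_per_well_dispersion > 0, is.logical(render))
  baseline_mix <- check_mix(baseline_mix, readout)
  positive_mix <- check_mix(positive_mix, readout)
  for (tgt in names(effect_map)) {
    ef <- effect_map[[tgt]]
    if (!is.null(ef$growth) &&
        (ef$growth <= 0 || ef$growth > 1)) {
      stop("growth multiplier for target '", tgt, "' must lie in (0, 1]")
    }
    if (!is.null(ef$mix)) effect_map[[tgt]]$mix <- resolve_mix(ef$mix, baseline_mix, readout)
  }
  p <- length(feature_names())
  if (!is.null(feature_model)) {
    stopifnot(ncol(feature_model$means) == p,
              all(dim(feature_model$cov) == c(p, p)))
    ev <- eigen(feature_model$cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev))) {
      stop("feature covariance is not positive semi-definite")
    }
    if (min(ev) <= 1e-12 * max(abs(ev))) {
      stop("feature covariance is singular")
    }
  }
  structure(list(
    layout = layout, readout = readout,
    baseline_mix = baseline_mix, positive_mix = positive_mix,
    effect_map = effect_map,
    cells_per_well_mean = cells_per_well_mean,
    cells_per_well_dispersion = cells_per_well_dispersion,
    feature_model = feature_model, render = render, seed = as.integer(seed)
  ), class = "synth_config")
}

# A partial mix override keeps unnamed classes at baseline, rescaled so the
# total is 1; a full mix must already sum to 1.
resolve_mix <- function(mix, baseline, readout) {
  cls <- readout_classes(readout)
  if (!all(names(mix) %in% cls)) stop("unknown class in effect mix")
  if (setequal(names(mix), cls)) return(check_mix(mix, readout))
  out <- baseline
  rest <- setdiff(cls, names(mix))
  out[names(mix)] <- mix
  slack <- 1 - sum(mix)
  if (slack < 0) stop("partial mix override exceeds probability 1")
  base_rest <- baseline[rest]
  out[rest] <- if (sum(base_rest) > 0) base_rest / sum(base_rest) * slack
               else slack / length(rest)
  check_mix(out, readout)
}

# Per-well condition: the phenotype mix and growth multiplier a well receives
# given its layout role and the effect map.
well_condition <- function(cfg, role, target, sirna) {
  if (role == "positive_control") {
    return(list(mix = cfg$positive_mix, growth = 0.8))
  }
  if (role == "negative_control" || is.na(target) ||
      is.null(cfg$effect_map[[target]])) {
    return(list(mix = cfg$baseline_mix, growth = 1.0))
  }
  ef <- cfg$effect_map[[target]]
  if (!is.null(ef$sirnas) && !is.null(ef$sirnas[[sirna]])) {
    es <- ef$sirnas[[sirna]]
    mix <- if (is.null(es$mix)) cfg$baseline_mix
           else resolve_mix(es$mix, cfg$baseline_mix, cfg$readout)
    return(list(mix = mix, growth = if (is.null(es$growth)) 1.0 else es$growth))
  }
  list(mix = if (is.null(ef$mix)) cfg$baseline_mix else ef$mix,
       growth = if (is.null(ef$growth)) 1.0 else ef$growth)
}
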