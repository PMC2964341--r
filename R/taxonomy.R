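#' Phenotype taxonomies per screen readout
#'
#' Each readout of the screen has a fixed set of per-cell phenotype classes.
#' The \code{rps2} readout (Rps2-YFP reporter, new 40S subunits) distinguishes
#' cytoplasmic, nucleoplasmic and nucleolar reporter localization plus
#' non-expressing, mitotic and debris cells. The \code{enp1} readout
#' (Enp1 immunofluorescence) has no reporter-negative class because every cell
#' is stained; the \code{rpl29} readout (Rpl29-GFP, new 60S subunits) merges
#' all nuclear localization into a single \code{nucleus} class.
#'
#' Class order is canonical: it fixes probability-column order and breaks
#' classifier ties (first class in this order wins an exact tie).
#'
#' @param readout one of \code{"rps2"}, \code{"enp1"}, \code{"rpl29"}
#' @return character vector of class labels in canonical order
#' @export
#' @examples
#' readout_classes("rps2")
readout_classes <- function(readout = c("rps2", "enp1", "rpl29")) {
  readout <- match.arg(readout)
  switch(readout,
    rps2  = c("cytoplasmic", "nucleoplasmic", "nucleolar",
              "no_reporter", "mitotic", "debris"),
    enp1  = c("nucleolus", "nucleoplasm", "cytoplasm", "mitotic", "debris"),
    rpl29 = c("cytoplasm", "nucleus", "no_reporter", "mitotic", "debris")
  )
}

#' Default hit-defining classes per readout
#'
#' For Rps2-YFP, overall nuclear accumulation — nucleoplasmic plus nucleolar —
#' defines a hit. For Enp1 the nuclear readout counts nucleoplasmic
#' accumulation (the cytoplasmic Enp1 readout is handled separately with
#' absolute rates, see [cytoplasmic_enp1_calls()]). For Rpl29-GFP the
#' hit class is nuclear restriction of the reporter.
#'
#' @inheritParams readout_classes
#' @return character vector, a subset of [readout_classes()]
#' @export
hit_classes <- function(readout = c("rps2", "enp1", "rpl29")) {
  readout <- match.arg(readout)
  switch(readout,
    rps2  = c("nucleolar", "nucleoplasmic"),
    enp1  = "nucleoplasm",
    rpl29 = "nucleus"
  )
}

#' Classes excluded from the interphase denominator
#'
#' Hit rates are computed over reporter-positive interphase cells; mitotic
#' cells and debris never enter the denominator, and neither do cells of the
#' readout's reporter-negative class where one exists.
#'
#' @inheritParams readout_classes
#' @return character vector of excluded class labels
#' @export
noninterphase_classes <- function(readout = c("rps2", "enp1", "rpl29")) {
  readout <- match.arg(readout)
  cls <- readout_classes(readout)
  intersect(c("mitotic", "debris", "no_reporter"), cls)
}

#' Names of the 30 per-cell features
#'
#' The fixed, versioned feature schema used by both the feature extractor and
#' the classifier: reporter intensity statistics in the nuclear and
#' cytoplasmic compartments, DNA-channel intensities, nucleus morphology,
#' five gray-level co-occurrence texture measures of the nuclear reporter
#' signal, the radial distribution of reporter over four concentric nuclear
#' rings (ring 1 innermost), granularity at two structuring-element scales,
#' and a bright-speckle count. Order is part of the schema: trained models
#' check it.
#'
#' @return character vector of length 30
#' @export
feature_names <- function() {
  c("reporter_nuc_mean", "reporter_nuc_median", "reporter_nuc_integrated",
    "reporter_cyto_mean", "nc_intensity_ratio",
    "dna_mean_intensity", "dna_integrated_intensity",
    "nucleus_area", "nucleus_perimeter", "eccentricity", "solidity",
    "extent", "major_axis", "minor_axis", "form_factor",
    "reporter_nuc_sd", "reporter_cyto_sd",
    "glcm_contrast", "glcm_correlation", "glcm_energy",
    "glcm_homogeneity", "glcm_entropy",
    "radial_frac_ring1", "radial_frac_ring2",
    "radial_frac_ring3", "radial_frac_ring4",
    "granularity_scale1", "granularity_scale2",
    "cyto_annulus_area", "nuclear_speckle_count")
}

# internal: validate a probability vector over a readout's classes
check_mix <- function(mix, readout, tol = 1e-9) {
  cls <- readout_classes(readout)
  if (is.null(names(mix)) || !all(names(mix) %in% cls)) {
    stop("phenotype mix must be named by classes of readout '", readout, "'")
  }
  full <- stats::setNames(numeric(length(cls)), cls)
  full[names(mix)] <- mix
  if (any(full < 0)) stop("phenotype mix has negative entries")
  if (abs(sum(full) - 1) > tol) {
    stop("phenotype mix must sum to 1 (got ", format(sum(full)), ")")
  }
  full
}
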