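#' Segment nuclei from the DNA channel
#'
#' Nuclei are identified from the Hoechst/DNA channel: the image is smoothed,
#' thresholded by Otsu's method on log intensity (plus a configurable
#' offset), holes are filled, touching nuclei are split by a
#' distance-transform watershed, and components outside the area bounds are
#' discarded. Labels are renumbered to consecutive positive integers;
#' label 0 is background. Coordinates are pixel-centered with origin at the
#' top-left.
#'
#' @param dna_channel single-channel 2-D numeric matrix (16-bit counts)
#' @param min_area,max_area nucleus area bounds in pixels
#' @param smooth_sigma Gaussian pre-smoothing sigma in pixels
#' @param threshold_offset additive offset on the Otsu threshold
#'   (log-intensity units; positive = stricter)
#' @param watershed_tolerance minimum object-height separation for the
#'   watershed split
#' @return object of class `nucleus_segmentation`: list with `labels`
#'   (integer matrix), `n` (nucleus count), `bbox` (per-nucleus bounding
#'   boxes), `annulus` (NULL until [define_cell_regions()] is applied)
#' @export
segment_nuclei <- function(dna_channel, min_area = 30, max_area = 2500,
                           smooth_sigma = 1, threshold_offset = 0,
                           watershed_tolerance = 1) {
  stopifnot(is.matrix(dna_channel))
  empty <- function() structure(list(labels = matrix(0L, nrow(dna_channel),
                                                     ncol(dna_channel)),
                                     n = 0L, bbox = NULL, annulus = NULL),
                                class = "nucleus_segmentation")
  rng <- range(dna_channel)
  if (diff(rng) == 0) return(empty())

  img <- EBImage::Image((dna_channel - rng[1]) / diff(rng))
  sm <- EBImage::gblur(img, sigma = smooth_sigma)
  lg <- log1p(sm * 1000) / log1p(1000)           # log-intensity in [0,1]
  thr <- EBImage::otsu(lg, range = c(0, 1)) + threshold_offset
  mask <- lg > thr
  if (!any(mask)) return(empty())
  mask <- EBImage::fillHull(mask)
  dm <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dm, tolerance = watershed_tolerance)
  lab <- EBImage::imageData(lab)

  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area & areas <= max_area)
  if (!length(keep)) return(empty())
  remap <- integer(length(areas))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- remap[lab[nz]]

  bbox <- do.call(rbind, lapply(seq_along(keep), function(k) {
    w <- which(out == k, arr.ind = TRUE)
    data.frame(label = k, x0 = min(w[, 1]), x1 = max(w[, 1]),
               y0 = min(w[, 2]), y1 = max(w[, 2]),
               area = nrow(w),
               cx = mean(w[, 1]), cy = mean(w[, 2]))
  }))
  structure(list(labels = out, n = length(keep), bbox = bbox, annulus = NULL),
            class = "nucleus_segmentation")
}

#' Define a cytoplasmic annulus around each nucleus
#'
#' Every nucleus receives a surrounding ring of the requested width as its
#' cytoplasmic measurement region. Where rings of neighboring cells would
#' collide, pixels go to the nearest nucleus (Voronoi propagation), so
#' annuli are always disjoint from each other and from every nucleus.
#'
#' @param seg a `nucleus_segmentation` from [segment_nuclei()]
#' @param annulus_width ring width in pixels (>= 1)
#' @return the segmentation with an `annulus` integer label matrix added
#'   (same label ids as the nuclei)
#' @export
define_cell_regions <- function(seg, annulus_width = 5) {
  stopifnot(inherits(seg, "nucleus_segmentation"))
  if (annulus_width < 1) stop("annulus_width must be at least 1 pixel")
  lab <- seg$labels
  if (seg$n == 0) {
    seg$annulus <- matrix(0L, nrow(lab), ncol(lab))
    return(seg)
  }
  nucmask <- lab > 0
  # distance of background pixels to the nearest nucleus pixel
  dist_to_nuc <- EBImage::distmap(EBImage::Image(1 - nucmask))
  region <- nucmask | (EBImage::imageData(dist_to_nuc) <= annulus_width)
  grown <- EBImage::propagate(EBImage::Image(matrix(0, nrow(lab), ncol(lab))),
                              seeds = EBImage::Image(lab),
                              mask = EBImage::Image(region))
  grown <- EBImage::imageData(grown)
  ann <- matrix(0L, nrow(lab), ncol(lab))
  sel <- grown > 0 & lab == 0
  ann[sel] <- as.integer(grown[sel])
  seg$annulus <- ann
  seg
}

#' @export
print.nucleus_segmentation <- function(x, ...) {
  cat("nucleus segmentation:", x$n, "nuclei on a",
      nrow(x$labels), "x", ncol(x$labels), "field;",
      if (is.null(x$annulus)) "no" else "with", "cytoplasm annuli\n")
  invisible(x)
}
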