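# Gray-level co-occurrence features of the nuclear reporter signal.
# Pixels inside the mask are quantized to n_levels over their own range
# (so texture is invariant to linear intensity scaling); co-occurrence is
# counted for horizontal and vertical unit offsets, symmetrized and
# normalized. A constant patch yields contrast 0, energy 1, entropy 0.
glcm_features <- function(vals, mask, n_levels = 8) {
  px <- vals[mask]
  if (!length(px) || diff(range(px)) == 0) {
    return(c(glcm_contrast = 0, glcm_correlation = 0, glcm_energy = 1,
             glcm_homogeneity = 1, glcm_entropy = 0))
  }
  q <- matrix(NA_integer_, nrow(vals), ncol(vals))
  brk <- seq(min(px), max(px), length.out = n_levels + 1)
  q[mask] <- pmin(findInterval(vals[mask], brk, rightmost.closed = TRUE),
                  n_levels)
  P <- matrix(0, n_levels, n_levels)
  nr <- nrow(q); nc <- ncol(q)
  for (off in list(c(1L, 0L), c(0L, 1L))) {
    a <- q[seq_len(nr - off[1]), seq_len(nc - off[2]), drop = FALSE]
    b <- q[(1 + off[1]):nr, (1 + off[2]):nc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      tab <- table(factor(a[ok], levels = 1:n_levels),
                   factor(b[ok], levels = 1:n_levels))
      P <- P + tab + t(tab)
    }
  }
  if (sum(P) == 0) {
    return(c(glcm_contrast = 0, glcm_correlation = 0, glcm_energy = 1,
             glcm_homogeneity = 1, glcm_entropy = 0))
  }
  P <- P / sum(P)
  i <- row(P); j <- col(P)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  sd_i <- sqrt(sum((i - mu_i)^2 * P)); sd_j <- sqrt(sum((j - mu_j)^2 * P))
  corr <- if (sd_i > 0 && sd_j > 0)
    sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j) else 0
  nzP <- P[P > 0]
  c(glcm_contrast = sum((i - j)^2 * P),
    glcm_correlation = corr,
    glcm_energy = sum(P^2),
    glcm_homogeneity = sum(P / (1 + abs(i - j))),
    glcm_entropy = -sum(nzP * log2(nzP)))
}

# Fraction of total nuclear reporter signal in 4 concentric rings.
# Depth into the nucleus (distance to its edge) is normalized per nucleus;
# ring 1 is the innermost quartile (where nucleoli sit), ring 4 the rim.
radial_fractions <- function(vals, mask) {
  if (!any(mask)) return(stats::setNames(rep(0, 4), paste0("radial_frac_ring", 1:4)))
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask)))
  dmax <- max(d[mask])
  total <- sum(vals[mask])
  out <- numeric(4)
  if (dmax == 0 || total == 0) {
    out[4] <- if (total > 0) 1 else 0
  } else {
    depth <- d[mask] / dmax                  # 0 at rim, 1 at core
    ring <- pmin(4L, findInterval(1 - depth, c(0, .25, .5, .75, 1),
                                  rightmost.closed = TRUE))
    for (k in 1:4) out[k] <- sum(vals[mask][ring == k]) / total
  }
  stats::setNames(out, paste0("radial_frac_ring", 1:4))
}

# Granularity: loss of nuclear reporter signal under grayscale opening with
# a disc of the given radius; near 0 for smooth signal, larger when signal
# is carried by structures smaller than the disc.
granularity_at <- function(vals, mask, radius) {
  if (!any(mask)) return(0)
  v <- vals; v[!mask] <- 0
  op <- EBImage::opening(EBImage::Image(v / max(v[mask], 1)),
                         EBImage::makeBrush(2 * radius + 1, shape = "disc"))
  op <- EBImage::imageData(op) * max(v[mask], 1)
  s0 <- sum(vals[mask])
  if (s0 == 0) return(0)
  max(0, 1 - sum(pmin(op[mask], vals[mask])) / s0)
}

# Count of bright speckles: connected components (>= 2 px) of reporter
# above 1.5x the nuclear mean, inside the nucleus.
speckle_count <- function(vals, mask) {
  if (!any(mask)) return(0L)
  thr <- 1.5 * mean(vals[mask])
  sp <- mask & vals > thr
  if (!any(sp)) return(0L)
  lab <- EBImage::bwlabel(EBImage::Image(sp))
  areas <- tabulate(EBImage::imageData(lab)[sp])
  sum(areas >= 2)
}

shoelace_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Extract the 30-feature vector for every segmented cell
#'
#' One row per nucleus. Reporter intensity statistics are computed over the
#' nucleus and the cytoplasmic annulus; morphology comes from the nucleus
#' mask; texture (gray-level co-occurrence), radial distribution,
#' granularity and speckle counts are computed on the nuclear reporter
#' signal. A cell is flagged reporter-positive when its mean whole-cell
#' reporter intensity exceeds `background_multiple` times the image
#' background median (pixels outside every cell region).
#'
#' @param seg `nucleus_segmentation` with annuli
#'   (see [define_cell_regions()]); if annuli are missing they are added
#'   with the default width
#' @param dna_channel,reporter_channel numeric matrices matching the
#'   segmentation dimensions
#' @param background_multiple reporter-positive threshold as a multiple of
#'   the image background median (default 2)
#' @return data.frame: cell_id, x, y, the 30 columns of [feature_names()],
#'   reporter_positive (logical)
#' @export
extract_features <- function(seg, dna_channel, reporter_channel,
                             background_multiple = 2) {
  stopifnot(inherits(seg, "nucleus_segmentation"))
  if (!all(dim(seg$labels) == dim(dna_channel)) ||
      !all(dim(seg$labels) == dim(reporter_channel))) {
    stop("channel dimensions do not match the segmentation")
  }
  if (is.null(seg$annulus)) seg <- define_cell_regions(seg)
  fn <- feature_names()
  if (seg$n == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, length(fn) + 3,
                                dimnames = list(NULL, c("cell_id", "x", "y", fn))))
    out$reporter_positive <- logical(0)
    return(out)
  }
  lab <- seg$labels; ann <- seg$annulus
  bg_px <- reporter_channel[lab == 0 & ann == 0]
  bg_med <- if (length(bg_px)) stats::median(bg_px) else 0

  # moment/shape descriptors from EBImage on the full label image
  mom <- EBImage::computeFeatures.moment(lab)
  shp <- EBImage::computeFeatures.shape(lab)

  rows <- vector("list", seg$n)
  for (k in seq_len(seg$n)) {
    bb <- seg$bbox[seg$bbox$label == k, ]
    xs <- bb$x0:bb$x1; ys <- bb$y0:bb$y1
    m <- lab[xs, ys, drop = FALSE] == k
    rsub <- reporter_channel[xs, ys, drop = FALSE]
    nuc_rep <- rsub[m]
    cyt_rep <- reporter_channel[ann == k]
    dna_px <- dna_channel[xs, ys, drop = FALSE][m]
    area <- sum(m)
    per <- shp[k, "s.perimeter"]
    ecc <- mom[k, "m.eccentricity"]
    maj <- mom[k, "m.majoraxis"]
    mnr <- maj * sqrt(max(0, 1 - ecc^2))
    w <- which(m, arr.ind = TRUE)
    hull <- grDevices::chull(w)
    # pixel-corner padding so a degenerate 1-px-wide hull has area
    sol <- area / max(shoelace_area(w[hull, , drop = FALSE]) + nrow(w[hull, , drop = FALSE]) / 2, area)
    ext <- area / (length(xs) * length(ys))
    cyt_mean <- if (length(cyt_rep)) mean(cyt_rep) else 0
    nuc_mean <- mean(nuc_rep)
    feats <- c(
      reporter_nuc_mean = nuc_mean,
      reporter_nuc_median = stats::median(nuc_rep),
      reporter_nuc_integrated = sum(nuc_rep),
      reporter_cyto_mean = cyt_mean,
      nc_intensity_ratio = if (cyt_mean > 0) nuc_mean / cyt_mean else NA_real_,
      dna_mean_intensity = mean(dna_px),
      dna_integrated_intensity = sum(dna_px),
      nucleus_area = area,
      nucleus_perimeter = per,
      eccentricity = ecc,
      solidity = sol,
      extent = ext,
      major_axis = maj,
      minor_axis = mnr,
      form_factor = 4 * pi * area / per^2,
      reporter_nuc_sd = if (length(nuc_rep) > 1) stats::sd(nuc_rep) else 0,
      reporter_cyto_sd = if (length(cyt_rep) > 1) stats::sd(cyt_rep) else 0,
      glcm_features(rsub, m),
      radial_fractions(rsub, m),
      granularity_scale1 = granularity_at(rsub, m, 2),
      granularity_scale2 = granularity_at(rsub, m, 4),
      cyto_annulus_area = sum(ann == k),
      nuclear_speckle_count = speckle_count(rsub, m)
    )
    feats <- feats[fn]
    stopifnot(!anyNA(names(feats)))
    cell_mean <- mean(c(nuc_rep, cyt_rep))
    rows[[k]] <- data.frame(cell_id = k,
                            x = bb$cx, y = bb$cy,
                            t(feats),
                            reporter_positive = cell_mean >
                              background_multiple * bg_med,
                            check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # nc ratio with empty annulus: fall back to ratio against background
  bad <- is.na(out$nc_intensity_ratio)
  if (any(bad)) {
    out$nc_intensity_ratio[bad] <-
      out$reporter_nuc_mean[bad] / max(bg_med, 1)
  }
  out
}
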