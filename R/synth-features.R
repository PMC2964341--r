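#' Generate a per-cell feature/label table for a synthetic screen
#'
#' The fast, feature-level simulation path: for every well in the layout a
#' cell count is drawn from a negative binomial with mean
#' `cells_per_well_mean * growth multiplier`, each cell's true class is drawn
#' from the well's phenotype mix, and (optionally) a 30-feature vector is
#' drawn from that class's Gaussian feature model. No images are rendered;
#' the output feeds the classifier and screen statistics directly.
#'
#' @param config a [synth_config()] object (`render` must be FALSE)
#' @param features draw feature vectors (TRUE) or classes only (FALSE);
#'   class-only tables are enough for screen-statistics work and much faster
#' @return list with `cells` (data.frame: plate, well, cell_id, true_class,
#'   and the 30 feature columns when `features = TRUE`) and `truth`
#'   (list: `well_mix` per-well true mixes, `planted_hits` targets with a
#'   phenotype effect, `well_condition` per-well growth/mix table)
#' @export
#' @examples
#' lay <- plate_layout(paste0("T", 1:30))
#' cfg <- synth_config(lay, cells_per_well_mean = 50, seed = 7)
#' tab <- generate_feature_table(cfg, features = FALSE)
#' head(tab$cells)
generate_feature_table <- function(config, features = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  if (isTRUE(config$render)) {
    stop("config requests rendering; use generate_screen() for the image path")
  }
  set.seed(config$seed)
  lay <- config$layout
  cls <- readout_classes(config$readout)
  fm <- config$feature_model
  cell_rows <- vector("list", nrow(lay))
  mix_rows <- vector("list", nrow(lay))
  for (i in seq_len(nrow(lay))) {
    cond <- well_condition(config, lay$role[i], lay$target[i], lay$sirna[i])
    n <- stats::rnbinom(1, size = config$cells_per_well_dispersion,
                        mu = config$cells_per_well_mean * cond$growth)
    mix_rows[[i]] <- data.frame(plate = lay$plate[i], well = lay$well[i],
                                t(cond$mix), growth = cond$growth,
                                check.names = FALSE)
    if (n == 0) next
    true_class <- sample(cls, n, replace = TRUE, prob = cond$mix)
    df <- data.frame(plate = lay$plate[i], well = lay$well[i],
                     cell_id = seq_len(n), true_class = true_class,
                     stringsAsFactors = FALSE)
    if (features) {
      X <- matrix(NA_real_, n, ncol(fm$means),
                  dimnames = list(NULL, colnames(fm$means)))
      for (k in cls) {
        idx <- which(true_class == k)
        if (length(idx)) {
          X[idx, ] <- MASS::mvrnorm(length(idx), mu = fm$means[k, ],
                                    Sigma = fm$cov)
        }
      }
      df <- cbind(df, as.data.frame(X))
    }
    cell_rows[[i]] <- df
  }
  cells <- do.call(rbind, cell_rows[!vapply(cell_rows, is.null, logical(1))])
  rownames(cells) <- NULL
  planted <- names(config$effect_map)[vapply(config$effect_map, function(e)
    !is.null(e$mix) || !is.null(e$sirnas), logical(1))]
  list(cells = cells,
       truth = list(well_mix = do.call(rbind, mix_rows),
                    planted_hits = planted))
}

#' Generate a complete synthetic screen bundle
#'
#' Dispatches to the feature-level path (`render = FALSE`) or the
#' image-rendering path (`render = TRUE`). The image path renders a
#' two-channel field per well and, when `dir` is given, writes multi-page
#' 16-bit TIFFs named `{plate}_{well}.tif` (page 1 DNA, page 2 reporter),
#' a per-cell ground-truth CSV and a JSON run manifest, making the output
#' self-describing.
#'
#' @param config a [synth_config()] object; its layout must give every plate
#'   3 negative- and 3 positive-control wells
#' @param dir optional output directory for the image path
#' @param image_size rendered field edge length in pixels (image path)
#' @param cells_per_image cells rendered per well on the image path (rendered
#'   fields are small; this caps the per-well draw)
#' @param ... passed to [generate_feature_table()]
#' @return feature path: the [generate_feature_table()] bundle plus `layout`;
#'   image path: list with `images` (per-well list of dna/reporter/truth),
#'   `layout`, `truth`, and `dir` when written
#' @export
generate_screen <- function(config, dir = NULL, image_size = 256,
                            cells_per_image = 15, ...) {
  stopifnot(inherits(config, "synth_config"))
  lay <- config$layout
  ctl <- stats::aggregate(cbind(neg = role == "negative_control",
                                pos = role == "positive_control") ~ plate,
                          data = lay, FUN = sum)
  if (any(ctl$neg != 3) || any(ctl$pos != 3)) {
    stop("every plate needs exactly 3 negative and 3 positive control wells")
  }
  n_sirna <- table(lay$target[lay$role == "sample"])
  if (any(n_sirna < 2)) {
    warning("target(s) with fewer than 2 siRNAs in layout: ",
            paste(names(n_sirna)[n_sirna < 2], collapse = ", "))
  }
  if (!isTRUE(config$render)) {
    out <- generate_feature_table(config, ...)
    out$layout <- lay
    return(out)
  }

  set.seed(config$seed)
  well_seeds <- sample.int(.Machine$integer.max - 1L, nrow(lay))
  images <- vector("list", nrow(lay))
  truth_rows <- vector("list", nrow(lay))
  for (i in seq_len(nrow(lay))) {
    cond <- well_condition(config, lay$role[i], lay$target[i], lay$sirna[i])
    n <- min(cells_per_image,
             stats::rnbinom(1, size = config$cells_per_well_dispersion,
                            mu = cells_per_image * cond$growth))
    img <- generate_cell_image(list(mix = cond$mix, n_cells = n),
                               image_size = image_size,
                               seed = well_seeds[i],
                               readout = config$readout)
    images[[i]] <- img
    if (nrow(img$truth$cells)) {
      truth_rows[[i]] <- cbind(plate = lay$plate[i], well = lay$well[i],
                               img$truth$cells)
    }
  }
  names(images) <- paste0(lay$plate, "_", lay$well)
  truth_cells <- do.call(rbind,
                         truth_rows[!vapply(truth_rows, is.null, logical(1))])
  planted <- names(config$effect_map)
  bundle <- list(images = images, layout = lay,
                 truth = list(cells = truth_cells, planted_hits = planted))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(lay))) {
      img <- images[[i]]
      tiff::writeTIFF(list(img$dna / 65535, img$reporter / 65535),
                      file.path(dir, sprintf("%d_%s.tif",
                                             lay$plate[i], lay$well[i])),
                      bits.per.sample = 16L)
    }
    utils::write.csv(truth_cells[, c("plate", "well", "cell_id", "true_class")],
                     file.path(dir, "ground_truth.csv"), row.names = FALSE)
    write_plate_layout(lay, file.path(dir, "layout.yaml"))
    manifest <- list(seed = config$seed, readout = config$readout,
                     image_size = image_size,
                     cells_per_image = cells_per_image,
                     planted_hits = planted,
                     baseline_mix = as.list(config$baseline_mix))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    bundle$dir <- dir
  }
  bundle
}
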