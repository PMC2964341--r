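#' Match segmented nuclei to generator ground truth
#'
#' Assigns every segmented nucleus the planted cell whose ground-truth mask
#' it overlaps best, with the pixelwise Jaccard index of the match. Used to
#' benchmark segmentation and to label rendered cells for classifier
#' training.
#'
#' @param seg `nucleus_segmentation`
#' @param truth ground-truth list from [generate_cell_image()] (needs
#'   `nucleus_mask` and `cells`)
#' @return data.frame: cell_id (segmentation label), truth_id, jaccard,
#'   true_class
#' @export
match_cells_to_truth <- function(seg, truth) {
  stopifnot(inherits(seg, "nucleus_segmentation"))
  lab <- seg$labels; tlab <- truth$nucleus_mask
  stopifnot(all(dim(lab) == dim(tlab)))
  if (seg$n == 0) {
    return(data.frame(cell_id = integer(), truth_id = integer(),
                      jaccard = numeric(), true_class = character(),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(seq_len(seg$n), function(k) {
    sm <- lab == k
    cand <- tlab[sm]
    cand <- cand[cand > 0]
    if (!length(cand)) {
      return(data.frame(cell_id = k, truth_id = NA_integer_, jaccard = 0,
                        true_class = NA_character_, stringsAsFactors = FALSE))
    }
    tid <- as.integer(names(which.max(table(cand))))
    tm <- tlab == tid
    jac <- sum(sm & tm) / sum(sm | tm)
    data.frame(cell_id = k, truth_id = tid, jaccard = jac,
               true_class = truth$cells$true_class[truth$cells$cell_id == tid],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the screen analysis pipeline end to end
#'
#' Feature-level path: generates (or accepts) a per-cell table, classifies
#' cells with the supplied model — or scores directly on ground-truth
#' classes when no model is given — then computes per-well statistics,
#' relative cell numbers, growth exclusion, control-normalized ranks,
#' candidate selection and high-confidence calls, and (Rps2) per-target
#' stage scores. Image path (`config$render = TRUE`): renders each well,
#' segments nuclei, extracts features, classifies with the supplied model,
#' then proceeds identically — both paths feed the same per-cell schema.
#'
#' When `out_dir` is given, the per-well table, per-target table,
#' hit-list TSV and a JSON run manifest (all thresholds, seeds, package
#' version) are written; re-running the same configuration reproduces the
#' tables bit-identically.
#'
#' @param config a [synth_config()]
#' @param run a [run_config()] (readouts must agree)
#' @param classifier optional `phenotype_classifier`; required on the
#'   image path
#' @param out_dir optional output directory
#' @param image_size,cells_per_image image-path rendering parameters
#' @return list: `wells`, `excluded`, `targets`, `hits` (character
#'   vector), `stage` (Rps2 only), `truth`, and `paths` when written
#' @export
run_pipeline <- function(config, run = run_config(config$readout),
                         classifier = NULL, out_dir = NULL,
                         image_size = 256, cells_per_image = 15) {
  stopifnot(inherits(config, "synth_config"), inherits(run, "run_config"))
  if (!identical(config$readout, run$readout)) {
    stop("pipeline stage 'config': synth and run readouts disagree")
  }
  if (isTRUE(config$render)) {
    if (is.null(classifier)) {
      stop("pipeline stage 'classify': the image path needs a trained ",
           "classifier")
    }
    screen <- generate_screen(config, dir = out_dir,
                              image_size = image_size,
                              cells_per_image = cells_per_image)
    cell_rows <- list()
    for (wk in names(screen$images)) {
      img <- screen$images[[wk]]
      seg <- segment_nuclei(img$dna)
      seg <- define_cell_regions(seg)
      feats <- extract_features(seg, img$dna, img$reporter,
                                background_multiple = run$background_multiple)
      if (!nrow(feats)) next
      pw <- strsplit(wk, "_", fixed = TRUE)[[1]]
      feats$plate <- as.integer(pw[1]); feats$well <- pw[2]
      cell_rows[[wk]] <- feats
    }
    cells <- do.call(rbind, cell_rows)
    rownames(cells) <- NULL
    cells <- classify_cells(classifier, cells)
    truth <- screen$truth
  } else {
    screen <- generate_screen(config, features = !is.null(classifier))
    cells <- screen$cells
    if (!is.null(classifier)) cells <- classify_cells(classifier, cells)
    truth <- screen$truth
  }
  class_col <- if (!is.null(classifier)) "pred_class" else "true_class"
  wells <- compute_well_statistics(cells, config$layout,
                                   readout = run$readout,
                                   class_col = class_col)
  wells <- relative_cell_number(wells)
  fg <- filter_growth(wells, run$min_relative_cell_number)
  ranked <- rank_sirna(fg$retained)
  targets <- score_targets(
    ranked, neg_summary = run$neg_summary,
    all_targets = unique(stats::na.omit(config$layout$target)))
  targets <- call_hits(targets, readout = run$readout, cutoff = run$cutoff)
  hits <- targets$target[targets$high_confidence]
  stage <- NULL
  if (run$readout == "rps2") {
    stage <- target_stage_score(nucleoplasmic_ratio(ranked))
  }
  out <- list(wells = ranked, excluded = fg$excluded, targets = targets,
              hits = hits, stage = stage, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      wells = file.path(out_dir, "well_statistics.csv"),
      targets = file.path(out_dir, "target_scores.csv"),
      hits = file.path(out_dir, "hit_list.tsv"),
      manifest = file.path(out_dir, "run_manifest.json")
    )
    write_well_table(ranked, paths$wells)
    write_target_table(targets, paths$targets)
    write_hit_list(targets, paths$hits)
    if (!is.null(stage)) {
      paths$stage <- file.path(out_dir, "stage_scores.csv")
      utils::write.csv(stage, paths$stage, row.names = FALSE, na = "")
    }
    write_run_manifest(run, paths$manifest,
                       extra = list(synth_seed = config$seed,
                                    n_wells = nrow(config$layout)))
    out$paths <- paths
  }
  out
}

#' Rank, select and call hits from an imported per-well table
#'
#' Runs the screen statistics on an externally supplied per-well summary
#' table (see [import_supplementary_wells()]): growth exclusion,
#' control-normalized ranking, two-siRNA candidate selection and the
#' readout's high-confidence cutoff. Lets the calling rules replay on
#' published per-well numbers without any image or per-cell data.
#'
#' @param wells imported per-well data.frame (needs roles and hit rates;
#'   relative cell number is computed from cell numbers when absent)
#' @param run a [run_config()]
#' @return list: `targets` (scored, called), `hits`, `wells` (ranked),
#'   `excluded`
#' @export
replay_well_table <- function(wells, run = run_config()) {
  if (!"relative_cell_number" %in% names(wells)) {
    wells <- relative_cell_number(wells)
  }
  fg <- filter_growth(wells, run$min_relative_cell_number)
  ranked <- rank_sirna(fg$retained)
  targets <- call_hits(score_targets(ranked, neg_summary = run$neg_summary),
                       readout = run$readout, cutoff = run$cutoff)
  list(targets = targets, hits = targets$target[targets$high_confidence],
       wells = ranked, excluded = fg$excluded)
}
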