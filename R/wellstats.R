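#' Default high-confidence rank cutoffs per readout
#'
#' A target is a high-confidence hit when its rank (mean of the two
#' highest-ranked siRNAs) strictly exceeds the readout's cutoff: 0.2 for
#' Rps2-YFP, 0.3 for Enp1 IF, 0.25 for Rpl29-GFP.
#'
#' @inheritParams readout_classes
#' @return numeric cutoff
#' @export
default_cutoff <- function(readout = c("rps2", "enp1", "rpl29")) {
  switch(match.arg(readout), rps2 = 0.2, enp1 = 0.3, rpl29 = 0.25)
}

#' Aggregate classified cells into per-well statistics
#'
#' For every well of the layout: total cell number, per-class counts, the
#' reporter-positive interphase denominator (mitotic cells, debris and the
#' readout's reporter-negative class are excluded; a `reporter_positive`
#' flag column further restricts the denominator when present), the
#' hit-classified count and the hit rate (hit-classified / denominator;
#' 0 with a `denominator_zero` flag when the denominator is empty). For the
#' Rps2-YFP readout the nucleolar/nucleoplasmic split is reported, and for
#' Enp1 the cytoplasmic count and absolute cytoplasmic hit rate.
#'
#' @param cells classified per-cell data.frame with columns plate, well and
#'   `class_col`
#' @param layout plate layout data.frame ([plate_layout()])
#' @param readout readout id
#' @param hit_cls hit-defining classes (default [hit_classes()] for the
#'   readout)
#' @param class_col name of the class column (default `pred_class`, falling
#'   back to `true_class` for ground-truth runs)
#' @return data.frame, one row per layout well
#' @export
compute_well_statistics <- function(cells, layout, readout = "rps2",
                                    hit_cls = hit_classes(readout),
                                    class_col = NULL) {
  cls <- readout_classes(readout)
  if (is.null(class_col)) {
    class_col <- if ("pred_class" %in% names(cells)) "pred_class"
                 else "true_class"
  }
  stopifnot(class_col %in% names(cells))
  bad <- setdiff(unique(cells[[class_col]]), cls)
  if (length(bad)) stop("unknown class label(s) for readout '", readout,
                        "': ", paste(bad, collapse = ", "))
  if (length(setdiff(hit_cls, cls))) {
    stop("hit classes must belong to the readout taxonomy")
  }
  excl <- noninterphase_classes(readout)
  has_flag <- "reporter_positive" %in% names(cells)
  key <- paste(cells$plate, cells$well)
  lkey <- paste(layout$plate, layout$well)
  rows <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    sel <- key == lkey[i]
    cl <- cells[[class_col]][sel]
    counts <- table(factor(cl, levels = cls))
    interphase <- !(cl %in% excl)
    denom_sel <- interphase
    if (has_flag) denom_sel <- denom_sel & cells$reporter_positive[sel]
    denom <- sum(denom_sel)
    hits <- sum(denom_sel & cl %in% hit_cls)
    row <- data.frame(plate = layout$plate[i], well = layout$well[i],
                      role = layout$role[i], target = layout$target[i],
                      sirna = layout$sirna[i],
                      cell_number = length(cl),
                      reporter_positive_interphase = denom,
                      hit_count = hits,
                      hit_rate = if (denom > 0) hits / denom else 0,
                      denominator_zero = denom == 0,
                      stringsAsFactors = FALSE)
    cn <- as.data.frame(t(as.numeric(counts)))
    names(cn) <- paste0("count_", cls)
    row <- cbind(row, cn)
    if (readout == "rps2") {
      row$nucleolar_count <- sum(denom_sel & cl == "nucleolar")
      row$nucleoplasmic_count <- sum(denom_sel & cl == "nucleoplasmic")
    }
    if (readout == "enp1") {
      cyt <- sum(denom_sel & cl == "cytoplasm")
      row$cytoplasmic_count <- cyt
      row$hit_rate_cyt <- if (denom > 0) cyt / denom else 0
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  if (any(out$denominator_zero & out$cell_number > 0)) {
    warning("well(s) with zero reporter-positive interphase denominator; ",
            "hit rate reported as 0 and flagged")
  }
  rownames(out) <- NULL
  out
}

#' Relative cell number against plate negative controls
#'
#' Each well's cell number divided by the mean cell number of the three
#' negative-control wells of its plate; negative controls receive their own
#' ratio against that common mean.
#'
#' @param wells per-well data.frame from [compute_well_statistics()]
#' @param require_three error when a plate has a number of negative
#'   controls other than 3 (default TRUE); when FALSE the available
#'   negatives are averaged
#' @return `wells` with a `relative_cell_number` column
#' @export
relative_cell_number <- function(wells, require_three = TRUE) {
  out <- wells
  out$relative_cell_number <- NA_real_
  for (p in unique(wells$plate)) {
    on_plate <- wells$plate == p
    negs <- wells$cell_number[on_plate & wells$role == "negative_control"]
    if (length(negs) != 3 && require_three) {
      stop("plate ", p, " has ", length(negs),
           " negative controls (3 required)")
    }
    if (!length(negs)) stop("plate ", p, " has no negative controls")
    out$relative_cell_number[on_plate] <-
      wells$cell_number[on_plate] / mean(negs)
  }
  out
}

#' Exclude wells with strong growth defects
#'
#' siRNAs that kill or strongly arrest cells are removed before ranking:
#' a sample well is excluded when its relative cell number falls strictly
#' below the threshold (a well exactly at the threshold is retained).
#' Control wells are never excluded. Exclusions are logged with the reason.
#'
#' @param wells per-well data.frame with `relative_cell_number`
#' @param min_relative_cell_number exclusion threshold (default 0.3)
#' @return list with `retained` and `excluded` data.frames; `excluded`
#'   carries a `reason` column
#' @export
filter_growth <- function(wells, min_relative_cell_number = 0.3) {
  stopifnot("relative_cell_number" %in% names(wells))
  drop <- wells$role == "sample" &
    wells$relative_cell_number < min_relative_cell_number
  excluded <- wells[drop, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$reason <- sprintf(
      "relative cell number %.3f below growth threshold %.3f",
      excluded$relative_cell_number, min_relative_cell_number)
  } else {
    excluded$reason <- character(0)
  }
  list(retained = wells[!drop, , drop = FALSE], excluded = excluded)
}
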