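#' Build a 96-well screen plate layout
#'
#' Assigns targets (three siRNAs each by default) and control wells to
#' 96-well plates, mirroring the screen design: each plate carries three
#' negative-control wells (non-targeting siRNA) and three positive-control
#' wells (Crm1 siRNA, a strong export block). With 3 siRNAs per target a
#' plate holds 30 targets (30 x 3 + 6 = 96).
#'
#' @param targets character vector of target gene identifiers
#' @param sirnas_per_target siRNAs per target (default 3). A target may be
#'   given fewer via `sirna_counts`; fewer than 2 triggers a warning since a
#'   single siRNA cannot satisfy the two-siRNA candidate rule.
#' @param n_negative,n_positive control wells per plate (default 3 each)
#' @param wells_per_plate plate capacity (default 96)
#' @param sirna_counts optional named integer vector overriding
#'   `sirnas_per_target` per target
#' @return data.frame with columns plate, well, role
#'   (sample/negative_control/positive_control), target, sirna
#' @export
#' @examples
#' lay <- plate_layout(paste0("T", 1:30))
#' table(lay$role)
plate_layout <- function(targets, sirnas_per_target = 3,
                         n_negative = 3, n_positive = 3,
                         wells_per_plate = 96, sirna_counts = NULL) {
  stopifnot(length(targets) >= 1, !anyDuplicated(targets))
  counts <- stats::setNames(rep(sirnas_per_target, length(targets)), targets)
  if (!is.null(sirna_counts)) counts[names(sirna_counts)] <- sirna_counts
  if (any(counts < 2)) {
    warning("target(s) with fewer than 2 siRNAs: ",
            paste(names(counts)[counts < 2], collapse = ", "))
  }
  sample_df <- data.frame(
    target = rep(names(counts), counts),
    sirna  = unlist(lapply(names(counts), function(t)
      paste0(t, "_si", seq_len(counts[[t]]))), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  per_plate <- wells_per_plate - n_negative - n_positive
  n_plates <- ceiling(nrow(sample_df) / per_plate)

  rows <- LETTERS[1:8]
  cols <- sprintf("%02d", 1:12)
  well_ids <- as.vector(t(outer(rows, cols, paste0)))[seq_len(wells_per_plate)]

  out <- vector("list", n_plates)
  idx <- 1
  for (p in seq_len(n_plates)) {
    n_samp <- min(per_plate, nrow(sample_df) - idx + 1)
    roles <- c(rep("negative_control", n_negative),
               rep("positive_control", n_positive),
               rep("sample", n_samp))
    tgt <- c(rep(NA_character_, n_negative + n_positive),
             sample_df$target[idx:(idx + n_samp - 1)])
    sir <- c(paste0("neg_ctrl_", seq_len(n_negative)),
             paste0("pos_ctrl_", seq_len(n_positive)),
             sample_df$sirna[idx:(idx + n_samp - 1)])
    out[[p]] <- data.frame(
      plate = p, well = well_ids[seq_along(roles)], role = roles,
      target = tgt, sirna = sir, stringsAsFactors = FALSE
    )
    idx <- idx + n_samp
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read / write a plate layout as YAML
#'
#' The on-disk layout is a YAML list of well records so that a screen run is
#' self-describing without the generating code.
#'
#' @param layout a layout data.frame as returned by [plate_layout()]
#' @param path file path
#' @return `read_plate_layout` returns the layout data.frame;
#'   `write_plate_layout` returns `path` invisibly.
#' @export
write_plate_layout <- function(layout, path) {
  stopifnot(all(c("plate", "well", "role", "target", "sirna") %in% names(layout)))
  recs <- lapply(seq_len(nrow(layout)), function(i) {
    r <- as.list(layout[i, c("plate", "well", "role", "target", "sirna")])
    if (is.na(r$target)) r$target <- NULL
    r
  })
  yaml::write_yaml(list(wells = recs), path)
  invisible(path)
}

#' @rdname write_plate_layout
#' @export
read_plate_layout <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$wells)) stop("layout YAML lacks a 'wells' list")
  recs <- lapply(obj$wells, function(r) {
    data.frame(plate = as.integer(r$plate), well = as.character(r$well),
               role = as.character(r$role),
               target = if (is.null(r$target)) NA_character_ else as.character(r$target),
               sirna = as.character(r$sirna), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
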