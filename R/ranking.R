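#' Plate control levels for ranking
#'
#' Per plate, the negative- and positive-control reference levels are the
#' mean of the two control wells with the highest hit rate (taking the two
#' highest of the three controls guards against a single failed control
#' well). A plate whose positive level does not exceed its negative level
#' is flagged failed; its sample wells receive no rank.
#'
#' @param wells per-well data.frame with `role` and the value column
#' @param value_col hit-rate column to summarize (default `hit_rate`)
#' @return data.frame: plate, h_neg, h_pos, failed
#' @export
plate_control_levels <- function(wells, value_col = "hit_rate") {
  top2mean <- function(v) mean(sort(v, decreasing = TRUE)[1:2])
  out <- lapply(unique(wells$plate), function(p) {
    on_plate <- wells$plate == p
    neg <- wells[[value_col]][on_plate & wells$role == "negative_control"]
    pos <- wells[[value_col]][on_plate & wells$role == "positive_control"]
    if (length(neg) < 2 || length(pos) < 2) {
      stop("plate ", p, " needs at least 2 negative and 2 positive ",
           "controls with computed hit rates")
    }
    h_neg <- top2mean(neg); h_pos <- top2mean(pos)
    data.frame(plate = p, h_neg = h_neg, h_pos = h_pos,
               failed = h_pos <= h_neg)
  })
  do.call(rbind, out)
}

#' Rank siRNA hit rates between plate controls
#'
#' The rank rescales each well's hit rate between the plate's
#' negative-control level (rank 0) and positive-control level (rank 1):
#' \deqn{rank = (h - h_{neg}) / (h_{pos} - h_{neg})}
#' where the control levels are the two-highest-control means of the same
#' plate (see [plate_control_levels()]). Ranks are not clipped: a well
#' below the negative level ranks negative, one above the positive level
#' ranks above 1. Sample wells of failed plates (positive level not above
#' negative) get `NA` and a warning.
#'
#' @param wells per-well data.frame with `plate`, `role`, and `value_col`
#' @param value_col hit-rate column (default `hit_rate`)
#' @param rank_col name of the output column (default `sirna_rank`)
#' @return `wells` with the rank column and `plate_failed` flag added
#' @export
rank_sirna <- function(wells, value_col = "hit_rate",
                       rank_col = "sirna_rank") {
  ctl <- plate_control_levels(wells, value_col)
  out <- wells
  out[[rank_col]] <- NA_real_
  out$plate_failed <- FALSE
  for (i in seq_len(nrow(ctl))) {
    on_plate <- out$plate == ctl$plate[i]
    if (ctl$failed[i]) {
      out$plate_failed[on_plate] <- TRUE
      next
    }
    out[[rank_col]][on_plate] <-
      (out[[value_col]][on_plate] - ctl$h_neg[i]) /
      (ctl$h_pos[i] - ctl$h_neg[i])
  }
  if (any(ctl$failed)) {
    warning("failed plate(s) (positive control level not above negative): ",
            paste(ctl$plate[ctl$failed], collapse = ", "),
            "; their wells are unranked")
  }
  out
}

# order siRNA wells of one target for top-two selection:
# rank desc, hit rate desc, siRNA id asc (stable, documented tie-break)
order_sirnas <- function(df, rank_col = "sirna_rank") {
  df[order(-df[[rank_col]], -df$hit_rate, df$sirna), , drop = FALSE]
}

#' Score targets: candidate filter, target rank, high-confidence calls
#'
#' Per target, over its non-excluded siRNA wells:
#' \itemize{
#'   \item \emph{candidate}: at least two siRNAs each with a hit rate
#'     strictly greater than twice the negative-control level of their own
#'     plate (the same two-highest-negatives mean used for ranking, or the
#'     mean of all three negatives with `neg_summary = "mean3"`);
#'   \item \emph{target rank}: the mean of the two highest siRNA ranks
#'     (ties broken by rank, then hit rate, then siRNA id);
#'   \item \emph{evaluable}: at least two usable (ranked, non-excluded)
#'     siRNAs; otherwise the target is reported not evaluable rather than
#'     not hit.
#' }
#'
#' @param wells ranked per-well data.frame ([rank_sirna()]), growth-filtered
#' @param neg_summary `"top2"` (default) or `"mean3"`: which summary of the
#'   plate negative controls the 2x candidate filter compares against
#' @param all_targets optional character vector of every screened target;
#'   targets whose wells were all excluded upstream are then still reported
#'   (as not evaluable) instead of silently disappearing
#' @return data.frame, one row per target: per-target siRNA count,
#'   candidate flag, target_rank, evaluable flag
#' @export
score_targets <- function(wells, neg_summary = c("top2", "mean3"),
                          all_targets = NULL) {
  neg_summary <- match.arg(neg_summary)
  stopifnot("sirna_rank" %in% names(wells))
  neg_level <- if (neg_summary == "top2") {
    ctl <- plate_control_levels(wells)
    stats::setNames(ctl$h_neg, ctl$plate)
  } else {
    vapply(split(wells, wells$plate), function(pw)
      mean(pw$hit_rate[pw$role == "negative_control"]), numeric(1))
  }
  samp <- wells[wells$role == "sample" & !is.na(wells$target), , drop = FALSE]
  out <- lapply(split(samp, samp$target), function(df) {
    usable <- df[!df$plate_failed, , drop = FALSE]
    n_over <- sum(usable$hit_rate >
                    2 * neg_level[as.character(usable$plate)])
    evaluable <- nrow(usable) >= 2
    tr <- NA_real_
    if (evaluable) {
      top <- order_sirnas(usable)[1:2, ]
      tr <- mean(top$sirna_rank)
    }
    data.frame(target = df$target[1], n_sirnas = nrow(df),
               n_usable = nrow(usable), n_over_2x = n_over,
               candidate = evaluable && n_over >= 2,
               target_rank = tr, evaluable = evaluable,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  gone <- setdiff(all_targets, res$target)
  if (length(gone)) {
    res <- rbind(res, data.frame(
      target = gone, n_sirnas = 0L, n_usable = 0L, n_over_2x = 0L,
      candidate = FALSE, target_rank = NA_real_, evaluable = FALSE,
      stringsAsFactors = FALSE))
    res <- res[order(res$target), ]
    rownames(res) <- NULL
  }
  res
}

#' Call high-confidence hits
#'
#' A target is a high-confidence hit when it passed the two-siRNA candidate
#' filter and its target rank strictly exceeds the readout cutoff
#' ([default_cutoff()]; 0.2 Rps2-YFP, 0.3 Enp1 IF, 0.25 Rpl29-GFP).
#'
#' @param targets per-target data.frame from [score_targets()]
#' @param readout readout id (sets the default cutoff)
#' @param cutoff rank cutoff; overrides the readout default
#' @return `targets` with a `high_confidence` column
#' @export
call_hits <- function(targets, readout = "rps2",
                      cutoff = default_cutoff(readout)) {
  out <- targets
  out$high_confidence <- out$candidate & !is.na(out$target_rank) &
    out$target_rank > cutoff
  attr(out, "cutoff") <- cutoff
  out
}

#' Cytoplasmic Enp1 calls from absolute hit rates
#'
#' The cytoplasmic Enp1 readout has no positive control that accumulates
#' the signal in the cytoplasm, so no control-normalized ranking is
#' possible; absolute cytoplasmic hit rates are used instead. The target
#' statistic is the mean of the two highest per-siRNA absolute cytoplasmic
#' rates; a target is called when that statistic strictly exceeds the
#' threshold and at least two siRNAs individually exceed twice the plate
#' negative-control cytoplasmic level (two-siRNA support, mirroring the
#' candidate rule).
#'
#' @param wells Enp1 per-well data.frame with `hit_rate_cyt`
#' @param threshold absolute-rate call threshold (default 0.2)
#' @return data.frame per target: statistic (mean of top two rates),
#'   two-siRNA support flag, hit flag
#' @export
cytoplasmic_enp1_calls <- function(wells, threshold = 0.2) {
  stopifnot("hit_rate_cyt" %in% names(wells))
  ctl <- plate_control_levels(wells, value_col = "hit_rate_cyt")
  neg_level <- stats::setNames(ctl$h_neg, ctl$plate)
  samp <- wells[wells$role == "sample" & !is.na(wells$target), , drop = FALSE]
  out <- lapply(split(samp, samp$target), function(df) {
    rates <- sort(df$hit_rate_cyt, decreasing = TRUE)
    statistic <- if (length(rates) >= 2) mean(rates[1:2]) else rates[1]
    support <- sum(df$hit_rate_cyt >
                     2 * neg_level[as.character(df$plate)]) >= 2
    data.frame(target = df$target[1], statistic = statistic,
               support = support,
               hit = support && statistic > threshold,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "threshold") <- threshold
  res
}
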