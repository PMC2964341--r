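# Independent brute-force re-implementation of the screen-calling rules,
# written as straight-line arithmetic over a per-well table. Deliberately
# shares no code with the package internals; used to cross-check ranking,
# candidate selection, hit calling, stage ratios and the Rio2 rule.

oracle_two_highest_mean <- function(v) {
  s <- sort(v, decreasing = TRUE)
  mean(s[1:2])
}

# per-plate control levels; NA-rank plates where positives fail
oracle_plate_calls <- function(wells, cutoff) {
  plates <- unique(wells$plate)
  h_neg <- h_pos <- setNames(numeric(length(plates)), plates)
  failed <- setNames(logical(length(plates)), plates)
  for (p in plates) {
    pw <- wells[wells$plate == p, ]
    h_neg[as.character(p)] <-
      oracle_two_highest_mean(pw$hit_rate[pw$role == "negative_control"])
    h_pos[as.character(p)] <-
      oracle_two_highest_mean(pw$hit_rate[pw$role == "positive_control"])
    failed[as.character(p)] <- h_pos[as.character(p)] <= h_neg[as.character(p)]
  }
  samp <- wells[wells$role == "sample", ]
  samp$rank <- NA_real_
  for (i in seq_len(nrow(samp))) {
    p <- as.character(samp$plate[i])
    if (!failed[p]) {
      samp$rank[i] <- (samp$hit_rate[i] - h_neg[p]) / (h_pos[p] - h_neg[p])
    }
  }
  res <- list()
  for (tgt in unique(samp$target)) {
    tw <- samp[samp$target == tgt, ]
    usable <- tw[!failed[as.character(tw$plate)], ]
    n_over <- 0
    for (i in seq_len(nrow(usable))) {
      if (usable$hit_rate[i] > 2 * h_neg[as.character(usable$plate[i])]) {
        n_over <- n_over + 1
      }
    }
    evaluable <- nrow(usable) >= 2
    tr <- NA_real_
    if (evaluable) {
      o <- order(-usable$rank, -usable$hit_rate, usable$sirna)
      tr <- mean(usable$rank[o[1:2]])
    }
    candidate <- evaluable && n_over >= 2
    res[[tgt]] <- data.frame(
      target = tgt, candidate = candidate, target_rank = tr,
      evaluable = evaluable,
      high_confidence = candidate && !is.na(tr) && tr > cutoff,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out[order(out$target), ]
}

oracle_np_ratio <- function(nucleoplasmic, nucleolar) {
  d <- nucleoplasmic + nucleolar
  ifelse(d > 0, nucleoplasmic / d, NA_real_)
}

oracle_rio2 <- function(fractions, threshold = 0.2) {
  s <- sort(fractions, decreasing = TRUE)
  stat <- if (length(s) >= 2) mean(s[1:2]) else s[1]
  list(statistic = stat, hit = stat > threshold)
}

# Mann-Whitney AUC, independent of pROC
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# random small plate with 3 + 3 controls and a handful of targets
random_plate <- function(seed, plate_id = 1, n_targets = NULL,
                         fail_prob = 0.1) {
  set.seed(seed)
  if (is.null(n_targets)) n_targets <- sample(3:8, 1)
  tgts <- paste0("G", seq_len(n_targets))
  rows <- data.frame(
    plate = plate_id,
    role = c(rep("negative_control", 3), rep("positive_control", 3),
             rep("sample", 3 * n_targets)),
    target = c(rep(NA, 6), rep(tgts, each = 3)),
    sirna = c(paste0("nc", 1:3), paste0("pc", 1:3),
              paste0(rep(tgts, each = 3), "_si", 1:3)),
    stringsAsFactors = FALSE)
  neg <- runif(3, 0, 0.08)
  pos <- if (runif(1) < fail_prob) runif(3, 0, 0.05) else runif(3, 0.3, 0.8)
  rows$hit_rate <- c(neg, pos, runif(3 * n_targets, 0, 0.9))
  rows$well <- sprintf("W%02d", seq_len(nrow(rows)))
  rows
}
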