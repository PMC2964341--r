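# compact builder: classified cell table for one well
cells_for <- function(plate, well, classes, reporter_positive = NULL) {
  df <- data.frame(plate = plate, well = well,
                   cell_id = seq_along(classes), pred_class = classes,
                   stringsAsFactors = FALSE)
  if (!is.null(reporter_positive)) df$reporter_positive <- reporter_positive
  df
}

one_well_layout <- data.frame(plate = 1, well = "A01", role = "sample",
                              target = "T1", sirna = "T1_si1",
                              stringsAsFactors = FALSE)

test_that("hit rate is hits over reporter-positive interphase cells", {
  # 0 hit-class cells of 200 reporter-positive interphase
  w <- compute_well_statistics(
    cells_for(1, "A01", rep("cytoplasmic", 200)), one_well_layout, "rps2")
  expect_equal(w$hit_rate, 0)
  expect_equal(w$reporter_positive_interphase, 200)

  # 30 hit of 120: mitotic/debris/no_reporter stay out of the denominator
  cl <- c(rep("nucleolar", 30), rep("cytoplasmic", 90),
          rep("mitotic", 7), rep("debris", 3), rep("no_reporter", 10))
  w <- compute_well_statistics(cells_for(1, "A01", cl), one_well_layout, "rps2")
  expect_equal(w$reporter_positive_interphase, 120)
  expect_equal(w$hit_rate, 0.25)
  expect_equal(w$cell_number, 140)

  # nuclear definition sums nucleolar + nucleoplasmic
  cl <- c(rep("nucleolar", 10), rep("nucleoplasmic", 20),
          rep("cytoplasmic", 70))
  w <- compute_well_statistics(cells_for(1, "A01", cl), one_well_layout, "rps2")
  expect_equal(w$hit_rate, 0.30)
  expect_equal(w$nucleolar_count, 10)
  expect_equal(w$nucleoplasmic_count, 20)

  # reporter_positive flag narrows the denominator further
  cl <- rep(c("nucleolar", "cytoplasmic"), c(10, 30))
  w <- compute_well_statistics(
    cells_for(1, "A01", cl, reporter_positive = rep(c(TRUE, FALSE), 20)),
    one_well_layout, "rps2")
  expect_equal(w$reporter_positive_interphase, 20)

  expect_error(
    compute_well_statistics(cells_for(1, "A01", "spindle"),
                            one_well_layout, "rps2"),
    "unknown class")
  expect_warning(
    compute_well_statistics(cells_for(1, "A01", rep("mitotic", 5)),
                            one_well_layout, "rps2"),
    "zero reporter-positive")
  # per-class counts conserve the cell number
  cl <- sample(readout_classes("rps2"), 57, replace = TRUE)
  w <- suppressWarnings(compute_well_statistics(cells_for(1, "A01", cl),
                                                one_well_layout, "rps2"))
  expect_equal(sum(w[paste0("count_", readout_classes("rps2"))]), 57)
})

make_wells <- function(cell_numbers, roles) {
  data.frame(plate = 1, well = sprintf("W%02d", seq_along(roles)),
             role = roles,
             target = ifelse(roles == "sample",
                             paste0("T", seq_along(roles)), NA),
             sirna = paste0("s", seq_along(roles)),
             cell_number = cell_numbers, stringsAsFactors = FALSE)
}

test_that("relative cell number is computed against the plate negatives", {
  w <- make_wells(c(100, 100, 100, 100),
                  c(rep("negative_control", 3), "sample"))
  expect_equal(relative_cell_number(w)$relative_cell_number[4], 1.0)
  w <- make_wells(c(90, 100, 110, 50),
                  c(rep("negative_control", 3), "sample"))
  r <- relative_cell_number(w)
  expect_equal(r$relative_cell_number[4], 0.5)
  expect_equal(r$relative_cell_number[1:3], c(0.9, 1.0, 1.1))
  bad <- w[-1, ]
  expect_error(relative_cell_number(bad), "3 required")
  expect_equal(relative_cell_number(bad, require_three = FALSE)$
                 relative_cell_number[3], 50 / 105)
})

test_that("growth exclusion uses a strict below-threshold rule", {
  w <- make_wells(c(100, 100, 100, 29, 30, 80),
                  c(rep("negative_control", 3), rep("sample", 3)))
  w <- relative_cell_number(w)
  fg <- filter_growth(w, 0.3)
  expect_false("T4" %in% fg$retained$target)  # 0.29 excluded
  expect_true("T5" %in% fg$retained$target)   # 0.30 retained
  expect_match(fg$excluded$reason, "growth threshold")
  expect_equal(nrow(filter_growth(w, 0)$excluded), 0)
  # controls are never excluded
  w2 <- make_wells(c(100, 100, 100, 1), c(rep("negative_control", 3), "sample"))
  w2$role[1] <- "negative_control"
  w2$cell_number[1] <- 1
  w2 <- relative_cell_number(w2)
  expect_true(all(filter_growth(w2, 0.3)$excluded$role == "sample"))
})

rank_fixture <- function(neg, pos, sample_rates, plate = 1) {
  n <- length(sample_rates)
  data.frame(plate = plate,
             well = sprintf("W%02d", seq_len(6 + n)),
             role = c(rep("negative_control", 3), rep("positive_control", 3),
                      rep("sample", n)),
             target = c(rep(NA, 6), paste0("T", seq_len(n))),
             sirna = paste0("s", seq_len(6 + n)),
             hit_rate = c(neg, pos, sample_rates),
             stringsAsFactors = FALSE)
}

test_that("the rank formula rescales between two-highest control means", {
  w <- rank_fixture(c(0.02, 0.04, 0.05), c(0.50, 0.55, 0.60), 0.35)
  r <- rank_sirna(w)
  h_neg <- mean(c(0.05, 0.04)); h_pos <- mean(c(0.60, 0.55))
  expect_equal(h_neg, 0.045); expect_equal(h_pos, 0.575)
  expect_equal(r$sirna_rank[r$role == "sample"],
               (0.35 - 0.045) / (0.575 - 0.045))
  # endpoints of the formula
  w2 <- rank_fixture(c(0.02, 0.04, 0.05), c(0.5, 0.55, 0.6), c(0.045, 0.575))
  r2 <- rank_sirna(w2)
  expect_equal(r2$sirna_rank[r2$role == "sample"], c(0, 1))
  # ranks are not clipped
  w3 <- rank_fixture(c(0.02, 0.04, 0.05), c(0.5, 0.55, 0.6), c(0.0, 0.9))
  r3 <- rank_sirna(w3)
  expect_lt(r3$sirna_rank[r3$role == "sample"][1], 0)
  expect_gt(r3$sirna_rank[r3$role == "sample"][2], 1)
})

test_that("failed plates are quarantined, not fatal", {
  w <- rank_fixture(c(0.30, 0.35, 0.40), c(0.05, 0.06, 0.07), c(0.5, 0.6))
  expect_warning(r <- rank_sirna(w), "failed plate")
  expect_true(all(is.na(r$sirna_rank[r$role == "sample"])))
  expect_true(all(r$plate_failed))
  ok <- rank_fixture(c(0.02, 0.03, 0.04), c(0.5, 0.6, 0.7), 0.3, plate = 2)
  both <- rbind(w, ok)
  expect_warning(r2 <- rank_sirna(both), "failed plate")
  expect_false(any(is.na(r2$sirna_rank[r2$plate == 2 & r2$role == "sample"])))
})

candidate_fixture <- function(rates, neg = c(0.02, 0.04, 0.05),
                              pos = c(0.5, 0.55, 0.6)) {
  n <- length(rates)
  data.frame(plate = 1, well = sprintf("W%02d", seq_len(6 + n)),
             role = c(rep("negative_control", 3), rep("positive_control", 3),
                      rep("sample", n)),
             target = c(rep(NA, 6), rep("T1", n)),
             sirna = c(paste0("c", 1:6), paste0("T1_si", seq_len(n))),
             hit_rate = c(neg, pos, rates), stringsAsFactors = FALSE)
}

test_that("the two-siRNA candidate filter uses a strict 2x rule", {
  # h_neg = 0.045; twice = 0.09
  t1 <- score_targets(rank_sirna(candidate_fixture(c(0.10, 0.12, 0.01))))
  expect_true(t1$candidate)
  t2 <- score_targets(rank_sirna(candidate_fixture(c(0.10, 0.07, 0.01))))
  expect_false(t2$candidate)
  t3 <- score_targets(rank_sirna(candidate_fixture(c(0.09, 0.09, 0.09),
                                                   neg = c(0.02, 0.04, 0.05))))
  expect_equal(t3$n_over_2x, 0)  # exactly 2x does not count
  # mean-of-three alternative is configurable
  t4 <- score_targets(rank_sirna(candidate_fixture(c(0.08, 0.08, 0.01))),
                      neg_summary = "mean3")
  expect_true(t4$candidate)  # 2 * mean(0.02,0.04,0.05) = 0.0733 < 0.08
})

test_that("target rank averages the two highest siRNA ranks with stable ties", {
  w <- rank_sirna(candidate_fixture(c(0.10, 0.35, 0.575)))
  tg <- score_targets(w)
  r <- sort(w$sirna_rank[w$role == "sample"], decreasing = TRUE)[1:2]
  expect_equal(tg$target_rank, mean(r))
  # a two-siRNA target is scored from both
  w2 <- rank_sirna(candidate_fixture(c(0.2, 0.4)))
  expect_equal(score_targets(w2)$target_rank,
               mean(w2$sirna_rank[w2$role == "sample"]))
  # fewer than two usable siRNAs: not evaluable rather than not hit
  w3 <- rank_sirna(candidate_fixture(0.4))
  tg3 <- score_targets(w3)
  expect_false(tg3$evaluable)
  expect_true(is.na(tg3$target_rank))
})

test_that("high-confidence cutoffs are per readout and strict", {
  mk <- function(tr) data.frame(target = "T1", candidate = TRUE,
                                target_rank = tr, evaluable = TRUE)
  expect_true(call_hits(mk(0.26), "rpl29")$high_confidence)   # > 0.25
  expect_false(call_hits(mk(0.25), "rpl29")$high_confidence)
  expect_false(call_hits(mk(0.20), "rps2")$high_confidence)   # boundary
  expect_true(call_hits(mk(0.21), "rps2")$high_confidence)
  expect_false(call_hits(mk(0.30), "enp1")$high_confidence)
  expect_false(call_hits(mk(0.9), "rps2")$high_confidence ==
                 call_hits(mk(0.9), "rps2", cutoff = 0.95)$high_confidence)
  expect_equal(default_cutoff("rps2"), 0.2)
  expect_equal(default_cutoff("enp1"), 0.3)
  expect_equal(default_cutoff("rpl29"), 0.25)
})

test_that("cytoplasmic Enp1 calls use absolute rates with two-siRNA support", {
  mk_enp1 <- function(rates, neg = c(0.01, 0.02, 0.02),
                      pos = c(0.01, 0.01, 0.02)) {
    n <- length(rates)
    data.frame(plate = 1, well = sprintf("W%02d", seq_len(6 + n)),
               role = c(rep("negative_control", 3),
                        rep("positive_control", 3), rep("sample", n)),
               target = c(rep(NA, 6), rep("T1", n)),
               sirna = c(paste0("c", 1:6), paste0("T1_si", seq_len(n))),
               hit_rate_cyt = c(neg, pos, rates), stringsAsFactors = FALSE)
  }
  r <- cytoplasmic_enp1_calls(mk_enp1(c(0.40, 0.35, 0.05)))
  expect_equal(r$statistic, 0.375)
  expect_true(r$hit)
  r0 <- cytoplasmic_enp1_calls(mk_enp1(c(0, 0, 0)))
  expect_equal(r0$statistic, 0)
  expect_false(r0$hit)
  r2 <- cytoplasmic_enp1_calls(mk_enp1(c(0.40, 0.0)))
  expect_equal(r2$statistic, 0.20)
  expect_false(r2$hit)  # 0.20 not > 0.20, and only one siRNA supports
})

test_that("ranks are invariant to affine rescaling of plate hit rates", {
  for (seed in 1:5) {
    w <- random_plate(seed, fail_prob = 0)
    base <- rank_sirna(w)$sirna_rank
    shifted <- w; shifted$hit_rate <- shifted$hit_rate + 0.13
    scaled <- w; scaled$hit_rate <- scaled$hit_rate * 2.7
    expect_equal(rank_sirna(shifted)$sirna_rank, base, tolerance = 1e-9)
    expect_equal(rank_sirna(scaled)$sirna_rank, base, tolerance = 1e-9)
  }
})

test_that("raising one siRNA's hit rate never lowers its target's rank", {
  for (seed in 1:10) {
    w <- random_plate(seed, fail_prob = 0)
    tg0 <- score_targets(suppressWarnings(rank_sirna(w)))
    i <- sample(which(w$role == "sample"), 1)
    w2 <- w
    w2$hit_rate[i] <- min(1, w2$hit_rate[i] + stats::runif(1, 0, 0.3))
    tg1 <- score_targets(suppressWarnings(rank_sirna(w2)))
    tgt <- w$target[i]
    expect_gte(tg1$target_rank[tg1$target == tgt] + 1e-12,
               tg0$target_rank[tg0$target == tgt])
  }
})

test_that("rank, candidate and hit outputs match the brute-force oracle", {
  for (seed in 101:140) {
    w <- random_plate(seed)
    got <- call_hits(score_targets(suppressWarnings(rank_sirna(w))), "rps2")
    got <- got[order(got$target), ]
    want <- oracle_plate_calls(w, cutoff = 0.2)
    expect_equal(got$target, want$target)
    expect_equal(got$candidate, want$candidate)
    expect_equal(got$target_rank, want$target_rank)
    expect_equal(got$high_confidence, want$high_confidence)
  }
})

test_that("fully growth-excluded targets surface as not evaluable", {
  w <- rank_sirna(candidate_fixture(c(0.3, 0.4, 0.5)))
  tg <- score_targets(w, all_targets = c("T1", "T9"))
  expect_true("T9" %in% tg$target)
  row <- tg[tg$target == "T9", ]
  expect_false(row$evaluable)
  expect_false(call_hits(tg)$high_confidence[tg$target == "T9"])
  expect_true(is.na(row$target_rank))
})
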