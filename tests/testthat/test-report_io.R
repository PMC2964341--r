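test_that("three-set Venn regions enumerate correctly and conserve the union", {
  v <- venn_overlap(list(a = c("p", "q"), b = c("r", "s", "t"),
                         c = c("u", "v", "w", "x")))
  expect_equal(unname(v[c("A_only", "B_only", "C_only")]), c(2, 3, 4))
  expect_equal(unname(v[c("AB", "AC", "BC", "ABC")]), rep(0, 4))
  v2 <- venn_overlap(list(a = c("x", "y"), b = c("y", "z"), c = "y"))
  expect_equal(unname(v2["ABC"]), 1)
  expect_equal(unname(v2["A_only"]), 1)
  expect_equal(unname(v2["B_only"]), 1)
  expect_equal(unname(v2["C_only"]), 0)
  same <- venn_overlap(list(a = letters[1:5], b = letters[1:5],
                            c = letters[1:5]))
  expect_equal(unname(same["ABC"]), 5)
  expect_equal(sum(same), 5)
  sets <- list(a = sample(letters, 12), b = sample(letters, 8),
               c = sample(letters, 15))
  expect_equal(sum(venn_overlap(sets)),
               length(unique(unlist(sets))))
})

test_that("category report computes per-category hit fractions", {
  catalog <- data.frame(
    target = paste0("g", 1:120),
    category = c(rep("miscellaneous", 103), rep("ribosome_synthesis", 17)),
    stringsAsFactors = FALSE)
  hits <- c(paste0("g", 1:5), paste0("g", 110:115))
  rep <- category_report(hits, catalog)
  misc <- rep[rep$category == "miscellaneous", ]
  expect_equal(misc$n_screened, 103)
  expect_equal(misc$n_hits, 5)
  expect_equal(misc$hit_fraction, 5 / 103)
  expect_equal(rep[rep$category == "ribosome_synthesis", "hit_fraction"],
               6 / 17)
  none <- category_report(character(0), catalog)
  expect_true(all(none$hit_fraction == 0))
  expect_error(category_report("unknown_gene", catalog), "missing from")
  # planted synthetic catalog reproduces ground truth exactly
  set.seed(3)
  planted <- sample(catalog$target, 20)
  rep2 <- category_report(planted, catalog)
  expect_equal(sum(rep2$n_hits), 20)
  expect_equal(sum(rep2$n_screened), 120)
})

test_that("well tables and layouts round-trip losslessly", {
  lay <- tiny_layout()
  p <- tempfile(fileext = ".yaml")
  write_plate_layout(lay, p)
  expect_equal(read_plate_layout(p), lay)

  cfg <- synth_config(lay, cells_per_well_mean = 40, seed = 4)
  tab <- generate_feature_table(cfg, features = FALSE)
  wells <- relative_cell_number(
    compute_well_statistics(tab$cells, lay, "rps2"))
  f <- tempfile(fileext = ".csv")
  write_well_table(wells, f)
  back <- read_well_table(f)
  expect_equal(back$hit_rate, wells$hit_rate)                 # full precision
  expect_equal(back$relative_cell_number, wells$relative_cell_number)
  expect_identical(back$target, wells$target)                 # NA, not 0
})

test_that("supplementary-layout well tables import and replay", {
  # build a screen, write its per-well numbers under published-style
  # headers, re-import and check the calling rules reproduce the hit list
  lay <- plate_layout(paste0("T", 1:30))
  eff <- setNames(lapply(1:6, function(i)
    list(mix = c(nucleolar = 0.2, nucleoplasmic = 0.2))), paste0("T", 1:6))
  cfg <- synth_config(lay, cells_per_well_mean = 300, seed = 9,
                      effect_map = eff)
  res <- run_pipeline(cfg)
  expect_setequal(res$hits, paste0("T", 1:6))

  pub <- data.frame(
    "plate number" = res$wells$plate, "well" = res$wells$well,
    "role" = res$wells$role, "target" = res$wells$target,
    "siRNA" = res$wells$sirna, "cell number" = res$wells$cell_number,
    "relative cell number" = res$wells$relative_cell_number,
    "YFP-positive cells" = res$wells$reporter_positive_interphase,
    "hit-classified cells" = res$wells$hit_count,
    "hit rate" = res$wells$hit_rate,
    "nucleolar" = res$wells$nucleolar_count,
    "nucleoplasmic" = res$wells$nucleoplasmic_count,
    check.names = FALSE)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(pub, f, row.names = FALSE)
  imp <- import_supplementary_wells(f, readout = "rps2")
  expect_equal(imp$hit_rate, res$wells$hit_rate)
  replay <- replay_well_table(imp, run_config("rps2"))
  expect_setequal(replay$hits, res$hits)
  expect_equal(
    replay$targets$target_rank[order(replay$targets$target)],
    res$targets$target_rank[order(res$targets$target)])
})

test_that("the pipeline emits all declared outputs and reruns bit-identically", {
  lay <- tiny_layout()
  cfg <- synth_config(lay, cells_per_well_mean = 120, seed = 5,
                      effect_map = list(T3 = list(
                        mix = c(nucleolar = 0.3, nucleoplasmic = 0.2))))
  d1 <- file.path(tempdir(), "run1"); d2 <- file.path(tempdir(), "run2")
  r1 <- run_pipeline(cfg, out_dir = d1)
  r2 <- run_pipeline(cfg, out_dir = d2)
  for (f in c("well_statistics.csv", "target_scores.csv", "hit_list.tsv",
              "stage_scores.csv", "run_manifest.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_equal(r1$hits, "T3")
  # manifest discloses every threshold used in the calls
  man <- jsonlite::read_json(file.path(d1, "run_manifest.json"))
  expect_true(all(c("cutoff", "min_relative_cell_number",
                    "background_multiple", "enp1_cyt_threshold",
                    "rio2_threshold", "neg_summary", "seed") %in% names(man)))
  expect_error(run_pipeline(cfg, run = run_config("enp1")), "readouts")
})

test_that("rendered screens are written as self-describing TIFF bundles", {
  lay <- plate_layout(c("T1", "T2"), wells_per_plate = 12)
  cfg <- synth_config(lay, readout = "rps2", render = TRUE, seed = 6)
  d <- file.path(tempdir(), "imgrun")
  bundle <- generate_screen(cfg, dir = d, image_size = 128,
                            cells_per_image = 5)
  expect_equal(length(bundle$images), 12)
  expect_true(file.exists(file.path(d, "layout.yaml")))
  expect_true(file.exists(file.path(d, "ground_truth.csv")))
  expect_true(file.exists(file.path(d, "manifest.json")))
  tifs <- list.files(d, pattern = "\\.tif$")
  expect_equal(length(tifs), 12)
  pages <- tiff::readTIFF(file.path(d, tifs[1]), all = TRUE)
  expect_equal(length(pages), 2)        # page 1 DNA, page 2 reporter
  gt <- utils::read.csv(file.path(d, "ground_truth.csv"))
  expect_true(all(c("plate", "well", "cell_id", "true_class") %in% names(gt)))
})

test_that("image-level run puts planted positive controls at the top hit rates", {
  # classifier trained on rendered fields labelled through ground-truth masks
  mix_tr <- c(cytoplasmic = 0.3, nucleoplasmic = 0.3, nucleolar = 0.3,
              no_reporter = 0.1)
  train_rows <- list()
  for (s in 1:10) {
    img <- generate_cell_image(list(mix = mix_tr, n_cells = 12),
                               image_size = 256, seed = 500 + s)
    seg <- define_cell_regions(segment_nuclei(img$dna), 5)
    if (seg$n == 0) next
    f <- extract_features(seg, img$dna, img$reporter)
    m <- match_cells_to_truth(seg, img$truth)
    f$class_label <- m$true_class
    train_rows[[s]] <- f[!is.na(f$class_label), ]
  }
  mdl <- train_classifier(do.call(rbind, train_rows), min_per_class = 5,
                          seed = 61)
  lay <- plate_layout(c("T1", "T2"), wells_per_plate = 12)
  base <- c(cytoplasmic = 0.85, nucleoplasmic = 0.05, nucleolar = 0.05,
            no_reporter = 0.05, mitotic = 0, debris = 0)
  posm <- c(cytoplasmic = 0.15, nucleoplasmic = 0.70, nucleolar = 0.10,
            no_reporter = 0.05, mitotic = 0, debris = 0)
  cfg <- synth_config(lay, baseline_mix = base, positive_mix = posm,
                      render = TRUE, seed = 62)
  expect_error(run_pipeline(cfg), "classifier")
  res <- run_pipeline(cfg, classifier = mdl, cells_per_image = 12)
  w <- res$wells
  top3 <- w$well[order(-w$hit_rate)][1:3]
  expect_setequal(w$role[w$well %in% top3], "positive_control")
  expect_gt(min(w$hit_rate[w$role == "positive_control"]),
            max(w$hit_rate[w$role != "positive_control"]))
})
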