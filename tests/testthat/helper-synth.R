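# Shared fixture builders (all generated in code, seeded).

tiny_layout <- function(n_targets = 6, wells_per_plate = n_targets * 3 + 6) {
  plate_layout(paste0("T", seq_len(n_targets)),
               wells_per_plate = wells_per_plate)
}

# per-class draws straight from a feature model (no wells involved)
sample_feature_cells <- function(n_per_class, readout = "rps2",
                                 separation = 4, seed = 1) {
  set.seed(seed)
  fm <- default_feature_model(readout, separation = separation)
  cls <- readout_classes(readout)
  do.call(rbind, lapply(cls, function(k) {
    X <- MASS::mvrnorm(n_per_class, mu = fm$means[k, ], Sigma = fm$cov)
    df <- as.data.frame(X)
    names(df) <- feature_names()
    df$class_label <- k
    df
  }))
}

# one circular "nucleus" drawn directly into a segmentation object
disc_segmentation <- function(size = 128, centers, radius = 10) {
  lab <- matrix(0L, size, size)
  for (k in seq_len(nrow(centers))) {
    for (x in 1:size) for (y in 1:size) {
      if ((x - centers[k, 1])^2 + (y - centers[k, 2])^2 <= radius^2 &&
          lab[x, y] == 0L) {
        lab[x, y] <- k
      }
    }
  }
  bbox <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    data.frame(label = k, x0 = min(w[, 1]), x1 = max(w[, 1]),
               y0 = min(w[, 2]), y1 = max(w[, 2]), area = nrow(w),
               cx = mean(w[, 1]), cy = mean(w[, 2]))
  }))
  structure(list(labels = lab, n = nrow(centers), bbox = bbox,
                 annulus = NULL),
            class = "nucleus_segmentation")
}

# per-truth-nucleus recovery: best Jaccard over segmented labels
truth_recovery <- function(seg, truth) {
  m <- match_cells_to_truth(seg, truth)
  vapply(truth$cells$cell_id, function(tid) {
    j <- m$jaccard[!is.na(m$truth_id) & m$truth_id == tid]
    if (length(j)) max(j) else 0
  }, numeric(1))
}
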