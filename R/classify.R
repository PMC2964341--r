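#' Train the per-cell phenotype classifier
#'
#' A probability random forest over the fixed 30-feature schema. The model
#' bundle records the feature schema (names and order), the readout's
#' canonical class order, and the training seed, so that classification is
#' reproducible and schema mismatches are caught at prediction time.
#'
#' @param train data.frame with the 30 feature columns and a `class_label`
#'   column; every class must appear at least `min_per_class` times
#' @param readout readout id fixing the class taxonomy
#' @param num_trees forest size (default 200)
#' @param min_per_class minimum training examples required per present
#'   class (default 10)
#' @param seed integer; training is deterministic given (data, params, seed)
#' @return object of class `phenotype_classifier`
#' @export
train_classifier <- function(train, readout = "rps2", num_trees = 200,
                             min_per_class = 10, seed = 1L) {
  fn <- feature_names()
  miss <- setdiff(c(fn, "class_label"), names(train))
  if (length(miss)) stop("training table lacks column(s): ",
                         paste(miss, collapse = ", "))
  cls <- readout_classes(readout)
  bad <- setdiff(unique(train$class_label), cls)
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  present <- intersect(cls, unique(train$class_label))
  if (length(present) < 2) {
    stop("training set must contain at least 2 classes")
  }
  tab <- table(train$class_label)
  low <- names(tab)[tab < min_per_class]
  if (length(low)) stop("class(es) below the ", min_per_class,
                        "-example floor: ", paste(low, collapse = ", "))
  df <- train[, fn]
  df$.class <- factor(train$class_label, levels = present)
  fit <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = num_trees, probability = TRUE,
    seed = seed, num.threads = 1,
    respect.unordered.factors = "order"
  )
  fit$call <- NULL                      # drop environment-bearing call
  structure(list(forest = fit, schema = fn, classes = present,
                 readout = readout, seed = as.integer(seed),
                 num_trees = num_trees,
                 schema_hash = sum(utf8ToInt(paste(fn, collapse = "|")))),
            class = "phenotype_classifier")
}

#' Save / load a trained classifier bundle
#'
#' The bundle is written as a single serialized file carrying the model,
#' feature schema and class order.
#'
#' @param model a `phenotype_classifier`
#' @param path file path
#' @return `load_classifier` returns the model; `save_classifier` returns
#'   `path` invisibly
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "phenotype_classifier"))
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "phenotype_classifier")) {
    stop("file does not contain a phenotype classifier bundle")
  }
  model
}

#' Classify cells into phenotypes
#'
#' Applies a trained classifier to a per-cell feature table. The table must
#' carry exactly the training feature schema (names and order are checked;
#' a mismatch names the offending column). Class probabilities per cell sum
#' to 1; the predicted class is the argmax, with exact ties broken in favor
#' of the earliest class in the readout's canonical order.
#'
#' @param model a `phenotype_classifier`
#' @param cells data.frame containing the 30 feature columns
#' @return `cells` with `pred_class` and one `prob_<class>` column per class
#' @export
classify_cells <- function(model, cells) {
  stopifnot(inherits(model, "phenotype_classifier"))
  fn <- model$schema
  miss <- setdiff(fn, names(cells))
  if (length(miss)) {
    stop("feature schema mismatch; missing column: ", miss[1])
  }
  got <- intersect(names(cells), fn)
  if (!identical(got, fn)) {
    first_bad <- fn[which(got != fn)[1]]
    stop("feature schema mismatch; column out of order: ", first_bad)
  }
  if (!nrow(cells)) {
    cells$pred_class <- character(0)
    return(cells)
  }
  pr <- stats::predict(model$forest, data = cells[, fn],
                       num.threads = 1)$predictions
  pr <- pr[, model$classes, drop = FALSE]
  pr <- pr / rowSums(pr)
  # argmax with first-in-canonical-order tie break (max.col ties.method
  # "first" scans columns in the canonical order we imposed above)
  pred <- model$classes[max.col(pr, ties.method = "first")]
  out <- cells
  out$pred_class <- pred
  colnames(pr) <- paste0("prob_", colnames(pr))
  cbind(out, as.data.frame(pr))
}

#' Cross-validated evaluation of the phenotype classifier
#'
#' Stratified k-fold cross-validation: each class's examples are split
#' evenly over folds, a model is trained on each training split, and the
#' confusion matrix aggregates held-out predictions only. Per-class
#' one-vs-rest ROC areas are computed from the held-out class
#' probabilities; an ROC area above 0.9 is the conventional bar for an
#' excellent per-class ranking.
#'
#' @inheritParams train_classifier
#' @param k_folds number of folds (>= 2); every class must have at least
#'   `k_folds` members
#' @return object of class `classifier_evaluation`: list with `confusion`
#'   (true x predicted counts), `roc_auc` (named per-class), `accuracy`,
#'   `k_folds`, `n`
#' @export
evaluate_classifier <- function(train, readout = "rps2", k_folds = 5,
                                num_trees = 200, seed = 1L) {
  if (k_folds < 2) stop("k_folds must be at least 2")
  cls_present <- intersect(readout_classes(readout),
                           unique(train$class_label))
  tab <- table(train$class_label)
  low <- names(tab)[tab < k_folds]
  if (length(low)) stop("class(es) with fewer members than folds: ",
                        paste(low, collapse = ", "))
  set.seed(seed)
  fold <- integer(nrow(train))
  for (cl in cls_present) {
    idx <- which(train$class_label == cl)
    fold[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
  }
  truth <- factor(train$class_label, levels = cls_present)
  pred <- character(nrow(train))
  prob <- matrix(NA_real_, nrow(train), length(cls_present),
                 dimnames = list(NULL, cls_present))
  for (f in seq_len(k_folds)) {
    mdl <- train_classifier(train[fold != f, , drop = FALSE],
                            readout = readout, num_trees = num_trees,
                            min_per_class = 1, seed = seed + f)
    res <- classify_cells(mdl, train[fold == f, , drop = FALSE])
    pred[fold == f] <- res$pred_class
    for (cl in mdl$classes) prob[fold == f, cl] <- res[[paste0("prob_", cl)]]
  }
  confusion <- table(true = truth,
                     predicted = factor(pred, levels = cls_present))
  auc <- vapply(cls_present, function(cl) {
    y <- as.integer(truth == cl)
    if (length(unique(y)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(y, prob[, cl], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, numeric(1))
  structure(list(confusion = confusion, roc_auc = auc,
                 accuracy = mean(pred == as.character(truth)),
                 k_folds = k_folds, n = nrow(train)),
            class = "classifier_evaluation")
}

#' @export
print.classifier_evaluation <- function(x, ...) {
  cat("phenotype classifier evaluation (", x$k_folds, "-fold, n = ", x$n,
      ")\n", sep = "")
  cat("overall accuracy:", round(x$accuracy, 4), "\n")
  cat("per-class ROC area:\n")
  print(round(x$roc_auc, 4))
  cat("confusion matrix (true x predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Write a classifier evaluation report
#'
#' JSON report (accuracy, per-class ROC areas, fold count) plus a
#' plain-text confusion matrix alongside it.
#'
#' @param eval a `classifier_evaluation`
#' @param path JSON output path; the confusion matrix goes to
#'   `<path>.confusion.txt`
#' @return `path`, invisibly
#' @export
write_evaluation_report <- function(eval, path) {
  stopifnot(inherits(eval, "classifier_evaluation"))
  jsonlite::write_json(list(accuracy = eval$accuracy,
                            roc_auc = as.list(eval$roc_auc),
                            k_folds = eval$k_folds, n = eval$n),
                       path, auto_unbox = TRUE, digits = NA)
  txt <- utils::capture.output(print(eval$confusion))
  writeLines(txt, paste0(path, ".confusion.txt"))
  invisible(path)
}
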