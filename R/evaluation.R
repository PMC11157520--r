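# Confusion-matrix metrics, ROC/AUC, and subject-level k-fold
# cross-validation. The positive class is MCI (label 1); prediction is the
# argmax of the class scores and ROC uses the class-1 softmax score.
# Metrics with a zero denominator are reported as NaN with a warning (a
# silent zero would corrupt fold averages); evaluation is per scan while
# splitting and fold assignment are per subject.

#' Confusion counts
#'
#' @param labels true labels in `{0, 1}` (1 = MCI, the positive class).
#' @param predictions predicted labels in `{0, 1}`.
#' @return List with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions) || length(labels) == 0)
    abort_mcigate("labels and predictions must be nonempty and equal length",
                  "mcigate_validation_error")
  list(TP = sum(labels == 1 & predictions == 1),
       TN = sum(labels == 0 & predictions == 0),
       FP = sum(labels == 0 & predictions == 1),
       FN = sum(labels == 1 & predictions == 0))
}

div_or_nan <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s undefined (zero denominator); reporting NaN", what),
            call. = FALSE)
    return(NaN)
  }
  num / den
}

#' Sensitivity, specificity, accuracy, and F1 from confusion counts
#'
#' `SEN = TP/(TP+FN)`, `SPE = TN/(TN+FP)`, `ACC = (TP+TN)/total`, and F1
#' the harmonic mean of precision and sensitivity. Undefined ratios are
#' reported as `NaN`, never silently zero.
#'
#' @param counts output of [confusion()] (or any list with TP/TN/FP/FN).
#' @return List with `SEN`, `SPE`, `ACC`, `F1`, and `counts`.
#' @export
metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  total <- tp + tn + fp + fn
  if (total == 0)
    abort_mcigate("no evaluated scans", "mcigate_validation_error")
  sen <- div_or_nan(tp, tp + fn, "sensitivity")
  spe <- div_or_nan(tn, tn + fp, "specificity")
  acc <- (tp + tn) / total
  pre <- div_or_nan(tp, tp + fp, "precision")
  f1 <- if (is.nan(pre) || is.nan(sen)) NaN
        else div_or_nan(2 * pre * sen, pre + sen, "F1")
  list(SEN = sen, SPE = spe, ACC = acc, F1 = f1, counts = counts)
}

#' ROC curve and AUC
#'
#' Sweeps thresholds over the distinct scores (higher score = more
#' MCI-like); the curve runs from (0,0) to (1,1) and the AUC is the
#' trapezoidal area, equivalent to the rank (pair-counting) formulation
#' with ties counted half.
#'
#' @param scores class-1 scores, one per scan.
#' @param labels true labels in `{0, 1}`; both classes must be present.
#' @return List with `curve` (data.frame of `fpr`, `tpr`, ordered) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels))
    abort_mcigate("scores and labels must have equal length",
                  "mcigate_validation_error")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    abort_mcigate("both classes must be present for ROC",
                  "mcigate_validation_error")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group ties: cumulative counts at each distinct threshold
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / npos)
  fpr <- c(0, fp[last] / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate a model on a cohort
#'
#' Runs the model on every scan, applies the argmax prediction rule, and
#' reports confusion counts, SEN/SPE/ACC/F1, AUC, and the ROC curve.
#'
#' @param model an `mcigate_model`.
#' @param cohort an `mci_cohort`.
#' @return List with `metrics` (including `AUC`), `roc`, `predictions`,
#'   `scores` (class-1 probabilities), and per-scan ids.
#' @export
evaluate_cohort <- function(model, cohort) {
  data <- load_cohort_arrays(cohort)
  ev <- eval_on(model, data)
  pred <- as.integer(max.col(ev$scores) - 1L)
  rep_ <- metrics(confusion(data$labels, pred))
  roc <- roc_auc(ev$prob1, data$labels)
  rep_$AUC <- roc$auc
  list(metrics = rep_, roc = roc, predictions = pred, scores = ev$prob1,
       labels = data$labels, scan_id = data$scan_id,
       subject_id = data$subject_id, loss = ev$loss)
}

#' Class-stratified subject folds
#'
#' Partitions the subjects of each class into `k` folds of near-equal
#' size, deterministically given `seed`. Every subject lands in exactly
#' one fold.
#'
#' @param cohort an `mci_cohort` with at least `k` subjects per class.
#' @param k number of folds.
#' @param seed integer seed.
#' @return List of `k` character vectors of held-out subject ids.
#' @export
make_folds <- function(cohort, k = 4L, seed = 0L) {
  subj <- cohort_subjects(cohort)
  folds <- vector("list", k)
  for (lab in c(0L, 1L)) {
    ids <- sort(subj$subject_id[subj$label == lab])
    if (length(ids) < k)
      abort_mcigate(sprintf("class %d has %d subjects, fewer than k = %d",
                            lab, length(ids), k), "mcigate_config_error")
    ids <- with_seed(derive_seed(seed, "folds", lab), sample(ids))
    assign_ <- rep_len(seq_len(k), length(ids))
    for (f in seq_len(k))
      folds[[f]] <- c(folds[[f]], ids[assign_ == f])
  }
  folds
}

#' Subject-level k-fold cross-validation
#'
#' Partitions subjects into `k` class-stratified folds, holds each fold
#' out once, trains a fresh model on the remainder, and reports per-fold
#' metrics plus their across-fold mean and standard deviation.
#'
#' @param cohort an `mci_cohort`.
#' @param k number of folds (default 4, each holding out 25% of subjects).
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param seed integer seed for fold assignment and per-fold training.
#' @param verbose print per-epoch progress.
#' @return List with `per_fold` (data.frame of SEN/SPE/ACC/F1/AUC per
#'   fold), `summary` (mean and sd per metric), and `folds`.
#' @export
cross_validate <- function(cohort, k = 4L, model_cfg = model_config(),
                           train_cfg = train_config(), seed = 0L,
                           verbose = FALSE) {
  folds <- make_folds(cohort, k, seed)
  rows <- list()
  for (f in seq_len(k)) {
    test_ids <- folds[[f]]
    train_c <- subset_cohort(cohort, setdiff(cohort$records$subject_id,
                                             test_ids))
    test_c <- subset_cohort(cohort, test_ids)
    cfg_f <- train_cfg
    cfg_f$seed <- derive_seed(seed, "fold", f)
    model <- build_model(model_cfg, seed = cfg_f$seed)
    fit <- train(model, train_c, cfg_f, verbose = verbose)
    ev <- evaluate_cohort(fit$model, test_c)
    m <- ev$metrics
    rows[[f]] <- data.frame(fold = f, SEN = m$SEN, SPE = m$SPE, ACC = m$ACC,
                            F1 = m$F1, AUC = m$AUC)
  }
  per_fold <- do.call(rbind, rows)
  cols <- c("SEN", "SPE", "ACC", "F1", "AUC")
  summary <- data.frame(
    metric = cols,
    mean = vapply(cols, function(cn) mean(per_fold[[cn]]), numeric(1)),
    sd = vapply(cols, function(cn) stats::sd(per_fold[[cn]]), numeric(1)))
  list(per_fold = per_fold, summary = summary, folds = folds)
}
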