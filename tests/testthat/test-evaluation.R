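test_that("confusion counts match a four-way tally", {
  expect_equal(confusion(c(1, 1, 0, 0), c(1, 1, 0, 0)),
               list(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  expect_equal(confusion(c(1, 0), c(0, 1)),
               list(TP = 0L, TN = 0L, FP = 1L, FN = 1L))
  set.seed(21)
  labels <- sample(0:1, 200, replace = TRUE)
  preds <- sample(0:1, 200, replace = TRUE)
  cc <- confusion(labels, preds)
  tally <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (i in 1:200) {
    key <- if (labels[i] == 1 && preds[i] == 1) "TP"
           else if (labels[i] == 0 && preds[i] == 0) "TN"
           else if (labels[i] == 0) "FP" else "FN"
    tally[key] <- tally[key] + 1
  }
  expect_equal(unlist(cc), tally[names(cc)], ignore_attr = TRUE)
  expect_error(confusion(c(1, 0), c(1)), class = "mcigate_validation_error")
})

test_that("120 correct of 147 scans gives 81.63% accuracy", {
  rep_ <- metrics(list(TP = 55, TN = 65, FP = 9, FN = 18))
  expect_equal(rep_$ACC, 120 / 147)
  expect_lt(abs(rep_$ACC * 100 - 81.63), 0.01)
})

test_that("metric formulas agree with direct evaluation on random counts", {
  expect_equal(metrics(list(TP = 7, TN = 9, FP = 0, FN = 0)),
               list(SEN = 1, SPE = 1, ACC = 1, F1 = 1,
                    counts = list(TP = 7, TN = 9, FP = 0, FN = 0)))
  set.seed(8)
  for (i in 1:50) {
    cc <- as.list(rpois(4, 20) + 1)
    names(cc) <- c("TP", "TN", "FP", "FN")
    rep_ <- metrics(cc)
    expect_equal(rep_$SEN, cc$TP / (cc$TP + cc$FN))
    expect_equal(rep_$SPE, cc$TN / (cc$TN + cc$FP))
    expect_equal(rep_$ACC, (cc$TP + cc$TN) / Reduce(`+`, cc))
    pre <- cc$TP / (cc$TP + cc$FP)
    expect_equal(rep_$F1, 2 / (1 / pre + 1 / rep_$SEN))   # harmonic mean
  }
})

test_that("zero-denominator metrics are NaN with a warning, never zero", {
  w <- capture_warnings(rep_ <- metrics(list(TP = 0, TN = 5, FP = 0, FN = 0)))
  expect_true(any(grepl("sensitivity", w)))
  expect_true(is.nan(rep_$SEN))
  expect_equal(rep_$SPE, 1)
  expect_equal(rep_$ACC, 1)
})

test_that("ROC endpoints, monotonicity, and reference AUCs", {
  r <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  r2 <- roc_auc(rep(0.5, 10), c(rep(1, 5), rep(0, 5)))
  expect_equal(r2$auc, 0.5)
  set.seed(13)
  for (i in 1:5) {
    scores <- round(runif(30), 1)       # ties likely
    labels <- sample(0:1, 30, replace = TRUE)
    if (length(unique(labels)) < 2) next
    r3 <- roc_auc(scores, labels)
    expect_equal(r3$auc, pair_count_auc(scores, labels), tolerance = 1e-9)
    expect_equal(r3$curve$fpr[1], 0)
    expect_equal(r3$curve$tpr[1], 0)
    expect_equal(utils::tail(r3$curve$fpr, 1), 1)
    expect_equal(utils::tail(r3$curve$tpr, 1), 1)
    expect_true(all(diff(r3$curve$fpr) >= 0))
    expect_true(all(diff(r3$curve$tpr) >= 0))
  }
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)),
               class = "mcigate_validation_error")
})

test_that("trapezoidal AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  scores <- runif(40)
  labels <- sample(0:1, 40, replace = TRUE, prob = c(0.4, 0.6))
  ours <- roc_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("fold assignment partitions subjects and stratifies classes", {
  cohort <- fake_cohort(8, scans = 2)
  folds <- make_folds(cohort, k = 4, seed = 0)
  held <- sort(unlist(folds))
  expect_identical(held, sort(unique(cohort$records$subject_id)))
  for (f in folds) {
    labs <- cohort$records$label[match(f, cohort$records$subject_id)]
    expect_equal(sum(labs == 0), 2)
    expect_equal(sum(labs == 1), 2)
  }
  expect_identical(make_folds(cohort, k = 4, seed = 0), folds)
  expect_error(make_folds(fake_cohort(2), k = 4),
               class = "mcigate_config_error")
})

test_that("cross-validation reports per-fold and aggregate metrics", {
  spec <- tiny_spec(n_subjects_per_class = 4L)
  cohort <- generate_cohort(spec, tempfile("cv_"))
  mcfg <- model_config("baseline", input_grid = tiny_grid,
                       base_channels = 2L)
  tcfg <- train_config(batch_size = 4L, epochs = 2L, val_fraction = 0)
  cv <- cross_validate(cohort, k = 2L, mcfg, tcfg, seed = 0)
  expect_equal(nrow(cv$per_fold), 2)
  expect_true(all(cv$per_fold$ACC >= 0 & cv$per_fold$ACC <= 1))
  expect_equal(cv$summary$mean[cv$summary$metric == "ACC"],
               mean(cv$per_fold$ACC))
  expect_identical(sort(unlist(cv$folds)),
                   sort(unique(cohort$records$subject_id)))
})
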