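test_that("learning-rate schedule follows the stepped decay", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, cfg), 0.001)
  expect_equal(lr_schedule(9, cfg), 0.001)
  expect_equal(lr_schedule(10, cfg), 0.0001)
  expect_equal(lr_schedule(25, cfg), 0.00001)
  expect_equal(lr_schedule(49, cfg), 0.001 * 0.1^4)
  flat <- train_config(lr_decay_factor = 1)
  expect_equal(vapply(0:49, lr_schedule, numeric(1), cfg = flat),
               rep(0.001, 50))
  expect_error(lr_schedule(-1, cfg), class = "mcigate_validation_error")
})

test_that("a two-volume set is memorized: accuracy 1, loss under 0.1", {
  spec <- tiny_spec(n_subjects_per_class = 1L, noise_sd = 0.02)
  cohort <- generate_cohort(spec, tempfile("mem_"))
  expect_equal(nrow(cohort$records), 2)
  mcfg <- model_config("baseline", input_grid = tiny_grid,
                       base_channels = 2L)
  model <- build_model(mcfg, seed = 0)
  cfg <- train_config(batch_size = 2L, epochs = 30L, val_fraction = 0,
                      lr_decay_factor = 1, seed = 0)
  fit <- train(model, cohort, cfg)
  last <- fit$history[nrow(fit$history), ]
  expect_equal(last$train_acc, 1)
  expect_lt(last$train_loss, 0.1)
})

test_that("training is deterministic given the seed", {
  r1 <- tiny_training_run(variant = "ag", epochs = 2L, seed = 3L,
                          val_fraction = 0.25)
  r2 <- tiny_training_run(variant = "ag", epochs = 2L, seed = 3L,
                          val_fraction = 0.25)
  expect_identical(r1$fit$history, r2$fit$history)
  r3 <- tiny_training_run(variant = "ag", epochs = 2L, seed = 4L,
                          val_fraction = 0.25)
  expect_false(identical(r1$fit$history$train_loss,
                         r3$fit$history$train_loss))
})

test_that("history carries the schedule exactly and validation stays disjoint", {
  run <- tiny_training_run(epochs = 3L, n_per_class = 5L,
                           val_fraction = 0.25)
  h <- run$fit$history
  expect_equal(nrow(h), 3)
  expect_equal(h$lr, vapply(0:2, lr_schedule, numeric(1), cfg = run$tcfg))
  expect_true(all(is.finite(h$train_loss)))
  expect_length(intersect(run$fit$val_subjects,
                          setdiff(run$cohort$records$subject_id,
                                  run$fit$val_subjects)), 0)
  expect_gt(length(run$fit$val_subjects), 0)
  expect_true(all(c("val_loss", "val_acc") %in% names(h)))
})

test_that("single-class training cohorts are refused", {
  spec <- tiny_spec(n_subjects_per_class = 2L)
  cohort <- generate_cohort(spec, tempfile("one_"))
  onec <- mcigate:::subset_cohort(cohort, c("nc001", "nc002"))
  model <- build_model(model_config("baseline", input_grid = tiny_grid,
                                    base_channels = 2L))
  expect_error(train(model, onec, train_config(epochs = 1, val_fraction = 0)),
               class = "mcigate_config_error")
})

test_that("checkpoints round-trip through disk", {
  run <- tiny_training_run(epochs = 1L)
  dir <- tempfile("ckpt_")
  save_checkpoint(run$fit$model, dir)
  back <- load_checkpoint(dir)
  set.seed(1)
  x <- array(runif(prod(tiny_grid)), c(tiny_grid, 1, 1))
  expect_identical(predict_scores(back, x)$scores,
                   predict_scores(run$fit$model, x)$scores)
  expect_equal(back$config$variant, "ag_aspp")
})
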