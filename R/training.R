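# Training regime: two-class cross-entropy minimized with Adam (default)
# at base learning rate 1e-3, decayed by a factor of 0.1 every 10 epochs,
# batch size 8, for 50 epochs. A subject-level validation fraction is
# carved from the training cohort; the checkpoint with the best validation
# accuracy is kept. Every stochastic component (shuffling, init) draws from
# substreams of the configured seed.

#' Training configuration
#'
#' @param batch_size samples per gradient step.
#' @param optimizer one of `"adam"`, `"sgd"`, `"momentum"`, `"rmsprop"`.
#' @param base_lr initial learning rate.
#' @param lr_decay_factor multiplicative decay, in (0, 1].
#' @param lr_decay_every epochs between decays.
#' @param epochs total training epochs.
#' @param val_fraction subject fraction held out for validation (0 disables
#'   validation; best-checkpoint selection then uses training accuracy).
#' @param seed integer seed.
#' @export
train_config <- function(batch_size = 8L,
                         optimizer = c("adam", "sgd", "momentum", "rmsprop"),
                         base_lr = 0.001, lr_decay_factor = 0.1,
                         lr_decay_every = 10L, epochs = 50L,
                         val_fraction = 0.2, seed = 0L) {
  optimizer <- match.arg(optimizer)
  if (batch_size < 1 || epochs < 1)
    abort_mcigate("batch_size and epochs must be >= 1", "mcigate_config_error")
  if (lr_decay_factor <= 0 || lr_decay_factor > 1)
    abort_mcigate("lr_decay_factor must be in (0, 1]", "mcigate_config_error")
  structure(list(batch_size = as.integer(batch_size), optimizer = optimizer,
                 base_lr = base_lr, lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 epochs = as.integer(epochs), val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "mcigate_train_config")
}

#' Stepped learning-rate schedule
#'
#' `base_lr * lr_decay_factor ^ floor(epoch / lr_decay_every)`, with epochs
#' counted from 0.
#'
#' @param epoch epoch index, `>= 0`.
#' @param cfg a [train_config()].
#' @return The learning rate for that epoch.
#' @examples
#' lr_schedule(0, train_config())   # 0.001
#' lr_schedule(10, train_config())  # 0.0001
#' @export
lr_schedule <- function(epoch, cfg = train_config()) {
  if (any(epoch < 0))
    abort_mcigate("epoch must be >= 0", "mcigate_validation_error")
  cfg$base_lr * cfg$lr_decay_factor ^ floor(epoch / cfg$lr_decay_every)
}

# --- optimizers -------------------------------------------------------------

make_optimizer <- function(kind, params) {
  st <- new.env(parent = emptyenv())
  st$kind <- kind
  st$t <- 0
  st$m <- lapply(params, function(p) array(0, dim = dim_or_len(p$val)))
  st$v <- lapply(params, function(p) array(0, dim = dim_or_len(p$val)))
  st
}

optimizer_step <- function(st, params, lr) {
  st$t <- st$t + 1
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; mom <- 0.9
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    if (any(!is.finite(g)))
      abort_mcigate(paste0("non-finite gradient in parameter ",
                           p$name %||% i), "mcigate_numeric_error")
    switch(st$kind,
      sgd = {
        p$val <- p$val - lr * g
      },
      momentum = {
        st$m[[i]] <- mom * st$m[[i]] + g
        p$val <- p$val - lr * st$m[[i]]
      },
      rmsprop = {
        st$v[[i]] <- 0.99 * st$v[[i]] + 0.01 * g^2
        p$val <- p$val - lr * g / (sqrt(st$v[[i]]) + eps)
      },
      adam = {
        st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
        st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * g^2
        mhat <- st$m[[i]] / (1 - b1^st$t)
        vhat <- st$v[[i]] / (1 - b2^st$t)
        p$val <- p$val - lr * mhat / (sqrt(vhat) + eps)
      })
  }
  invisible(st)
}

# Re-estimate batch-norm running statistics as the average batch statistics
# over the supplied data ("precise BN"). With batches this small the
# exponentially averaged statistics tracked during optimization are noisy
# and can leave evaluation-mode normalization far from any state the
# weights were trained under; averaging over a full pass fixes that.
bn_recalibrate <- function(model, data, batch_size = 8L) {
  n <- length(data$labels)
  starts <- seq(1, n, by = batch_size)
  for (st in model$bn) {
    st$running_mean[] <- 0
    st$running_var[] <- 0
  }
  k <- 0
  for (start in starts) {
    idx <- start:min(n, start + batch_size - 1L)
    k <- k + 1
    model$bn_momentum <- 1 / k          # incremental arithmetic average
    model_forward(model, batch_of(data, idx)$x, training = TRUE)
  }
  model$bn_momentum <- NULL
  invisible(model)
}

# --- data assembly ----------------------------------------------------------

# Load every scan of a cohort into memory as a (D,H,W,1,N) array + labels.
load_cohort_arrays <- function(cohort) {
  r <- cohort$records
  g <- cohort$grid_shape
  x <- array(0, dim = c(g, 1L, nrow(r)))
  for (k in seq_len(nrow(r))) {
    v <- read_volume(r$path[k], r[k, ], g)
    x[, , , 1L, k] <- v$voxels
  }
  list(x = x, labels = r$label, subject_id = r$subject_id,
       scan_id = r$scan_id)
}

batch_of <- function(data, idx) {
  xb <- data$x[, , , , idx, drop = FALSE]
  list(x = xb, labels = data$labels[idx])
}

eval_on <- function(model, data, batch_size = 8L) {
  n <- length(data$labels)
  loss_sum <- 0; correct <- 0
  scores <- matrix(0, n, model$config$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    b <- batch_of(data, idx)
    out <- model_forward(model, b$x, training = FALSE)
    s <- out$scores$val
    scores[idx, ] <- s
    p <- softmax_rows(s)
    picks <- cbind(seq_along(idx), b$labels + 1L)
    loss_sum <- loss_sum - sum(log(pmax(p[picks], 1e-12)))
    correct <- correct + sum(max.col(s) - 1L == b$labels)
  }
  list(loss = loss_sum / n, acc = correct / n, scores = scores,
       prob1 = softmax_rows(scores)[, 2])
}

#' Train a model on a cohort
#'
#' Carves a subject-level validation split from the training cohort,
#' minimizes two-class cross-entropy with the configured optimizer and the
#' stepped learning-rate schedule, and returns the weights that achieved
#' the best validation accuracy (ties resolved toward the earlier epoch).
#' Fully reproducible given `cfg$seed`.
#'
#' @param model an `mcigate_model` (trained in place and returned).
#' @param train_cohort an `mci_cohort` containing both classes.
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return List with `model` (best weights restored), `history` (one row
#'   per epoch: losses, accuracies, learning rate), `best_epoch`, and the
#'   validation cohort's subject ids.
#' @export
train <- function(model, train_cohort, cfg = train_config(), verbose = FALSE) {
  subj <- cohort_subjects(train_cohort)
  if (length(unique(subj$label)) < 2)
    abort_mcigate("training cohort must contain both classes",
                  "mcigate_config_error")
  if (cfg$val_fraction > 0) {
    sp <- subject_split(train_cohort, cfg$val_fraction,
                        seed = derive_seed(cfg$seed, "val"))
    fit_cohort <- sp$train; val_cohort <- sp$test
    stopifnot(length(intersect(fit_cohort$records$subject_id,
                               val_cohort$records$subject_id)) == 0)
  } else {
    fit_cohort <- train_cohort; val_cohort <- NULL
  }
  fit <- load_cohort_arrays(fit_cohort)
  val <- if (!is.null(val_cohort)) load_cohort_arrays(val_cohort)
  n <- length(fit$labels)
  opt <- make_optimizer(cfg$optimizer, model$params)

  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        train_loss = numeric(0), train_acc = numeric(0),
                        val_loss = numeric(0), val_acc = numeric(0))
  best <- list(metric = -Inf, epoch = NA_integer_, params = NULL, bn = NULL)

  for (epoch in seq_len(cfg$epochs) - 1L) {
    lr <- lr_schedule(epoch, cfg)
    ord <- with_seed(derive_seed(cfg$seed, "shuffle", epoch), sample.int(n))
    loss_sum <- 0; correct <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(n, start + cfg$batch_size - 1L)]
      b <- batch_of(fit, idx)
      out <- model_forward(model, b$x, training = TRUE)
      loss <- op_cross_entropy(out$scores, b$labels)
      if (!is.finite(loss$val))
        abort_mcigate(sprintf("non-finite training loss at epoch %d", epoch),
                      "mcigate_numeric_error")
      ag_backward(loss, 1)
      optimizer_step(opt, model$params, lr)
      loss_sum <- loss_sum + loss$val * length(idx)
      correct <- correct + sum(max.col(out$scores$val) - 1L == b$labels)
    }
    train_loss <- loss_sum / n
    train_acc <- correct / n
    bn_recalibrate(model, fit, cfg$batch_size)
    if (!is.null(val)) {
      ev <- eval_on(model, val, cfg$batch_size)
      val_loss <- ev$loss; val_acc <- ev$acc
      metric <- val_acc
    } else {
      val_loss <- NA_real_; val_acc <- NA_real_
      metric <- train_acc
    }
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, train_loss = train_loss, train_acc = train_acc,
      val_loss = val_loss, val_acc = val_acc))
    if (metric > best$metric) {
      best$metric <- metric
      best$epoch <- epoch
      best$params <- lapply(model$params, function(p) p$val)
      best$bn <- lapply(model$bn, function(st)
        list(running_mean = st$running_mean, running_var = st$running_var))
    }
    if (verbose)
      message(sprintf(
        "epoch %2d lr %.2e train loss %.4f acc %.3f val loss %s acc %s",
        epoch, lr, train_loss, train_acc,
        formatC(val_loss, digits = 4, format = "f"),
        formatC(val_acc, digits = 3, format = "f")))
  }
  for (nm in names(best$params)) model$params[[nm]]$val <- best$params[[nm]]
  for (nm in names(best$bn)) {
    model$bn[[nm]]$running_mean <- best$bn[[nm]]$running_mean
    model$bn[[nm]]$running_var <- best$bn[[nm]]$running_var
  }
  list(model = model, history = history, best_epoch = best$epoch,
       val_subjects = if (!is.null(val_cohort))
       unique(val_cohort$records$subject_id) else character(0))
}
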