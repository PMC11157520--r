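# Shared fixtures: tiny phantom specs, in-memory cohorts, and independent
# oracles used across test files.

tiny_grid <- c(16L, 20L, 16L)

tiny_spec <- function(...) {
  args <- list(...)
  defaults <- list(grid_shape = tiny_grid, n_subjects_per_class = 4L,
                   scans_per_subject = 1L, atrophy_factor = 0.6,
                   noise_sd = 0.05, subject_effect_sd = 0.1, seed = 0L)
  defaults[names(args)] <- args
  do.call(phantom_spec, defaults)
}

# A records-only cohort (no files on disk); enough for split/fold logic.
fake_cohort <- function(n_per_class, scans = 1L, grid = tiny_grid) {
  rows <- list()
  for (lab in 0:1)
    for (i in seq_len(n_per_class))
      for (t in seq_len(scans)) {
        sid <- sprintf("%s%03d", c("nc", "mci")[lab + 1], i)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, scan_id = sprintf("%s_t%02d", sid, t),
          label = lab, path = sprintf("%s_t%02d.nii.gz", sid, t))
      }
  new_cohort(do.call(rbind, rows), grid)
}

# Brute-force dilated convolution per the spaced-tap definition; the oracle
# the compiled path is checked against.
brute_dilated_conv <- function(x, w, r) {
  d <- dim(x); k <- dim(w)
  eff <- k + (k - 1) * (r - 1)
  pad <- (eff - 1) %/% 2
  y <- array(0, d)
  for (m in 1:d[1]) for (n in 1:d[2]) for (q in 1:d[3]) {
    s <- 0
    for (i in 1:k[1]) for (j in 1:k[2]) for (l in 1:k[3]) {
      di <- m + r * (i - 1) - pad[1]
      hj <- n + r * (j - 1) - pad[2]
      wl <- q + r * (l - 1) - pad[3]
      if (di >= 1 && di <= d[1] && hj >= 1 && hj <= d[2] &&
          wl >= 1 && wl <= d[3])
        s <- s + x[di, hj, wl] * w[i, j, l]
    }
    y[m, n, q] <- s
  }
  y
}

# All-pairs AUC estimator: P(score+ > score-) + 0.5 P(tie).
pair_count_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Small training run used by several files: tiny grid, narrow model.
tiny_training_run <- function(variant = "ag_aspp", epochs = 2L, seed = 0L,
                              n_per_class = 4L, base_channels = 2L,
                              val_fraction = 0) {
  spec <- tiny_spec(n_subjects_per_class = n_per_class, seed = seed)
  dir <- file.path(tempfile("tinycoh_"))
  cohort <- generate_cohort(spec, dir)
  mcfg <- model_config(variant, input_grid = tiny_grid,
                       base_channels = base_channels)
  tcfg <- train_config(batch_size = 4L, epochs = epochs, seed = seed,
                       val_fraction = val_fraction)
  model <- build_model(mcfg, seed = seed)
  fit <- train(model, cohort, tcfg)
  list(fit = fit, cohort = cohort, spec = spec, mcfg = mcfg, tcfg = tcfg)
}
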