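test_that("effective kernel size follows k + (k-1)(d-1)", {
  expect_equal(effective_kernel_size(3, 2), 5)
  expect_equal(effective_kernel_size(3, 3), 7)
  for (k in c(1L, 3L, 5L, 7L, 9L))
    expect_equal(effective_kernel_size(k, 1), k)
  # strictly increasing in d for k > 1
  for (k in c(3L, 5L)) {
    sizes <- vapply(1:5, function(d) effective_kernel_size(k, d), integer(1))
    expect_true(all(diff(sizes) > 0))
  }
  expect_equal(diff(vapply(1:5, function(d) effective_kernel_size(1L, d),
                           integer(1))), rep(0L, 4))
  expect_error(effective_kernel_size(4, 2), class = "mcigate_validation_error")
  expect_error(effective_kernel_size(3, 0), class = "mcigate_validation_error")
})

test_that("dilated convolution matches the brute-force spaced-tap oracle", {
  set.seed(11)
  for (r in 1:3) for (shape in list(c(7L, 7L, 7L), c(9L, 8L, 7L),
                                    c(9L, 9L, 9L))) {
    x <- array(rnorm(prod(shape)), shape)
    w <- array(rnorm(27), c(3, 3, 3))
    expect_lt(max(abs(dilated_conv(x, w, r) - brute_dilated_conv(x, w, r))),
              1e-5)
  }
  # rate 1 is ordinary convolution
  x <- array(rnorm(7 * 7 * 7), c(7, 7, 7))
  w <- array(rnorm(27), c(3, 3, 3))
  expect_equal(dilated_conv(x, w, 1), brute_dilated_conv(x, w, 1),
               tolerance = 1e-12)
})

test_that("ones-input interior value counts in-bounds taps at rate 2", {
  x <- array(1, c(7, 7, 7))
  w <- array(1, c(3, 3, 3))
  y <- dilated_conv(x, w, 2)
  expect_equal(y[4, 4, 4], 27)            # fully interior: all taps in bounds
  expect_equal(y, brute_dilated_conv(x, w, 2))
})

test_that("impulse response places kernel taps at the dilation spacing", {
  x <- array(0, c(13, 13, 13))
  x[7, 7, 7] <- 1
  set.seed(3)
  w <- array(rnorm(27), c(3, 3, 3))
  y <- dilated_conv(x, w, 3)
  expected <- array(0, c(13, 13, 13))
  for (i in 1:3) for (j in 1:3) for (l in 1:3)
    expected[7 - 3 * (i - 2), 7 - 3 * (j - 2), 7 - 3 * (l - 2)] <- w[i, j, l]
  expect_equal(y, expected, tolerance = 1e-12)
})

test_that("dilated convolution rejects kernels exceeding the input", {
  x <- array(1, c(5, 5, 5))
  w <- array(1, c(3, 3, 3))
  expect_error(dilated_conv(x, w, 3), class = "mcigate_validation_error")
  expect_error(dilated_conv(x, w, 0), class = "mcigate_validation_error")
})

test_that("softmax attention coefficients sum to 1 per sample", {
  for (seed in 1:10) {
    p <- attention_gate_params(F_l = 3, F_g = 4, F_int = 2, seed = seed)
    set.seed(seed)
    x_l <- array(rnorm(8 * 10 * 8 * 3 * 2), c(8, 10, 8, 3, 2))
    g <- array(rnorm(2 * 3 * 2 * 4 * 2), c(2, 3, 2, 4, 2))
    out <- attention_gate(x_l, g, p)
    expect_true(all(out$alpha >= 0))
    sums <- apply(out$alpha, 5, sum)
    expect_equal(sums, c(1, 1), tolerance = 1e-6)
    expect_identical(dim(out$gated), dim(x_l))
  }
})

test_that("attention gate matches scalar evaluation on a 4-position toy", {
  # 1 channel, grid (1,2,2), unit weights, zero biases, ReLU + softmax
  p <- attention_gate_params(1, 1, 1, seed = 0)
  p$W_x[] <- 1; p$W_g[] <- 1; p$psi[] <- 1
  x <- array(c(0.3, -0.2, 0.5, 0.1), c(1, 2, 2, 1, 1))
  g <- array(c(0.4, 0.1, -0.6, 0.2), c(1, 2, 2, 1, 1))
  out <- attention_gate(x, g, p)
  q <- pmax(as.vector(x) + as.vector(g), 0)       # psi' relu(x + g), all maps 1
  alpha <- exp(q) / sum(exp(q))
  expect_equal(as.vector(out$alpha), alpha, tolerance = 1e-12)
  expect_equal(as.vector(out$gated), as.vector(x) * alpha, tolerance = 1e-12)
})

test_that("near-zero attention coefficients null the gated features", {
  p <- attention_gate_params(2, 2, 2, sigma2 = "sigmoid", seed = 1)
  p$psi[] <- 0
  p$b_psi <- -50                       # sigmoid(-50) ~ 0 everywhere
  set.seed(4)
  x_l <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2, 1))
  g <- array(rnorm(2 * 2 * 2 * 2), c(2, 2, 2, 2, 1))
  out <- attention_gate(x_l, g, p)
  expect_lt(max(abs(out$gated)), 1e-15)
})

test_that("attention gate validates channel counts", {
  p <- attention_gate_params(3, 4, 2)
  x_l <- array(0, c(4, 4, 4, 2, 1))    # 2 channels, params expect 3
  g <- array(0, c(2, 2, 2, 4, 1))
  expect_error(attention_gate(x_l, g, p), class = "mcigate_validation_error")
})

test_that("ASPP preserves spatial dims and stacks branch channels", {
  set.seed(5)
  x <- array(rnorm(6 * 8 * 6 * 3), c(6, 8, 6, 3, 1))
  for (rates in list(1L, c(1L, 2L), c(1L, 2L, 3L), c(2L, 3L))) {
    p <- aspp_params(3, rates = rates, out_channels = 5, seed = 1)
    y <- aspp(x, p)
    expect_identical(dim(y)[1:3], dim(x)[1:3])
    expect_equal(dim(y)[4], 5L)
    # pre-projection concatenation: (n_rates + 1) x input channels
    expect_equal(dim(p$proj$w)[4], (length(rates) + 1L) * 3L)
  }
  expect_error(aspp_params(3, rates = integer(0)),
               class = "mcigate_validation_error")
})

test_that("single-rate ASPP with pass-through projection equals plain convolution", {
  p <- aspp_params(1, rates = 1L, out_channels = 1, seed = 2)
  p$point$w[] <- 0                     # silence the 1x1x1 branch
  p$proj$w[] <- 0
  p$proj$w[1, 1, 1, 1, 1] <- 1         # select the dilated branch unchanged
  set.seed(6)
  x <- array(rnorm(7 * 7 * 7), c(7, 7, 7, 1, 1))
  y <- aspp(x, p)
  ref <- brute_dilated_conv(array(x, c(7, 7, 7)), array(p$branches[[1]]$w,
                                                        c(3, 3, 3)), 1)
  expect_equal(array(y, c(7, 7, 7)), ref, tolerance = 1e-10)
})

test_that("all variants produce (B, 2) scores and nest by parameter count", {
  x <- array(runif(32 * 40 * 32 * 2), c(32, 40, 32, 1, 2))
  counts <- numeric(3)
  for (i in seq_along(c("baseline", "ag", "ag_aspp"))) {
    variant <- c("baseline", "ag", "ag_aspp")[i]
    cfg <- model_config(variant, input_grid = c(32L, 40L, 32L),
                        base_channels = 8L)
    m <- build_model(cfg, seed = 1)
    s <- predict_scores(m, x)
    expect_identical(dim(s$scores), c(2L, 2L))
    expect_equal(rowSums(s$prob), c(1, 1), tolerance = 1e-12)
    counts[i] <- count_params(m)
  }
  expect_lt(counts[1], counts[2])
  expect_lt(counts[2], counts[3])
})

test_that("model construction and forward are deterministic given a seed", {
  cfg <- model_config("ag_aspp", input_grid = tiny_grid, base_channels = 2L)
  m1 <- build_model(cfg, seed = 5)
  m2 <- build_model(cfg, seed = 5)
  for (nm in names(m1$params))
    expect_identical(m1$params[[nm]]$val, m2$params[[nm]]$val)
  set.seed(9)
  x <- array(runif(prod(tiny_grid) * 2), c(tiny_grid, 1, 2))
  expect_identical(predict_scores(m1, x)$scores, predict_scores(m2, x)$scores)
  m3 <- build_model(cfg, seed = 6)
  expect_false(identical(m1$params[["stem.conv.w"]]$val,
                         m3$params[["stem.conv.w"]]$val))
})

test_that("truncated-normal init respects the two-sigma clip and zero biases", {
  cfg <- model_config("baseline", input_grid = tiny_grid, base_channels = 4L,
                      init_sd = 0.1)
  m <- build_model(cfg, seed = 2)
  w <- m$params[["stem.conv.w"]]$val
  expect_true(all(abs(w) <= 0.2 + 1e-12))
  expect_gt(stats::sd(w), 0.05)
  expect_equal(m$params[["fc.b"]]$val, c(0, 0))
})

test_that("too-small grids are rejected with the minimal admissible grid", {
  cfg <- model_config("baseline", input_grid = c(8L, 8L, 8L))
  expect_error(build_model(cfg), class = "mcigate_validation_error")
  expect_error(build_model(cfg), regexp = "16x16x16")
})

test_that("gradients flow to every parameter of every variant", {
  set.seed(12)
  x <- array(runif(prod(tiny_grid) * 4), c(tiny_grid, 1, 4))
  labels <- c(0L, 1L, 0L, 1L)
  for (variant in c("baseline", "ag", "ag_aspp")) {
    cfg <- model_config(variant, input_grid = tiny_grid, base_channels = 2L)
    m <- build_model(cfg, seed = 3)
    out <- mcigate:::model_forward(m, x, training = TRUE)
    loss <- mcigate:::op_cross_entropy(out$scores, labels)
    mcigate:::ag_backward(loss, 1)
    for (nm in names(m$params)) {
      g <- m$params[[nm]]$grad
      expect_false(is.null(g), info = paste(variant, nm))
      expect_true(all(is.finite(g)), info = paste(variant, nm))
      # spatial softmax is invariant to a constant shift of its input, so
      # the attention output bias b_psi receives an exactly-zero gradient
      if (!grepl("b_psi", nm))
        expect_gt(max(abs(g)), 0, label = paste(variant, nm, "max |grad|"))
    }
  }
})
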