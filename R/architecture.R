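# The network: 3D residual backbone with additive attention gates and
# parallel dilated convolution (atrous spatial pyramid pooling).
#
# Feature maps are column-major arrays (D, H, W, C, B); convolution kernels
# are (kd, kh, kw, Cin, Cout). The attention gate computes, per spatial
# position i of the gating grid,
#   q_i = psi' relu(Wx' x_i + Wg' g_i + b_xg) + b_psi,   alpha = sigma2(q),
# with sigma2 either a softmax over all spatial positions of a sample (the
# coefficients then sum to 1) or an elementwise sigmoid. Dilated convolution
# spaces the taps of a k-per-side kernel r voxels apart, so the effective
# side grows to k + (k-1)(r-1) without extra parameters.

#' Effective side length of a dilated convolution kernel
#'
#' A kernel with `k` taps per side and dilation rate `d` covers the same
#' extent as a dense kernel of side `k + (k - 1) * (d - 1)`.
#'
#' @param k odd kernel side length (taps per axis), `k >= 1`.
#' @param d integer dilation rate, `d >= 1`.
#' @return Integer effective side length.
#' @examples
#' effective_kernel_size(3, 2)  # 5
#' effective_kernel_size(3, 3)  # 7
#' @export
effective_kernel_size <- function(k, d) {
  if (length(k) != 1 || length(d) != 1 || is.na(k) || is.na(d) ||
      k < 1 || d < 1 || k != as.integer(k) || d != as.integer(d))
    abort_mcigate("k and d must be positive integers", "mcigate_validation_error")
  if (k %% 2 == 0)
    abort_mcigate("kernel side k must be odd", "mcigate_validation_error")
  as.integer(k + (k - 1) * (d - 1))
}

#' Dilated (atrous) 3D convolution
#'
#' Convolves a feature map with a kernel whose taps are spaced `r` voxels
#' apart, under zero "same" padding so spatial dimensions are preserved.
#' With rate 1 this is ordinary convolution.
#'
#' @param x a rank-3 array `(D, H, W)` treated as one single-channel sample,
#'   or a rank-5 array `(D, H, W, C, B)`.
#' @param w a rank-3 kernel (single channel) or rank-5 kernel
#'   `(kd, kh, kw, Cin, Cout)`; odd side lengths.
#' @param r integer dilation rate (at least 1).
#' @return Array of the same rank as `x` with unchanged spatial dimensions.
#' @export
dilated_conv <- function(x, w, r = 1L) {
  if (length(r) != 1 || r < 1 || r != as.integer(r))
    abort_mcigate("dilation rate r must be a positive integer",
                  "mcigate_validation_error")
  rank3 <- length(dim(x)) == 3L
  if (rank3) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(w)) == 3L) dim(w) <- c(dim(w), 1L, 1L)
  kd <- dim(w)[1:3]
  eff <- kd + (kd - 1L) * (as.integer(r) - 1L)
  if (any(dim(x)[1:3] < eff))
    abort_mcigate(sprintf(
      "effective kernel (%s) exceeds input extent (%s) under same padding",
      paste(eff, collapse = "x"), paste(dim(x)[1:3], collapse = "x")),
      "mcigate_validation_error")
  xn <- ag_leaf(x)
  wn <- ag_leaf(w)
  bn <- ag_leaf(numeric(dim(w)[5]))
  out <- op_conv3d(xn, wn, bn, dilation = rep(as.integer(r), 3))$val
  if (rank3) dim(out) <- dim(out)[1:3]
  out
}

# --- parameter containers ---------------------------------------------------

new_param <- function(val) ag_leaf(val)

conv_weight <- function(k, cin, cout, init_sd) {
  array(rtrunc_norm(k^3 * cin * cout, init_sd), dim = c(k, k, k, cin, cout))
}

#' Attention-gate parameters
#'
#' Creates the linear maps of the additive attention gate: `W_x`
#' (`F_l -> F_int`), `W_g` (`F_g -> F_int`), `psi` (`F_int -> 1`), all as
#' 1x1x1 convolutions, plus biases `b_xg` (length `F_int`) and scalar
#' `b_psi`. Weights are truncated-normal, biases zero.
#'
#' @param F_l channels of the local feature map.
#' @param F_g channels of the gating signal.
#' @param F_int intermediate channels, `>= 1`.
#' @param sigma2 `"softmax"` (spatial, coefficients sum to 1 per sample) or
#'   `"sigmoid"`.
#' @param init_sd standard deviation of the truncated-normal initializer.
#' @param seed integer seed for the weight draw.
#' @return An object of class `attention_gate_params`.
#' @export
attention_gate_params <- function(F_l, F_g, F_int, sigma2 = c("softmax", "sigmoid"),
                                  init_sd = 0.1, seed = 0L) {
  sigma2 <- match.arg(sigma2)
  if (F_int < 1)
    abort_mcigate("F_int must be >= 1", "mcigate_validation_error")
  p <- with_seed(seed, list(
    W_x = conv_weight(1L, F_l, F_int, init_sd),
    W_g = conv_weight(1L, F_g, F_int, init_sd),
    psi = conv_weight(1L, F_int, 1L, init_sd),
    b_xg = numeric(F_int),
    b_psi = 0,
    F_l = F_l, F_g = F_g, F_int = F_int, sigma2 = sigma2
  ))
  structure(p, class = "attention_gate_params")
}

# Node-level attention gate; x_l and g are ag nodes, params plain arrays.
# Returns nodes: gated (x_l grid), alpha (g grid), alpha_up (x_l grid).
ag_gate_nodes <- function(x_l, g, params) {
  dx <- dim(x_l$val); dg <- dim(g$val)
  if (dx[4] != params$F_l || dg[4] != params$F_g)
    abort_mcigate(sprintf(
      "attention gate channel mismatch: x_l has %d (expect %d), g has %d (expect %d)",
      dx[4], params$F_l, dg[4], params$F_g), "mcigate_validation_error")
  stride <- pmax(1L, as.integer(ceiling(dx[1:3] / dg[1:3])))
  Wx <- new_param(params$W_x); Wg <- new_param(params$W_g)
  psi <- new_param(params$psi)
  b0 <- new_param(numeric(params$F_int))
  bxg <- new_param(params$b_xg)
  bpsi <- new_param(params$b_psi)
  xp <- op_conv3d(x_l, Wx, b0, stride = stride, pad = c(0L, 0L, 0L))
  xp <- op_adaptive_avgpool(xp, dg[1:3])     # exact alignment to g's grid
  gp <- op_conv3d(g, Wg, new_param(numeric(params$F_int)))
  q <- op_bias_channel(op_add(xp, gp), bxg)
  q <- op_relu(q)
  q <- op_conv3d(q, psi, bpsi)               # 1 channel on g's grid
  alpha <- if (params$sigma2 == "softmax") op_softmax_spatial(q) else op_sigmoid(q)
  alpha_up <- op_resize_trilinear(alpha, dx[1:3])
  gated <- op_gate(x_l, alpha_up)
  list(gated = gated, alpha = alpha, alpha_up = alpha_up,
       params = list(W_x = Wx, W_g = Wg, psi = psi, b_xg = bxg, b_psi = bpsi))
}

#' Apply an attention gate to a local feature map
#'
#' Computes additive attention coefficients from a local feature map `x_l`
#' and a coarser gating signal `g`, then multiplicatively gates `x_l`.
#' `x_l` is projected onto `g`'s grid by a strided 1x1x1 convolution, the
#' coefficients are computed there, and are trilinearly resampled back to
#' `x_l`'s grid before gating.
#'
#' @param x_l rank-5 local feature map `(D, H, W, F_l, B)`.
#' @param g rank-5 gating signal with spatial dims `<=` those of `x_l`.
#' @param params an [attention_gate_params()] object.
#' @return List with `gated` (same shape as `x_l`), `alpha` (coefficients on
#'   `g`'s grid, pre-resampling), and `alpha_up` (coefficients on `x_l`'s
#'   grid).
#' @export
attention_gate <- function(x_l, g, params) {
  out <- ag_gate_nodes(ag_leaf(x_l), ag_leaf(g), params)
  list(gated = out$gated$val, alpha = out$alpha$val, alpha_up = out$alpha_up$val)
}

#' ASPP parameters
#'
#' One 3-tap-per-axis dilated branch per rate plus a 1x1x1 branch; branch
#' outputs are concatenated along channels and projected to `out_channels`
#' by a 1x1x1 convolution. All branches preserve channel count `cin`.
#'
#' @param cin input channels.
#' @param rates integer dilation rates (nonempty, all `>= 1`).
#' @param out_channels channels after the final projection.
#' @param init_sd truncated-normal init standard deviation.
#' @param seed seed for the weight draw.
#' @export
aspp_params <- function(cin, rates = c(1L, 2L, 3L), out_channels = cin,
                        init_sd = 0.1, seed = 0L) {
  if (length(rates) == 0 || any(rates < 1))
    abort_mcigate("rates must be a nonempty list of integers >= 1",
                  "mcigate_validation_error")
  with_seed(seed, {
    branches <- lapply(rates, function(r)
      list(w = conv_weight(3L, cin, cin, init_sd), b = numeric(cin), rate = r))
    point <- list(w = conv_weight(1L, cin, cin, init_sd), b = numeric(cin))
    proj <- list(w = conv_weight(1L, cin * (length(rates) + 1L), out_channels,
                                 init_sd),
                 b = numeric(out_channels))
    structure(list(branches = branches, point = point, proj = proj,
                   rates = as.integer(rates), cin = cin,
                   out_channels = out_channels),
              class = "aspp_params")
  })
}

aspp_nodes <- function(x, params) {
  outs <- lapply(params$branches, function(br)
    op_conv3d(x, new_param(br$w), new_param(br$b),
              dilation = rep(br$rate, 3)))
  outs[[length(outs) + 1L]] <-
    op_conv3d(x, new_param(params$point$w), new_param(params$point$b))
  cat_ <- op_concat_channels(outs)
  op_conv3d(cat_, new_param(params$proj$w), new_param(params$proj$b))
}

#' Atrous spatial pyramid pooling
#'
#' Applies parallel dilated-convolution branches at the configured rates,
#' channel-concatenates the branch outputs, and projects to
#' `out_channels`. Spatial dimensions are unchanged.
#'
#' @param x rank-5 feature map `(D, H, W, C, B)`.
#' @param params an [aspp_params()] object.
#' @return Rank-5 array with `out_channels` channels.
#' @export
aspp <- function(x, params) {
  if (dim(x)[4] != params$cin)
    abort_mcigate("aspp: channel mismatch", "mcigate_validation_error")
  aspp_nodes(ag_leaf(x), params)$val
}

# --- model ------------------------------------------------------------------

#' Model configuration
#'
#' @param variant `"baseline"` (plain residual classifier), `"ag"` (adds
#'   attention gates on stages 2-3 gated by the deepest feature map), or
#'   `"ag_aspp"` (additionally passes gated maps through ASPP before fusion
#'   with the gating signal).
#' @param input_grid integer triple `(D, H, W)` of the input volume.
#' @param base_channels stem width; stages use 1x, 2x, 4x, 8x this.
#' @param aspp_rates dilation rates of the ASPP branches.
#' @param sigma2 attention normalization, `"softmax"` or `"sigmoid"`.
#' @param init_sd truncated-normal initializer standard deviation.
#' @param n_classes number of output classes (2: NC vs MCI).
#' @export
model_config <- function(variant = c("ag_aspp", "ag", "baseline"),
                         input_grid = c(84L, 102L, 84L),
                         base_channels = 64L,
                         aspp_rates = c(1L, 2L, 3L),
                         sigma2 = c("softmax", "sigmoid"),
                         init_sd = 0.1,
                         n_classes = 2L) {
  variant <- match.arg(variant)
  sigma2 <- match.arg(sigma2)
  if (init_sd <= 0)
    abort_mcigate("init_sd must be > 0", "mcigate_validation_error")
  if (variant == "ag_aspp" && length(aspp_rates) == 0)
    abort_mcigate("variant ag_aspp requires nonempty aspp_rates",
                  "mcigate_validation_error")
  structure(list(variant = variant, input_grid = as.integer(input_grid),
                 base_channels = as.integer(base_channels),
                 aspp_rates = as.integer(aspp_rates), sigma2 = sigma2,
                 init_sd = init_sd, n_classes = as.integer(n_classes)),
            class = "mcigate_model_config")
}

mc_param <- function(model, name, val) {
  model$params[[name]] <- ag_leaf(val, name = name)
  model$params[[name]]
}

mc_bn <- function(model, name, c) {
  mc_param(model, paste0(name, ".gamma"), rep(1, c))
  mc_param(model, paste0(name, ".beta"), rep(0, c))
  st <- new.env(parent = emptyenv())
  st$running_mean <- rep(0, c)
  st$running_var <- rep(1, c)
  model$bn[[name]] <- st
  invisible(model)
}

mc_conv <- function(model, name, k, cin, cout, init_sd, bias = FALSE) {
  mc_param(model, paste0(name, ".w"), conv_weight(k, cin, cout, init_sd))
  if (bias) mc_param(model, paste0(name, ".b"), numeric(cout))
  invisible(model)
}

#' Build the classifier
#'
#' Instantiates the 3D residual network in one of three variants: the plain
#' backbone (`baseline`), with attention gates on stages 2 and 3 driven by
#' the deepest feature map (`ag`), or with ASPP applied to the gated maps
#' before fusion with the gating signal (`ag_aspp`). The backbone is the
#' 18-layer residual pattern: a 3x3x3 stem plus four stages of two
#' residual blocks, stage widths 1x/2x/4x/8x `base_channels`, stages 2-4
#' downsampling by stride 2. All convolution and fully connected weights
#' are initialized truncated-normal (resampled outside two standard
#' deviations); biases start at zero.
#'
#' @param config a [model_config()].
#' @param seed integer seed governing the weight initialization.
#' @return An object of class `mcigate_model`.
#' @export
build_model <- function(config, seed = 0L) {
  if (any(config$input_grid < 16L))
    abort_mcigate(paste0(
      "input grid ", paste(config$input_grid, collapse = "x"),
      " too small for four downsamplings; minimal admissible grid is 16x16x16"),
      "mcigate_validation_error")
  model <- new.env(parent = emptyenv())
  model$config <- config
  model$params <- list()
  model$bn <- list()
  class(model) <- "mcigate_model"
  c0 <- config$base_channels
  widths <- c0 * c(1L, 2L, 4L, 8L)
  sd0 <- config$init_sd

  with_seed(derive_seed(seed, "init"), {
    mc_conv(model, "stem.conv", 3L, 1L, c0, sd0)
    mc_bn(model, "stem.bn", c0)
    cin <- c0
    for (s in 1:4) {
      cout <- widths[s]
      for (b in 1:2) {
        pre <- sprintf("stage%d.block%d", s, b)
        stride <- if (s > 1 && b == 1) 2L else 1L
        bin <- if (b == 1) cin else cout
        mc_conv(model, paste0(pre, ".conv1"), 3L, bin, cout, sd0)
        mc_bn(model, paste0(pre, ".bn1"), cout)
        mc_conv(model, paste0(pre, ".conv2"), 3L, cout, cout, sd0)
        mc_bn(model, paste0(pre, ".bn2"), cout)
        if (stride > 1 || bin != cout) {
          mc_conv(model, paste0(pre, ".down"), 1L, bin, cout, sd0)
          mc_bn(model, paste0(pre, ".downbn"), cout)
        }
      }
      cin <- cout
    }
    g_ch <- widths[4]
    if (config$variant %in% c("ag", "ag_aspp")) {
      for (l in 2:3) {
        Fl <- widths[l]
        Fint <- max(1L, Fl %/% 2L)
        pre <- sprintf("ag%d", l)
        mc_conv(model, paste0(pre, ".Wx"), 1L, Fl, Fint, sd0)
        mc_conv(model, paste0(pre, ".Wg"), 1L, g_ch, Fint, sd0)
        mc_conv(model, paste0(pre, ".psi"), 1L, Fint, 1L, sd0)
        mc_param(model, paste0(pre, ".b_xg"), numeric(Fint))
        mc_param(model, paste0(pre, ".b_psi"), 0)
      }
      if (config$variant == "ag_aspp") {
        for (l in 2:3) {
          Fl <- widths[l]
          pre <- sprintf("aspp%d", l)
          for (i in seq_along(config$aspp_rates))
            mc_conv(model, sprintf("%s.branch%d", pre, i), 3L, Fl, Fl, sd0,
                    bias = TRUE)
          mc_conv(model, paste0(pre, ".point"), 1L, Fl, Fl, sd0, bias = TRUE)
          mc_conv(model, paste0(pre, ".proj"), 1L,
                  Fl * (length(config$aspp_rates) + 1L), Fl, sd0, bias = TRUE)
        }
      }
      fuse_in <- widths[2] + widths[3] + g_ch
      mc_conv(model, "fuse.proj", 1L, fuse_in, g_ch, sd0)
      mc_bn(model, "fuse.bn", g_ch)
    }
    mc_param(model, "fc.w", matrix(rtrunc_norm(g_ch * config$n_classes, sd0),
                                   g_ch, config$n_classes))
    mc_param(model, "fc.b", numeric(config$n_classes))
  })
  model
}

#' @export
print.mcigate_model <- function(x, ...) {
  cat(sprintf("<mcigate_model> variant=%s grid=%s base_channels=%d params=%d\n",
              x$config$variant, paste(x$config$input_grid, collapse = "x"),
              x$config$base_channels, count_params(x)))
  invisible(x)
}

#' Number of trainable parameters
#' @param model an `mcigate_model`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, function(p) length(p$val), numeric(1)))
}

mc_bn_fwd <- function(model, x, name, training) {
  op_batchnorm(x, model$params[[paste0(name, ".gamma")]],
               model$params[[paste0(name, ".beta")]],
               model$bn[[name]], training,
               momentum = model$bn_momentum %||% 0.1)
}

mc_conv_fwd <- function(model, x, name, stride = c(1L, 1L, 1L),
                        dilation = c(1L, 1L, 1L), pad = NULL) {
  w <- model$params[[paste0(name, ".w")]]
  b <- model$params[[paste0(name, ".b")]]
  if (is.null(b)) b <- ag_leaf(numeric(dim(w$val)[5]))
  op_conv3d(x, w, b, stride = stride, dilation = dilation, pad = pad)
}

res_block_fwd <- function(model, x, pre, stride, training) {
  out <- mc_conv_fwd(model, x, paste0(pre, ".conv1"), stride = rep(stride, 3))
  out <- op_relu(mc_bn_fwd(model, out, paste0(pre, ".bn1"), training))
  out <- mc_conv_fwd(model, out, paste0(pre, ".conv2"))
  out <- mc_bn_fwd(model, out, paste0(pre, ".bn2"), training)
  short <- x
  if (!is.null(model$params[[paste0(pre, ".down.w")]])) {
    short <- mc_conv_fwd(model, x, paste0(pre, ".down"),
                         stride = rep(stride, 3), pad = c(0L, 0L, 0L))
    short <- mc_bn_fwd(model, short, paste0(pre, ".downbn"), training)
  }
  op_relu(op_add(out, short))
}

model_ag_fwd <- function(model, x_l, g, l, training) {
  pre <- sprintf("ag%d", l)
  dx <- dim(x_l$val); dg <- dim(g$val)
  stride <- pmax(1L, as.integer(ceiling(dx[1:3] / dg[1:3])))
  xp <- mc_conv_fwd(model, x_l, paste0(pre, ".Wx"), stride = stride,
                    pad = c(0L, 0L, 0L))
  xp <- op_adaptive_avgpool(xp, dg[1:3])
  gp <- mc_conv_fwd(model, g, paste0(pre, ".Wg"))
  q <- op_bias_channel(op_add(xp, gp), model$params[[paste0(pre, ".b_xg")]])
  q <- op_relu(q)
  q <- op_conv3d(q, model$params[[paste0(pre, ".psi.w")]],
                 model$params[[paste0(pre, ".b_psi")]])
  alpha <- if (model$config$sigma2 == "softmax") op_softmax_spatial(q)
           else op_sigmoid(q)
  alpha_up <- op_resize_trilinear(alpha, dx[1:3])
  list(gated = op_gate(x_l, alpha_up), alpha = alpha)
}

model_aspp_fwd <- function(model, x, l) {
  pre <- sprintf("aspp%d", l)
  rates <- model$config$aspp_rates
  outs <- lapply(seq_along(rates), function(i)
    mc_conv_fwd(model, x, sprintf("%s.branch%d", pre, i),
                dilation = rep(rates[i], 3)))
  outs[[length(outs) + 1L]] <- mc_conv_fwd(model, x, paste0(pre, ".point"))
  mc_conv_fwd(model, op_concat_channels(outs), paste0(pre, ".proj"))
}

# Full forward pass. `x` is a (D,H,W,1,B) array. Returns the score node
# plus named intermediate nodes (for Grad-CAM and the attention maps).
model_forward <- function(model, x, training = FALSE) {
  cfg <- model$config
  if (!all(dim(x)[1:3] == cfg$input_grid))
    abort_mcigate(sprintf("input grid %s does not match model grid %s",
                          paste(dim(x)[1:3], collapse = "x"),
                          paste(cfg$input_grid, collapse = "x")),
                  "mcigate_validation_error")
  xn <- ag_leaf(x)
  h <- mc_conv_fwd(model, xn, "stem.conv")
  h <- op_relu(mc_bn_fwd(model, h, "stem.bn", training))
  h <- op_maxpool(h)
  stages <- list()
  for (s in 1:4) {
    stride <- if (s > 1) 2L else 1L
    h <- res_block_fwd(model, h, sprintf("stage%d.block1", s), stride, training)
    h <- res_block_fwd(model, h, sprintf("stage%d.block2", s), 1L, training)
    stages[[s]] <- h
  }
  g <- stages[[4]]
  nodes <- list(input = xn, stem = NULL, stage1 = stages[[1]],
                stage2 = stages[[2]], stage3 = stages[[3]], stage4 = g)
  if (cfg$variant == "baseline") {
    pooled <- op_gap(g)
  } else {
    gated <- list()
    for (l in 2:3) {
      agout <- model_ag_fwd(model, stages[[l]], g, l, training)
      nodes[[sprintf("alpha%d", l)]] <- agout$alpha
      gl <- agout$gated
      if (cfg$variant == "ag_aspp") gl <- model_aspp_fwd(model, gl, l)
      gated[[l - 1L]] <- op_adaptive_avgpool(gl, dim(g$val)[1:3])
    }
    fus <- op_concat_channels(c(gated, list(g)))
    fus <- mc_conv_fwd(model, fus, "fuse.proj")
    fus <- op_relu(mc_bn_fwd(model, fus, "fuse.bn", training))
    nodes$fusion <- fus
    pooled <- op_gap(fus)
  }
  scores <- op_linear(pooled, model$params[["fc.w"]], model$params[["fc.b"]])
  nodes$scores <- scores
  nodes
}

#' Class scores and probabilities for a batch of volumes
#'
#' @param model an `mcigate_model`.
#' @param x rank-5 input `(D, H, W, 1, B)` or rank-3 single volume.
#' @return List with `scores` (B x 2) and `prob` (B x 2 softmax rows).
#' @export
predict_scores <- function(model, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L, 1L)
  out <- model_forward(model, x, training = FALSE)
  list(scores = out$scores$val, prob = softmax_rows(out$scores$val))
}

# --- checkpoint I/O ---------------------------------------------------------

#' Save / load model checkpoints
#'
#' A checkpoint directory holds the weight archive (`weights.rds`) and the
#' model configuration (`model.yaml`), so the config always travels with
#' the weights.
#'
#' @param model an `mcigate_model`.
#' @param dir checkpoint directory (created if missing).
#' @return `save_checkpoint` returns `dir` invisibly; `load_checkpoint`
#'   returns the restored model.
#' @export
save_checkpoint <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vals <- lapply(model$params, function(p) p$val)
  bn <- lapply(model$bn, function(st)
    list(running_mean = st$running_mean, running_var = st$running_var))
  saveRDS(list(params = vals, bn = bn), file.path(dir, "weights.rds"))
  cfg <- unclass(model$config)
  yaml::write_yaml(cfg, file.path(dir, "model.yaml"))
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "model.yaml"))
  config <- model_config(variant = cfg$variant, input_grid = cfg$input_grid,
                         base_channels = cfg$base_channels,
                         aspp_rates = cfg$aspp_rates, sigma2 = cfg$sigma2,
                         init_sd = cfg$init_sd, n_classes = cfg$n_classes)
  model <- build_model(config, seed = 0L)
  blob <- readRDS(file.path(dir, "weights.rds"))
  for (nm in names(blob$params)) model$params[[nm]]$val <- blob$params[[nm]]
  for (nm in names(blob$bn)) {
    model$bn[[nm]]$running_mean <- blob$bn[[nm]]$running_mean
    model$bn[[nm]]$running_var <- blob$bn[[nm]]$running_var
  }
  model
}
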