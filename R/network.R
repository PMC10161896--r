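#' Architecture specification of the correction network
#'
#' The artifact-correction network is a fully convolutional residual
#' network that maps the four Haar sub-bands of a corrupted sinogram to
#' the predicted stripe component of each sub-band. It comprises 14
#' convolution layers: a head 3x3 convolution (4 -> 64 channels, ReLU),
#' six residual blocks (each two 3x3 convolutions at 64 channels with an
#' identity shortcut), and a tail 3x3 convolution (64 -> 4 channels,
#' linear, since artifact coefficients are signed). Stride is 1 and
#' padding is replicate everywhere, so the spatial size never changes —
#' down-sampling would destroy single-pixel stripes, the very thing the
#' network must detect.
#'
#' @param in_channels,out_channels Input/output channel counts (the four
#'   sub-bands).
#' @param hidden_channels Channels of every hidden convolution.
#' @param n_res_blocks Number of residual blocks.
#' @return A `model_spec` list.
#' @export
model_spec <- function(in_channels = 4L, out_channels = 4L,
                       hidden_channels = 64L, n_res_blocks = 6L) {
  stopifnot(in_channels >= 1L, out_channels >= 1L, hidden_channels >= 1L,
            n_res_blocks >= 1L)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 hidden_channels = as.integer(hidden_channels),
                 n_res_blocks = as.integer(n_res_blocks),
                 kernel = 3L),
            class = "model_spec")
}

# He fan-in initialization for one conv layer, as a (c_out x 9*c_in)
# weight matrix plus zero bias.
init_conv <- function(c_in, c_out) {
  sd <- sqrt(2 / (9 * c_in))
  list(w = matrix(stats::rnorm(c_out * 9L * c_in, sd = sd), c_out, 9L * c_in),
       b = numeric(c_out))
}

#' Build a correction network with seeded random parameters
#'
#' @param spec A [model_spec()].
#' @param init_seed Integer seed for the He-style weight initialization;
#'   two builds with the same seed are parameter-identical.
#' @param coefficient_mode `"complete"` (all four sub-bands) or
#'   `"related"` (the ablation variant: only the WA and WH channels carry
#'   information — WV/WD are zeroed at input and output, mirroring a model
#'   trained on approximation + horizontal coefficients alone).
#' @param input_scale `"per-sample"` (default) standardizes each sample's
#'   coefficients by one scalar (their standard deviation) before the
#'   network and rescales the prediction back, making the corrector
#'   invariant to the sinogram's intensity units; `"none"` feeds raw
#'   coefficients.
#' @return A `correction_model`.
#' @export
build_model <- function(spec = model_spec(), init_seed = 1L,
                        coefficient_mode = c("complete", "related"),
                        input_scale = c("per-sample", "none")) {
  coefficient_mode <- match.arg(coefficient_mode)
  input_scale <- match.arg(input_scale)
  layers <- with_seed(init_seed, {
    hid <- spec$hidden_channels
    head <- init_conv(spec$in_channels, hid)
    blocks <- lapply(seq_len(spec$n_res_blocks), function(i) {
      # zero-init the closing conv of each residual branch so every block
      # starts as the identity; keeps activation magnitudes flat across
      # depth without normalization layers
      bl <- list(a = init_conv(hid, hid), b = init_conv(hid, hid))
      bl$b$w[] <- 0
      bl
    })
    # zero-initialized tail: the untrained network predicts a zero
    # artifact, i.e. starts as the identity corrector, so optimization
    # can only improve on the uncorrected baseline
    tail <- init_conv(hid, spec$out_channels)
    tail$w[] <- 0
    list(head = head, blocks = blocks, tail = tail)
  })
  structure(list(spec = spec, layers = layers,
                 coefficient_mode = coefficient_mode,
                 input_scale = input_scale,
                 provenance = list(init_seed = init_seed)),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf(
    "<correction_model> %d conv layers (%d residual blocks, %d hidden channels), %s mode, %s parameters\n",
    n_conv_layers(x), x$spec$n_res_blocks, x$spec$hidden_channels,
    x$coefficient_mode, format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Convolution-layer and parameter counts
#'
#' @param model A `correction_model`.
#' @return `n_conv_layers()`: the number of convolution layers
#'   (`2 + 2 * n_res_blocks`); `n_parameters()`: the total number of
#'   weights and biases.
#' @export
n_conv_layers <- function(model) {
  2L + 2L * model$spec$n_res_blocks
}

#' @rdname n_conv_layers
#' @export
n_parameters <- function(model) {
  sum(vapply(flatten_params(model), length, numeric(1)))
}

# Parameters as a flat named list (order is stable; used by the optimizer
# and the checkpoint format).
flatten_params <- function(model) {
  out <- list(head.w = model$layers$head$w, head.b = model$layers$head$b)
  for (i in seq_along(model$layers$blocks)) {
    bl <- model$layers$blocks[[i]]
    out[[paste0("block", i, ".a.w")]] <- bl$a$w
    out[[paste0("block", i, ".a.b")]] <- bl$a$b
    out[[paste0("block", i, ".b.w")]] <- bl$b$w
    out[[paste0("block", i, ".b.b")]] <- bl$b$b
  }
  out$tail.w <- model$layers$tail$w
  out$tail.b <- model$layers$tail$b
  out
}

unflatten_params <- function(model, params) {
  model$layers$head$w <- params$head.w
  model$layers$head$b <- params$head.b
  for (i in seq_along(model$layers$blocks)) {
    model$layers$blocks[[i]]$a$w <- params[[paste0("block", i, ".a.w")]]
    model$layers$blocks[[i]]$a$b <- params[[paste0("block", i, ".a.b")]]
    model$layers$blocks[[i]]$b$w <- params[[paste0("block", i, ".b.w")]]
    model$layers$blocks[[i]]$b$b <- params[[paste0("block", i, ".b.b")]]
  }
  model$layers$tail$w <- params$tail.w
  model$layers$tail$b <- params$tail.b
  model
}

# Ordered per-conv-layer weight/bias lists (head, block1.a, block1.b, ...,
# tail) used by the fused C++ forward/backward path.
conv_layer_names <- function(model) {
  nb <- model$spec$n_res_blocks
  c("head",
    as.vector(t(outer(paste0("block", seq_len(nb)), c(".a", ".b"), paste0))),
    "tail")
}

weights_lists <- function(model) {
  params <- flatten_params(model)
  nms <- conv_layer_names(model)
  list(W = unname(params[paste0(nms, ".w")]),
       b = unname(params[paste0(nms, ".b")]))
}

# One scalar standardization factor per sample (over all four bands).
sample_scale <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) 1 else s
}

# Per-band centering of a stacked coefficient array: conv stacks without
# normalization layers handle zero-mean inputs much better, and the
# artifact estimate is translation-free, so centering does not bias it.
center_bands <- function(x) {
  for (c in seq_len(dim(x)[3])) x[, , c] <- x[, , c] - mean(x[, , c])
  x
}

# Map the loss_config onto the C++ kernel's arguments.
loss_cfg_cpp <- function(cfg) {
  list(reg_channels = match(cfg$bands, band_names) - 1L,
       axis = if (cfg$stripe_axis == "angle") 0L else 1L,
       l2 = cfg$smoothness_norm == "l2")
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# In related mode only the WA/WH channels carry signal.
related_mask_channels <- 3:4

mask_related <- function(a) {
  a[, , related_mask_channels] <- 0
  a
}

# Forward pass on an H x W x C_in array. With cache = TRUE also returns
# every conv input and ReLU pre-activation needed for backprop.
model_forward_array <- function(model, x, cache = FALSE) {
  if (length(dim(x)) != 3L || dim(x)[3] != model$spec$in_channels) {
    stop("network input must be H x W x ", model$spec$in_channels,
         call. = FALSE)
  }
  if (any(dim(x)[1:2] < model$spec$kernel)) {
    stop("input spatial size (", dim(x)[1], " x ", dim(x)[2],
         ") is smaller than the ", model$spec$kernel, "x", model$spec$kernel,
         " kernel", call. = FALSE)
  }
  if (model$coefficient_mode == "related") x <- mask_related(x)
  cc <- if (cache) list(x0 = x) else NULL
  h0 <- conv3x3_forward(x, model$layers$head$w, model$layers$head$b)
  a <- relu(h0)
  if (cache) { cc$h0 <- h0 }
  if (cache) cc$blocks <- vector("list", length(model$layers$blocks))
  for (i in seq_along(model$layers$blocks)) {
    bl <- model$layers$blocks[[i]]
    u1 <- conv3x3_forward(a, bl$a$w, bl$a$b)
    r1 <- relu(u1)
    u2 <- conv3x3_forward(r1, bl$b$w, bl$b$b)
    s <- a + u2
    out <- relu(s)
    if (cache) cc$blocks[[i]] <- list(a_in = a, u1 = u1, r1 = r1, s = s)
    a <- out
  }
  if (cache) cc$a_tail <- a
  y <- conv3x3_forward(a, model$layers$tail$w, model$layers$tail$b)
  if (model$coefficient_mode == "related") y <- mask_related(y)
  if (cache) list(out = y, cache = cc) else y
}

# Backward pass: gradient of a scalar loss w.r.t. every parameter, given
# d(loss)/d(output). Returns a flat gradient list aligned with
# flatten_params().
model_backward_array <- function(model, cache, grad_out) {
  if (model$coefficient_mode == "related") grad_out <- mask_related(grad_out)
  g <- list()
  bw <- conv3x3_backward(cache$a_tail, model$layers$tail$w, grad_out)
  g$tail.w <- bw$gw; g$tail.b <- bw$gb
  ga <- bw$gx
  for (i in rev(seq_along(model$layers$blocks))) {
    bl <- model$layers$blocks[[i]]
    ci <- cache$blocks[[i]]
    gs <- ga * (ci$s > 0)              # through the post-shortcut ReLU
    bw2 <- conv3x3_backward(ci$r1, bl$b$w, gs)
    g[[paste0("block", i, ".b.w")]] <- bw2$gw
    g[[paste0("block", i, ".b.b")]] <- bw2$gb
    gu1 <- bw2$gx * (ci$u1 > 0)
    bw1 <- conv3x3_backward(ci$a_in, bl$a$w, gu1)
    g[[paste0("block", i, ".a.w")]] <- bw1$gw
    g[[paste0("block", i, ".a.b")]] <- bw1$gb
    ga <- gs + bw1$gx                  # shortcut + conv path
  }
  gh0 <- ga * (cache$h0 > 0)
  bwh <- conv3x3_backward(cache$x0, model$layers$head$w, gh0)
  g$head.w <- bwh$gw; g$head.b <- bwh$gb
  g
}

#' Predict per-band stripe components from wavelet coefficients
#'
#' @param model A `correction_model`, or any function mapping
#'   `wavelet_coeffs` to an artifact estimate (e.g. an oracle stub in
#'   tests).
#' @param coeffs `wavelet_coeffs` of a (corrupted) sinogram.
#' @return An `artifact_estimate`: a `wavelet_coeffs`-shaped list of the
#'   predicted stripe component of each sub-band.
#' @export
predict_artifact <- function(model, coeffs) {
  coeffs <- as_wavelet_coeffs(coeffs)
  if (is.function(model)) {
    est <- as_wavelet_coeffs(model(coeffs))
    class(est) <- c("artifact_estimate", class(est))
    return(est)
  }
  x <- coeffs_to_array(coeffs)
  if (any(dim(x)[1:2] < model$spec$kernel)) {
    stop("input spatial size (", dim(x)[1], " x ", dim(x)[2],
         ") is smaller than the ", model$spec$kernel, "x", model$spec$kernel,
         " kernel", call. = FALSE)
  }
  wl <- weights_lists(model)
  xin <- x
  sc <- 1
  if (!identical(model$input_scale, "none")) {
    sc <- sample_scale(x)
    xin <- center_bands(x) / sc
  }
  out <- sc * net_forward_cpp(xin, wl$W, wl$b,
                              related = model$coefficient_mode == "related")
  est <- array_to_coeffs(out)
  class(est) <- c("artifact_estimate", class(est))
  est
}

#' Remove predicted stripe artifacts from one sinogram
#'
#' The full application path: pad to even size, Haar-decompose, predict
#' the stripe component of each sub-band, subtract it from the input
#' coefficients, inverse-transform, and crop back. Angle metadata is
#' preserved.
#'
#' @param model A `correction_model`.
#' @param s A [sinogram()].
#' @return The corrected [sinogram()].
#' @export
correct_sinogram <- function(model, s) {
  stopifnot(is_sinogram(s), is.function(model) || inherits(model, "correction_model"))
  p <- pad_to_even(sino_data(s))
  coeffs <- hdwt(p$image)
  est <- predict_artifact(model, coeffs)
  cleaned <- coeffs_map2(coeffs, est, `-`)
  out <- crop_pad(ihdwt(cleaned), p$pad)
  restamp_sinogram(out, s)
}

#' Save / load a model checkpoint
#'
#' A checkpoint stores the parameters, the architecture spec, the
#' coefficient mode and a provenance record (seeds, training history
#' summary, dataset fingerprint) in a versioned single-file format.
#'
#' @param model A `correction_model`.
#' @param path File path (conventionally `.rds`).
#' @param provenance Optional named list merged into the stored
#'   provenance.
#' @return `save_checkpoint()` returns `path` invisibly;
#'   `load_checkpoint()` returns the `correction_model`.
#' @export
save_checkpoint <- function(model, path, provenance = list()) {
  stopifnot(inherits(model, "correction_model"))
  payload <- list(format = "destriper-checkpoint", version = 1L,
                  spec = model$spec,
                  coefficient_mode = model$coefficient_mode,
                  input_scale = model$input_scale,
                  params = flatten_params(model),
                  provenance = utils::modifyList(model$provenance, provenance))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "destriper-checkpoint")) {
    stop("not a destriper checkpoint: ", path, call. = FALSE)
  }
  model <- build_model(payload$spec, init_seed = 0L,
                       coefficient_mode = payload$coefficient_mode,
                       input_scale = payload$input_scale %||% "per-sample")
  model <- unflatten_params(model, payload$params)
  model$provenance <- payload$provenance
  model
}

# Structural compatibility check used by fine_tune().
assert_spec_match <- function(model, spec) {
  if (!identical(unclass(model$spec), unclass(spec))) {
    stop("checkpoint architecture does not match the requested model spec",
         call. = FALSE)
  }
  invisible(TRUE)
}
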