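#' Mean square error between two equal-shaped arrays
#'
#' `(1/N) * sum((a - b)^2)` with `N` the total pixel count.
#'
#' @param a,b Numeric arrays of one common shape.
#' @return Non-negative scalar.
#' @export
mse <- function(a, b) {
  a <- as_matrix2d(a, "mse input"); b <- as_matrix2d(b, "mse input")
  if (!identical(dim(a), dim(b))) {
    stop("mse requires equal shapes (got ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"), ")", call. = FALSE)
  }
  mean((a - b)^2)
}

#' Loss configuration for the destriping objective
#'
#' The training objective is `L = L_M + lambda * L_W` where `L_M` sums the
#' per-band MSE between the predicted and true artifact coefficients over
#' all four Haar sub-bands, and the regularizer `L_W` penalizes variation
#' of the predicted stripe components along the stripe direction (a true
#' stripe is nearly constant along its length). By its printed definition
#' `L_W` is evaluated on the WA and WH stripe components; because which
#' detail band carries stripe energy depends on the sinogram orientation
#' convention, the `bands` argument lets the regularized bands be
#' overridden (e.g. `c("WA", "WV")` when stripes are detector columns
#' under the row = angle convention).
#'
#' @param lambda_reg Non-negative regularization weight (balances the two
#'   loss terms; default 0.1, see [calibrate_lambda()]).
#' @param smoothness_norm `"l2"` (mean of squared differences) or `"l1"`
#'   (mean of absolute differences).
#' @param stripe_axis Axis the stripes run along: `"angle"` (stripes are
#'   detector columns, differences taken down each column) or
#'   `"detector"`.
#' @param bands Sub-bands whose predicted stripe components are
#'   regularized.
#' @return A `loss_config` list.
#' @export
loss_config <- function(lambda_reg = 0.1,
                        smoothness_norm = c("l2", "l1"),
                        stripe_axis = c("angle", "detector"),
                        bands = c("WA", "WH")) {
  if (lambda_reg < 0) stop("lambda_reg must be non-negative", call. = FALSE)
  smoothness_norm <- match.arg(smoothness_norm)
  stripe_axis <- match.arg(stripe_axis)
  stopifnot(all(bands %in% band_names))
  structure(list(lambda_reg = lambda_reg, smoothness_norm = smoothness_norm,
                 stripe_axis = stripe_axis, bands = bands),
            class = "loss_config")
}

#' Wavelet-domain data loss `L_M`
#'
#' Unweighted sum of the four per-band mean square errors between the
#' predicted artifact coefficients and the label coefficients:
#' `L_M = MSE_WA + MSE_WH + MSE_WV + MSE_WD`.
#'
#' @param pred Predicted artifact coefficients (`wavelet_coeffs` or a list
#'   of four bands).
#' @param label Ground-truth artifact coefficients.
#' @return Non-negative scalar.
#' @export
wavelet_loss <- function(pred, label) {
  pred <- as_wavelet_coeffs(pred); label <- as_wavelet_coeffs(label)
  sum(vapply(band_names, function(b) mse(pred[[b]], label[[b]]), numeric(1)))
}

# Forward finite difference along the stripe axis.
stripe_diff <- function(m, stripe_axis) {
  if (stripe_axis == "angle") {
    m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
  } else {
    m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  }
}

#' Along-stripe smoothness regularizer `L_W`
#'
#' Mean norm of the forward finite difference, taken along the stripe
#' direction, of the predicted stripe components of the configured
#' sub-bands (WA and WH by default):
#' `L_W = ||grad S_WA|| + ||grad S_WH||`. A perfect full-length stripe is
#' constant along its direction, so ideal stripe estimates score zero.
#'
#' @param pred Predicted artifact coefficients.
#' @param cfg A [loss_config()].
#' @return Non-negative scalar.
#' @export
regular_loss <- function(pred, cfg = loss_config()) {
  pred <- as_wavelet_coeffs(pred)
  sum(vapply(cfg$bands, function(b) {
    d <- stripe_diff(pred[[b]], cfg$stripe_axis)
    if (cfg$smoothness_norm == "l2") mean(d^2) else mean(abs(d))
  }, numeric(1)))
}

#' Composite training objective `L = L_M + lambda * L_W`
#'
#' @inheritParams regular_loss
#' @param label Ground-truth artifact coefficients.
#' @return Non-negative scalar.
#' @export
total_loss <- function(pred, label, cfg = loss_config()) {
  wavelet_loss(pred, label) + cfg$lambda_reg * regular_loss(pred, cfg)
}

# Analytic gradient of total_loss with respect to the prediction, as an
# H' x W' x 4 array matching coeffs_to_array() channel order.
total_loss_gradient <- function(pred_arr, label_arr, cfg) {
  dims <- dim(pred_arr)
  n_px <- dims[1] * dims[2]
  g <- 2 * (pred_arr - label_arr) / n_px          # d(L_M)/dpred, per band
  if (cfg$lambda_reg > 0) {
    for (b in cfg$bands) {
      ch <- match(b, band_names)
      m <- pred_arr[, , ch]
      d <- stripe_diff(m, cfg$stripe_axis)
      n_d <- length(d)
      gd <- if (cfg$smoothness_norm == "l2") 2 * d / n_d else sign(d) / n_d
      gm <- matrix(0, dims[1], dims[2])
      if (cfg$stripe_axis == "angle") {
        gm[-1, ] <- gm[-1, ] + gd
        gm[-dims[1], ] <- gm[-dims[1], ] - gd
      } else {
        gm[, -1] <- gm[, -1] + gd
        gm[, -dims[2]] <- gm[, -dims[2]] - gd
      }
      g[, , ch] <- g[, , ch] + cfg$lambda_reg * gm
    }
  }
  g
}

#' Calibrate the regularization weight on a pilot batch
#'
#' Picks `lambda_reg` so that `lambda * L_W` matches `L_M` in magnitude
#' when both are evaluated at the trivial zero prediction against the true
#' artifact labels of a pilot batch — i.e. the two terms start training on
#' an equal footing under the current stripe distribution.
#'
#' @param records List of `sample_record`s (a pilot batch).
#' @param cfg A [loss_config()] supplying the norm/axis/bands.
#' @return A positive scalar `lambda_reg`.
#' @export
calibrate_lambda <- function(records, cfg = loss_config()) {
  stopifnot(length(records) > 0)
  ratios <- vapply(records, function(r) {
    zero <- lapply(r$artifact_coeffs, function(b) b * 0)
    lm <- wavelet_loss(zero, r$artifact_coeffs)
    lw <- regular_loss(r$artifact_coeffs, cfg)
    if (lw <= .Machine$double.eps) return(NA_real_)
    lm / lw
  }, numeric(1))
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) == 0L) return(cfg$lambda_reg)
  stats::median(ratios)
}
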