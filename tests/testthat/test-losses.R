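make_bands <- function(h, w, f) {
  nm <- c("WA", "WH", "WV", "WD")
  stats::setNames(lapply(seq_along(nm), function(i) f(i, h, w)), nm)
}

test_that("mse matches its hand-evaluated definition", {
  a <- rand_mat(5, 7)
  expect_equal(mse(a, a), 0)
  expect_equal(mse(matrix(c(0, 1, 0, 1), 2, 2), matrix(0, 2, 2)), 0.5)
  b <- rand_mat(5, 7, seed = 2)
  expect_equal(mse(a, b), mse(b, a))
  expect_error(mse(matrix(0, 2, 2), matrix(0, 2, 3)), "equal shapes")
})

test_that("the wavelet loss sums the four per-band MSEs", {
  lab <- make_bands(4, 4, function(i, h, w) rand_mat(h, w, seed = i))
  expect_equal(wavelet_loss(lab, lab), 0)

  pred <- lab
  pred$WA <- pred$WA + 1  # per-band mse exactly 1, others zero
  expect_equal(wavelet_loss(pred, lab), 1)

  # bands constructed with per-band MSE 0.1, 0.2, 0.3, 0.4 against zero
  zeros <- make_bands(4, 4, function(i, h, w) matrix(0, h, w))
  pred2 <- make_bands(4, 4, function(i, h, w) matrix(sqrt(i / 10), h, w))
  expect_equal(wavelet_loss(pred2, zeros), 1.0)
})

test_that("the smoothness regularizer is zero for ideal stripes and counts steps", {
  cfg <- loss_config()
  # column-constant estimates (perfect full-length stripes): zero penalty
  const_cols <- make_bands(6, 5, function(i, h, w)
    matrix(rep(stats::runif(w), each = h), h, w))
  expect_equal(regular_loss(const_cols, cfg), 0)
  zero <- make_bands(6, 5, function(i, h, w) matrix(0, h, w))
  expect_equal(regular_loss(zero, cfg), 0)

  # a single unit step along the stripe axis in one column of WA:
  # one nonzero difference among (m-1)*n, squared-L2 norm
  m <- 6; n <- 5
  step <- zero
  step$WA[4:m, 2] <- 1
  expect_equal(regular_loss(step, cfg), 1 / ((m - 1) * n))

  # L1 norm of the same estimate
  cfg1 <- loss_config(smoothness_norm = "l1")
  expect_equal(regular_loss(step, cfg1), 1 / ((m - 1) * n))

  # band override: penalizing only WV ignores the WA step
  cfg2 <- loss_config(bands = c("WV"))
  expect_equal(regular_loss(step, cfg2), 0)

  # detector-axis stripes: a row-constant estimate scores zero
  cfg3 <- loss_config(stripe_axis = "detector")
  const_rows <- make_bands(6, 5, function(i, h, w)
    matrix(rep(stats::runif(h), times = w), h, w))
  expect_equal(regular_loss(const_rows, cfg3), 0)
})

test_that("the total loss is affine in the regularization weight", {
  lab <- make_bands(4, 4, function(i, h, w) matrix(0, h, w))
  pred <- make_bands(4, 4, function(i, h, w) matrix(sqrt(i / 10), h, w))
  pred$WA[3:4, ] <- pred$WA[3:4, ] + 1

  expect_equal(total_loss(pred, lab, loss_config(lambda_reg = 0)),
               wavelet_loss(pred, lab))
  l0 <- total_loss(pred, lab, loss_config(lambda_reg = 0))
  l2 <- total_loss(pred, lab, loss_config(lambda_reg = 2))
  expect_equal(l2 - l0, 2 * regular_loss(pred, loss_config()))

  # arithmetic composition: L_M = 1, L_W = 0.5, lambda = 0.1 -> 1.05
  m <- 3; n <- 5
  zero <- make_bands(m, n, function(i, h, w) matrix(0, h, w))
  lab2 <- zero
  pred2 <- make_bands(m, n, function(i, h, w) matrix(sqrt(i / 10), h, w))
  k <- 0.5 * (m - 1) * n  # scale one WA step so L_W = 0.5
  pred2$WA <- matrix(0, m, n)
  pred2$WA[2:m, 1] <- sqrt(k)
  pred2$WA <- pred2$WA + 0  # keep L_M contribution from WA equal to
  # mse(pred2$WA, 0); rebuild the other bands so the total L_M is 1
  msewa <- mean(pred2$WA^2)
  pred2$WH <- matrix(sqrt(max(1 - msewa, 0) / 3), m, n)
  pred2$WV <- matrix(sqrt(max(1 - msewa, 0) / 3), m, n)
  pred2$WD <- matrix(sqrt(max(1 - msewa, 0) / 3), m, n)
  expect_equal(wavelet_loss(pred2, lab2), 1.0)
  expect_equal(regular_loss(pred2, loss_config()), 0.5)
  expect_equal(total_loss(pred2, lab2, loss_config(lambda_reg = 0.1)), 1.05)
})

test_that("loss terms are non-negative for arbitrary inputs", {
  for (seed in 1:10) {
    pred <- make_bands(5, 4, function(i, h, w) rand_mat(h, w, seed = seed * 10 + i))
    lab <- make_bands(5, 4, function(i, h, w) rand_mat(h, w, seed = seed * 50 + i))
    expect_gte(wavelet_loss(pred, lab), 0)
    expect_gte(regular_loss(pred, loss_config()), 0)
    expect_gte(total_loss(pred, lab, loss_config(lambda_reg = 0.3)), 0)
  }
})

test_that("the analytic prediction gradient matches finite differences", {
  cfg <- loss_config(lambda_reg = 0.2)
  pred <- array(rand_mat(6, 20, seed = 1), c(6, 5, 4))
  lab <- array(rand_mat(6, 20, seed = 2), c(6, 5, 4))
  g <- destriper:::total_loss_gradient(pred, lab, cfg)
  h <- 1e-6
  idx <- rbind(c(1, 1, 1), c(3, 2, 1), c(6, 5, 2), c(2, 4, 3), c(5, 3, 4))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, ]
    pp <- pred; pp[i[1], i[2], i[3]] <- pp[i[1], i[2], i[3]] + h
    pm <- pred; pm[i[1], i[2], i[3]] <- pm[i[1], i[2], i[3]] - h
    fd <- (total_loss(destriper:::array_to_coeffs(pp), destriper:::array_to_coeffs(lab), cfg) -
           total_loss(destriper:::array_to_coeffs(pm), destriper:::array_to_coeffs(lab), cfg)) / (2 * h)
    expect_equal(g[i[1], i[2], i[3]], fd, tolerance = 1e-6)
  }
})

test_that("network parameter gradients agree with numerical differentiation", {
  spec <- model_spec(hidden_channels = 6, n_res_blocks = 2)
  model <- build_model(spec, init_seed = 3)
  cfg <- loss_config(lambda_reg = 0.1)
  x <- array(rand_mat(6, 32, seed = 5), c(6, 8, 4))
  y <- array(rand_mat(6, 32, seed = 6), c(6, 8, 4))
  wl <- destriper:::weights_lists(model)
  lc <- destriper:::loss_cfg_cpp(cfg)
  res <- destriper:::net_grad_cpp(x, y, wl$W, wl$b, FALSE, cfg$lambda_reg,
                                  lc$reg_channels, lc$axis, lc$l2)
  nms <- destriper:::conv_layer_names(model)
  grads <- stats::setNames(c(res$gw, res$gb),
                           c(paste0(nms, ".w"), paste0(nms, ".b")))
  params <- destriper:::flatten_params(model)
  loss_at <- function(p) {
    m2 <- destriper:::unflatten_params(model, p)
    out <- destriper:::model_forward_array(m2, x)
    total_loss(destriper:::array_to_coeffs(out),
               destriper:::array_to_coeffs(y), cfg)
  }
  h <- 1e-5
  probe <- list(c("head.w", 5L), c("block1.a.w", 17L), c("block2.b.w", 40L),
                c("tail.w", 3L), c("block1.b.b", 2L), c("tail.b", 4L))
  for (pr in probe) {
    nm <- pr[[1]]; k <- as.integer(pr[[2]])
    pp <- params; pp[[nm]][k] <- pp[[nm]][k] + h
    pm <- params; pm[[nm]][k] <- pm[[nm]][k] - h
    fd <- (loss_at(pp) - loss_at(pm)) / (2 * h)
    expect_equal(unname(grads[[nm]][k]), fd, tolerance = 1e-4)
  }
})

test_that("lambda calibration balances the two loss terms", {
  recs <- tiny_dataset()$train[1:4]
  cfg <- loss_config()
  lam <- calibrate_lambda(recs, cfg)
  expect_gt(lam, 0)
  # with the calibrated weight, the two terms evaluated on the labels are
  # comparable (within an order of magnitude) for the median record
  ratios <- vapply(recs, function(r) {
    zero <- lapply(r$artifact_coeffs, function(b) b * 0)
    lm <- wavelet_loss(zero, r$artifact_coeffs)
    lw <- lam * regular_loss(r$artifact_coeffs, cfg)
    lm / lw
  }, numeric(1))
  expect_true(stats::median(ratios) > 0.1 && stats::median(ratios) < 10)
})
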