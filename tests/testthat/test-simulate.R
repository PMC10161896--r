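test_that("default_angles matches the acquisition protocol", {
  a <- default_angles()
  expect_length(a, 360)
  expect_equal(a[1], 0)
  expect_equal(a[360], 179.5)
  expect_equal(unique(round(diff(a), 10)), 0.5)

  expect_equal(default_angles(2, 0, 90), c(0, 90))
  for (n in c(5, 37, 100)) {
    a2 <- default_angles(n, 10, 70)
    expect_equal(unique(round(diff(a2), 9)), round((70 - 10) / (n - 1), 9))
  }
  expect_error(default_angles(1), "at least 2")
})

test_that("phantoms are seeded, bounded and supported on the inscribed circle", {
  expect_identical(make_phantom(32, seed = 5), make_phantom(32, seed = 5))
  expect_false(identical(make_phantom(32, seed = 5), make_phantom(32, seed = 6)))
  expect_equal(make_phantom(32, n_shapes = 0, seed = 1), matrix(0, 32, 32))
  expect_error(make_phantom(8), "size_px")

  for (seed in 1:25) {
    ph <- make_phantom(24, seed = seed)
    expect_true(all(ph >= 0 & ph <= 1))
  }
})

test_that("radon conserves projection mass and centers the middle ray", {
  ph <- make_phantom(64, seed = 3)
  s <- radon(ph, default_angles(45, 0, 179))
  cx <- (64 - 1) / 2
  mask <- outer((0:63) - cx, (0:63) - cx, function(y, x) x^2 + y^2 <= cx^2)
  mass <- sum(ph[mask])
  expect_lt(max(abs(rowSums(sino_data(s)) - mass)) / mass, 0.01)

  expect_equal(sino_data(radon(matrix(0, 32, 32), c(0, 45, 90))),
               matrix(0, 3, 32))

  # single bright pixel at the rotation center projects onto the central
  # detector column at every angle
  img <- matrix(0, 33, 33)
  img[17, 17] <- 1
  sc <- radon(img, default_angles(20, 0, 171))
  expect_true(all(apply(sino_data(sc), 1, which.max) == 17))

  expect_error(radon(matrix(0, 16, 20), c(0, 90)), "square")
  expect_error(radon(matrix(0, 16, 16), c(0, 180)), "\\[0, 180\\)")
})

test_that("stripe injection honors its specification", {
  s <- one_record()$clean

  # zero amplitude: corruption is a no-op
  r0 <- add_stripes(s, stripe_spec(amplitude_range = c(0, 0), seed = 1))
  expect_equal(sino_data(r0$corrupted), sino_data(r0$clean))

  # one full-length additive stripe of known amplitude
  sp <- stripe_spec(n_stripes_range = c(1, 1), width_range_px = c(1, 1),
                    amplitude_range = c(0.1, 0.1), partial_fraction = 0,
                    seed = 8)
  r1 <- add_stripes(s, sp)
  d <- sino_data(r1$corrupted) - sino_data(r1$clean)
  cols_hit <- which(colSums(abs(d)) > 0)
  expect_length(cols_hit, 1)
  expected_amp <- 0.1 * diff(range(sino_data(s)))
  expect_equal(unique(d[, cols_hit]), r1$meta$stripes[[1]]$amplitude *
                 diff(range(sino_data(s))))
  expect_equal(abs(unique(d[, cols_hit])), expected_amp)

  # seeded determinism
  expect_identical(sino_data(add_stripes(s, sp)$corrupted),
                   sino_data(add_stripes(s, sp)$corrupted))

  expect_error(add_stripes(s, stripe_spec(width_range_px = c(1, ncol(s)))),
               "width")
})

test_that("sample records satisfy their algebraic invariants", {
  r <- one_record()
  expect_equal(sino_data(r$clean) + r$artifact_field,
               sino_data(r$corrupted))
  lab <- r$artifact_coeffs
  direct <- hdwt(r$artifact_field)
  for (b in c("WA", "WH", "WV", "WD")) {
    expect_lt(max(abs(lab[[b]] - direct[[b]])), 1e-10)
  }
})

test_that("multiplicative stripes apply a constant gain", {
  s <- one_record()$clean
  sp <- stripe_spec(n_stripes_range = c(1, 1), width_range_px = c(1, 1),
                    amplitude_range = c(0.2, 0.2), partial_fraction = 0,
                    mode = "multiplicative", seed = 2)
  r <- add_stripes(s, sp)
  ratio <- sino_data(r$corrupted) / sino_data(r$clean)
  ratio[!is.finite(ratio)] <- 1
  gains <- unique(round(ratio, 10))
  expect_true(all(gains %in% round(c(1, 1 + r$meta$stripes[[1]]$amplitude), 10)))
})

test_that("degradation PSNR tracks artifact severity", {
  s <- one_record()$clean
  r0 <- add_stripes(s, stripe_spec(amplitude_range = c(0, 0), seed = 1))
  expect_identical(degradation_psnr(r0), Inf)

  amps <- c(0.02, 0.04, 0.08, 0.16)
  vals <- vapply(amps, function(a) {
    degradation_psnr(add_stripes(s, stripe_spec(amplitude_range = c(a, a),
                                                seed = 5)))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))

  r <- one_record()
  expect_identical(degradation_psnr(r), psnr(r$clean, r$corrupted))
})

test_that("build_dataset splits deterministically and exhaustively", {
  ds <- tiny_dataset()
  expect_length(ds$train, 10)
  expect_length(ds$test, 4)
  expect_length(intersect(ds$meta$train_idx, ds$meta$test_idx), 0)
  expect_setequal(c(ds$meta$train_idx, ds$meta$test_idx), 1:14)

  ds2 <- build_dataset(n_total = 6, train_fraction = 0.5, size_px = 32,
                       angles = default_angles(16, 0, 168.75), seed = 9)
  ds3 <- build_dataset(n_total = 6, train_fraction = 0.5, size_px = 32,
                       angles = default_angles(16, 0, 168.75), seed = 9)
  expect_identical(ds2, ds3)
  expect_length(ds2$train, 3)

  expect_error(build_dataset(n_total = 1), "at least 2")
  expect_error(build_dataset(n_total = 10, train_fraction = 1.2),
               "strictly between")
  expect_error(build_dataset(n_total = 10, train_fraction = 0.01),
               "degenerate")
})

test_that("striped sinograms reconstruct to ring-dominated error images", {
  ph <- make_phantom(64, seed = 12)
  s <- radon(ph, default_angles(90))
  strong <- add_stripes(s, stripe_spec(amplitude_range = c(0.1, 0.1), seed = 3))
  weak_spec <- stripe_spec(amplitude_range = c(0.01, 0.01), seed = 3)
  weak <- add_stripes(s, weak_spec)
  rc <- fbp(s)
  e_strong <- sum((fbp(strong$corrupted) - rc)^2)
  e_weak <- sum((fbp(weak$corrupted) - rc)^2)
  expect_gt(e_strong, 10 * e_weak)
})
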