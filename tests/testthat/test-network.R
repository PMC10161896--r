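test_that("the architecture honors its layer and parameter contract", {
  m <- build_model(init_seed = 1)
  expect_equal(n_conv_layers(m), 14L)

  # independent per-layer arithmetic: k^2 * c_in * c_out + c_out
  per_layer <- function(cin, cout) 3 * 3 * cin * cout + cout
  expected <- per_layer(4, 64) +
    6 * (per_layer(64, 64) + per_layer(64, 64)) +
    per_layer(64, 4)
  expect_equal(expected, 447812L)
  expect_equal(n_parameters(m), expected)

  # every hidden conv has 64 output channels, only the last has 4
  wl <- destriper:::weights_lists(m)
  outs <- vapply(wl$W, nrow, integer(1))
  expect_equal(outs, c(rep(64L, 13), 4L))
})

test_that("initialization is a pure function of the seed", {
  p1 <- destriper:::flatten_params(build_model(init_seed = 7))
  p2 <- destriper:::flatten_params(build_model(init_seed = 7))
  p3 <- destriper:::flatten_params(build_model(init_seed = 8))
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
})

test_that("the forward pass preserves spatial size and zero maps to zero", {
  m <- build_model(init_seed = 2)
  for (dims in list(c(30, 40), c(33, 41), c(3, 3))) {
    x <- array(stats::rnorm(prod(dims) * 4), c(dims, 4))
    y <- destriper:::model_forward_array(m, x)
    expect_equal(dim(y), c(dims, 4L))
  }
  zm <- zero_model()
  x <- array(stats::rnorm(10 * 12 * 4), c(10, 12, 4))
  expect_equal(destriper:::model_forward_array(zm, x),
               array(0, c(10, 12, 4)))
  expect_error(destriper:::model_forward_array(m, array(0, c(2, 8, 4))),
               "smaller than")
})

test_that("reference R forward and fused C++ forward agree exactly", {
  m <- build_model(init_seed = 4)
  x <- array(stats::rnorm(12 * 10 * 4), c(12, 10, 4))
  wl <- destriper:::weights_lists(m)
  expect_equal(destriper:::model_forward_array(m, x),
               destriper:::net_forward_cpp(x, wl$W, wl$b, FALSE))
  m$coefficient_mode <- "related"
  expect_equal(destriper:::model_forward_array(m, x),
               destriper:::net_forward_cpp(x, wl$W, wl$b, TRUE))
})

test_that("the network is translation-equivariant along the stripe axis", {
  m <- build_model(init_seed = 9)
  h <- 64; w <- 24
  x <- array(stats::rnorm(h * w * 4), c(h, w, 4))
  shift <- 2L
  xs <- x
  xs[(1 + shift):h, , ] <- x[1:(h - shift), , ]
  y <- destriper:::model_forward_array(m, x)
  ys <- destriper:::model_forward_array(m, xs)
  # interior rows beyond the receptive-field margin of 14 conv layers
  margin <- 16L
  rows <- (margin + shift):(h - margin)
  expect_equal(ys[rows, , ], y[rows - shift, , ], tolerance = 1e-8)
})

test_that("related mode silences the WV and WD channels end to end", {
  m <- build_model(init_seed = 3, coefficient_mode = "related")
  # give the (zero-initialized) tail random weights so the network has
  # nonzero output to mask
  params <- destriper:::flatten_params(m)
  params$tail.w <- rand_mat(nrow(params$tail.w), ncol(params$tail.w), seed = 1)
  m <- destriper:::unflatten_params(m, params)
  r <- one_record()
  est <- predict_artifact(m, r$corrupted_coeffs)
  expect_equal(est$WV, est$WV * 0)
  expect_equal(est$WD, est$WD * 0)
  expect_gt(sum(abs(est$WA)), 0)
})

test_that("sinogram correction composes the pipeline correctly", {
  r <- one_record()
  # zero network: exact identity through pad -> hdwt -> ihdwt -> crop
  out0 <- correct_sinogram(zero_model(), r$corrupted)
  expect_equal(sino_data(out0), sino_data(r$corrupted), tolerance = 1e-12)
  expect_equal(angles(out0), angles(r$corrupted))

  # oracle stub returning the true artifact coefficients recovers the
  # clean sinogram
  oracle <- function(coeffs) r$artifact_coeffs
  out1 <- correct_sinogram(oracle, r$corrupted)
  expect_lt(max(abs(sino_data(out1) - sino_data(r$clean))), 1e-6)

  # odd detector count survives the pad/crop round trip
  odd <- sinogram(sino_data(r$corrupted)[, 1:31], angles(r$corrupted))
  out2 <- correct_sinogram(build_model(init_seed = 1), odd)
  expect_equal(dim(out2), c(40L, 31L))
})

test_that("correction is additive in the artifact estimate", {
  r <- one_record()
  e1 <- lapply(r$artifact_coeffs, function(b) b * 0.3)
  e2 <- lapply(r$artifact_coeffs, function(b) b * 0.5)
  e12 <- destriper:::coeffs_map2(as_wavelet_coeffs(e1),
                                 as_wavelet_coeffs(e2), `+`)
  joint <- correct_sinogram(function(coeffs) e12, r$corrupted)
  seq1 <- correct_sinogram(function(coeffs) as_wavelet_coeffs(e1), r$corrupted)
  seq2 <- correct_sinogram(function(coeffs) as_wavelet_coeffs(e2), seq1)
  expect_equal(sino_data(joint), sino_data(seq2), tolerance = 1e-10)
})

test_that("checkpoints round-trip parameters, spec and provenance", {
  m <- build_model(init_seed = 6)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f, provenance = list(note = "unit"))
  m2 <- load_checkpoint(f)
  expect_identical(destriper:::flatten_params(m), destriper:::flatten_params(m2))
  expect_identical(m$spec, m2$spec)
  expect_identical(m2$provenance$note, "unit")

  g <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), g)
  expect_error(load_checkpoint(g), "not a destriper checkpoint")
})
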