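test_that("FBP inverts the Radon transform to within discretization error", {
  expect_equal(fbp(sinogram(matrix(0, 10, 16), default_angles(10, 0, 170))),
               matrix(0, 16, 16))

  ph <- make_phantom(128, seed = 5)
  s <- radon(ph, default_angles(180))
  rec <- fbp(s)
  msk <- destriper:::support_mask(128)
  nrmse <- sqrt(mean((rec[msk] - ph[msk])^2)) / diff(range(ph[msk]))
  expect_lt(nrmse, 0.1)

  expect_error(fbp(s, "butterworth"), "unknown FBP filter")
  for (f in c("shepp-logan", "hann", "hamming")) {
    expect_true(all(is.finite(fbp(sinogram(sino_data(s)[, 1:64][1:32, ],
                                           default_angles(32, 0, 178)),
                                  filter_name = f))))
  }
})

test_that("a constant-column sinogram stripe back-projects to a ring", {
  n <- 128
  col <- 96                      # detector offset -> ring radius
  m <- matrix(0, 90, n)
  m[, col] <- 1
  art <- fbp(sinogram(m, default_angles(90)))
  cx <- (n - 1) / 2
  radius <- abs(col - 1 - cx)
  rr <- sqrt(outer(((0:(n - 1)) - cx)^2, ((0:(n - 1)) - cx)^2, `+`))
  in_annulus <- abs(rr - radius) <= 3
  frac <- sum(art[in_annulus]^2) / sum(art^2)
  expect_gte(frac, 0.5)
})

test_that("psnr follows its closed form and severity ordering", {
  a <- rand_mat(16, 16)
  expect_identical(psnr(a, a), Inf)

  # data_range 1, mse 0.01 -> 20 dB: constant error of 0.1 everywhere
  ref <- matrix(c(0, 1, rep(0.5, 62)), 8, 8)
  test_img <- ref + 0.1
  expect_equal(psnr(ref, test_img), 20)

  base <- one_record()
  clean <- sino_data(base$clean)
  noise <- rand_mat(nrow(clean), ncol(clean), seed = 2)
  vals <- vapply(c(1, 1.5, 2.5, 4), function(k) {
    psnr(clean, clean + k * noise)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))

  expect_error(psnr(matrix(0, 2, 2), matrix(0, 3, 2)), "equal shapes")
})

test_that("ssim is bounded, symmetric and degrades with noise", {
  a <- make_phantom(32, seed = 8)
  expect_equal(ssim(a, a), 1)

  weak <- a + 0.02 * rand_mat(32, 32, seed = 1)
  strong <- a + 0.3 * rand_mat(32, 32, seed = 1)
  expect_lt(ssim(a, strong), ssim(a, weak))
  expect_equal(ssim(a, strong), ssim(strong, a))
  expect_lte(ssim(a, strong), 1)

  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "window")
  expect_error(ssim(a, a[, 1:16]), "equal shapes")
})

test_that("evaluate ranks an oracle corrector at the ceiling", {
  ds <- tiny_dataset()
  test_recs <- ds$test
  oracle_env <- new.env(); oracle_env$i <- 0L
  methods <- list(
    oracle = function(s) {
      # match the incoming corrupted sinogram back to its record
      for (r in test_recs) {
        if (isTRUE(all.equal(sino_data(r$corrupted), sino_data(s)))) {
          return(r$clean)
        }
      }
      stop("unmatched sinogram")
    })
  rep <- evaluate(methods, test_recs, bins = 2, reconstruct = FALSE)
  expect_equal(nrow(rep$samples), 2 * length(test_recs))
  by_m <- glance(rep)
  expect_equal(by_m$ssim_sino[by_m$method == "oracle"], 1)
  s_or <- rep$samples[rep$samples$method == "oracle", ]
  expect_true(all(!is.finite(s_or$psnr_sino)))  # identical pairs -> Inf
})

test_that("evaluate tolerates per-sample method failures", {
  ds <- tiny_dataset()
  methods <- list(broken = function(s) stop("boom"))
  rep <- evaluate(methods, ds$test[1:2], reconstruct = FALSE)
  br <- rep$samples[rep$samples$method == "broken", ]
  expect_true(all(br$error == "boom"))
  idp <- rep$samples[rep$samples$method == "identity", ]
  expect_true(all(is.na(idp$error)))
})

test_that("identity on artifact-free records hits the sentinel values", {
  s <- one_record()$clean
  r0 <- add_stripes(s, stripe_spec(amplitude_range = c(0, 0), seed = 1))
  rep <- evaluate(list(), list(r0), reconstruct = FALSE)
  row <- rep$samples
  expect_identical(row$psnr_sino, Inf)
  expect_equal(row$ssim_sino, 1)
})

test_that("slice-level metrics are computed inside the support circle", {
  ds <- tiny_dataset()
  rep <- evaluate(list(), ds$test[1:2], reconstruct = TRUE)
  expect_true(all(is.finite(rep$samples$psnr_slice)))
  expect_true(all(rep$samples$ssim_slice >= 0 & rep$samples$ssim_slice <= 1))
})

test_that("evaluation reports round-trip through CSV + JSON", {
  ds <- tiny_dataset()
  rep <- evaluate(list(fw = function(s) fw_destripe(s, fw_params(decomposition_levels = 2))),
                  ds$test, bins = 2, reconstruct = FALSE)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_report(rep, csv, js)
  back <- read_report(csv, js)
  expect_equal(as.data.frame(back$samples[, -4]),
               as.data.frame(rep$samples[, -4]), tolerance = 1e-12)
  expect_equal(as.character(back$samples$degradation_bin),
               as.character(rep$samples$degradation_bin))
  expect_equal(back$aggregates$psnr_sino_mean, rep$aggregates$psnr_sino_mean,
               tolerance = 1e-12)
  expect_s3_class(autoplot(rep), "ggplot")
})
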