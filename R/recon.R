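#' Filtered back projection reconstruction
#'
#' Standard parallel-beam FBP: each projection row is convolved with the
#' band-limited ramp filter (applied in the frequency domain, optionally
#' apodized), then smeared back across the image along its ray direction
#' with linear interpolation. The output is square with side equal to the
#' detector count.
#'
#' @param s A [sinogram()] with at least 2 ascending angles in
#'   `[0, 180)`.
#' @param filter_name `"ramp"`, `"shepp-logan"`, `"hann"` or `"hamming"`.
#' @return Reconstructed slice as a square numeric matrix.
#' @export
fbp <- function(s, filter_name = "ramp") {
  stopifnot(is_sinogram(s))
  ang <- angles(s)
  if (length(ang) < 2L) stop("fbp needs at least 2 angles", call. = FALSE)
  if (any(ang < 0 | ang >= 180)) {
    stop("fbp expects angles in [0, 180) degrees", call. = FALSE)
  }
  p <- sino_data(s)
  n_det <- ncol(p)
  filt <- fbp_filter(n_det, filter_name)
  L <- length(filt)
  # filter every projection row (rows of p), zero-padded to length L
  P <- matrix(0, nrow(p), L)
  P[, seq_len(n_det)] <- p
  Q <- t(apply(P, 1L, function(row) {
    Re(stats::fft(stats::fft(row) * filt, inverse = TRUE)) / L
  }))[, seq_len(n_det), drop = FALSE]
  cx <- (n_det - 1) / 2
  xs <- (0:(n_det - 1)) - cx
  X <- matrix(xs, n_det, n_det, byrow = TRUE)
  Y <- matrix(xs, n_det, n_det)
  recon <- matrix(0, n_det, n_det)
  d_theta <- pi / 180 * mean(diff(ang))
  for (ai in seq_along(ang)) {
    th <- ang[ai] * pi / 180
    tpos <- X * cos(th) + Y * sin(th) + cx  # detector coordinate, 0-based
    t0 <- floor(tpos); ft <- tpos - t0
    q <- Q[ai, ]
    get_q <- function(idx) {
      v <- numeric(length(idx))
      ok <- idx >= 0 & idx <= n_det - 1
      v[ok] <- q[idx[ok] + 1]
      v
    }
    recon <- recon + matrix((1 - ft) * get_q(t0) + ft * get_q(t0 + 1),
                            n_det, n_det)
  }
  recon * d_theta
}

# Frequency response of the discrete band-limited ramp (Kak & Slaney
# real-space kernel transformed), times an optional apodization window.
fbp_filter <- function(n_det, filter_name) {
  known <- c("ramp", "shepp-logan", "hann", "hamming")
  if (!filter_name %in% known) {
    stop("unknown FBP filter '", filter_name, "'; available: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  L <- 2^ceiling(log2(2L * n_det))
  h <- numeric(L)
  h[1] <- 0.25
  k <- seq(1L, L / 2, by = 2L)                  # odd lags
  h[1 + k] <- -1 / (pi * k)^2
  h[L + 1 - k] <- -1 / (pi * k)^2               # symmetric negative lags
  H <- Re(stats::fft(h))
  f <- c(seq(0, L / 2), seq(L / 2 - 1, 1)) / L  # cycles/sample per bin
  w <- switch(filter_name,
    ramp = rep(1, L),
    `shepp-logan` = { x <- pi * f / (2 * max(f)); ifelse(x == 0, 1, sin(x) / x) },
    hann = 0.5 * (1 + cos(pi * f / max(f))),
    hamming = 0.54 + 0.46 * cos(pi * f / max(f)))
  H * w
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / mse)` in dB; higher means fewer artifacts.
#' Identical images return `Inf` (the sentinel for a zero-error pair).
#'
#' @param reference,test Equal-shaped numeric arrays; the first argument
#'   is the ground truth.
#' @param data_range Peak-to-peak intensity range; defaults to the
#'   reference's `max - min`. Pass a fixed value for cross-sample
#'   comparability.
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test, data_range = NULL) {
  reference <- as_matrix2d(reference, "psnr reference")
  test <- as_matrix2d(test, "psnr test")
  err <- mse(reference, test)
  if (err == 0) return(Inf)
  if (is.null(data_range)) data_range <- diff(range(reference))
  if (data_range <= 0) stop("data_range must be positive", call. = FALSE)
  10 * log10(data_range^2 / err)
}

#' Structural similarity index
#'
#' Mean local SSIM with the standard Gaussian window (11 x 11, sigma 1.5)
#' and stabilizing constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` where
#' `L` is the data range. Computed over the fully valid interior (no
#' boundary padding). Identical images give 1.
#'
#' @param reference,test Equal-shaped numeric matrices, at least the
#'   window size in each dimension.
#' @param data_range Intensity range `L`; defaults to the larger of the
#'   two images' ranges (making the measure symmetric by default).
#' @param window_size,window_sigma Gaussian window parameters.
#' @return Mean SSIM (<= 1; can be negative for anti-correlated
#'   structure).
#' @export
ssim <- function(reference, test, data_range = NULL,
                 window_size = 11L, window_sigma = 1.5) {
  x <- as_matrix2d(reference, "ssim reference")
  y <- as_matrix2d(test, "ssim test")
  if (!identical(dim(x), dim(y))) stop("ssim requires equal shapes", call. = FALSE)
  if (any(dim(x) < window_size)) {
    stop("image smaller than the ", window_size, "x", window_size,
         " SSIM window", call. = FALSE)
  }
  if (is.null(data_range)) {
    data_range <- max(diff(range(x)), diff(range(y)))
    if (data_range == 0) data_range <- 1
  }
  g <- stats::dnorm(seq_len(window_size) - (window_size + 1) / 2,
                    sd = window_sigma)
  g <- g / sum(g)
  f <- function(m) gauss_filter_valid(m, g)
  mu_x <- f(x); mu_y <- f(y)
  sxx <- f(x * x) - mu_x^2
  syy <- f(y * y) - mu_y^2
  sxy <- f(x * y) - mu_x * mu_y
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  s <- ((2 * mu_x * mu_y + c1) * (2 * sxy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2))
  mean(s)
}

# Separable valid-region Gaussian filtering (no padding).
gauss_filter_valid <- function(m, g) {
  k <- length(g)
  h <- nrow(m) - k + 1L
  out <- matrix(0, h, ncol(m))
  for (i in seq_len(k)) out <- out + g[i] * m[i:(i + h - 1L), , drop = FALSE]
  w <- ncol(out) - k + 1L
  out2 <- matrix(0, h, w)
  for (j in seq_len(k)) out2 <- out2 + g[j] * out[, j:(j + w - 1L), drop = FALSE]
  out2
}

# Mask selecting the inscribed reconstruction support circle; slice
# metrics are computed inside it only (outside is FBP geometry artifact).
support_mask <- function(n) {
  cx <- (n - 1) / 2
  xs <- (0:(n - 1)) - cx
  outer(xs, xs, function(y, x) x^2 + y^2 <= cx^2)
}

masked_metrics <- function(reference, test, mask) {
  ref_v <- reference; test_v <- test
  ref_v[!mask] <- 0; test_v[!mask] <- 0
  err <- sum((ref_v - test_v)^2) / sum(mask)
  rng <- diff(range(reference[mask]))
  p <- if (err == 0) Inf else if (rng > 0) 10 * log10(rng^2 / err) else NA_real_
  list(psnr = p, ssim = ssim(ref_v, test_v))
}

#' Evaluate correction methods on a test split
#'
#' The quantitative comparison protocol: every method corrects every
#' corrupted test sinogram; PSNR and SSIM against the clean counterpart
#' are computed on the sinograms and, after FBP of both, on the
#' reconstructed slices (inside the support circle). Samples are binned by
#' their degradation PSNR (artifact severity) and aggregated per method
#' and bin. The identity method ("no correction") is always included as
#' the floor.
#'
#' @param methods Named list of functions, each mapping a corrupted
#'   [sinogram()] to a corrected one. An `identity` entry is added if
#'   missing.
#' @param test_split List of `sample_record`s.
#' @param bins Number of degradation bins (quantile-based), or a numeric
#'   vector of bin edges in dB.
#' @param reconstruct If `FALSE`, skip the slice-level (FBP) metrics.
#' @param filter_name FBP filter for the slice metrics.
#' @return An `evaluation_report`: list with per-sample tibble `samples`,
#'   per-bin tibble `aggregates`, and `meta`. [tidy()] returns `samples`,
#'   [glance()] the per-method means.
#' @export
evaluate <- function(methods, test_split, bins = 3L, reconstruct = TRUE,
                     filter_name = "ramp") {
  stopifnot(length(test_split) > 0L)
  if (!is.list(methods)) stop("methods must be a named list of functions", call. = FALSE)
  if (!"identity" %in% names(methods)) {
    methods <- c(list(identity = function(s) s), methods)
  }
  deg <- vapply(test_split, degradation_psnr, numeric(1))
  deg_bin <- bin_labels(deg, bins)
  rows <- purrr::imap(methods, function(fn, method_name) {
    purrr::imap(test_split, function(rec, i) {
      corrected <- tryCatch(fn(rec$corrupted), error = function(e) e)
      if (inherits(corrected, "error")) {
        return(tibble::tibble(method = method_name, sample = i,
                              degradation_db = deg[i], degradation_bin = deg_bin[i],
                              psnr_sino = NA_real_, ssim_sino = NA_real_,
                              psnr_slice = NA_real_, ssim_slice = NA_real_,
                              error = conditionMessage(corrected)))
      }
      clean <- sino_data(rec$clean)
      cor_m <- sino_data(corrected)
      p_s <- psnr(clean, cor_m)
      s_s <- ssim(clean, cor_m)
      p_r <- NA_real_; s_r <- NA_real_
      if (reconstruct) {
        ref_slice <- fbp(rec$clean, filter_name)
        test_slice <- fbp(corrected, filter_name)
        mm <- masked_metrics(ref_slice, test_slice, support_mask(nrow(ref_slice)))
        p_r <- mm$psnr; s_r <- mm$ssim
      }
      tibble::tibble(method = method_name, sample = i,
                     degradation_db = deg[i], degradation_bin = deg_bin[i],
                     psnr_sino = p_s, ssim_sino = clip01(s_s),
                     psnr_slice = p_r, ssim_slice = clip01(s_r),
                     error = NA_character_)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  aggregates <- rows |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::group_by(.data$method, .data$degradation_bin) |>
    dplyr::summarise(dplyr::across(
      c("psnr_sino", "ssim_sino", "psnr_slice", "ssim_slice"),
      list(mean = ~ mean(.x[is.finite(.x)]),
           sd = ~ stats::sd(.x[is.finite(.x)]))),
      n = dplyr::n(), .groups = "drop")
  structure(list(samples = rows, aggregates = aggregates,
                 meta = list(n_samples = length(test_split),
                             methods = names(methods),
                             bins = bins, reconstruct = reconstruct,
                             filter_name = filter_name)),
            class = "evaluation_report")
}

clip01 <- function(x) ifelse(is.na(x), x, pmin(pmax(x, 0), 1))

bin_labels <- function(deg, bins) {
  finite <- is.finite(deg)
  if (length(bins) == 1L) {
    if (!any(finite) || length(unique(deg[finite])) < bins) {
      return(factor(rep("all", length(deg))))
    }
    edges <- unique(stats::quantile(deg[finite], probs = seq(0, 1, length.out = bins + 1)))
    if (length(edges) < 3L) return(factor(rep("all", length(deg))))
  } else {
    edges <- sort(unique(bins))
  }
  cut(deg, breaks = edges, include.lowest = TRUE,
      labels = sprintf("%.1f-%.1f dB", utils::head(edges, -1), edges[-1]))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d methods x %d samples\n",
              length(x$meta$methods), x$meta$n_samples))
  print(glance(x))
  invisible(x)
}

#' @rdname evaluate
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @export
tidy.evaluation_report <- function(x, ...) x$samples

#' @rdname evaluate
#' @export
glance.evaluation_report <- function(x, ...) {
  x$samples |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(dplyr::across(
      c("psnr_sino", "ssim_sino", "psnr_slice", "ssim_slice"),
      ~ mean(.x[is.finite(.x)])), n = dplyr::n(), .groups = "drop")
}

#' Write / read an evaluation report
#'
#' Per-sample rows go to CSV, aggregates and metadata to JSON; the pair
#' round-trips losslessly through [read_report()].
#'
#' @param report An `evaluation_report`.
#' @param csv_path,json_path Output paths.
#' @return `write_report()`: the paths, invisibly. `read_report()`: the
#'   `evaluation_report`.
#' @export
write_report <- function(report, csv_path, json_path) {
  utils::write.csv(report$samples, csv_path, row.names = FALSE)
  jsonlite::write_json(list(aggregates = report$aggregates, meta = report$meta),
                       json_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(csv = csv_path, json = json_path))
}

#' @rdname write_report
#' @export
read_report <- function(csv_path, json_path) {
  samples <- tibble::as_tibble(utils::read.csv(csv_path)) |>
    dplyr::mutate(dplyr::across(
      c("psnr_sino", "ssim_sino", "psnr_slice", "ssim_slice"), as.numeric),
      degradation_bin = factor(.data$degradation_bin),
      error = as.character(.data$error))
  js <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  structure(list(samples = samples,
                 aggregates = tibble::as_tibble(js$aggregates) |>
                   dplyr::mutate(degradation_bin = factor(.data$degradation_bin)),
                 meta = js$meta),
            class = "evaluation_report")
}
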