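#' Evenly spaced projection angles
#'
#' Default acquisition geometry: 360 projections over 0 to 179.5 degrees
#' (0.5 degree spacing), the protocol used to build the synthetic dataset.
#'
#' @param n Number of angles (>= 2).
#' @param start,stop First and last angle in degrees, both included.
#' @return Numeric vector of `n` equally spaced angles.
#' @export
#' @examples
#' a <- default_angles()
#' diff(a)[1] # 0.5 degrees
default_angles <- function(n = 360L, start = 0, stop = 179.5) {
  if (n < 2L) stop("at least 2 projection angles are required", call. = FALSE)
  seq(start, stop, length.out = n)
}

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Sub-seeds derived from one master seed, kept below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Seeded random grayscale phantom
#'
#' Generates a square grayscale test image of overlapping ellipses and
#' rectangles with smooth intensity ramps, confined to the inscribed
#' circular support (the region a parallel-beam scan actually covers).
#' Values lie in `[0, 1]` and the image is a deterministic function of its
#' arguments. These phantoms stand in for natural-image slice sources when
#' building synthetic sinogram datasets; [load_image_folder()] accepts
#' user-supplied images instead.
#'
#' @param size_px Image side length in pixels (>= 16).
#' @param n_shapes Number of random shapes to overlay (0 gives the empty
#'   support).
#' @param seed Integer seed.
#' @return `size_px` x `size_px` numeric matrix in `[0, 1]`.
#' @export
make_phantom <- function(size_px, n_shapes = 8L, seed = 1L) {
  if (size_px < 16L) {
    stop("phantom size_px must be at least 16 (got ", size_px, ")",
         call. = FALSE)
  }
  if (n_shapes < 0L) stop("n_shapes must be non-negative", call. = FALSE)
  cx <- (size_px - 1) / 2
  xs <- ((0:(size_px - 1)) - cx) / cx   # [-1, 1]
  X <- matrix(xs, size_px, size_px, byrow = TRUE)  # column coordinate
  Y <- matrix(xs, size_px, size_px)                # row coordinate
  img <- matrix(0, size_px, size_px)
  with_seed(seed, {
    for (k in seq_len(n_shapes)) {
      type <- sample(c("ellipse", "rectangle"), 1L)
      ccx <- stats::runif(1, -0.55, 0.55)
      ccy <- stats::runif(1, -0.55, 0.55)
      ax <- stats::runif(1, 0.08, 0.45)
      ay <- stats::runif(1, 0.08, 0.45)
      th <- stats::runif(1, 0, pi)
      amp <- stats::runif(1, -0.5, 1)
      ramp_dir <- stats::runif(1, 0, 2 * pi)
      u <- (X - ccx) * cos(th) + (Y - ccy) * sin(th)
      v <- -(X - ccx) * sin(th) + (Y - ccy) * cos(th)
      inside <- if (type == "ellipse") {
        d2 <- (u / ax)^2 + (v / ay)^2
        pmax(0, 1 - d2)           # smooth parabolic ramp to the edge
      } else {
        (abs(u) <= ax) * (abs(v) <= ay) *
          (0.6 + 0.4 * (cos(ramp_dir) * u / ax + sin(ramp_dir) * v / ay))
      }
      img <- img + amp * inside
    }
  })
  img <- pmin(pmax(img, 0), 1)
  img[X^2 + Y^2 > 1] <- 0
  img
}

#' Seeded smooth (band-limited) phantom
#'
#' Sum of broad Gaussian blobs tapered to zero at the edge of the
#' circular support: a test image with essentially no high-frequency
#' content. Used to measure the resolution cost of destriping filters on
#' stripe-free smooth content, where an ideal filter should change
#' nothing.
#'
#' @param size_px Image side length in pixels (>= 16).
#' @param n_blobs Number of Gaussian blobs.
#' @param seed Integer seed.
#' @return `size_px` x `size_px` non-negative numeric matrix.
#' @export
make_smooth_phantom <- function(size_px, n_blobs = 6L, seed = 1L) {
  if (size_px < 16L) {
    stop("phantom size_px must be at least 16 (got ", size_px, ")",
         call. = FALSE)
  }
  cx <- (size_px - 1) / 2
  xs <- ((0:(size_px - 1)) - cx) / cx
  X <- matrix(xs, size_px, size_px, byrow = TRUE)
  Y <- matrix(xs, size_px, size_px)
  img <- matrix(0, size_px, size_px)
  with_seed(seed, {
    for (i in seq_len(n_blobs)) {
      ccx <- stats::runif(1, -0.5, 0.5)
      ccy <- stats::runif(1, -0.5, 0.5)
      sg <- stats::runif(1, 0.15, 0.4)
      amp <- stats::runif(1, 0.2, 1)
      img <- img + amp * exp(-((X - ccx)^2 + (Y - ccy)^2) / (2 * sg^2))
    }
  })
  img * exp(-pmax(0, sqrt(X^2 + Y^2) - 0.85)^2 / (2 * 0.05^2))
}

#' Parallel-beam Radon transform
#'
#' Computes line integrals of a square image over the inscribed-circle
#' support, one projection row per angle. Rays are sampled at unit pixel
#' steps with bilinear interpolation, so each projection row's sum matches
#' the total image mass to within discretization error (about 1%).
#'
#' @param image Square numeric matrix.
#' @param angles_deg Ascending projection angles in degrees, within
#'   `[0, 180)`.
#' @return A [sinogram()] with `length(angles_deg)` rows and `nrow(image)`
#'   detector columns.
#' @export
radon <- function(image, angles_deg) {
  image <- as_matrix2d(image)
  n <- nrow(image)
  if (ncol(image) != n) {
    stop("radon requires a square image (got ", n, " x ", ncol(image), ")",
         call. = FALSE)
  }
  if (any(angles_deg < 0 | angles_deg >= 180)) {
    stop("projection angles must lie in [0, 180) degrees", call. = FALSE)
  }
  cx <- (n - 1) / 2
  xs <- (0:(n - 1)) - cx
  # restrict to the inscribed circle: outside it rays exit the image and
  # the transform would not be invertible
  mask <- outer(xs, xs, function(y, x) x^2 + y^2 <= cx^2)
  img <- image * mask
  tt <- rep(xs, each = n)   # detector coordinate, varies slowly
  ss <- rep(xs, times = n)  # position along the ray
  out <- matrix(0, length(angles_deg), n)
  for (ai in seq_along(angles_deg)) {
    th <- angles_deg[ai] * pi / 180
    px <- tt * cos(th) - ss * sin(th)
    py <- tt * sin(th) + ss * cos(th)
    vals <- bilinear_lookup(img, py + cx, px + cx)
    out[ai, ] <- colSums(matrix(vals, n, n))
  }
  sinogram(out, angles_deg = angles_deg)
}

# Bilinear interpolation of matrix `img` at fractional (row0, col0)
# positions given in 0-based coordinates; zero outside the image.
bilinear_lookup <- function(img, ri, ci) {
  n <- nrow(img); m <- ncol(img)
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  val <- numeric(length(ri))
  get_px <- function(r, c) {
    ok <- r >= 0 & r <= n - 1 & c >= 0 & c <= m - 1
    v <- numeric(length(r))
    v[ok] <- img[cbind(r[ok] + 1, c[ok] + 1)]
    v
  }
  val <- (1 - fr) * (1 - fc) * get_px(r0, c0) +
    (1 - fr) * fc * get_px(r0, c0 + 1) +
    fr * (1 - fc) * get_px(r0 + 1, c0) +
    fr * fc * get_px(r0 + 1, c0 + 1)
  val
}

#' Stripe artifact specification
#'
#' Describes the random stripe population injected into clean sinograms.
#' Most detector-defect stripes observed in practice are one to a few
#' pixels wide; a fraction of them span only part of the angular range
#' (semi-ring artifacts). Amplitudes are expressed as a fraction of the
#' clean sinogram's dynamic range.
#'
#' @param n_stripes_range Integer interval for the stripe count per
#'   sinogram.
#' @param width_range_px Integer interval of stripe widths in detector
#'   pixels (>= 1).
#' @param amplitude_range Interval of absolute stripe amplitudes as a
#'   fraction of the sinogram's dynamic range; each stripe's sign is random.
#' @param partial_fraction Probability in `[0, 1]` that a stripe spans only
#'   a contiguous angular sub-range.
#' @param mode `"additive"` (constant offset) or `"multiplicative"`
#'   (constant gain `1 +/- amplitude`).
#' @param seed Default integer seed used by [add_stripes()].
#' @return A `stripe_spec` list.
#' @export
stripe_spec <- function(n_stripes_range = c(5L, 30L),
                        width_range_px = c(1L, 3L),
                        amplitude_range = c(0.02, 0.15),
                        partial_fraction = 0.3,
                        mode = c("additive", "multiplicative"),
                        seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(n_stripes_range) == 2L, length(width_range_px) == 2L,
            length(amplitude_range) == 2L)
  if (diff(n_stripes_range) < 0 || diff(width_range_px) < 0 ||
      diff(amplitude_range) < 0) {
    stop("stripe_spec ranges must be non-empty (lo <= hi)", call. = FALSE)
  }
  if (width_range_px[1] < 1) stop("stripe widths must be >= 1 px", call. = FALSE)
  if (partial_fraction < 0 || partial_fraction > 1) {
    stop("partial_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_stripes_range = as.integer(n_stripes_range),
                 width_range_px = as.integer(width_range_px),
                 amplitude_range = as.numeric(amplitude_range),
                 partial_fraction = partial_fraction,
                 mode = mode, seed = as.integer(seed)),
            class = "stripe_spec")
}

sample_in_range <- function(range) {
  if (range[1] == range[2]) return(range[1])
  sample(seq(range[1], range[2]), 1L)
}

#' Inject random stripe artifacts into a clean sinogram
#'
#' Draws a random population of constant-column stripes (full-length rings
#' or partial-length semi-rings) per `spec` and applies them to the clean
#' sinogram, returning the paired training record: clean and corrupted
#' sinograms, the artifact field, and the Haar-domain coefficients of all
#' three. The artifact's wavelet coefficients
#' (`corrupted_coeffs - clean_coeffs`) are the network's training label.
#'
#' @param s Clean [sinogram()].
#' @param spec A [stripe_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return A `sample_record` list with elements `clean`, `corrupted`,
#'   `artifact_field`, `clean_coeffs`, `corrupted_coeffs`,
#'   `artifact_coeffs`, `pad`, and `meta`.
#' @export
add_stripes <- function(s, spec = stripe_spec(), seed = spec$seed) {
  stopifnot(is_sinogram(s), inherits(spec, "stripe_spec"))
  clean <- sino_data(s)
  n_ang <- nrow(clean); n_det <- ncol(clean)
  if (spec$width_range_px[2] >= n_det) {
    stop("stripe width must be smaller than the detector count (", n_det, ")",
         call. = FALSE)
  }
  dyn <- diff(range(clean))
  field <- matrix(0, n_ang, n_det)
  gain <- matrix(1, n_ang, n_det)
  stripes <- list()
  with_seed(seed, {
    n_stripes <- sample_in_range(spec$n_stripes_range)
    for (k in seq_len(n_stripes)) {
      width <- sample_in_range(spec$width_range_px)
      col0 <- sample.int(n_det - width + 1L, 1L)
      cols <- col0:(col0 + width - 1L)
      amp <- stats::runif(1, spec$amplitude_range[1], spec$amplitude_range[2])
      sgn <- sample(c(-1, 1), 1L)
      partial <- stats::runif(1) < spec$partial_fraction
      rows <- if (partial) {
        ends <- sort(sample.int(n_ang, 2L))
        ends[1]:ends[2]
      } else {
        seq_len(n_ang)
      }
      if (spec$mode == "additive") {
        field[rows, cols] <- field[rows, cols] + sgn * amp * dyn
      } else {
        gain[rows, cols] <- gain[rows, cols] * (1 + sgn * amp)
      }
      stripes[[k]] <- list(cols = cols, partial = partial,
                           amplitude = sgn * amp)
    }
  })
  corrupted_mat <- if (spec$mode == "additive") clean + field else clean * gain
  if (spec$mode == "multiplicative") field <- corrupted_mat - clean
  corrupted <- restamp_sinogram(corrupted_mat, s)
  pc <- pad_to_even(clean)
  pcor <- pad_to_even(corrupted_mat)
  clean_coeffs <- hdwt(pc$image)
  corrupted_coeffs <- hdwt(pcor$image)
  structure(list(
    clean = s,
    corrupted = corrupted,
    artifact_field = field,
    clean_coeffs = clean_coeffs,
    corrupted_coeffs = corrupted_coeffs,
    artifact_coeffs = coeffs_map2(corrupted_coeffs, clean_coeffs, `-`),
    pad = pc$pad,
    meta = list(seed = seed, spec = spec, n_stripes = length(stripes),
                stripes = stripes)
  ), class = "sample_record")
}

#' @export
print.sample_record <- function(x, ...) {
  cat(sprintf("<sample_record> %d x %d sinogram, %d stripes, degradation %.2f dB\n",
              nrow(x$clean), ncol(x$clean), x$meta$n_stripes,
              degradation_psnr(x)))
  invisible(x)
}

#' Severity of the injected artifacts
#'
#' PSNR of the corrupted sinogram against its clean counterpart, used to
#' bin test samples by artifact strength when reporting correction quality.
#' Higher is milder; identical sinograms give `Inf`.
#'
#' @param record A `sample_record` from [add_stripes()].
#' @return PSNR in dB.
#' @export
degradation_psnr <- function(record) {
  psnr(record$clean, record$corrupted)
}

#' Build a paired synthetic train/test dataset
#'
#' Full synthetic-data protocol: seeded phantoms are Radon-transformed into
#' clean sinograms, random stripes are injected, and the records are split
#' at random into train and test sets. At full protocol scale
#' (`n_total = 824`, 512 px images, 360 angles, `train_fraction = 712/824`)
#' this yields the 712/112 split; the defaults here are the package-scale
#' study conditions (200 records, 64 px phantoms, 90 angles).
#'
#' @param n_total Total number of sample records (>= 2).
#' @param train_fraction Fraction assigned to the training split, in (0,1).
#' @param size_px Phantom side length in pixels.
#' @param n_shapes Shapes per phantom.
#' @param angles Projection angles in degrees.
#' @param spec A [stripe_spec()].
#' @param seed Master seed; every phantom, stripe draw and the split
#'   permutation derive from it.
#' @return A `sino_dataset` list with `train` and `test` lists of
#'   `sample_record`s and a `meta` list.
#' @export
build_dataset <- function(n_total = 200L, train_fraction = 0.8,
                          size_px = 64L, n_shapes = 8L,
                          angles = default_angles(90L),
                          spec = stripe_spec(), seed = 1L) {
  if (n_total < 2L) stop("n_total must be at least 2", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  n_train <- round(n_total * train_fraction)
  if (n_train < 1L || n_train > n_total - 1L) {
    stop("degenerate split: ", n_train, " train of ", n_total, call. = FALSE)
  }
  seeds <- derive_seeds(seed, 2L * n_total + 1L)
  phantom_seeds <- seeds[seq_len(n_total)]
  stripe_seeds <- seeds[n_total + seq_len(n_total)]
  perm <- with_seed(seeds[2L * n_total + 1L], sample.int(n_total))
  records <- purrr::map(seq_len(n_total), function(i) {
    ph <- make_phantom(size_px, n_shapes = n_shapes, seed = phantom_seeds[i])
    add_stripes(radon(ph, angles), spec, seed = stripe_seeds[i])
  })
  train_idx <- sort(perm[seq_len(n_train)])
  test_idx <- sort(perm[-seq_len(n_train)])
  structure(list(
    train = records[train_idx],
    test = records[test_idx],
    meta = list(n_total = n_total, train_fraction = train_fraction,
                size_px = size_px, n_shapes = n_shapes, angles = angles,
                spec = spec, seed = seed,
                train_idx = train_idx, test_idx = test_idx)
  ), class = "sino_dataset")
}

#' @export
print.sino_dataset <- function(x, ...) {
  cat(sprintf("<sino_dataset> %d train / %d test records (%d x %d sinograms, seed %d)\n",
              length(x$train), length(x$test), nrow(x$train[[1]]$clean),
              ncol(x$train[[1]]$clean), x$meta$seed))
  invisible(x)
}

#' Load user-supplied grayscale images as phantom sources
#'
#' Alternative to [make_phantom()] for users who have a natural-image
#' corpus: reads every TIFF/PNG in a folder, converts to grayscale,
#' center-crops to a square of `size_px`, and rescales to `[0, 1]`.
#'
#' @param path Directory of `.tif`/`.tiff`/`.png` images.
#' @param size_px Output side length; images smaller than this are
#'   rejected.
#' @return List of `size_px` x `size_px` matrices in `[0, 1]`.
#' @export
load_image_folder <- function(path, size_px = 512L) {
  files <- sort(list.files(path, pattern = "\\.(tiff?|png)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) {
    stop("no TIFF/PNG images found under ", path, call. = FALSE)
  }
  purrr::map(files, function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
      png::readPNG(f)
    } else {
      tiff::readTIFF(f)
    }
    if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
    img <- as.matrix(img)
    if (nrow(img) < size_px || ncol(img) < size_px) {
      stop("image ", basename(f), " is smaller than size_px = ", size_px,
           call. = FALSE)
    }
    r0 <- floor((nrow(img) - size_px) / 2)
    c0 <- floor((ncol(img) - size_px) / 2)
    img <- img[r0 + seq_len(size_px), c0 + seq_len(size_px)]
    rng <- range(img)
    if (diff(rng) > 0) img <- (img - rng[1]) / diff(rng)
    img
  })
}
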