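# Orthogonal Daubechies filter banks (standard published scaling
# coefficients), periodized transform. "haar" is Daubechies-1.
daub_lo <- list(
  haar = c(1, 1) / sqrt(2),
  db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
  db4 = c(0.23037781330885523, 0.71484657055254153, 0.63088076792959036,
          -0.02798376941698385, -0.18703481171888114, 0.03084138183598697,
          0.03288301166698295, -0.01059740178499728)
)

wavelet_filters <- function(name) {
  if (!name %in% names(daub_lo)) {
    stop("unknown wavelet '", name, "'; available: ",
         paste(names(daub_lo), collapse = ", "), call. = FALSE)
  }
  h <- daub_lo[[name]]
  g <- rev(h) * (-1)^(seq_along(h) - 1)  # quadrature mirror filter
  list(lo = h, hi = g)
}

# One level of the periodized 1-D DWT applied down the rows of `m`
# (transforms each column). Returns approximation and detail halves.
dwt_step_rows <- function(m, filt) {
  L <- nrow(m)
  stopifnot(L %% 2L == 0L)
  k <- seq(0L, L / 2 - 1L)
  lo <- matrix(0, L / 2, ncol(m))
  hi <- matrix(0, L / 2, ncol(m))
  for (n in seq_along(filt$lo)) {
    idx <- (2L * k + (n - 1L)) %% L + 1L
    lo <- lo + filt$lo[n] * m[idx, , drop = FALSE]
    hi <- hi + filt$hi[n] * m[idx, , drop = FALSE]
  }
  list(lo = lo, hi = hi)
}

idwt_step_rows <- function(lo, hi, filt) {
  Lh <- nrow(lo)
  L <- 2L * Lh
  out <- matrix(0, L, ncol(lo))
  k <- seq(0L, Lh - 1L)
  for (n in seq_along(filt$lo)) {
    # idx values are distinct within each n (stride-2 residues), so plain
    # indexed accumulation is safe
    idx <- (2L * k + (n - 1L)) %% L + 1L
    out[idx, ] <- out[idx, , drop = FALSE] +
      filt$lo[n] * lo + filt$hi[n] * hi
  }
  out
}

# Single-level separable 2-D DWT: rows (dim 1) then columns (dim 2).
# Band naming: ll (low/low), lh (low along rows, high along columns),
# hl (high along rows, low along columns), hh.
dwt2_step <- function(m, filt) {
  r <- dwt_step_rows(m, filt)
  lo_c <- dwt_step_rows(t(r$lo), filt)
  hi_c <- dwt_step_rows(t(r$hi), filt)
  list(ll = t(lo_c$lo), lh = t(lo_c$hi), hl = t(hi_c$lo), hh = t(hi_c$hi))
}

idwt2_step <- function(b, filt) {
  lo <- t(idwt_step_rows(t(b$ll), t(b$lh), filt))
  hi <- t(idwt_step_rows(t(b$hl), t(b$hh), filt))
  idwt_step_rows(lo, hi, filt)
}

#' Parameters of the combined wavelet-Fourier destriping filter
#'
#' @param decomposition_levels Number of DWT levels (>= 1).
#' @param damping_sigma Gaussian damping width in frequency bins (> 0);
#'   larger damps a wider low-frequency band, removing wider stripes at a
#'   higher resolution cost.
#' @param wavelet_name `"db4"` (default), `"db2"` or `"haar"`.
#' @param stripe_axis Axis the stripes run along (shared convention with
#'   [loss_config()]).
#' @return An `fw_params` list.
#' @export
fw_params <- function(decomposition_levels = 4L, damping_sigma = 2,
                      wavelet_name = "db4",
                      stripe_axis = c("angle", "detector")) {
  stripe_axis <- match.arg(stripe_axis)
  if (decomposition_levels < 1L) stop("need at least 1 level", call. = FALSE)
  if (damping_sigma <= 0) stop("damping_sigma must be positive", call. = FALSE)
  wavelet_filters(wavelet_name)  # validates the name
  structure(list(decomposition_levels = as.integer(decomposition_levels),
                 damping_sigma = damping_sigma, wavelet_name = wavelet_name,
                 stripe_axis = stripe_axis),
            class = "fw_params")
}

#' Combined wavelet-Fourier stripe removal (classical baseline)
#'
#' The widely used destriping filter that the learned corrector is
#' compared against: the sinogram is decomposed over several DWT levels;
#' in each level's detail band that condenses the stripes (high frequency
#' across the stripes, low frequency along them), a 1-D Fourier transform
#' is taken along the stripe axis and its low-frequency components are
#' damped by `1 - exp(-k^2 / (2 sigma^2))`; the result is
#' inverse-transformed and reconstructed. Effective for near-constant
#' stripes, but its parameters trade resolution against stripe residuals.
#'
#' @param s A [sinogram()] (even dimensions are handled by internal
#'   replicate padding).
#' @param p An [fw_params()].
#' @return The destriped [sinogram()], same shape as the input.
#' @export
fw_destripe <- function(s, p = fw_params()) {
  stopifnot(is_sinogram(s))
  filt <- wavelet_filters(p$wavelet_name)
  pad <- pad_to_even(sino_data(s))
  m <- pad$image
  work <- if (p$stripe_axis == "angle") m else t(m)
  # every level's input band must be at least the filter length
  min_side <- min(dim(work))
  if (min_side / 2^(p$decomposition_levels - 1) < length(filt$lo)) {
    stop("decomposition_levels = ", p$decomposition_levels,
         " is too deep for a ", nrow(m), " x ", ncol(m), " sinogram",
         call. = FALSE)
  }
  details <- vector("list", p$decomposition_levels)
  level_pads <- vector("list", p$decomposition_levels)
  for (lev in seq_len(p$decomposition_levels)) {
    lp <- pad_to_even(work)        # odd intermediate sizes: replicate-pad
    level_pads[[lev]] <- lp$pad
    b <- dwt2_step(lp$image, filt)
    # stripes run along dim 1 (rows): constant along rows, sharp across
    # columns -> low-pass along rows, high-pass along columns = band "lh"
    b$lh <- damp_low_freq(b$lh, p$damping_sigma)
    details[[lev]] <- b[c("lh", "hl", "hh")]
    work <- b$ll
  }
  for (lev in rev(seq_len(p$decomposition_levels))) {
    b <- details[[lev]]
    b$ll <- work
    work <- crop_pad(idwt2_step(b, filt), level_pads[[lev]])
  }
  out <- if (p$stripe_axis == "angle") work else t(work)
  restamp_sinogram(crop_pad(out, pad$pad), s)
}

# FFT down each column; damp low (along-stripe) frequencies with the
# Gaussian notch 1 - exp(-k^2 / (2 sigma^2)); DC (a perfectly constant
# stripe) is removed entirely.
damp_low_freq <- function(band, sigma) {
  L <- nrow(band)
  k <- c(seq(0, floor(L / 2)), seq(ceiling(L / 2) - 1, 1))[seq_len(L)]
  damp <- 1 - exp(-k^2 / (2 * sigma^2))
  spec <- stats::mvfft(band)
  Re(stats::mvfft(spec * damp, inverse = TRUE)) / L
}
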