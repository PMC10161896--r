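#' Single-level 2-D Haar discrete wavelet transform
#'
#' Decomposes an image (or sinogram) with even height and width into four
#' half-resolution sub-bands: the approximation coefficient `WA` and the
#' horizontal, vertical and diagonal detail coefficients `WH`, `WV`, `WD`.
#' For each disjoint 2x2 block `[[p00, p01], [p10, p11]]`,
#' \deqn{WA = (p00+p01+p10+p11)/2, \quad WH = (p00+p01-p10-p11)/2,}
#' \deqn{WV = (p00-p01+p10-p11)/2, \quad WD = (p00-p01-p10+p11)/2.}
#' This is the orthonormal scaling: the transform preserves the sum of
#' squares, so mean-square errors measured in the wavelet domain are
#' commensurate with image-domain errors.
#'
#' @param x 2-D numeric matrix or [sinogram()] with even dimensions; use
#'   [pad_to_even()] first for odd sizes.
#' @return An object of class `wavelet_coeffs`: a list with equal-shaped
#'   matrices `WA`, `WH`, `WV`, `WD`, each of shape `(H/2, W/2)`.
#' @seealso [ihdwt()] for the exact inverse, [pad_to_even()].
#' @export
#' @examples
#' w <- hdwt(matrix(c(1, 3, 2, 4), 2, 2)) # [[1,2],[3,4]] in row-major terms
#' w$WA # 5
hdwt <- function(x) {
  x <- as_matrix2d(x)
  h <- nrow(x); w <- ncol(x)
  if (h %% 2L != 0L) {
    stop("hdwt requires an even number of rows (got ", h, ")", call. = FALSE)
  }
  if (w %% 2L != 0L) {
    stop("hdwt requires an even number of columns (got ", w, ")", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("hdwt input contains non-finite values", call. = FALSE)
  ro <- seq(1L, h, 2L); re <- ro + 1L
  co <- seq(1L, w, 2L); ce <- co + 1L
  p00 <- x[ro, co, drop = FALSE]; p01 <- x[ro, ce, drop = FALSE]
  p10 <- x[re, co, drop = FALSE]; p11 <- x[re, ce, drop = FALSE]
  structure(
    list(
      WA = (p00 + p01 + p10 + p11) / 2,
      WH = (p00 + p01 - p10 - p11) / 2,
      WV = (p00 - p01 + p10 - p11) / 2,
      WD = (p00 - p01 - p10 + p11) / 2
    ),
    class = "wavelet_coeffs"
  )
}

#' Inverse single-level 2-D Haar transform
#'
#' Exact algebraic inverse of [hdwt()]: four sub-bands of shape `(H', W')`
#' reconstruct the `(2H', 2W')` source to numerical precision.
#'
#' @param coeffs A `wavelet_coeffs` object (or a list with matrices
#'   `WA`, `WH`, `WV`, `WD` of one common shape).
#' @return A numeric matrix of shape `(2H', 2W')`.
#' @export
ihdwt <- function(coeffs) {
  coeffs <- as_wavelet_coeffs(coeffs)
  WA <- coeffs$WA; WH <- coeffs$WH; WV <- coeffs$WV; WD <- coeffs$WD
  h2 <- nrow(WA); w2 <- ncol(WA)
  out <- matrix(0, 2L * h2, 2L * w2)
  ro <- seq(1L, 2L * h2, 2L); re <- ro + 1L
  co <- seq(1L, 2L * w2, 2L); ce <- co + 1L
  out[ro, co] <- (WA + WH + WV + WD) / 2
  out[ro, ce] <- (WA + WH - WV - WD) / 2
  out[re, co] <- (WA - WH + WV - WD) / 2
  out[re, ce] <- (WA - WH - WV + WD) / 2
  out
}

band_names <- c("WA", "WH", "WV", "WD")

#' Coerce a list of four sub-bands to a `wavelet_coeffs` object
#'
#' Validates that all four bands are present and share one shape.
#'
#' @param x List with matrices `WA`, `WH`, `WV`, `WD`.
#' @return A `wavelet_coeffs` object.
#' @export
as_wavelet_coeffs <- function(x) {
  if (!all(band_names %in% names(x))) {
    stop("wavelet coefficients need the four sub-bands WA, WH, WV, WD",
         call. = FALSE)
  }
  x <- lapply(x[band_names], function(b) {
    b <- as.matrix(b); storage.mode(b) <- "double"; b
  })
  dims <- vapply(x, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all four wavelet sub-bands must share one shape", call. = FALSE)
  }
  structure(x, class = "wavelet_coeffs")
}

#' @export
print.wavelet_coeffs <- function(x, ...) {
  cat(sprintf("<wavelet_coeffs> four %d x %d sub-bands (WA, WH, WV, WD)\n",
              nrow(x$WA), ncol(x$WA)))
  invisible(x)
}

# Arithmetic on coefficient sets, band by band.
coeffs_map2 <- function(a, b, f) {
  as_wavelet_coeffs(lapply(stats::setNames(band_names, band_names),
                           function(nm) f(a[[nm]], b[[nm]])))
}

#' Replicate-pad an image so both dimensions are even
#'
#' Appends at most one replicated row and one replicated column. The
#' returned `pad` record allows exact cropping back with [crop_pad()].
#'
#' @param x 2-D numeric matrix.
#' @return List with the (possibly padded) `image` and an integer `pad`
#'   vector `c(bottom, right)` of zeros/ones.
#' @export
pad_to_even <- function(x) {
  x <- as_matrix2d(x)
  pad <- c(bottom = nrow(x) %% 2L, right = ncol(x) %% 2L)
  if (pad[["bottom"]] == 1L) x <- rbind(x, x[nrow(x), , drop = FALSE])
  if (pad[["right"]] == 1L) x <- cbind(x, x[, ncol(x), drop = FALSE])
  list(image = x, pad = pad)
}

#' @rdname pad_to_even
#' @param pad The pad record returned by [pad_to_even()].
#' @export
crop_pad <- function(x, pad) {
  x <- as_matrix2d(x)
  x[seq_len(nrow(x) - pad[["bottom"]]), seq_len(ncol(x) - pad[["right"]]),
    drop = FALSE]
}

# Stack four sub-bands into an H' x W' x 4 array (network input layout)
# and back. Channel order is WA, WH, WV, WD throughout the package.
coeffs_to_array <- function(coeffs) {
  coeffs <- as_wavelet_coeffs(coeffs)
  array(c(coeffs$WA, coeffs$WH, coeffs$WV, coeffs$WD),
        dim = c(dim(coeffs$WA), 4L))
}

array_to_coeffs <- function(a) {
  stopifnot(length(dim(a)) == 3L, dim(a)[3] == 4L)
  as_wavelet_coeffs(list(WA = a[, , 1], WH = a[, , 2],
                         WV = a[, , 3], WD = a[, , 4]))
}
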