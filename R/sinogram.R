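#' Sinogram objects
#'
#' A sinogram is a 2-D array of parallel-beam projection data with one row
#' per rotation angle and one column per detector pixel. Under this
#' convention a systematic detector-pixel error appears as a (possibly
#' partial) constant-column stripe, which maps to a ring (or semi-ring) in
#' the reconstructed slice.
#'
#' @param data Numeric matrix, rows = projection angles, columns = detector
#'   pixels. All values must be finite.
#' @param angles_deg Ascending numeric vector of projection angles in
#'   degrees, one per row of `data`.
#'
#' @return An object of class `sinogram`: the data matrix carrying an
#'   `angles_deg` attribute.
#' @export
#' @examples
#' s <- sinogram(matrix(0, 4, 8), angles_deg = c(0, 45, 90, 135))
#' angles(s)
sinogram <- function(data, angles_deg) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  angles_deg <- as.numeric(angles_deg)
  if (nrow(data) != length(angles_deg)) {
    stop("sinogram has ", nrow(data), " rows but ", length(angles_deg),
         " angles; one angle per projection row is required", call. = FALSE)
  }
  if (is.unsorted(angles_deg, strictly = TRUE)) {
    stop("projection angles must be strictly ascending", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("sinogram contains non-finite values", call. = FALSE)
  }
  structure(data, angles_deg = angles_deg, class = c("sinogram", "matrix", "array"))
}

#' @rdname sinogram
#' @param x A `sinogram`.
#' @export
angles <- function(x) attr(x, "angles_deg")

#' @rdname sinogram
#' @export
is_sinogram <- function(x) inherits(x, "sinogram")

#' Strip sinogram metadata, returning the bare projection matrix
#'
#' @param x A `sinogram` or plain matrix.
#' @return A plain numeric matrix.
#' @export
sino_data <- function(x) {
  x <- unclass(x)
  attr(x, "angles_deg") <- NULL
  x
}

# Rebuild a sinogram from a plain matrix, reusing the metadata of `template`.
restamp_sinogram <- function(data, template) {
  sinogram(data, angles_deg = angles(template))
}

#' @export
print.sinogram <- function(x, ...) {
  a <- angles(x)
  cat(sprintf("<sinogram> %d angles x %d detector pixels, angles %.4g..%.4g deg\n",
              nrow(x), ncol(x), min(a), max(a)))
  invisible(x)
}

as_matrix2d <- function(x, what = "image") {
  x <- if (is_sinogram(x)) sino_data(x) else as.matrix(x)
  storage.mode(x) <- "double"
  if (length(dim(x)) != 2L) stop(what, " must be a 2-D array", call. = FALSE)
  x
}
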