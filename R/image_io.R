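#' Load a micrograph as a normalized grayscale matrix
#'
#' Reads PNG, TIFF or JPEG, collapses RGB to luminance (ITU-R 601 weights
#' 0.299, 0.587, 0.114) and min-max normalizes intensities to \[0, 1\].
#' A constant image (zero intensity range) maps to all zeros, so that
#' downstream segmentation yields an empty foreground instead of failing.
#'
#' @param path path to a raster image file.
#' @return A numeric matrix (rows x columns) with values in \[0, 1\].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("unreadable image file: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  a <- EBImage::imageData(img)
  if (length(a) == 0) stop("zero-size image: ", path, call. = FALSE)
  # EBImage stores x (columns of the displayed image) first; treat the
  # first index as matrix rows throughout -- the pipeline is orientation
  # agnostic and output coordinates follow this convention.
  if (length(dim(a)) == 3) {
    nch <- dim(a)[3]
    a <- if (nch >= 3) {
      0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else {
      a[, , 1]
    }
  }
  normalize_gray(a)
}

#' Min-max normalize a grayscale matrix to \[0, 1\]
#'
#' @param I numeric matrix.
#' @return Matrix with range \[0, 1\]; constant input maps to zeros.
#' @export
normalize_gray <- function(I) {
  stopifnot(is.matrix(I), all(dim(I) > 0))
  rng <- range(I)
  if (!all(is.finite(rng))) stop("image contains non-finite values", call. = FALSE)
  if (rng[2] == rng[1]) {
    return(array(0, dim = dim(I)))
  }
  (I - rng[1]) / (rng[2] - rng[1])
}
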