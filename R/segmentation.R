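#' Local mean filter with truncated border windows
#'
#' Each output pixel is the mean of the input over the `(2w+1) x (2w+1)`
#' square window centred on it. Near the image border the window is
#' truncated to its intersection with the image and the mean is taken over
#' the pixels actually present, which avoids spurious foreground along the
#' border. Implemented with integral images (running sums), so the cost is
#' independent of `w`.
#'
#' @param I numeric matrix.
#' @param w window half-width in pixels (`>= 1`).
#' @return Matrix of local means, same dimensions as `I`.
#' @export
mean_filter <- function(I, w) {
  stopifnot(is.matrix(I), w >= 1)
  w <- as.integer(w)
  nr <- nrow(I); nc <- ncol(I)
  # integral image with a zero top row / left column
  S <- matrix(0, nr + 1, nc + 1)
  S[-1, -1] <- apply(apply(I, 2, cumsum), 1, cumsum) |> t()
  r1 <- pmax(seq_len(nr) - w, 1L); r2 <- pmin(seq_len(nr) + w, nr)
  c1 <- pmax(seq_len(nc) - w, 1L); c2 <- pmin(seq_len(nc) + w, nc)
  sums <- S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  counts <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  sums / counts
}

#' Difference image: intensity minus local mean
#'
#' Computes `I - mean_filter(I, w)`, the signed deviation of every pixel
#' from its local neighbourhood mean. Structure that is locally brighter
#' than its surroundings has positive values; locally darker structure is
#' negative. The transform is invariant to adding a constant to `I`.
#'
#' @inheritParams mean_filter
#' @return Matrix of signed differences in \[-1, 1\] for normalized input.
#' @export
difference_image <- function(I, w) {
  I - mean_filter(I, w)
}

#' Segment root pixels by local thresholding
#'
#' A pixel is foreground when its difference-image value exceeds the
#' threshold `T` (strictly). With `polarity = "dark_walls"` (the default;
#' stained cell walls are darker than the background in these micrographs)
#' the rule is applied to the negated image, so that the dark wall network
#' becomes the foreground.
#'
#' @param I normalized grayscale matrix.
#' @param p an [ra_params()] object (uses `T`, `w`, `polarity`).
#' @param T optional threshold override (used by the relaxed `T/2`
#'   recovery pass).
#' @return Integer matrix of the same size, 1 = root (wall) pixel,
#'   0 = background.
#' @export
local_threshold <- function(I, p, T = p$T) {
  stopifnot(is.matrix(I))
  J <- if (p$polarity == "dark_walls") 1 - I else I
  Ihat <- difference_image(J, p$w)
  mask <- matrix(0L, nrow(I), ncol(I))
  mask[Ihat > T] <- 1L
  mask
}

#' Global Otsu segmentation (reference method)
#'
#' Single global threshold chosen by Otsu's method, applied with the same
#' polarity convention as [local_threshold()]. Provided as the baseline
#' that local thresholding is designed to outperform on images with
#' inhomogeneous backgrounds; it is not used by the pipeline itself.
#'
#' @inheritParams local_threshold
#' @return Binary integer matrix, 1 = foreground.
#' @export
global_threshold_otsu <- function(I, p) {
  J <- if (p$polarity == "dark_walls") 1 - I else I
  t <- EBImage::otsu(EBImage::Image(J), range = c(0, 1))
  mask <- matrix(0L, nrow(I), ncol(I))
  mask[J > t] <- 1L
  mask
}
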