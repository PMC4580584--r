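# Shared geometric helpers: contours, masks, radial interpolation.
# Contours are n x 2 matrices of (row, col) pixel coordinates, 1-based,
# ordered around the region (from EBImage::ocontour, shifted by +1).

ocontour1 <- function(lab) {
  lapply(EBImage::ocontour(lab), function(m) m + 1L)
}

shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# ids of labelled components touching the image border
border_labels <- function(lab) {
  unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
}

# largest connected foreground component of a binary mask, hole-filled;
# returns its filled mask, outer contour polygon and pixel area
largest_region <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) stop("empty mask: no region to outline", call. = FALSE)
  areas <- tabulate(lab[lab > 0])
  keep <- which.max(areas)
  comp <- matrix(0L, nrow(mask), ncol(mask))
  comp[lab == keep] <- 1L
  filled <- EBImage::imageData(EBImage::fillHull(comp))
  poly <- ocontour1(filled)[[1]]
  list(mask = filled, polygon = poly, area = sum(filled))
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# minimum distance from each query point (n x 2) to any vertex of a
# pixel-dense contour; vertices are <= ~1.5 px apart so vertex distance
# is an adequate point-to-curve distance here
min_dist_to_contour <- function(pts, contour) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  apply(pts, 1, function(q) {
    sqrt(min((contour[, 1] - q[1])^2 + (contour[, 2] - q[2])^2))
  })
}

# radius-by-angle lookup for a near-convex contour around a centre point:
# returns a function theta -> radius, theta measured counter-clockwise
# from image east (increasing column), in [0, 2*pi)
contour_radius_fn <- function(contour, centre) {
  dr <- contour[, 1] - centre[1]
  dc <- contour[, 2] - centre[2]
  theta <- atan2(-dr, dc) %% (2 * pi)
  rad <- sqrt(dr^2 + dc^2)
  o <- order(theta)
  th <- theta[o]; rd <- rad[o]
  # wrap both ends so interpolation is periodic
  th <- c(th[length(th)] - 2 * pi, th, th[1] + 2 * pi)
  rd <- c(rd[length(rd)], rd, rd[1])
  function(q) {
    q <- q %% (2 * pi)
    stats::approx(th, rd, xout = q, rule = 2, ties = "ordered")$y
  }
}

# angle (ccw from east) and radius of points relative to a centre
polar_about <- function(pts, centre) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  dr <- pts[, 1] - centre[1]
  dc <- pts[, 2] - centre[2]
  list(theta = atan2(-dr, dc) %% (2 * pi), r = sqrt(dr^2 + dc^2))
}

# k nearest neighbour indices among reference points (excluding self when
# query and reference coincide); returns list(idx = matrix, dist = matrix)
knn_points <- function(query, ref, k, self = FALSE) {
  nq <- nrow(query); nref <- nrow(ref)
  d2 <- outer(query[, 1], ref[, 1], "-")^2 + outer(query[, 2], ref[, 2], "-")^2
  idx <- matrix(NA_integer_, nq, k)
  dst <- matrix(NA_real_, nq, k)
  for (i in seq_len(nq)) {
    di <- d2[i, ]
    if (!self) di[which(di < 1e-12)[1]] <- Inf  # drop the point itself
    kk <- min(k, sum(is.finite(di) & di < Inf))
    if (kk > 0) {
      o <- order(di)[seq_len(kk)]
      idx[i, seq_len(kk)] <- o
      dst[i, seq_len(kk)] <- sqrt(di[o])
    }
  }
  list(idx = idx, dist = dst)
}

# Otsu threshold on a numeric vector (maximises between-class variance
# over a fixed-bin histogram); returns a cut value
otsu_cut <- function(x, nbins = 64) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  # the class boundary is the upper edge of the winning bin, so that
  # thresholding with <= assigns every point of that bin to the lower class
  br[which.max(between[-nbins]) + 1]
}

disc_brush <- function(radius) {
  size <- 2 * floor(radius) + 1
  EBImage::makeBrush(size, shape = "disc")
}
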