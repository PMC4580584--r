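#' Dilate a binary wall mask with a 2 x 2 kernel
#'
#' Morphological dilation with a 2 x 2 all-ones structuring element,
#' anchored at its top-left element: a foreground pixel at `(r, c)`
#' produces the block `(r, c), (r, c+1), (r+1, c), (r+1, c+1)`. The small
#' asymmetric kernel closes one-to-two-pixel leaks in cell walls without
#' noticeably eroding the smallest stele cells.
#'
#' @param B binary integer matrix (1 = wall foreground).
#' @return Dilated binary matrix, a superset of `B`.
#' @export
dilate_mask <- function(B) {
  stopifnot(is.matrix(B))
  out <- pmax(B,
              shift_mat(B, 1L, 0L),
              shift_mat(B, 0L, 1L),
              shift_mat(B, 1L, 1L))
  storage.mode(out) <- "integer"
  out
}

#' Detect enclosed cells in a segmented wall mask
#'
#' Every maximal 4-connected background component of the dilated wall mask
#' that does not touch the image border is one cell interior. Components
#' touching the border (the outer background, and any cell cut off by the
#' image edge) are discarded. Boundaries are obtained by contour tracing
#' of each component.
#'
#' When the pre-dilation mask `B` is supplied, pixels that were background
#' in `B` but were turned into wall purely by the directional 2 x 2
#' dilation are reclaimed into the adjacent cell, so that reported cell
#' areas are measured on the original segmentation and do not carry the
#' dilation's one-pixel bias along two sides.
#'
#' @param Bd dilated binary wall mask (see [dilate_mask()]).
#' @param I optional grayscale image; if given, per-cell mean interior
#'   intensity is recorded (needed by [remove_lateral_roots()]).
#' @param B optional pre-dilation wall mask enabling area reclaim.
#' @return An object of class `ra_cells`: a list with `labels` (integer
#'   matrix of per-pixel cell ids, 0 elsewhere), `cells` (data frame with
#'   `id`, `area`, `centroid_r`, `centroid_c`, `mean_intensity`) and
#'   `contours` (list of (row, col) boundary polygons, keyed by id).
#' @export
detect_cells <- function(Bd, I = NULL, B = NULL) {
  stopifnot(is.matrix(Bd))
  bg <- 1L - Bd
  lab <- EBImage::imageData(EBImage::bwlabel(bg))
  drop <- border_labels(lab)
  lab[lab %in% drop] <- 0L
  ids <- sort(unique(lab[lab > 0]))
  # relabel consecutively, keeping bwlabel's deterministic raster order
  if (length(ids) > 0 && !identical(ids, seq_along(ids))) {
    map <- integer(max(ids)); map[ids] <- seq_along(ids)
    lab[lab > 0] <- map[lab[lab > 0]]
  }
  n <- length(ids)
  storage.mode(lab) <- "integer"

  if (n > 0 && !is.null(B)) {
    lab <- reclaim_dilation_bias(lab, B, Bd)
  }

  if (n == 0) {
    cells <- data.frame(id = integer(), area = integer(),
                        centroid_r = numeric(), centroid_c = numeric(),
                        mean_intensity = numeric())
    return(structure(list(labels = lab, cells = cells, contours = list()),
                     class = "ra_cells"))
  }

  px <- which(lab > 0)
  id_px <- lab[px]
  rr <- (px - 1L) %% nrow(lab) + 1L
  cc <- (px - 1L) %/% nrow(lab) + 1L
  area <- tabulate(id_px, n)
  centroid_r <- rowsum(as.numeric(rr), id_px)[, 1] / area
  centroid_c <- rowsum(as.numeric(cc), id_px)[, 1] / area
  mean_int <- if (!is.null(I)) rowsum(I[px], id_px)[, 1] / area else rep(NA_real_, n)
  contours <- ocontour1(lab)
  names(contours) <- as.character(seq_len(n))

  cells <- data.frame(id = seq_len(n), area = area,
                      centroid_r = centroid_r, centroid_c = centroid_c,
                      mean_intensity = mean_int)
  structure(list(labels = lab, cells = cells, contours = contours),
            class = "ra_cells")
}

# give back pixels the top-left-anchored dilation stole from cell
# interiors: background in B, wall in Bd, 4/8-adjacent to a cell on its
# lower/right side (the direction the dilation grew from)
reclaim_dilation_bias <- function(lab, B, Bd) {
  nr <- nrow(lab)
  cand <- which(lab == 0L & B == 0L & Bd == 1L)
  if (length(cand) == 0) return(lab)
  rr <- (cand - 1L) %% nr + 1L
  cc <- (cand - 1L) %/% nr + 1L
  ok <- rr < nr & cc < ncol(lab)
  cand <- cand[ok]; rr <- rr[ok]; cc <- cc[ok]
  below <- lab[cand + 1L]
  right <- lab[cand + nr]
  diag_ <- lab[cand + nr + 1L]
  got <- ifelse(below > 0L, below, ifelse(right > 0L, right, diag_))
  take <- got > 0L
  lab[cand[take]] <- got[take]
  lab
}

#' @export
print.ra_cells <- function(x, ...) {
  cat("ra_cells:", nrow(x$cells), "detected cells on a",
      paste(dim(x$labels), collapse = " x "), "grid\n")
  invisible(x)
}

#' Remove lateral-root artefacts by interior intensity
#'
#' Lateral root formations attached to the cross section appear as dark
#' enclosed regions and get detected as cells. Regions whose mean interior
#' intensity is below `lateral_intensity_fraction` (default one third) of
#' the mean intensity over all detected regions are removed.
#'
#' @param cells an `ra_cells` object with `mean_intensity` recorded.
#' @param I grayscale image (used to fill in intensities if absent).
#' @param p an [ra_params()] object.
#' @return The filtered `ra_cells` object (ids are preserved).
#' @export
remove_lateral_roots <- function(cells, I, p) {
  df <- cells$cells
  if (nrow(df) == 0) return(cells)
  if (all(is.na(df$mean_intensity))) {
    px <- which(cells$labels > 0)
    df$mean_intensity <- rowsum(I[px], cells$labels[px])[, 1] /
      tabulate(cells$labels[px], nrow(df))
  }
  cutoff <- p$lateral_intensity_fraction * mean(df$mean_intensity)
  drop <- df$id[df$mean_intensity < cutoff]
  if (length(drop) > 0) {
    cells$labels[cells$labels %in% drop] <- 0L
    cells$contours[as.character(drop)] <- NULL
    df <- df[!df$id %in% drop, , drop = FALSE]
    rownames(df) <- NULL
  }
  cells$cells <- df
  cells
}

#' Initial root boundary from detected cells
#'
#' The outer contour of the filled union of the wall foreground and all
#' detected cell interiors; the largest connected component is taken as
#' the root body. Cell interiors that leaked into the background (broken
#' walls) are not part of this union, which is what the later recovery
#' pass exploits.
#'
#' @param cells an `ra_cells` object.
#' @param Bd the (dilated) wall mask the cells were detected on.
#' @return A list with `polygon` (closed (row, col) contour), `mask`
#'   (filled binary matrix of the enclosed region) and `area` (px^2).
#' @export
initial_root_boundary <- function(cells, Bd) {
  if (nrow(cells$cells) == 0) {
    stop("no cells detected: cannot form a root boundary (segmentation failed?)",
         call. = FALSE)
  }
  u <- matrix(0L, nrow(Bd), ncol(Bd))
  u[Bd == 1L | cells$labels > 0L] <- 1L
  largest_region(u)
}

#' Euclidean distance transform of a wall mask
#'
#' Each pixel stores the Euclidean distance (in pixels) to the nearest
#' foreground (wall) pixel; wall pixels themselves are zero. Peaks of the
#' map mark cell centres.
#'
#' @param B binary wall mask with at least one foreground pixel.
#' @return Numeric matrix of distances.
#' @export
distance_map <- function(B) {
  stopifnot(is.matrix(B))
  if (sum(B) == 0) stop("all-background mask: distance map undefined", call. = FALSE)
  EBImage::imageData(EBImage::distmap(1L - B))
}

#' Regional maxima of a distance map
#'
#' Pixels whose value is maximal within their 8-neighbourhood (plateaus
#' included) and at least `min_height`. The default height gate,
#' `sqrt(A_s / pi) / 2`, is half the radius of the smallest admissible
#' cell, which suppresses sub-cell-scale ripples.
#'
#' @param D distance map matrix.
#' @param min_height minimum peak height in pixels.
#' @return Matrix with columns `r`, `c`, `height`, one row per peak pixel.
#' @export
find_distance_peaks <- function(D, min_height = 2) {
  nb <- pmax(shift_mat(D,  1,  0, -Inf), shift_mat(D, -1,  0, -Inf),
             shift_mat(D,  0,  1, -Inf), shift_mat(D,  0, -1, -Inf),
             shift_mat(D,  1,  1, -Inf), shift_mat(D,  1, -1, -Inf),
             shift_mat(D, -1,  1, -Inf), shift_mat(D, -1, -1, -Inf))
  idx <- which(D >= nb & D >= min_height)
  cbind(r = (idx - 1L) %% nrow(D) + 1L,
        c = (idx - 1L) %/% nrow(D) + 1L,
        height = D[idx])
}
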