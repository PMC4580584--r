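#' First-pass root model: segment, dilate, detect, filter, outline
#'
#' Runs the initial detection stage on a normalized grayscale image:
#' local-threshold segmentation at `T`, 2 x 2 dilation, enclosed-cell
#' detection, lateral-root removal, the initial root boundary and the
#' Euclidean distance transform of the first-pass mask.
#'
#' @param I normalized grayscale matrix.
#' @param p an [ra_params()] object.
#' @return An object of class `ra_root` holding the image, masks, the
#'   detected cells (`$cells`, `$labels`, `$contours`), `$gamma_ini`,
#'   `$gamma_final` (initially equal to `gamma_ini`) and the distance
#'   map `$D`.
#' @export
detect_root_model <- function(I, p) {
  stopifnot(is.matrix(I))
  B <- local_threshold(I, p)
  Bd <- dilate_mask(B)
  cells <- detect_cells(Bd, I, B)
  cells <- remove_lateral_roots(cells, I, p)
  gamma_ini <- initial_root_boundary(cells, Bd)
  D <- distance_map(B)
  model <- list(
    image = I, params = p,
    B = B, Bd = Bd,
    cells = cells$cells, labels = cells$labels, contours = cells$contours,
    gamma_ini = gamma_ini, gamma_final = gamma_ini,
    D = D, recovered_ids = integer()
  )
  model$cells$tissue <- rep("unassigned", nrow(model$cells))
  model$cells$size_class <- rep("unassigned", nrow(model$cells))
  structure(model, class = "ra_root")
}

#' @export
print.ra_root <- function(x, ...) {
  cat("ra_root model: ", nrow(x$cells), " cells",
      if (length(x$recovered_ids)) paste0(" (", length(x$recovered_ids),
                                          " recovered)"), "\n", sep = "")
  if (!is.null(x$stele_centre)) {
    cat("  stele centre: (", paste(round(x$stele_centre, 1), collapse = ", "),
        ")\n", sep = "")
  }
  if (any(x$cells$tissue != "unassigned")) {
    print(table(x$cells$tissue))
  }
  invisible(x)
}

#' Recover cells missed by the first segmentation pass
#'
#' Cells with faint or slightly perforated walls leak into the background
#' and are absent from the first pass. The image is re-segmented at half
#' the local threshold (`T/2`) -- far too noisy for regular detection but
#' often enough to complete the faint boundaries -- and cells are detected
#' on that relaxed mask. A relaxed-pass region is promoted into the model
#' only when it contains a peak of the first-pass distance map lying
#' outside the initial root boundary: such a peak marks a cell-scale
#' cavity that the first pass failed to enclose. Everything else from the
#' relaxed pass is discarded as noise, and no first-pass cell is ever
#' removed. The root boundary is then recomputed (`gamma_final`).
#'
#' @param I normalized grayscale matrix (same image the model came from).
#' @param p an [ra_params()] object.
#' @param model an `ra_root` from [detect_root_model()].
#' @return The updated `ra_root`, with recovered cells appended and
#'   `gamma_final` recomputed.
#' @export
recover_missed_cells <- function(I, p, model) {
  stopifnot(inherits(model, "ra_root"))
  B2 <- local_threshold(I, p, T = p$T / 2)
  Bd2 <- dilate_mask(B2)
  relaxed <- detect_cells(Bd2, I, B2)

  peaks <- find_distance_peaks(model$D, min_height = sqrt(p$A_s / pi) / 2)
  if (nrow(peaks) == 0) return(finalize_boundary(model))
  inside_ini <- model$gamma_ini$mask[cbind(peaks[, "r"], peaks[, "c"])] > 0
  peaks <- peaks[!inside_ini, , drop = FALSE]
  if (nrow(peaks) == 0) return(finalize_boundary(model))

  hit_ids <- unique(relaxed$labels[cbind(peaks[, "r"], peaks[, "c"])])
  hit_ids <- sort(hit_ids[hit_ids > 0])

  next_id <- if (nrow(model$cells) > 0) max(model$cells$id) else 0L
  for (rid in hit_ids) {
    px <- which(relaxed$labels == rid)
    px <- px[model$labels[px] == 0L]  # never overwrite a first-pass cell
    if (length(px) == 0) next
    inside_frac <- mean(model$gamma_ini$mask[px] > 0)
    if (inside_frac >= 0.5) next     # not actually a missed exterior cell
    next_id <- next_id + 1L
    model$labels[px] <- next_id
    rr <- (px - 1L) %% nrow(I) + 1L
    cc <- (px - 1L) %/% nrow(I) + 1L
    tmp <- matrix(0L, nrow(I), ncol(I))
    tmp[px] <- 1L
    cont <- ocontour1(tmp)[[1]]
    model$contours[[as.character(next_id)]] <- cont
    model$cells <- rbind(model$cells, data.frame(
      id = next_id, area = length(px),
      centroid_r = mean(rr), centroid_c = mean(cc),
      mean_intensity = mean(I[px]),
      tissue = "unassigned", size_class = "unassigned"
    ))
    model$recovered_ids <- c(model$recovered_ids, next_id)
  }
  rownames(model$cells) <- NULL
  finalize_boundary(model)
}

finalize_boundary <- function(model) {
  u <- matrix(0L, nrow(model$Bd), ncol(model$Bd))
  u[model$Bd == 1L | model$labels > 0L] <- 1L
  model$gamma_final <- largest_region(u)
  model
}
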