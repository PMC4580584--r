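#' Least-squares ellipse fit to a boundary
#'
#' Direct algebraic least-squares ellipse fit (the numerically stable
#' Halir--Flusser formulation of Fitzgibbon's method) to a set of
#' boundary points. When the algebraic system is degenerate the fit falls
#' back to the second-moment ellipse of the points. The eccentricity is
#' `E = sqrt(1 - b^2 / a^2)` with `a >= b` the semi-axes, so `E = 0` for
#' a circle.
#'
#' @param boundary n x 2 matrix of (row, col) boundary coordinates,
#'   `n >= 5`, not collinear.
#' @return An object of class `ra_ellipse`: list with semi-axes `a`,
#'   `b` (`a >= b`), `centre` (row, col), `orientation` (radians,
#'   measured in the (col, -row) plane) and eccentricity `E`.
#' @examples
#' t <- seq(0, 2 * pi, length.out = 100)
#' fit_ellipse(cbind(3 * sin(t), 5 * cos(t)))$E  # 0.8
#' @export
fit_ellipse <- function(boundary) {
  if (is.null(dim(boundary)) || nrow(boundary) < 5) {
    stop("ellipse fit needs at least 5 boundary points", call. = FALSE)
  }
  x <- boundary[, 2]; y <- boundary[, 1]
  mx <- mean(x); my <- mean(y)
  xc <- x - mx; yc <- y - my
  if (collinear_points(xc, yc)) {
    stop("ellipse fit undefined for collinear points", call. = FALSE)
  }
  fit <- tryCatch(fit_ellipse_algebraic(xc, yc), error = function(e) NULL)
  if (is.null(fit)) fit <- fit_ellipse_moments(xc, yc)
  a <- max(fit$a, fit$b); b <- min(fit$a, fit$b)
  structure(list(a = a, b = b,
                 centre = c(fit$cy + my, fit$cx + mx),
                 orientation = fit$theta,
                 E = sqrt(max(0, 1 - b^2 / a^2))),
            class = "ra_ellipse")
}

collinear_points <- function(x, y) {
  s <- svd(cbind(x, y))$d
  s[2] < 1e-9 * max(s[1], 1e-12)
}

fit_ellipse_algebraic <- function(x, y) {
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0) stop("no elliptical solution")
  a1 <- V[, ok[1]]
  coef <- c(a1, Tm %*% a1)  # A B C D E F for Ax^2+Bxy+Cy^2+Dx+Ey+F
  conic_to_ellipse(coef)
}

conic_to_ellipse <- function(k) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  den <- B^2 - 4 * A * C
  if (!is.finite(den) || den >= 0) stop("degenerate conic")
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 + F * B^2 - B * D * E - 4 * A * C * F)
  root <- sqrt((A - C)^2 + B^2)
  a2 <- num / (den * (-(A + C) - root))
  b2 <- num / (den * (-(A + C) + root))
  if (!is.finite(a2) || !is.finite(b2) || a2 <= 0 || b2 <= 0) {
    stop("degenerate conic")
  }
  theta <- 0.5 * atan2(B, A - C)
  list(a = sqrt(a2), b = sqrt(b2), cx = cx, cy = cy, theta = theta)
}

# second-moment fallback: principal axes of the point scatter, scaled so
# that an angle-uniform sample of a true ellipse is recovered exactly
fit_ellipse_moments <- function(x, y) {
  S <- stats::cov(cbind(x, y))
  ev <- eigen(S, symmetric = TRUE)
  list(a = sqrt(2 * max(ev$values[1], 1e-12)),
       b = sqrt(2 * max(ev$values[2], 1e-12)),
       cx = 0, cy = 0,
       theta = atan2(ev$vectors[2, 1], ev$vectors[1, 1]))
}

#' @export
print.ra_ellipse <- function(x, ...) {
  cat(sprintf("ellipse: a = %.3f, b = %.3f, E = %.4f\n", x$a, x$b, x$E))
  invisible(x)
}

# per-cell eccentricity from traced contours; cells whose contour is too
# small or degenerate get NA
cell_eccentricities <- function(model) {
  vapply(as.character(model$cells$id), function(k) {
    cont <- model$contours[[k]]
    if (is.null(cont) || nrow(cont) < 5) return(NA_real_)
    tryCatch(fit_ellipse(cont)$E, error = function(e) NA_real_)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Primary per-tissue statistics
#'
#' Computes the primary statistics table: whole-root total area and
#' eccentricity; per tissue region (cortex, stele, endodermis, metaxylem,
#' and for maize also protoxylem and aerenchyma) the total area, cell
#' count, mean cell area and mean cell eccentricity; and the eccentricity
#' of the stele region. Pixel measures are converted to microns with
#' `scale` (um/px; areas by `scale^2`) at this reporting step only.
#'
#' The stele total area is measured as the area enclosed by the outer
#' endodermis contour, i.e. including the cell walls of the region, to
#' match the visual extent of the vascular cylinder; per-cell areas
#' always exclude walls. When a region holds exactly one cell (the usual
#' single central metaxylem of a wheat primary root) the "mean" fields
#' are simply that cell's values.
#'
#' @param model a classified `ra_root` model.
#' @param scale microns per pixel (defaults to the model's parameter).
#' @return A data frame with columns `region`, `feature`, `value`,
#'   `unit`.
#' @export
compute_tissue_stats <- function(model, scale = model$params$scale) {
  df <- model$cells
  df <- df[df$tissue != "noise", , drop = FALSE]
  if (is.null(df$eccentricity)) df$eccentricity <- rep(NA_real_, nrow(df))
  s2 <- scale^2
  rows <- list()
  add <- function(region, feature, value, unit) {
    rows[[length(rows) + 1]] <<- data.frame(region = region, feature = feature,
                                            value = value, unit = unit)
  }
  root_area <- if (!is.null(model$gamma_final)) model$gamma_final$area else NA
  add("whole_root", "total_area", root_area * s2, "um^2")
  root_ecc <- tryCatch(fit_ellipse(model$gamma_final$polygon)$E,
                       error = function(e) NA_real_)
  add("whole_root", "eccentricity", root_ecc, "eccentricity")

  tissues <- c("cortex", "stele", "endodermis", "metaxylem")
  if (model$params$species == "maize") {
    tissues <- c(tissues, "protoxylem", "aerenchyma")
  }
  for (ti in tissues) {
    sub <- df[df$tissue == ti, , drop = FALSE]
    total <- if (ti == "stele" && !is.null(model$stele_region)) {
      # region area: everything inside the endodermis outer contour
      sum(model$stele_region$mask)
    } else {
      sum(sub$area)
    }
    add(ti, "total_area", total * s2, "um^2")
    add(ti, "cell_count", nrow(sub), "count")
    add(ti, "mean_cell_area",
        if (nrow(sub)) mean(sub$area) * s2 else NA_real_, "um^2")
    add(ti, "mean_cell_eccentricity",
        if (nrow(sub)) mean(sub$eccentricity, na.rm = TRUE) else NA_real_,
        "eccentricity")
  }
  stele_ecc <- if (!is.null(model$stele_region)) {
    tryCatch(fit_ellipse(model$stele_region$polygon)$E,
             error = function(e) NA_real_)
  } else NA_real_
  add("stele", "eccentricity", stele_ecc, "eccentricity")
  do.call(rbind, rows)
}

#' Radial "cheesewheel" statistics
#'
#' Partitions the stele zone (stele centre out to the endodermis contour)
#' and the cortex zone (endodermis contour out to the root boundary) each
#' into 6 annuli x 6 wedges and aggregates cell count, mean cell area and
#' mean cell eccentricity per region. Annuli interpolate linearly between
#' the two bounding contours along each ray from the stele centre, so
#' they follow non-circular roots; wedges are 60 degrees each, anchored
#' at image east and counted counter-clockwise. Cells are assigned by
#' centroid, so each cell of a zone falls in exactly one region.
#'
#' @param model a classified `ra_root` with `stele_centre`,
#'   `stele_region` and `gamma_final`.
#' @return Data frame with columns `zone` (`"stele-zone"`,
#'   `"cortex-zone"`), `annulus` (1 = innermost), `wedge` (1 = first 60
#'   degrees from east, counter-clockwise), `cell_count`, `mean_area`
#'   (px^2), `mean_eccentricity`.
#' @export
cheesewheel <- function(model) {
  if (is.null(model$stele_region) || is.null(model$stele_centre)) {
    stop("cheesewheel statistics need a classified model with an endodermis contour",
         call. = FALSE)
  }
  centre <- model$stele_centre
  r_endo <- contour_radius_fn(model$stele_region$polygon, centre)
  r_outer <- contour_radius_fn(model$gamma_final$polygon, centre)
  df <- model$cells
  if (is.null(df$eccentricity)) df$eccentricity <- rep(NA_real_, nrow(df))

  zone_of <- function(tissue) {
    ifelse(tissue %in% c("stele", "endodermis", "metaxylem", "protoxylem"),
           "stele-zone",
           ifelse(tissue %in% c("cortex", "aerenchyma"), "cortex-zone", NA))
  }
  df$zone <- zone_of(df$tissue)
  pol <- polar_about(cbind(df$centroid_r, df$centroid_c), centre)
  re <- r_endo(pol$theta)
  ro <- r_outer(pol$theta)
  frac <- ifelse(df$zone == "stele-zone",
                 pol$r / re,
                 (pol$r - re) / pmax(ro - re, 1e-9))
  frac <- pmin(pmax(frac, 0), 1 - 1e-9)
  df$annulus <- floor(frac * 6) + 1L
  df$wedge <- floor(pol$theta / (pi / 3)) %% 6 + 1L

  grid <- expand.grid(zone = c("stele-zone", "cortex-zone"),
                      annulus = 1:6, wedge = 1:6,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  used <- df[!is.na(df$zone), , drop = FALSE]
  agg <- function(zone, annulus, wedge) {
    s <- used[used$zone == zone & used$annulus == annulus & used$wedge == wedge, ]
    c(cell_count = nrow(s),
      mean_area = if (nrow(s)) mean(s$area) else NA_real_,
      mean_eccentricity = if (nrow(s)) mean(s$eccentricity, na.rm = TRUE)
                          else NA_real_)
  }
  vals <- t(mapply(agg, grid$zone, grid$annulus, grid$wedge))
  out <- cbind(grid, as.data.frame(vals))
  out <- out[order(out$zone, out$annulus, out$wedge), ]
  rownames(out) <- NULL
  out
}

#' Write the statistics files for one analyzed image
#'
#' Writes three CSV files (RFC 4180, UTF-8): `<base>_summary.csv` (the
#' primary statistics table), `<base>_cells.csv` (one row per non-noise
#' cell: id, tissue, area in um^2, eccentricity, centroid in px) and
#' `<base>_cheesewheel.csv`. An empty model produces headers-only files.
#'
#' @param model a classified `ra_root`.
#' @param dir output directory (created if needed).
#' @param base file-name stem.
#' @return Invisibly, the vector of written paths.
#' @export
write_stats <- function(model, dir, base = "root") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  s2 <- model$params$scale^2
  paths <- file.path(dir, paste0(base, c("_summary.csv", "_cells.csv",
                                         "_cheesewheel.csv")))
  summary_df <- tryCatch(compute_tissue_stats(model),
                         error = function(e) data.frame(
                           region = character(), feature = character(),
                           value = numeric(), unit = character()))
  write.csv(summary_df, paths[1], row.names = FALSE)

  df <- model$cells
  df <- df[df$tissue != "noise", , drop = FALSE]
  if (is.null(df$eccentricity)) df$eccentricity <- rep(NA_real_, nrow(df))
  cells_df <- data.frame(id = df$id, tissue = df$tissue,
                         area_um2 = df$area * s2,
                         eccentricity = df$eccentricity,
                         centroid_r = df$centroid_r,
                         centroid_c = df$centroid_c)
  write.csv(cells_df, paths[2], row.names = FALSE)

  cw <- tryCatch(cheesewheel(model), error = function(e) data.frame(
    zone = character(), annulus = integer(), wedge = integer(),
    cell_count = integer(), mean_area = numeric(),
    mean_eccentricity = numeric()))
  write.csv(cw, paths[3], row.names = FALSE)
  invisible(paths)
}
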