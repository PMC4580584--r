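# Synthetic root cross-section generator. Renders a concentric tessellation
# of cells (epidermal ring, cortex rings, endodermal ring, packed stele,
# central or polyarch metaxylem, optional maize protoxylem / aerenchyma) as
# dark 2 px cell walls on a bright background with a linear illumination
# gradient and Gaussian noise, and returns exact per-cell ground truth.
# Geometry is ring-wise: each ring is split into angularly jittered sectors,
# which reproduces the statistical structure the classifier relies on
# (relative cell sizes and positions) without modelling tissue growth.

#' Specification of a synthetic root cross section
#'
#' Builds a validated parameter set for [generate_root()]. All lengths are
#' pixels, intensities are on the \[0, 1\] gray scale. Defaults describe a
#' typical wheat primary-root section at 10x magnification; passing
#' `species = "maize"` switches to a larger root with six polyarch
#' metaxylem vessels, protoxylem elements and cortical aerenchyma.
#'
#' @param species `"wheat"` or `"maize"`.
#' @param root_radius outer radius of the root.
#' @param stele_radius outer radius of the endodermis ring (the
#'   small-cell cluster boundary); must be below `root_radius`.
#' @param n_epidermis number of epidermal cells on the perimeter ring.
#' @param n_cortex_rings number of concentric cortex cell rings.
#' @param cortex_cell_scale target angular width (px of arc) of cortex
#'   cells; with the ring thickness this sets cortex cell areas.
#' @param stele_cell_scale target stele cell pitch (ring thickness and
#'   arc), i.e. the linear size of stele cells.
#' @param stele_ring_taper geometric factor for stele ring thicknesses
#'   from inside out; `1` gives equal rings, values below 1 make outer
#'   stele cells progressively flatter (radially increasing
#'   eccentricity).
#' @param endodermis_thickness,epidermis_thickness ring thicknesses.
#' @param n_metaxylem number of metaxylem vessels (1 central for wheat;
#'   several, arranged symmetrically, for maize).
#' @param metaxylem_radius radius of each metaxylem vessel.
#' @param metaxylem_orbit_fraction for multiple vessels, orbit radius as
#'   a fraction of the stele packing radius.
#' @param n_protoxylem number of protoxylem elements (maize).
#' @param proto_fractions radial positions of protoxylem centres as
#'   fractions of `stele_radius`; length `n_protoxylem`.
#' @param proto_radius radius of each protoxylem element.
#' @param n_aerenchyma number of enlarged aerenchyma lacunae created by
#'   merging adjacent cortex cells (maize).
#' @param wall_intensity gray value of cell walls before the gradient is
#'   applied; the background sits at 0.8, so the default 0.65 gives the
#'   weak staining contrast (0.15) typical of the difficult micrographs
#'   this pipeline targets.
#' @param background_gradient_amplitude strength of the illumination
#'   inhomogeneity: a linear gradient of this peak-to-peak swing across
#'   the image diagonal plus a large smooth dark region (depth 0.8 times
#'   the amplitude) overlapping one side of the root, the classic
#'   failure mode of global thresholding.
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param break_probability per-epidermal-cell probability of a faint
#'   break in the outer wall: a 3--5 px arc is rendered at a contrast
#'   that fails the nominal threshold `T` but passes `T/2`, emulating
#'   locally failed staining. Whenever breaks are enabled at least one
#'   5 px boundary break is guaranteed, so the recovery pass is always
#'   exercised.
#' @param lateral_root attach a dark lateral-root blob to the perimeter.
#' @param seed RNG seed; generation is fully deterministic given the
#'   spec.
#' @return An object of class `ra_synth_spec` (validated list).
#' @export
synthetic_spec <- function(species = c("wheat", "maize"),
                           root_radius = NULL, stele_radius = NULL,
                           n_epidermis = NULL, n_cortex_rings = 2,
                           cortex_cell_scale = 70, stele_cell_scale = 18,
                           stele_ring_taper = 1,
                           endodermis_thickness = 14, epidermis_thickness = 15,
                           n_metaxylem = NULL, metaxylem_radius = NULL,
                           metaxylem_orbit_fraction = 0.6,
                           n_protoxylem = NULL, proto_fractions = NULL,
                           proto_radius = 22,
                           n_aerenchyma = NULL,
                           wall_intensity = 0.65,
                           background_gradient_amplitude = 0.3,
                           noise_sigma = 0.01,
                           break_probability = 0,
                           lateral_root = FALSE,
                           seed = 1) {
  species <- match.arg(species)
  maize <- species == "maize"
  if (is.null(root_radius))     root_radius <- if (maize) 260 else 190
  if (is.null(stele_radius))    stele_radius <- if (maize) 170 else 112
  if (is.null(n_epidermis))     n_epidermis <- if (maize) 78 else 60
  if (is.null(n_metaxylem))     n_metaxylem <- if (maize) 6 else 1
  if (is.null(metaxylem_radius)) metaxylem_radius <- if (maize) 28 else 22
  if (is.null(n_protoxylem))    n_protoxylem <- if (maize) 2 else 0
  if (is.null(n_aerenchyma))    n_aerenchyma <- if (maize) 6 else 0
  if (n_protoxylem > 0 && is.null(proto_fractions)) {
    proto_fractions <- seq(0.35, 0.8, length.out = n_protoxylem)
  }
  spec <- list(species = species, root_radius = root_radius,
               stele_radius = stele_radius, n_epidermis = n_epidermis,
               n_cortex_rings = n_cortex_rings,
               cortex_cell_scale = cortex_cell_scale,
               stele_cell_scale = stele_cell_scale,
               stele_ring_taper = stele_ring_taper,
               endodermis_thickness = endodermis_thickness,
               epidermis_thickness = epidermis_thickness,
               n_metaxylem = n_metaxylem, metaxylem_radius = metaxylem_radius,
               metaxylem_orbit_fraction = metaxylem_orbit_fraction,
               n_protoxylem = n_protoxylem, proto_fractions = proto_fractions,
               proto_radius = proto_radius, n_aerenchyma = n_aerenchyma,
               wall_intensity = wall_intensity,
               background_gradient_amplitude = background_gradient_amplitude,
               noise_sigma = noise_sigma,
               break_probability = break_probability,
               lateral_root = lateral_root, seed = seed)
  validate_synth_spec(spec)
  structure(spec, class = "ra_synth_spec")
}

validate_synth_spec <- function(s) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid synthetic spec: ", msg,
                                                 call. = FALSE)
  chk(s$stele_radius < s$root_radius, "stele_radius must be below root_radius")
  chk(s$stele_radius > s$endodermis_thickness + 2 * s$stele_cell_scale,
      "stele too small for its cell scale")
  chk(s$root_radius - s$epidermis_thickness > s$stele_radius,
      "no room for a cortex between stele and epidermis")
  chk(s$n_epidermis >= 8, "need at least 8 epidermal cells")
  chk(s$n_cortex_rings >= 1, "need at least one cortex ring")
  chk(s$n_metaxylem >= 0 && s$n_protoxylem >= 0 && s$n_aerenchyma >= 0,
      "counts must be non-negative")
  chk(s$break_probability >= 0 && s$break_probability <= 1,
      "break_probability must be in [0, 1]")
  chk(s$wall_intensity > 0 && s$wall_intensity < 0.8,
      "wall_intensity must be below the 0.8 background level")
  chk(s$background_gradient_amplitude >= 0 && s$background_gradient_amplitude <= 1,
      "gradient amplitude must be in [0, 1]")
  chk(s$noise_sigma >= 0, "noise_sigma must be non-negative")
  if (s$n_protoxylem > 0) {
    chk(length(s$proto_fractions) == s$n_protoxylem,
        "proto_fractions must have length n_protoxylem")
    chk(all(s$proto_fractions > 0 & s$proto_fractions < 1),
        "proto_fractions must lie in (0, 1)")
  }
  invisible(s)
}

# internal rendering constants
.synth_bg <- 0.8          # nominal background / cell interior intensity
.synth_faint <- 0.06      # wall contrast of a "broken" (faint) wall arc
.synth_lateral_radius <- 24
.synth_lateral_wall <- 0.05
.synth_lateral_interior <- 0.2

#' Generate a synthetic root cross-section image with ground truth
#'
#' Renders the tessellation described by a [synthetic_spec()] and returns
#' the image together with exact per-cell ground truth. Deterministic for
#' a fixed spec (including its seed).
#'
#' @param spec an `ra_synth_spec`.
#' @return An object of class `ra_synth`: list with `image` (normalized
#'   grayscale matrix), `truth` (class `ra_truth`: `label_image` of
#'   per-pixel cell ids with walls at 0, `cells` data frame of id,
#'   tissue, area, centroid, `tissue_of` named vector, `true_boundaries`
#'   contour list, `true_stats` per-tissue summary) and the `spec`.
#' @export
generate_root <- function(spec) {
  stopifnot(inherits(spec, "ra_synth_spec"))
  withr::with_seed(spec$seed, generate_root_impl(spec))
}

generate_root_impl <- function(s) {
  margin <- if (s$lateral_root) 2 * .synth_lateral_radius + 10 else 14
  n <- 2 * ceiling(s$root_radius + margin)
  cr <- (n + 1) / 2; cc <- (n + 1) / 2
  rowm <- matrix(seq_len(n), n, n)
  colm <- matrix(seq_len(n), n, n, byrow = TRUE)
  rad <- sqrt((rowm - cr)^2 + (colm - cc)^2)
  ang <- atan2(-(rowm - cr), colm - cc) %% (2 * pi)

  id <- matrix(0L, n, n)
  cells <- list()
  next_id <- 0L

  paint_ring <- function(type, r0, r1, ncell, arc_jitter = 0.25) {
    ncell <- max(1L, as.integer(ncell))
    base <- 2 * pi * (seq_len(ncell) - 1) / ncell
    off <- runif(1, 0, 2 * pi / ncell)
    jit <- runif(ncell, -arc_jitter, arc_jitter) * 2 * pi / ncell
    bnd <- sort((base + off + jit) %% (2 * pi))
    sel <- which(rad >= r0 & rad < r1)
    sector <- findInterval(ang[sel], bnd)
    sector[sector == 0L] <- ncell
    id[sel] <<- next_id + sector
    width <- diff(c(bnd, bnd[1] + 2 * pi))
    for (j in seq_len(ncell)) {
      cells[[next_id + j]] <<- list(id = next_id + j, tissue = type,
                                    theta0 = bnd[j], width = width[j],
                                    r0 = r0, r1 = r1)
    }
    next_id <<- next_id + ncell
    invisible(NULL)
  }
  paint_disc <- function(type, centre_r, centre_c, radius) {
    next_id <<- next_id + 1L
    sel <- (rowm - centre_r)^2 + (colm - centre_c)^2 <= radius^2
    id[sel] <<- next_id
    cells[[next_id]] <<- list(id = next_id, tissue = type,
                              theta0 = NA, width = NA, r0 = NA, r1 = radius)
    invisible(NULL)
  }

  # --- stele packing (inside the endodermis) -------------------------------
  packing <- s$stele_radius - s$endodermis_thickness
  inner <- if (s$species == "wheat" && s$n_metaxylem > 0) s$metaxylem_radius else 0
  span <- packing - inner
  n_rings <- max(1L, round(span / s$stele_cell_scale))
  wts <- s$stele_ring_taper^(seq_len(n_rings) - 1)
  thick <- span * wts / sum(wts)
  edges <- inner + cumsum(c(0, thick))
  for (k in seq_len(n_rings)) {
    r0 <- edges[k]; r1 <- edges[k + 1]
    r_mid <- (r0 + r1) / 2
    arc <- max(thick[k], s$stele_cell_scale)
    paint_ring("stele", r0, r1, round(2 * pi * r_mid / arc))
  }
  # --- endodermis ring -----------------------------------------------------
  r_mid <- s$stele_radius - s$endodermis_thickness / 2
  paint_ring("endodermis", packing, s$stele_radius,
             round(2 * pi * r_mid / 25))
  # --- metaxylem and protoxylem vessels (override stele sectors) -----------
  if (s$n_metaxylem == 1) {
    paint_disc("metaxylem", cr, cc, s$metaxylem_radius)
  } else if (s$n_metaxylem > 1) {
    orbit <- s$metaxylem_orbit_fraction * packing
    phis <- 2 * pi * (seq_len(s$n_metaxylem) - 1) / s$n_metaxylem +
      runif(1, 0, 2 * pi)
    for (phi in phis) {
      paint_disc("metaxylem", cr - orbit * sin(phi), cc + orbit * cos(phi),
                 s$metaxylem_radius)
    }
  }
  if (s$n_protoxylem > 0) {
    phis <- 2 * pi * (seq_len(s$n_protoxylem) - 1) / s$n_protoxylem +
      runif(1, 0, 2 * pi) + pi / s$n_metaxylem
    for (j in seq_len(s$n_protoxylem)) {
      rj <- s$proto_fractions[j] * s$stele_radius
      paint_disc("protoxylem", cr - rj * sin(phis[j]), cc + rj * cos(phis[j]),
                 s$proto_radius)
    }
  }
  # --- cortex rings --------------------------------------------------------
  cortex_in <- s$stele_radius
  cortex_out <- s$root_radius - s$epidermis_thickness
  tC <- (cortex_out - cortex_in) / s$n_cortex_rings
  cortex_rings <- list()
  for (k in seq_len(s$n_cortex_rings)) {
    r0 <- cortex_in + (k - 1) * tC; r1 <- cortex_in + k * tC
    r_mid <- (r0 + r1) / 2
    first <- next_id + 1L
    paint_ring("cortex", r0, r1, round(2 * pi * r_mid / s$cortex_cell_scale))
    cortex_rings[[k]] <- c(first, next_id)
  }
  # --- epidermis ring ------------------------------------------------------
  epi_first_id <- next_id + 1L
  paint_ring("epidermis", cortex_out, s$root_radius, s$n_epidermis)
  epi_last_id <- next_id

  # --- aerenchyma: merge pairs of adjacent cortex cells --------------------
  if (s$n_aerenchyma > 0) {
    # pair each candidate with the next (angularly adjacent) cell of its
    # own ring; taking every second cell keeps the pairs disjoint
    cand <- unlist(lapply(cortex_rings, function(rg) {
      ids <- rg[1]:rg[2]
      ids[seq(1, length(ids) - 1, by = 2)]
    }))
    take <- sample(cand, min(s$n_aerenchyma, length(cand)))
    for (a in take) {
      id[id == a + 1L] <- a
      cells[[a]]$tissue <- "aerenchyma"
      cells[[a]]$width <- cells[[a]]$width + cells[[a + 1L]]$width
      cells[[a + 1L]] <- list(id = a + 1L, tissue = "merged",
                              theta0 = NA, width = NA, r0 = NA, r1 = NA)
    }
  }

  # --- walls: pixels whose 4-neighbourhood crosses a cell boundary ---------
  wall <- matrix(FALSE, n, n)
  for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- shift_mat(id, sh[1], sh[2], fill = 0L)
    wall <- wall | (id != nb & (id > 0L | nb > 0L))
  }

  # --- faint boundary breaks on epidermal outer walls ----------------------
  faint <- matrix(FALSE, n, n)
  if (s$break_probability > 0) {
    epi_ids <- epi_first_id:epi_last_id
    sel <- epi_ids[runif(length(epi_ids)) < s$break_probability]
    forced <- sample(epi_ids, 1)
    sel <- union(sel, forced)
    gaps <- sample(3:5, length(sel), replace = TRUE)
    gaps[sel == forced] <- 5L
    for (j in seq_along(sel)) {
      cell <- cells[[sel[j]]]
      mid <- (cell$theta0 + cell$width / 2) %% (2 * pi)
      pr <- cr - s$root_radius * sin(mid)
      pc <- cc + s$root_radius * cos(mid)
      hit <- wall & ((rowm - pr)^2 + (colm - pc)^2 <= (gaps[j] / 2)^2)
      faint <- faint | hit
      wall <- wall & !hit
    }
  }

  # --- optional lateral-root blob tangent to the perimeter -----------------
  lat_wall <- lat_int <- matrix(FALSE, n, n)
  if (s$lateral_root) {
    phi <- runif(1, 0, 2 * pi)
    br <- .synth_lateral_radius
    bc_r <- cr - (s$root_radius + br + 1) * sin(phi)
    bc_c <- cc + (s$root_radius + br + 1) * cos(phi)
    db <- sqrt((rowm - bc_r)^2 + (colm - bc_c)^2)
    free <- id == 0L & !wall
    lat_wall <- free & db <= br & db > br - 2
    lat_int <- free & db <= br - 2
  }

  # --- render --------------------------------------------------------------
  img <- matrix(.synth_bg, n, n)
  img[wall] <- s$wall_intensity
  img[faint] <- .synth_bg - .synth_faint
  img[lat_wall] <- .synth_lateral_wall
  img[lat_int] <- .synth_lateral_interior
  # illumination inhomogeneity: a linear ramp across the diagonal plus a
  # large smooth dark region overlapping one side of the root -- the
  # pattern that defeats a single global threshold while leaving local
  # contrast intact
  A <- s$background_gradient_amplitude
  if (A > 0) {
    ramp <- A * ((rowm / n + colm / n) / 2 - 0.5)
    br_ <- cr - 0.6 * s$root_radius * sin(3 * pi / 4)
    bc_ <- cc + 0.6 * s$root_radius * cos(3 * pi / 4)
    sig <- 0.7 * s$root_radius
    blotch <- 0.8 * A * exp(-((rowm - br_)^2 + (colm - bc_)^2) / (2 * sig^2))
    img <- img + ramp - blotch
  }
  if (s$noise_sigma > 0) img <- img + rnorm(n * n, 0, s$noise_sigma)
  img <- pmin(pmax(img, 0), 1)

  # --- ground truth --------------------------------------------------------
  label <- id
  label[wall | faint] <- 0L
  counts0 <- tabulate(label[label > 0L], next_id)
  tis0 <- vapply(cells, function(ce) ce$tissue, character(1))
  keep <- which(tis0 != "merged" & counts0 > 0)
  # relabel consecutively so contours index cleanly
  map <- integer(next_id); map[keep] <- seq_along(keep)
  label[label > 0L] <- map[label[label > 0L]]
  px <- which(label > 0L)
  idp <- label[px]
  m <- length(keep)
  area <- tabulate(idp, m)
  crow <- rowsum(as.numeric((px - 1L) %% n + 1L), idp)[, 1] / area
  ccol <- rowsum(as.numeric((px - 1L) %/% n + 1L), idp)[, 1] / area
  tissue <- tis0[keep]
  truth_cells <- data.frame(id = seq_len(m), tissue = tissue, area = area,
                            centroid_r = crow, centroid_c = ccol)
  boundaries <- ocontour1(label)
  names(boundaries) <- as.character(seq_len(m))
  stats <- aggregate(area ~ tissue, truth_cells, function(a)
    c(n = length(a), total = sum(a), mean = mean(a)))
  true_stats <- data.frame(tissue = stats$tissue,
                           n_cells = stats$area[, "n"],
                           total_area = stats$area[, "total"],
                           mean_area = stats$area[, "mean"])
  truth <- structure(list(label_image = label, cells = truth_cells,
                          tissue_of = setNames(tissue, seq_len(m)),
                          true_boundaries = boundaries,
                          true_stats = true_stats,
                          wall_mask = wall,
                          centre = c(cr, cc)),
                     class = "ra_truth")
  structure(list(image = img, truth = truth, spec = s), class = "ra_synth")
}

#' @export
print.ra_synth <- function(x, ...) {
  cat("synthetic", x$spec$species, "root:",
      paste(dim(x$image), collapse = " x "), "px,",
      nrow(x$truth$cells), "cells\n")
  print(table(x$truth$cells$tissue))
  invisible(x)
}

#' Write a synthetic root to disk
#'
#' Saves the rendered image as PNG, the ground-truth label image as
#' 16-bit PNG and the per-cell truth table as CSV.
#'
#' @param x an `ra_synth` object.
#' @param dir output directory.
#' @param base file-name stem.
#' @return Invisibly, the written paths.
#' @export
write_synth <- function(x, dir, base = "synthetic_root") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(base, c(".png", "_labels.png", "_truth.csv")))
  EBImage::writeImage(EBImage::Image(x$image), paths[1])
  EBImage::writeImage(EBImage::Image(x$truth$label_image / 65535), paths[2],
                      bits.per.sample = 16)
  write.csv(x$truth$cells, paths[3], row.names = FALSE)
  invisible(paths)
}
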