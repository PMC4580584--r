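#' Analysis parameters
#'
#' Construct the parameter set driving segmentation, cell detection and
#' tissue classification. All defaults are the values used throughout the
#' package's validation on micrographs at roughly 1024x1024 resolution;
#' `T`, `w`, `A_s` and `A_l` are resolution dependent and are the ones a
#' user will most often adjust.
#'
#' @param species `"wheat"` or `"maize"`. Maize enables the additional
#'   protoxylem and aerenchyma classification stages.
#' @param T intensity-difference threshold of the local segmentation rule,
#'   on the normalized \[0,1\] intensity scale. Default `0.05`.
#' @param w half-width of the local mean window in pixels; the window is
#'   `(2w+1) x (2w+1)`. Default `12`.
#' @param A_s minimum area (px^2) for a detected region to count as a cell
#'   at all; smaller regions are segmentation noise. Default `50`.
#' @param A_l minimum area (px^2) of a "large" cell (cortex scale). If
#'   `A_s` is supplied without `A_l`, `A_l = 33 * A_s` is used, a ratio
#'   that holds across image resolutions. Default `1000`.
#' @param epidermis_fraction fraction of root-perimeter cells (sorted by
#'   increasing area) labelled epidermis. Default `0.80`.
#' @param k_neighbors number of nearest-neighbour cells consulted by the
#'   classification rules. Default `5`.
#' @param neighbor_dist_max maximum centroid distance (px) to the
#'   `k_neighbors` nearest small cells for a cell to join the
#'   stele/endodermis candidate set. Default `50`.
#' @param ecc_min eccentricity above which a cell near the endodermis
#'   boundary is pulled into the stele/endodermis set. Default `0.9`.
#' @param boundary_margin distance (px) from the approximate endodermis
#'   boundary used by that same rule. Default `10`.
#' @param cortex_vote_fraction fraction of cortex nearest neighbours above
#'   which a stele/endodermis candidate is reassigned to the cortex.
#'   Default `0.5`.
#' @param lateral_intensity_fraction regions with mean interior intensity
#'   below this fraction of the mean over all regions are discarded as
#'   lateral-root artefacts. Default `1/3`.
#' @param cluster_sigma_mult the small-cell cluster keeps cells within
#'   `mean + cluster_sigma_mult * sd` of the centroid-distance
#'   distribution. Default `3`.
#' @param scale microns per pixel; applied only when statistics are
#'   reported. Default `1`.
#' @param polarity `"dark_walls"` (stained walls darker than background,
#'   the usual case; the image is negated before thresholding) or
#'   `"bright_walls"`.
#' @param perimeter_margin maximum distance (px) between a cell's contour
#'   and the outer background for the cell to count as lying on the root
#'   perimeter. Default `6` (about twice the wall thickness).
#'
#' @return An object of class `ra_params` (a validated named list).
#' @examples
#' p <- ra_params(species = "wheat")
#' p$T
#' @export
ra_params <- function(species = c("wheat", "maize"),
                      T = 0.05, w = 12,
                      A_s = 50, A_l = NULL,
                      epidermis_fraction = 0.80,
                      k_neighbors = 5,
                      neighbor_dist_max = 50,
                      ecc_min = 0.9,
                      boundary_margin = 10,
                      cortex_vote_fraction = 0.5,
                      lateral_intensity_fraction = 1 / 3,
                      cluster_sigma_mult = 3,
                      scale = 1,
                      polarity = c("dark_walls", "bright_walls"),
                      perimeter_margin = 6) {
  species <- match.arg(species)
  polarity <- match.arg(polarity)
  if (is.null(A_l)) {
    # the 33x rule only stands in when A_l is not given explicitly;
    # with the stock A_s = 50 the documented default 1000 is kept
    A_l <- if (missing(A_s)) 1000 else 33 * A_s
  }
  p <- list(
    species = species, T = T, w = w, A_s = A_s, A_l = A_l,
    epidermis_fraction = epidermis_fraction,
    k_neighbors = k_neighbors,
    neighbor_dist_max = neighbor_dist_max,
    ecc_min = ecc_min,
    boundary_margin = boundary_margin,
    cortex_vote_fraction = cortex_vote_fraction,
    lateral_intensity_fraction = lateral_intensity_fraction,
    cluster_sigma_mult = cluster_sigma_mult,
    scale = scale, polarity = polarity,
    perimeter_margin = perimeter_margin
  )
  validate_params(p)
  structure(p, class = "ra_params")
}

validate_params <- function(p) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid parameter: ", msg, call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk(p$species %in% c("wheat", "maize"), "species must be 'wheat' or 'maize'")
  chk(num1(p$T) && p$T > 0 && p$T < 1, "T must lie in (0, 1)")
  chk(num1(p$w) && p$w >= 1, "w must be >= 1")
  chk(num1(p$A_s) && p$A_s > 0, "A_s must be positive")
  chk(num1(p$A_l) && p$A_l > p$A_s, "A_l must exceed A_s")
  for (f in c("epidermis_fraction", "cortex_vote_fraction",
              "lateral_intensity_fraction")) {
    chk(num1(p[[f]]) && p[[f]] > 0 && p[[f]] <= 1,
        paste(f, "must lie in (0, 1]"))
  }
  chk(num1(p$k_neighbors) && p$k_neighbors >= 1, "k_neighbors must be >= 1")
  chk(num1(p$neighbor_dist_max) && p$neighbor_dist_max > 0,
      "neighbor_dist_max must be positive")
  chk(num1(p$ecc_min) && p$ecc_min >= 0 && p$ecc_min < 1,
      "ecc_min must lie in [0, 1)")
  chk(num1(p$boundary_margin) && p$boundary_margin >= 0,
      "boundary_margin must be non-negative")
  chk(num1(p$cluster_sigma_mult) && p$cluster_sigma_mult > 0,
      "cluster_sigma_mult must be positive")
  chk(num1(p$scale) && p$scale > 0, "scale must be positive")
  chk(num1(p$perimeter_margin) && p$perimeter_margin > 0,
      "perimeter_margin must be positive")
  invisible(p)
}

#' @export
print.ra_params <- function(x, ...) {
  cat("rootanat parameters (", x$species, ")\n", sep = "")
  for (nm in setdiff(names(x), "species")) {
    cat(sprintf("  %-27s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}

#' Read parameters from a key = value text file
#'
#' The file format is flat `key = value` lines; blank lines and lines
#' starting with `#` are ignored, as is anything after a `#` on a value
#' line. Keys are the argument names of [ra_params()]; `species` is
#' required. Unspecified keys take the documented defaults, except that a
#' file giving `A_s` but not `A_l` gets `A_l = 33 * A_s`.
#'
#' @param path path to the parameter file.
#' @return An `ra_params` object.
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (ln == "") next
    if (!grepl("=", ln, fixed = TRUE)) {
      stop(sprintf("malformed parameter line %d: '%s'", i, lines[i]),
           call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (key == "" || val == "") {
      stop(sprintf("malformed parameter line %d: '%s'", i, lines[i]),
           call. = FALSE)
    }
    known <- names(formals(ra_params))
    if (!key %in% known) {
      stop(sprintf("unknown parameter '%s' on line %d", key, i), call. = FALSE)
    }
    if (!key %in% c("species", "polarity")) {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) {
        stop(sprintf("malformed numeric value on line %d: '%s'", i, lines[i]),
             call. = FALSE)
      }
      val <- num
    }
    kv[[key]] <- val
  }
  if (is.null(kv$species)) {
    stop("parameter file must specify species (wheat or maize)", call. = FALSE)
  }
  do.call(ra_params, kv)
}

#' Suggest the large-cell area threshold from root diameter
#'
#' Across image resolutions the large-cell area gate follows the root
#' cross-section diameter `d` (in pixels) approximately quadratically:
#' `A_l = 0.0004 d^2 + 0.668 d - 112`. The polynomial goes negative for
#' small diameters, so the result is floored at `A_s` (a large-cell gate
#' can never undercut the small-cell gate).
#'
#' @param d root cross-section diameter in pixels; must be positive.
#' @param A_s lower floor for the returned value. Default `50`.
#' @return Suggested `A_l` in square pixels.
#' @examples
#' suggest_A_l(1000) # 956
#' @export
suggest_A_l <- function(d, A_s = 50) {
  if (!is.numeric(d) || any(!is.finite(d)) || any(d <= 0)) {
    stop("root diameter d must be positive", call. = FALSE)
  }
  pmax(0.0004 * d^2 + 0.668 * d - 112, A_s)
}
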