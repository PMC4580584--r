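# Tissue classification: a rule cascade driven by a-priori root anatomy
# (relative cell sizes and spatial arrangement), deliberately avoiding
# intensity contrast between regions. Stages are exported individually;
# classify_cells() runs them in order.

#' Classify epidermal cells on the root perimeter
#'
#' Cells lying on the root perimeter are mostly epidermis, with a few
#' cortex cells showing through where the epidermal layer is damaged.
#' Since epidermal cells are on average the smaller ones, the perimeter
#' cells are sorted by increasing area and the first `epidermis_fraction`
#' (default 80%) are labelled epidermis; the remainder are labelled
#' cortex. Ties are broken by ascending cell id.
#'
#' @param model an `ra_root` with `on_perimeter` computed (see
#'   [classify_cells()]).
#' @param p an [ra_params()] object.
#' @return The model with `tissue` set for perimeter cells.
#' @export
classify_epidermis <- function(model, p = model$params) {
  df <- model$cells
  if (is.null(df$on_perimeter)) model <- flag_perimeter_cells(model, p)
  df <- model$cells
  idx <- which(df$on_perimeter)
  if (length(idx) == 0) return(model)
  o <- idx[order(df$area[idx], df$id[idx])]
  n_epi <- floor(p$epidermis_fraction * length(o))
  df$tissue[o[seq_len(n_epi)]] <- "epidermis"
  df$size_class[o[seq_len(n_epi)]] <- "epidermal-candidate"
  if (n_epi < length(o)) df$tissue[o[(n_epi + 1):length(o)]] <- "cortex"
  model$cells <- df
  model
}

# distance from each cell contour to the outer background decides
# perimeter membership
flag_perimeter_cells <- function(model, p = model$params) {
  Dout <- EBImage::imageData(EBImage::distmap(model$gamma_final$mask))
  df <- model$cells
  df$on_perimeter <- vapply(as.character(df$id), function(k) {
    cont <- model$contours[[k]]
    min(Dout[cont]) <= p$perimeter_margin
  }, logical(1), USE.NAMES = FALSE)
  model$cells <- df
  model
}

#' Size-classify non-epidermal cells by area
#'
#' Cells smaller than `A_s` are segmentation noise and are excluded from
#' all further analysis. Cells with area in `[A_s, A_l)` are "small"
#' (stele / endodermis scale); cells at or above `A_l` are "large"
#' (cortex scale). Epidermis cells keep their label.
#'
#' @inheritParams classify_epidermis
#' @return The model with `size_class` filled in.
#' @export
classify_by_area <- function(model, p = model$params) {
  df <- model$cells
  idx <- df$tissue != "epidermis" & df$size_class != "epidermal-candidate"
  df$size_class[idx & df$area < p$A_s] <- "noise"
  df$tissue[idx & df$area < p$A_s] <- "noise"
  df$size_class[idx & df$area >= p$A_s & df$area < p$A_l] <- "small"
  df$size_class[idx & df$area >= p$A_l] <- "large"
  model$cells <- df
  model
}

#' Locate the small-cell cluster approximating stele plus endodermis
#'
#' The centre of mass of all small cells approximates the stele centre.
#' The distribution of small-cell centroid distances to that centre is
#' examined: when it is bimodal (stele cells near, stray small cortex
#' cells far) a Gaussian is fitted to the lower mode, isolated by an Otsu
#' cut on the distances; otherwise a Gaussian is fitted to all distances.
#' Small cells within `mean + cluster_sigma_mult * sd` (default +3 sigma)
#' are kept as the stele/endodermis candidate cluster.
#'
#' @inheritParams classify_epidermis
#' @return An object of class `ra_cluster`: `member_ids`, `centroid`,
#'   `mu`, `sigma` (of the fitted distance distribution) and `extent`
#'   (`mu + cluster_sigma_mult * sigma`).
#' @export
stele_cluster <- function(model, p = model$params) {
  df <- model$cells
  small <- df[df$size_class == "small", , drop = FALSE]
  if (nrow(small) < 3) {
    stop("degenerate root: fewer than 3 small cells, cannot locate the stele",
         call. = FALSE)
  }
  centre <- c(mean(small$centroid_r), mean(small$centroid_c))
  d <- sqrt((small$centroid_r - centre[1])^2 + (small$centroid_c - centre[2])^2)
  lower <- d
  if (length(unique(round(d, 6))) > 2) {
    t <- otsu_cut(d)
    L <- d[d <= t]; U <- d[d > t]
    if (length(U) > 0 && length(L) >= 3) {
      gap <- min(U) - max(L)
      span <- max(L) - min(L)
      if (gap > max(2, 0.25 * span)) lower <- L  # well-separated far mode
    }
  }
  mu <- mean(lower)
  sigma <- stats::sd(lower)
  if (!is.finite(sigma)) sigma <- 0
  extent <- mu + p$cluster_sigma_mult * sigma
  keep <- small$id[d <= extent]
  structure(list(member_ids = keep, centroid = centre, mu = mu, sigma = sigma,
                 extent = extent),
            class = "ra_cluster")
}

#' @export
print.ra_cluster <- function(x, ...) {
  cat(sprintf("small-cell cluster: %d members, centre (%.1f, %.1f), mu %.1f, sigma %.1f\n",
              length(x$member_ids), x$centroid[1], x$centroid[2], x$mu, x$sigma))
  invisible(x)
}

#' Detect metaxylem cells inside the small-cell cluster
#'
#' A cell is metaxylem when it (a) sits in the inner part of the cluster
#' (centroid within the mean member distance of the cluster centre --
#' metaxylem lie near the centre of mass of the stele), (b) is completely
#' surrounded by cluster cells, operationalized as all of its
#' `k_neighbors` nearest cells being cluster members or fellow metaxylem
#' candidates, and (c) is a relatively large cell (area class "large")
#' significantly larger than the cluster cells: area above the member
#' mean plus two standard deviations. Since polyarch metaxylem vessels
#' are mutually similar in size, candidates below 70% of the largest
#' candidate's area (such as protoxylem elements) are left for the later
#' stele stages. The centre of
#' mass of the metaxylem cells becomes the stele centre; with no
#' metaxylem found, the cluster centroid is the fallback.
#'
#' @inheritParams classify_epidermis
#' @param cluster an `ra_cluster` from [stele_cluster()].
#' @return The model with metaxylem labelled and `stele_centre` set.
#' @export
detect_metaxylem <- function(model, cluster, p = model$params) {
  df <- model$cells
  pool <- which(df$tissue != "noise")
  members <- which(df$id %in% cluster$member_ids)
  m_area <- mean(df$area[members])
  s_area <- stats::sd(df$area[members])
  if (!is.finite(s_area)) s_area <- 0
  d_centre <- sqrt((df$centroid_r - cluster$centroid[1])^2 +
                   (df$centroid_c - cluster$centroid[2])^2)
  cand <- which(df$tissue != "noise" &
                df$tissue != "epidermis" &
                df$size_class == "large" &
                d_centre <= cluster$mu &
                df$area > m_area + 2 * s_area)
  # metaxylem vessels are mutually similar in size and dominate all other
  # large stele cells (e.g. protoxylem); keep only candidates within 70%
  # of the largest one
  if (length(cand) > 1) {
    cand <- cand[df$area[cand] >= 0.7 * max(df$area[cand])]
  }
  accepted <- integer()
  if (length(cand) > 0) {
    pts <- cbind(df$centroid_r, df$centroid_c)
    nn <- knn_points(pts[cand, , drop = FALSE], pts[pool, , drop = FALSE],
                     k = min(p$k_neighbors, length(pool) - 1))
    allowed <- union(members, cand)
    for (i in seq_along(cand)) {
      nb <- pool[nn$idx[i, !is.na(nn$idx[i, ])]]
      nb <- setdiff(nb, cand[i])
      if (length(nb) > 0 && all(nb %in% allowed)) {
        accepted <- c(accepted, cand[i])
      }
    }
  }
  if (length(accepted) > 0) {
    df$tissue[accepted] <- "metaxylem"
    w <- df$area[accepted]
    model$stele_centre <- c(sum(df$centroid_r[accepted] * w) / sum(w),
                            sum(df$centroid_c[accepted] * w) / sum(w))
  } else {
    model$stele_centre <- cluster$centroid
  }
  model$cells <- df
  model$cluster <- cluster
  model
}

#' Nearest-neighbour screening of stele/endodermis candidates
#'
#' Cells inside the stele are surrounded by other small cells at short
#' range, while stray small cortex cells are not. Every small cell within
#' the cluster extent is kept as a stele/endodermis candidate if the
#' distance to the farthest of its `k_neighbors` nearest small cells is
#' at most `neighbor_dist_max` (default 50 px); with fewer than
#' `k_neighbors` other small cells, all available neighbours are used.
#' All other non-noise, non-epidermis, non-metaxylem cells become cortex
#' candidates at this point.
#'
#' @inheritParams detect_metaxylem
#' @return The model with `tissue` set to `"stele_endo"` or `"cortex"`.
#' @export
classify_stele_candidates <- function(model, cluster = model$cluster,
                                      p = model$params) {
  df <- model$cells
  small <- which(df$size_class == "small" & df$tissue != "metaxylem" &
                 df$tissue != "epidermis")
  pts <- cbind(df$centroid_r, df$centroid_c)
  d_centre <- sqrt((pts[, 1] - cluster$centroid[1])^2 +
                   (pts[, 2] - cluster$centroid[2])^2)
  near <- small[d_centre[small] <= cluster$extent]
  cand <- integer()
  if (length(near) > 0 && length(small) >= 2) {
    k <- min(p$k_neighbors, length(small) - 1)
    nn <- knn_points(pts[near, , drop = FALSE], pts[small, , drop = FALSE],
                     k = k)
    maxd <- apply(nn$dist, 1, max, na.rm = TRUE)
    cand <- near[maxd <= p$neighbor_dist_max]
  }
  df$tissue[cand] <- "stele_endo"
  rest <- df$tissue != "noise" & df$tissue != "epidermis" &
    df$tissue != "metaxylem" & df$tissue != "stele_endo"
  df$tissue[rest] <- "cortex"
  model$cells <- df
  model
}

#' Refine the stele/endodermis candidate set
#'
#' Three corrections around the approximate endodermis boundary (the
#' outer contour of the morphological closing of the candidate union):
#' (i) large non-metaxylem cells lying entirely inside that boundary
#' (e.g. protoxylem-scale vessels) join the stele set; (ii) strongly
#' elongated cells (eccentricity above `ecc_min`) whose centroid is
#' within `boundary_margin` pixels of the boundary join the set -- these
#' are mostly flattened endodermis cells sitting just outside it; (iii)
#' candidates whose nearest cells are mostly cortex (fraction above
#' `cortex_vote_fraction`) are handed back to the cortex.
#'
#' @inheritParams classify_epidermis
#' @return The model, with `stele_region` (approximate boundary) stored.
#' @export
refine_stele <- function(model, p = model$params) {
  df <- model$cells
  region <- candidate_region(model, include = c("stele_endo", "metaxylem"), p = p)
  if (is.null(region)) return(model)
  model$stele_region <- region

  # (i) large cells fully inside the approximate endodermis boundary
  large <- which(df$size_class == "large" & df$tissue == "cortex")
  for (i in large) {
    cont <- model$contours[[as.character(df$id[i])]]
    if (all(region$mask[cont] > 0)) df$tissue[i] <- "stele_endo"
  }
  # (ii) elongated cells hugging the boundary
  ecc <- df$eccentricity
  near <- which(df$tissue == "cortex" & !is.na(ecc) & ecc > p$ecc_min)
  if (length(near) > 0) {
    dist_b <- min_dist_to_contour(cbind(df$centroid_r[near], df$centroid_c[near]),
                                  region$polygon)
    df$tissue[near[dist_b <= p$boundary_margin]] <- "stele_endo"
  }
  # (iii) majority-cortex neighbourhood vote, on a snapshot of the labels
  cand <- which(df$tissue == "stele_endo")
  pool <- which(df$tissue != "noise")
  if (length(cand) > 0 && length(pool) > 1) {
    pts <- cbind(df$centroid_r, df$centroid_c)
    nn <- knn_points(pts[cand, , drop = FALSE], pts[pool, , drop = FALSE],
                     k = min(p$k_neighbors, length(pool) - 1))
    snapshot <- df$tissue
    for (i in seq_along(cand)) {
      nb <- pool[nn$idx[i, !is.na(nn$idx[i, ])]]
      nb <- setdiff(nb, cand[i])
      if (length(nb) > 0 &&
          mean(snapshot[nb] == "cortex") > p$cortex_vote_fraction) {
        df$tissue[cand[i]] <- "cortex"
      }
    }
  }
  model$cells <- df
  model
}

# closing of the union of the named cells' pixels; returns largest_region
# or NULL when the union is empty
candidate_region <- function(model, include, p = model$params) {
  ids <- model$cells$id[model$cells$tissue %in% include]
  if (length(ids) == 0) return(NULL)
  u <- matrix(0L, nrow(model$labels), ncol(model$labels))
  u[model$labels %in% ids] <- 1L
  closed <- EBImage::imageData(EBImage::closing(u, disc_brush(p$neighbor_dist_max / 2)))
  storage.mode(closed) <- "integer"
  largest_region(closed)
}

#' Split the stele/endodermis set into stele and endodermis
#'
#' The endodermis is the outermost single layer of the small-cell
#' cluster, so set members whose boundary touches the outer contour of
#' the set's union region are labelled endodermis and all remaining
#' members stele. A single-member set is labelled endodermis. The
#' enclosing region (including the metaxylem) is stored as
#' `stele_region` for the morphometrics stage.
#'
#' @inheritParams classify_epidermis
#' @return The model with final wheat-path tissue labels.
#' @export
identify_endodermis <- function(model, p = model$params) {
  df <- model$cells
  set <- which(df$tissue == "stele_endo")
  if (length(set) == 0) {
    model$stele_region <- candidate_region(model, "metaxylem", p = p)
    return(model)
  }
  region <- candidate_region(model, "stele_endo", p = p)
  if (length(set) == 1) {
    df$tissue[set] <- "endodermis"
  } else {
    for (i in set) {
      cont <- model$contours[[as.character(df$id[i])]]
      touches <- min(min_dist_to_contour(cont, region$polygon)) <= p$perimeter_margin
      df$tissue[i] <- if (touches) "endodermis" else "stele"
    }
  }
  model$cells <- df
  model$stele_region <- candidate_region(
    model, include = c("stele", "endodermis", "metaxylem"), p = p)
  model
}

#' Run the full tissue-classification cascade
#'
#' Computes per-cell eccentricities and perimeter flags, then applies the
#' classification stages in order: epidermis, area classes, small-cell
#' cluster, metaxylem, stele candidates, refinement, endodermis, and for
#' maize the protoxylem and aerenchyma extensions. The cascade is fully
#' deterministic.
#'
#' @param model an `ra_root` from [detect_root_model()] /
#'   [recover_missed_cells()].
#' @param p an [ra_params()] object.
#' @return The classified model: every non-noise cell carries exactly one
#'   tissue label.
#' @export
classify_cells <- function(model, p = model$params) {
  model$params <- p
  model$cells$eccentricity <- cell_eccentricities(model)
  model <- flag_perimeter_cells(model, p)
  model <- classify_epidermis(model, p)
  model <- classify_by_area(model, p)
  cluster <- stele_cluster(model, p)
  model <- detect_metaxylem(model, cluster, p)
  model <- classify_stele_candidates(model, cluster, p)
  model <- refine_stele(model, p)
  model <- identify_endodermis(model, p)
  if (p$species == "maize") {
    model <- detect_protoxylem(model, p)
    model <- detect_aerenchyma(model, p)
  }
  model
}
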