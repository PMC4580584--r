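# Maize extension: protoxylem elements near the stele periphery and
# aerenchyma (enlarged air spaces) in the cortex. Both stages are no-ops
# for wheat, where protoxylem is indistinguishable from xylem parenchyma
# and aerenchyma is absent.

#' Detect protoxylem elements (maize)
#'
#' Large non-metaxylem cells classified as stele are protoxylem
#' candidates. For each candidate the ray from the stele centre through
#' the cell centroid is extended to the stele boundary (the outer contour
#' of the stele/endodermis region); candidates whose centroid lies more
#' than half way along that ray -- near the stele periphery, where
#' protoxylem poles sit -- are relabelled protoxylem. The position
#' fraction is a ratio of collinear distances, hence invariant to
#' uniform image scaling.
#'
#' @param model a classified `ra_root`.
#' @param p an [ra_params()] object; must have `species = "maize"` for
#'   the stage to act.
#' @return The model, with protoxylem labelled when species is maize.
#' @export
detect_protoxylem <- function(model, p = model$params) {
  if (p$species != "maize") return(model)
  if (is.null(model$stele_region) || is.null(model$stele_centre)) return(model)
  df <- model$cells
  cand <- which(df$tissue == "stele" & df$size_class == "large")
  if (length(cand) == 0) return(model)
  r_b <- contour_radius_fn(model$stele_region$polygon, model$stele_centre)
  pol <- polar_about(cbind(df$centroid_r[cand], df$centroid_c[cand]),
                     model$stele_centre)
  frac <- pol$r / r_b(pol$theta)
  df$tissue[cand[frac > 0.5]] <- "protoxylem"
  model$cells <- df
  model
}

#' Radial position of a cell along its stele ray
#'
#' Fraction `|centre -> centroid| / |centre -> boundary|` along the ray
#' from the stele centre through the cell centroid, the quantity the
#' protoxylem rule thresholds at one half.
#'
#' @param model a classified `ra_root`.
#' @param ids cell ids (default: all cells).
#' @return Numeric vector of fractions.
#' @export
radial_fraction <- function(model, ids = model$cells$id) {
  idx <- match(ids, model$cells$id)
  r_b <- contour_radius_fn(model$stele_region$polygon, model$stele_centre)
  pol <- polar_about(cbind(model$cells$centroid_r[idx],
                           model$cells$centroid_c[idx]), model$stele_centre)
  pol$r / r_b(pol$theta)
}

#' Detect aerenchyma in the cortex (maize)
#'
#' The areas of large cortex cells are modelled as a two-component
#' Gaussian mixture: regular cortex cells and the substantially larger
#' aerenchyma lacunae. The classification threshold is set one standard
#' deviation below the mean of the larger component, and every large
#' cortex cell above it is relabelled aerenchyma. When the two fitted
#' components are not separated by at least one pooled standard
#' deviation (or the fit degenerates), the distribution is treated as
#' unimodal and no aerenchyma is reported.
#'
#' @inheritParams detect_protoxylem
#' @return The model, with aerenchyma labelled when species is maize.
#' @export
detect_aerenchyma <- function(model, p = model$params) {
  if (p$species != "maize") return(model)
  df <- model$cells
  cand <- which(df$tissue == "cortex" & df$size_class == "large")
  if (length(cand) < 2) return(model)
  thr <- aerenchyma_threshold(df$area[cand])
  if (is.na(thr)) return(model)
  df$tissue[cand[df$area[cand] > thr]] <- "aerenchyma"
  model$cells <- df
  model
}

#' Two-Gaussian area threshold for aerenchyma
#'
#' Fits a two-component univariate Gaussian mixture by
#' expectation-maximization (deterministic quartile-based k-means
#' initialisation, variance floor for singleton components) to a vector
#' of cell areas and returns the threshold `mu_larger - sigma_larger`.
#' `NA` signals a degenerate or effectively unimodal fit: fewer than two
#' distinct values, or component means closer than one pooled standard
#' deviation.
#'
#' @param areas numeric vector of large-cortex cell areas (px^2).
#' @return The area threshold, or `NA`.
#' @export
aerenchyma_threshold <- function(areas) {
  if (length(areas) < 2 || length(unique(areas)) < 2) return(NA_real_)
  fit <- em_gmm2(areas)
  if (is.null(fit)) return(NA_real_)
  hi <- which.max(fit$mu); lo <- which.min(fit$mu)
  pooled <- sqrt(sum(fit$pro * fit$sigma^2))
  if (!is.finite(pooled) || pooled <= 0) pooled <- stats::sd(areas)
  if ((fit$mu[hi] - fit$mu[lo]) < pooled) return(NA_real_)  # unimodal
  fit$mu[hi] - fit$sigma[hi]
}

# two-component 1-D Gaussian mixture via EM; initialisation from a
# k-means split at the lower/upper quartiles, so the fit is fully
# deterministic; component variances are floored to keep singleton
# components finite
em_gmm2 <- function(x, max_iter = 200, tol = 1e-8) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  if (q[1] == q[2]) q <- range(x)
  km <- suppressWarnings(stats::kmeans(x, centers = matrix(q, 2, 1)))
  floor_sd <- max(1e-3 * diff(range(x)), 1e-9)
  mu <- as.numeric(km$centers)
  sg <- vapply(1:2, function(g) {
    s <- stats::sd(x[km$cluster == g])
    if (!is.finite(s) || s < floor_sd) floor_sd else s
  }, numeric(1))
  pro <- tabulate(km$cluster, 2) / length(x)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- pro[1] * stats::dnorm(x, mu[1], sg[1])
    d2 <- pro[2] * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    z <- d1 / tot
    n1 <- sum(z); n2 <- length(x) - n1
    if (n1 < 1e-8 || n2 < 1e-8) return(NULL)  # component collapsed away
    mu <- c(sum(z * x) / n1, sum((1 - z) * x) / n2)
    sg <- c(sqrt(sum(z * (x - mu[1])^2) / n1),
            sqrt(sum((1 - z) * (x - mu[2])^2) / n2))
    sg <- pmax(sg, floor_sd)
    pro <- c(n1, n2) / length(x)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(mu = mu, sigma = sg, pro = pro)
}
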