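# Brute-force oracles and shared fixtures for the test suite.

# direct double-loop evaluation of the local mean with truncated windows;
# independent of the integral-image implementation under test
brute_mean_filter <- function(I, w) {
  nr <- nrow(I); nc <- ncol(I)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      out[i, j] <- mean(I[max(1, i - w):min(nr, i + w),
                          max(1, j - w):min(nc, j + w)])
    }
  }
  out
}

brute_local_threshold <- function(I, w, T) {
  (I - brute_mean_filter(I, w) > T) * 1L
}

# match ground-truth cells to detected cells by looking up the detected
# label at each truth centroid; returns per-truth-cell detected id (0 =
# missed) plus relative area error for the matched ones
match_truth <- function(model, truth) {
  det_id <- model$labels[cbind(round(truth$cells$centroid_r),
                               round(truth$cells$centroid_c))]
  idx <- match(det_id, model$cells$id)
  area_err <- ifelse(det_id > 0,
                     abs(model$cells$area[idx] - truth$cells$area) /
                       truth$cells$area, NA)
  pred <- ifelse(det_id > 0, model$cells$tissue[idx], NA)
  list(det_id = det_id, area_err = area_err, pred = pred)
}

# fixture cache: synthetic roots and analyzed models are expensive enough
# to share across test files
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

wheat_synth <- function(seed = 1, ...) {
  extra <- list(...)
  key <- paste0("wheat_", seed, "_",
                paste(names(extra), unlist(extra), collapse = "_"))
  cached(key, generate_root(synthetic_spec("wheat", seed = seed, ...)))
}

wheat_model <- function(seed = 1) {
  cached(paste0("wheat_model_", seed), {
    analyze_image(wheat_synth(seed)$image, ra_params("wheat"))
  })
}

maize_model_fixture <- function(seed = 1) {
  cached(paste0("maize_model_", seed), {
    synth <- generate_root(synthetic_spec("maize", seed = seed,
                                          proto_fractions = c(0.3, 0.8)))
    list(synth = synth,
         model = analyze_image(synth$image, ra_params("maize")))
  })
}

# a bare-bones classified-model stand-in for unit tests of single
# classification stages that only consult the cells data frame
fake_model <- function(cells, p = ra_params("wheat")) {
  structure(list(cells = cells, params = p, contours = list(),
                 labels = matrix(0L, 1, 1), recovered_ids = integer()),
            class = "ra_root")
}
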