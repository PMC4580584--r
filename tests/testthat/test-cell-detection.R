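square_ring <- function(n, r0, c0, side, nc = n) {
  m <- matrix(0L, n, nc)
  m[r0, c0:(c0 + side - 1)] <- 1L
  m[r0 + side - 1, c0:(c0 + side - 1)] <- 1L
  m[r0:(r0 + side - 1), c0] <- 1L
  m[r0:(r0 + side - 1), c0 + side - 1] <- 1L
  m
}

test_that("2x2 dilation follows the documented top-left anchor", {
  e <- matrix(0L, 8, 8)
  expect_identical(dilate_mask(e), e)
  f <- matrix(1L, 8, 8)
  expect_identical(dilate_mask(f), f)
  s <- matrix(0L, 8, 8); s[3, 4] <- 1L
  d <- dilate_mask(s)
  expect_identical(d[3:4, 4:5], matrix(1L, 2, 2))  # the 2x2 block
  expect_equal(sum(d), 4)
  # dilation is a superset of the input
  set.seed(5)
  b <- matrix(rbinom(400, 1, 0.2), 20, 20)
  expect_true(all(dilate_mask(b) >= b))
})

test_that("enclosed background components become cells; border components do not", {
  expect_equal(nrow(detect_cells(matrix(0L, 20, 20))$cells), 0)

  ring <- square_ring(16, 4, 5, 10)
  cells <- detect_cells(ring)
  expect_equal(nrow(cells$cells), 1)
  expect_equal(cells$cells$area, 64)  # 8 x 8 interior
  expect_equal(cells$cells$centroid_r, 4 + (10 - 1) / 2)

  nested <- square_ring(30, 3, 3, 24) + square_ring(30, 9, 9, 12)
  cells2 <- detect_cells(pmin(nested, 1L))
  expect_equal(nrow(cells2$cells), 2)  # inner square + annulus between rings
  # interiors are pairwise disjoint by construction of the labelling
  expect_equal(sum(cells2$labels > 0),
               sum(cells2$cells$area))
})

test_that("lateral-root artefacts are removed by the one-third intensity rule", {
  # three enclosed cells with interior intensities 0.6, 0.6, 0.1:
  # overall mean 0.4333, cutoff 0.1444 -> only the dark one goes
  m <- matrix(0L, 14, 34)
  img <- matrix(0.9, 14, 34)
  for (k in 0:2) {
    m <- m + square_ring(14, 4, 3 + k * 10, 8, nc = 34)
    img[5:10, (4 + k * 10):(9 + k * 10)] <- c(0.6, 0.6, 0.1)[k + 1]
  }
  cells <- detect_cells(pmin(m, 1L), img)
  expect_equal(nrow(cells$cells), 3)
  filt <- remove_lateral_roots(cells, img, ra_params("wheat"))
  expect_equal(nrow(filt$cells), 2)
  expect_true(all(filt$cells$mean_intensity > 0.5))

  # equal intensities: nothing removed; single cell: never removed
  cells_eq <- detect_cells(pmin(m, 1L), matrix(0.5, 14, 34))
  expect_equal(nrow(remove_lateral_roots(cells_eq, img, ra_params("wheat"))$cells), 3)
  one <- detect_cells(square_ring(14, 4, 3, 8), matrix(0.05, 14, 14))
  expect_equal(nrow(remove_lateral_roots(one, img, ra_params("wheat"))$cells), 1)
})

test_that("the initial root boundary encloses all detected cells", {
  synth <- wheat_synth(seed = 2)
  p <- ra_params("wheat")
  B <- local_threshold(synth$image, p)
  Bd <- dilate_mask(B)
  cells <- detect_cells(Bd, synth$image, B)
  gb <- initial_root_boundary(cells, Bd)
  # every centroid inside the boundary mask, area at least the cell total
  inside <- gb$mask[cbind(round(cells$cells$centroid_r),
                          round(cells$cells$centroid_c))]
  expect_true(all(inside > 0))
  expect_gte(gb$area, sum(cells$cells$area))
  # circular root: enclosed area within 5% of pi r^2
  expect_lt(abs(gb$area - pi * 190^2) / (pi * 190^2), 0.05)

  empty <- structure(list(labels = matrix(0L, 5, 5),
                          cells = data.frame(id = integer())),
                     class = "ra_cells")
  expect_error(initial_root_boundary(empty, matrix(0L, 5, 5)), "no cells")
})

test_that("distance transform and its peaks behave as the geometry dictates", {
  expect_equal(distance_map(matrix(1L, 10, 10)), matrix(0, 10, 10))
  b <- matrix(0L, 12, 12); b[4, 5] <- 1L
  D <- distance_map(b)
  expect_equal(D[7, 9], 5)  # offset (3,4)
  expect_error(distance_map(matrix(0L, 4, 4)), "all-background")

  ring <- square_ring(21, 1, 1, 21)  # centre is 10 px from the ring
  Dr <- distance_map(ring)
  expect_equal(max(Dr[2:20, 2:20]), 10)
  pk <- find_distance_peaks(Dr, min_height = 2)
  expect_true(all(Dr[cbind(pk[, "r"], pk[, "c"])] == 10))
})

test_that("first-pass detection recovers planted cells with accurate areas", {
  synth <- wheat_synth(seed = 2)
  model <- detect_root_model(synth$image, ra_params("wheat"))
  m <- match_truth(model, synth$truth)
  expect_gte(mean(m$det_id > 0), 0.95)
  expect_lte(mean(m$area_err, na.rm = TRUE), 0.10)
})

test_that("the relaxed pass adds broken boundary cells and never removes any", {
  p <- ra_params("wheat")
  broken <- generate_root(synthetic_spec("wheat", seed = 11,
                                         break_probability = 0.05))
  m1 <- detect_root_model(broken$image, p)
  m2 <- recover_missed_cells(broken$image, p, m1)
  expect_gt(nrow(m2$cells), nrow(m1$cells))
  expect_true(all(m1$cells$id %in% m2$cells$id))
  # recovered cells lie inside the recomputed boundary
  rec <- m2$cells[m2$cells$id %in% m2$recovered_ids, ]
  inside <- m2$gamma_final$mask[cbind(round(rec$centroid_r),
                                      round(rec$centroid_c))]
  expect_true(all(inside > 0))

  # intact root: no additions, gamma_final equals gamma_ini
  intact <- wheat_synth(seed = 2)
  i1 <- detect_root_model(intact$image, p)
  i2 <- recover_missed_cells(intact$image, p, i1)
  expect_equal(length(i2$recovered_ids), 0)
  expect_identical(i2$gamma_final$polygon, i2$gamma_ini$polygon)
})
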