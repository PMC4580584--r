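circle_pts <- function(r, n = 200, noise = 0) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-1]
  cbind(r * sin(t), r * cos(t)) + matrix(rnorm(2 * n, 0, noise), n, 2)
}

test_that("ellipse fits recover axes, eccentricity and invariances", {
  f <- fit_ellipse(circle_pts(20))
  expect_lt(f$E, 0.02)
  expect_equal(f$a, 20, tolerance = 1e-6)

  t <- seq(0, 2 * pi, length.out = 101)[-1]
  e53 <- cbind(3 * sin(t), 5 * cos(t))
  f2 <- fit_ellipse(e53)
  expect_equal(f2$E, 0.8, tolerance = 1e-9)  # sqrt(1 - 9/25)
  expect_equal(c(f2$a, f2$b), c(5, 3), tolerance = 1e-9)

  # 1-px coordinate noise on a 100 x 60 ellipse: axes within 1%
  set.seed(33)
  big <- cbind(60 * sin(t), 100 * cos(t)) + matrix(rnorm(200, 0, 1), 100, 2)
  f3 <- fit_ellipse(big)
  expect_lt(abs(f3$a - 100) / 100, 0.01)
  expect_lt(abs(f3$b - 60) / 60, 0.01)

  # scale invariance of E
  for (s in c(0.1, 3, 42)) {
    expect_equal(fit_ellipse(e53 * s)$E, 0.8, tolerance = 1e-6)
  }

  expect_error(fit_ellipse(e53[1:4, ]), "at least 5")
  line <- cbind(1:10, 2 * (1:10))
  expect_error(fit_ellipse(line), "collinear")
})

test_that("tissue statistics carry the Table-1 schema, units and identities", {
  model <- wheat_model(seed = 1)
  stats <- compute_tissue_stats(model, scale = 2)
  expect_setequal(unique(stats$region),
                  c("whole_root", "cortex", "stele", "endodermis", "metaxylem"))
  # every tissue region reports all four features (stele adds its own
  # region eccentricity)
  for (ti in c("cortex", "endodermis", "metaxylem")) {
    expect_setequal(stats$feature[stats$region == ti],
                    c("total_area", "cell_count", "mean_cell_area",
                      "mean_cell_eccentricity"))
  }
  expect_setequal(stats$feature[stats$region == "stele"],
                  c("total_area", "cell_count", "mean_cell_area",
                    "mean_cell_eccentricity", "eccentricity"))

  # counts identity over the partition
  counts <- stats$value[stats$feature == "cell_count"]
  df <- model$cells
  expect_equal(sum(counts),
               sum(!df$tissue %in% c("noise", "epidermis")))

  # unit conversion: areas scale with the square of microns-per-pixel
  s1 <- compute_tissue_stats(model, scale = 1)
  a1 <- s1$value[s1$region == "metaxylem" & s1$feature == "total_area"]
  a2 <- stats$value[stats$region == "metaxylem" & stats$feature == "total_area"]
  expect_equal(a2, 4 * a1)

  # whole root >= stele region >= metaxylem
  root_a <- s1$value[s1$region == "whole_root" & s1$feature == "total_area"]
  stele_a <- s1$value[s1$region == "stele" & s1$feature == "total_area"]
  expect_gte(root_a, stele_a)
  expect_gte(stele_a, a1)

  # single planted metaxylem: count 1 and area close to the planted cell
  synth <- wheat_synth(seed = 1)
  mx_true <- synth$truth$cells$area[synth$truth$cells$tissue == "metaxylem"]
  expect_equal(s1$value[s1$region == "metaxylem" & s1$feature == "cell_count"], 1)
  expect_lt(abs(a1 - mx_true) / mx_true, 0.10)
})

test_that("stats are invariant to the order cells are stored in", {
  model <- wheat_model(seed = 1)
  shuf <- model
  set.seed(9)
  o <- sample(nrow(shuf$cells))
  shuf$cells <- shuf$cells[o, ]
  s1 <- compute_tissue_stats(model, scale = 1)
  s2 <- compute_tissue_stats(shuf, scale = 1)
  expect_equal(s1, s2)
})

test_that("the cheesewheel partitions each zone into exactly 36 regions", {
  model <- wheat_model(seed = 1)
  cw <- cheesewheel(model)
  expect_equal(nrow(cw), 72)
  expect_equal(sum(cw$zone == "stele-zone"), 36)
  expect_equal(sum(cw$zone == "cortex-zone"), 36)
  # partition: counts add up to the zone cell totals
  df <- model$cells
  expect_equal(sum(cw$cell_count[cw$zone == "stele-zone"]),
               sum(df$tissue %in% c("stele", "endodermis", "metaxylem")))
  expect_equal(sum(cw$cell_count[cw$zone == "cortex-zone"]),
               sum(df$tissue == "cortex"))

  no_region <- model; no_region$stele_region <- NULL
  expect_error(cheesewheel(no_region), "endodermis contour")
})

test_that("radially flattening stele cells show up as an outward eccentricity trend", {
  synth <- generate_root(synthetic_spec("wheat", seed = 6,
                                        stele_ring_taper = 0.7))
  model <- analyze_image(synth$image, ra_params("wheat"))
  cw <- cheesewheel(model)
  sz <- cw[cw$zone == "stele-zone" & cw$cell_count > 0, ]
  inner <- min(sz$annulus); outer <- max(sz$annulus)
  e_in <- mean(sz$mean_eccentricity[sz$annulus == inner], na.rm = TRUE)
  e_out <- mean(sz$mean_eccentricity[sz$annulus == outer], na.rm = TRUE)
  expect_gt(e_out, e_in)
})

test_that("write_stats produces the three CSVs, also for an empty model", {
  model <- wheat_model(seed = 1)
  dir <- withr::local_tempdir()
  paths <- write_stats(model, dir, "wheat1")
  expect_true(all(file.exists(paths)))
  summ <- read.csv(paths[1])
  expect_named(summ, c("region", "feature", "value", "unit"))
  cells <- read.csv(paths[2])
  expect_named(cells, c("id", "tissue", "area_um2", "eccentricity",
                        "centroid_r", "centroid_c"))
  cw <- read.csv(paths[3])
  expect_equal(nrow(cw), 72)

  empty <- fake_model(data.frame(id = integer(), area = integer(),
                                 centroid_r = numeric(), centroid_c = numeric(),
                                 mean_intensity = numeric(),
                                 tissue = character(),
                                 size_class = character()))
  paths2 <- write_stats(empty, dir, "empty")
  expect_true(all(file.exists(paths2)))
  expect_equal(nrow(read.csv(paths2[2])), 0)
})
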