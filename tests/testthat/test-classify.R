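test_that("perimeter cells split 80/20 into epidermis and cortex by area", {
  p <- ra_params("wheat")
  cells <- data.frame(id = 1:12, area = c(1:10, 500, 600),
                      centroid_r = 1:12, centroid_c = 1:12,
                      mean_intensity = 0.5, tissue = "unassigned",
                      size_class = "unassigned",
                      on_perimeter = c(rep(TRUE, 10), FALSE, FALSE))
  m <- classify_epidermis(fake_model(cells), p)
  expect_equal(m$cells$tissue[1:8], rep("epidermis", 8))
  expect_equal(m$cells$tissue[9:10], rep("cortex", 2))
  expect_equal(m$cells$tissue[11:12], rep("unassigned", 2))

  # equal areas: floor(0.8 * 5) = 4 epidermis, tie-break by id
  eq <- data.frame(id = 1:5, area = 7, centroid_r = 1:5, centroid_c = 1:5,
                   mean_intensity = 0.5, tissue = "unassigned",
                   size_class = "unassigned", on_perimeter = TRUE)
  m2 <- classify_epidermis(fake_model(eq), p)
  expect_equal(m2$cells$tissue, c(rep("epidermis", 4), "cortex"))

  none <- eq; none$on_perimeter <- FALSE
  m3 <- classify_epidermis(fake_model(none), p)
  expect_equal(m3$cells$tissue, rep("unassigned", 5))
})

test_that("area gates split cells into noise, small and large", {
  p <- ra_params("wheat")
  cells <- data.frame(id = 1:4, area = c(30, 500, 1500, 80),
                      centroid_r = 1:4, centroid_c = 1:4,
                      mean_intensity = 0.5,
                      tissue = c("unassigned", "unassigned", "unassigned",
                                 "epidermis"),
                      size_class = c(rep("unassigned", 3),
                                     "epidermal-candidate"),
                      on_perimeter = FALSE)
  m <- classify_by_area(fake_model(cells), p)
  expect_equal(m$cells$size_class[1:3], c("noise", "small", "large"))
  expect_equal(m$cells$tissue[1], "noise")
  expect_equal(m$cells$size_class[4], "epidermal-candidate")  # untouched
})

test_that("the small-cell cluster isolates the stele against scattered far cells", {
  p <- ra_params("wheat")
  set.seed(21)
  th <- runif(50, 0, 2 * pi); rr <- sqrt(runif(50)) * 40
  far_th <- runif(10, 0, 2 * pi); far_r <- runif(10, 200, 260)
  cells <- data.frame(id = 1:60,
                      area = 300,
                      centroid_r = c(rr * sin(th), far_r * sin(far_th)),
                      centroid_c = c(rr * cos(th), far_r * cos(far_th)),
                      mean_intensity = 0.5, tissue = "unassigned",
                      size_class = "small", on_perimeter = FALSE)
  cl <- stele_cluster(fake_model(cells), p)
  expect_setequal(cl$member_ids, 1:50)

  # one tight disc: everyone retained
  tight <- cells[1:50, ]
  cl2 <- stele_cluster(fake_model(tight), p)
  expect_setequal(cl2$member_ids, 1:50)

  # symmetric point set: centroid at the origin
  sym <- data.frame(id = 1:4, area = 300,
                    centroid_r = c(-10, 10, 0, 0),
                    centroid_c = c(0, 0, -10, 10),
                    mean_intensity = 0.5, tissue = "unassigned",
                    size_class = "small", on_perimeter = FALSE)
  expect_equal(stele_cluster(fake_model(sym), p)$centroid, c(0, 0))

  few <- sym[1:2, ]
  expect_error(stele_cluster(fake_model(few), p), "fewer than 3")
})

test_that("metaxylem needs size, a central position and an all-member neighbourhood", {
  p <- ra_params("wheat")
  # ring of small cluster cells around one large centre cell
  th <- 2 * pi * (0:19) / 20
  cells <- data.frame(id = 1:22,
                      area = c(rep(100, 20), 1200, 1300),
                      centroid_r = c(30 * sin(th), 0, 200),
                      centroid_c = c(30 * cos(th), 0, 215),
                      mean_intensity = 0.5, tissue = "unassigned",
                      size_class = c(rep("small", 20), "large", "large"),
                      on_perimeter = FALSE)
  cl <- stele_cluster(fake_model(cells), p)
  m <- detect_metaxylem(fake_model(cells), cl, p)
  expect_equal(m$cells$tissue[21], "metaxylem")
  expect_equal(m$cells$tissue[22], "unassigned")  # far away: rules (a),(b) fail
  expect_equal(m$stele_centre, c(0, 0), tolerance = 1e-9)

  # no large cell at all: empty set, centre falls back to cluster centroid
  small_only <- cells[1:20, ]
  cl2 <- stele_cluster(fake_model(small_only), p)
  m2 <- detect_metaxylem(fake_model(small_only), cl2, p)
  expect_false(any(m2$cells$tissue == "metaxylem"))
  expect_equal(m2$stele_centre, cl2$centroid)
})

test_that("stele candidacy uses the max distance to the five nearest small cells", {
  p <- ra_params("wheat")
  # 5 x 5 grid at 20 px pitch: max 5-NN distance = sqrt(800) ~ 28.3 <= 50
  g <- expand.grid(r = seq(0, 80, 20), c = seq(0, 80, 20))
  n <- nrow(g)
  cells <- data.frame(id = seq_len(n + 1),
                      area = 300,
                      centroid_r = c(g$r, 40),
                      centroid_c = c(g$c, 300),  # one isolated far cell
                      mean_intensity = 0.5, tissue = "unassigned",
                      size_class = "small", on_perimeter = FALSE)
  cl <- stele_cluster(fake_model(cells), p)
  m <- classify_stele_candidates(fake_model(cells), cl, p)
  expect_equal(m$cells$tissue[seq_len(n)], rep("stele_endo", n))
  expect_equal(m$cells$tissue[n + 1], "cortex")

  # three mutually close small cells: all candidates with two neighbours
  tri <- data.frame(id = 1:3, area = 300,
                    centroid_r = c(0, 30, 0), centroid_c = c(0, 0, 30),
                    mean_intensity = 0.5, tissue = "unassigned",
                    size_class = "small", on_perimeter = FALSE)
  cl3 <- stele_cluster(fake_model(tri), p)
  m3 <- classify_stele_candidates(fake_model(tri), cl3, p)
  expect_equal(m3$cells$tissue, rep("stele_endo", 3))
})

test_that("the full cascade labels synthetic wheat tissues at 90%+ accuracy", {
  accs <- numeric(0); mx_ok <- logical(0)
  for (s in 1:3) {
    synth <- wheat_synth(seed = s)
    model <- wheat_model(seed = s)
    m <- match_truth(model, synth$truth)
    accs <- c(accs, mean(m$pred == synth$truth$cells$tissue, na.rm = TRUE))
    mx_ok <- c(mx_ok, sum(model$cells$tissue == "metaxylem") ==
                 sum(synth$truth$cells$tissue == "metaxylem"))
    # label partition: every non-noise cell carries exactly one tissue label
    lab <- model$cells$tissue
    expect_true(all(lab %in% c("epidermis", "cortex", "stele", "endodermis",
                               "metaxylem", "noise")))
    expect_equal(sum(lab != "noise"),
                 sum(lab == "epidermis") + sum(lab == "cortex") +
                   sum(lab == "stele") + sum(lab == "endodermis") +
                   sum(lab == "metaxylem"))
  }
  expect_true(all(accs >= 0.9))
  expect_true(all(mx_ok))
})

test_that("endodermis is the outermost ring of the stele cluster", {
  synth <- wheat_synth(seed = 1)
  model <- wheat_model(seed = 1)
  m <- match_truth(model, synth$truth)
  truth_t <- synth$truth$cells$tissue
  agree <- mean(m$pred[truth_t == "endodermis"] == "endodermis", na.rm = TRUE)
  expect_gte(agree, 0.9)
  # every endodermis cell touches the outer contour of the stele region
  endo <- model$cells$id[model$cells$tissue == "endodermis"]
  dists <- vapply(endo, function(id) {
    cont <- model$contours[[as.character(id)]]
    min(apply(cont, 1, function(q)
      sqrt(min((model$stele_region$polygon[, 1] - q[1])^2 +
                 (model$stele_region$polygon[, 2] - q[2])^2))))
  }, numeric(1))
  expect_true(all(dists <= model$params$perimeter_margin))
})

test_that("the cascade is deterministic", {
  synth <- wheat_synth(seed = 1)
  p <- ra_params("wheat")
  m1 <- analyze_image(synth$image, p)
  m2 <- analyze_image(synth$image, p)
  expect_identical(m1$cells, m2$cells)
})
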