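params_triple <- function() fluo_detection_params(dapi_min_mean = 25)

test_that("nucleus detection handles blanks, thresholds, and planted scenes", {
  blank <- raster_image(list(DAPI = matrix(0, 200, 200),
                             KI67 = matrix(0, 200, 200),
                             CK20 = matrix(0, 200, 200),
                             TUNEL = matrix(0, 200, 200)),
                        calibration = 0.225)
  expect_equal(nrow(detect_nuclei_fluor(blank, params_triple())), 0)

  g <- generate_fluorescence_section(
    n_cells = 150, dim = c(1150, 1150), seed = 61,
    class_mix = c(ki67_ck20 = 0.5, ki67_only = 0, ck20_only = 0.5,
                  negative = 0, tunel = 0))
  cells <- detect_nuclei_fluor(g$image, params_triple())
  expect_true(abs(nrow(cells) - 150) <= 3)

  # a probability threshold of 1 kills every detection (score < 1 by design)
  p1 <- fluo_detection_params(probability_threshold = 1, dapi_min_mean = 25)
  expect_equal(nrow(detect_nuclei_fluor(g$image, p1)), 0)

  noDAPI <- raster_image(list(KI67 = matrix(0, 50, 50)), calibration = 0.225)
  expect_error(detect_nuclei_fluor(noDAPI, params_triple()), "DAPI")
})

test_that("channel aliases resolve acquisition names", {
  img <- raster_image(list(`Ch1-T2` = matrix(0, 20, 20)), calibration = 1)
  p <- fluo_detection_params(dapi_channel = "DAPI")
  expect_equal(nrow(detect_nuclei_fluor(img, p)), 0)   # resolves, no nuclei
})

test_that("nucleus exclusion rules are pure and order-independent", {
  cells <- tibble::tibble(id = 1:4, label = 1:4,
                          area_um2 = c(10, 100, 100, 200),
                          dapi_mean = c(120, 50, 120, 120))
  attr(cells, "channels") <- list()
  p <- fluo_detection_params(dapi_min_mean = 60)
  kept <- filter_nuclei(cells, p)
  expect_equal(kept$id, 3L)   # area 10 too small, DAPI 50 too dim, 200 too big
  shuf <- cells[c(3, 1, 4, 2), ]
  expect_equal(filter_nuclei(shuf, p)$id, 3L)
})

test_that("cytoplasm expansion matches the analytic annulus and stays disjoint", {
  # single circular nucleus r = 3 um, expansion 5 um
  cal <- 0.5
  d <- 160
  dapi <- matrix(0, d, d)
  for (i in 1:d) for (j in 1:d) {
    if ((i - 80)^2 + (j - 80)^2 <= (3 / cal)^2) dapi[i, j] <- 200
  }
  img <- raster_image(list(DAPI = dapi), calibration = cal)
  # mask threshold at half-max so the detected mask matches the hard disk
  p <- fluo_detection_params(requested_pixel_size = cal, area_min = 5,
                             area_max = 300, dapi_min_mean = 25,
                             mask_threshold = 100)
  cells <- filter_nuclei(detect_nuclei_fluor(img, p), p)
  expect_equal(nrow(cells), 1)
  ex <- expand_cytoplasm(cells, radius = 5)
  expect_equal(ex$cyto_area_um2, pi * (8^2 - 3^2), tolerance = 0.08)

  ex0 <- expand_cytoplasm(cells, radius = 0)
  expect_equal(ex0$cyto_area_um2, 0)
  expect_error(expand_cytoplasm(cells, radius = -1), ">= 0")

  # two adjacent nuclei: cytoplasm partitions are disjoint
  dapi2 <- matrix(0, d, d)
  for (i in 1:d) for (j in 1:d) {
    if ((i - 70)^2 + (j - 60)^2 <= 36) dapi2[i, j] <- 200
    if ((i - 70)^2 + (j - 90)^2 <= 36) dapi2[i, j] <- 200
  }
  img2 <- raster_image(list(DAPI = dapi2), calibration = cal)
  cells2 <- filter_nuclei(detect_nuclei_fluor(img2, p), p)
  expect_equal(nrow(cells2), 2)
  ex2 <- expand_cytoplasm(cells2, radius = 5)
  cyto <- attr(ex2, "cyto_labels")
  nuc <- attr(ex2, "labels")
  expect_true(all(cyto[nuc > 0] == 0))          # disjoint from every nucleus
  expect_equal(sort(unique(as.vector(cyto[cyto > 0]))), sort(cells2$label))
})

test_that("compound classification recovers planted class fractions", {
  cellsA <- tibble::tibble(id = 1:2, label = 1:2,
                           ki67_mean = c(30, 10), ck20_cyto_mean = c(20, 20))
  attr(cellsA, "channels") <- list()
  cc <- classify_compound(cellsA)
  expect_equal(cc$cells$ck20_pos, c(TRUE, TRUE))
  expect_equal(cc$cells$ki67_pos, c(TRUE, FALSE))
  expect_equal(cc$percent_ki67_in_ck20_pos, 50)
  none <- dplyr::mutate(cellsA, ck20_cyto_mean = 5)
  attr(none, "channels") <- list()
  expect_error(classify_compound(none), "CK20-positive")

  g <- generate_fluorescence_section(
    n_cells = 300, seed = 5,
    class_mix = c(ki67_ck20 = 0.3, ki67_only = 0.2, ck20_only = 0.3,
                  negative = 0.2, tunel = 0))
  p <- params_triple()
  cells <- filter_nuclei(detect_nuclei_fluor(g$image, p), p)
  cc2 <- classify_compound(expand_cytoplasm(cells, 5))
  # planted: 90 double-positive of 180 CK20+ -> 50%
  expect_lt(abs(cc2$percent_ki67_in_ck20_pos - 50), 2)
  n_pos <- sum(cc2$cells$ck20_pos & cc2$cells$ki67_pos)
  expect_lt(abs(100 * n_pos / nrow(cc2$cells) - 30), 2)
})

test_that("all-negative scenes yield zero double positives", {
  g <- generate_fluorescence_section(
    n_cells = 40, dim = c(700, 700), seed = 66,
    class_mix = c(ki67_ck20 = 0, ki67_only = 0, ck20_only = 1,
                  negative = 0, tunel = 0))
  p <- params_triple()
  cells <- filter_nuclei(detect_nuclei_fluor(g$image, p), p)
  cc <- classify_compound(expand_cytoplasm(cells, 5))
  expect_equal(sum(cc$cells$ki67_pos & cc$cells$ck20_pos), 0)
})

test_that("TUNEL area per cell matches planted truth", {
  g <- generate_fluorescence_section(
    n_cells = 100, dim = c(1100, 1100), seed = 9,
    class_mix = c(ki67_ck20 = 0, ki67_only = 0, ck20_only = 0, negative = 1,
                  tunel = 0),
    tunel_patch_areas_um2 = c(250, 250))
  p <- fluo_detection_params()   # TUNEL mode: DAPI minimum 60
  cells <- filter_nuclei(detect_nuclei_fluor(g$image, p), p)
  res <- tunel_area_metric(g$image, cells)
  truth_metric <- attr(g$tunel_truth, "total_um2") / nrow(cells)
  expect_equal(res$um2_per_cell, truth_metric, tolerance = 0.06)
  expect_equal(res$n_dapi_cells, nrow(cells))

  # nothing above threshold -> zero area, zero metric
  res0 <- tunel_area_metric(g$image, cells, green_threshold = 300)
  expect_equal(res0$tunel_area_um2, 0)
  expect_equal(res0$um2_per_cell, 0)
  expect_error(tunel_area_metric(g$image, cells[0, ]), "zero kept")
})

test_that("polygon simplification changes convex-region area by under 2%", {
  d <- 300
  tun <- matrix(0, d, d)
  for (i in 1:d) for (j in 1:d) {
    if ((i - 150)^2 + (j - 150)^2 <= 60^2) tun[i, j] <- 150
  }
  img <- raster_image(list(DAPI = matrix(100, d, d), TUNEL = tun),
                      calibration = 1)
  cells <- tibble::tibble(id = 1, label = 1)
  raw <- tunel_area_metric(img, cells, simplify_tolerance = 0)
  simp <- tunel_area_metric(img, cells, simplify_tolerance = 1.5)
  expect_lt(abs(simp$tunel_area_um2 - raw$tunel_area_um2) /
              raw$tunel_area_um2, 0.02)
  # simplified polygon area (shoelace oracle) close to the rasterized count
  poly <- attr(simp, "polygons")[[1]]
  expect_equal(oracle_polygon_area(poly), simp$tunel_area_um2,
               tolerance = 0.02)
})
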