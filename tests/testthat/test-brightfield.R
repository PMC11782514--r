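test_that("Phansalkar threshold matches its closed form on a flat image", {
  img <- matrix(128, 24, 24)   # normalised value 128/255
  m <- 128 / 255
  t_expect <- m * (1 + 2 * exp(-10 * m) + 0.25 * (0 / 0.5 - 1))
  expect_lt(t_expect, m)   # so a flat image is all-foreground for bright polarity
  expect_true(all(phansalkar_threshold(img, radius = 5,
                                       polarity = "bright_objects")))
  expect_false(any(phansalkar_threshold(img, radius = 5,
                                        polarity = "dark_objects")))
})

test_that("Phansalkar mask equals the brute-force oracle", {
  set.seed(41)
  for (i in 1:6) {
    img <- matrix(sample(0:255, 64 * 64, TRUE), 64)
    expect_identical(phansalkar_threshold(img, radius = 5),
                     oracle_phansalkar(img, radius = 5))
  }
  # a step edge: foreground confined to the dark side
  step <- cbind(matrix(40, 40, 20), matrix(220, 40, 20))
  mask <- phansalkar_threshold(step, radius = 4, polarity = "dark_objects")
  expect_identical(mask, oracle_phansalkar(step, radius = 4))
  expect_true(all(mask[, 1:15]))      # dark side away from the transition
  expect_false(any(mask[, 26:40]))    # bright side clean
})

test_that("non-8-bit input is rejected", {
  expect_error(phansalkar_threshold(matrix(0.5, 8, 8), radius = 2), "8-bit")
  img16 <- raster_image(matrix(1000, 8, 8), calibration = 1, bit_depth = 16)
  expect_error(phansalkar_threshold(img16, radius = 2), "8-bit")
})

test_that("particle analysis applies edge exclusion, hole filling, min size", {
  mask <- matrix(FALSE, 80, 80)
  disk <- function(cy, cx, r) {
    for (i in max(1, cy - r):min(80, cy + r)) {
      for (j in max(1, cx - r):min(80, cx + r)) {
        if ((i - cy)^2 + (j - cx)^2 <= r^2) mask[i, j] <<- TRUE
      }
    }
  }
  disk(20, 20, 8); disk(55, 55, 6); disk(3, 70, 6)   # third crosses the top
  p <- analyze_particles(mask, calibration = 1, min_size = 10)
  expect_equal(nrow(p), 2)   # edge-touching disk excluded

  # annulus: hole filled, area equals the filled disk
  mask2 <- matrix(FALSE, 60, 60)
  for (i in 1:60) for (j in 1:60) {
    d2 <- (i - 30)^2 + (j - 30)^2
    if (d2 <= 10^2 && d2 > 4^2) mask2[i, j] <- TRUE
  }
  filled_px <- sum(outer(1:60, 1:60,
                         function(i, j) (i - 30)^2 + (j - 30)^2 <= 100))
  p2 <- analyze_particles(mask2, calibration = 1, min_size = 10)
  expect_equal(p2$area_px, filled_px)
  expect_equal(p2$area_px, pi * 10^2, tolerance = 0.05)

  expect_equal(nrow(analyze_particles(matrix(FALSE, 30, 30), 1)), 0)
  expect_error(analyze_particles(mask, 1, roi = cbind(c(1, 1), c(1, 2))),
               "degenerate")
})

test_that("particles outside the region of interest are dropped", {
  mask <- matrix(FALSE, 60, 60)
  mask[10:14, 10:14] <- TRUE
  mask[40:44, 40:44] <- TRUE
  roi <- cbind(c(2, 2, 30, 30), c(2, 30, 30, 2))  # top-left quadrant
  p <- analyze_particles(mask, calibration = 2, roi = roi, min_size = 10)
  expect_equal(nrow(p), 1)
  expect_lt(p$centroid_row, 20)
})

test_that("top-K mean equals a sort oracle and is monotone", {
  set.seed(42)
  areas <- runif(150, 10, 5000)
  parts <- tibble::tibble(id = 1:150, area = areas)
  s <- topk_mean_area(parts, k = 100)
  expect_equal(s$mean_top_k_area, mean(sort(areas, decreasing = TRUE)[1:100]))
  expect_false(s$truncated)

  s_all <- topk_mean_area(parts[1:100, ], k = 100)
  expect_equal(s_all$mean_top_k_area, mean(areas[1:100]))

  s10 <- topk_mean_area(parts[1:10, ], k = 100)
  expect_true(s10$truncated)
  expect_equal(s10$top_k, 10)

  # adding a particle larger than the current k-th never decreases the mean
  bigger <- dplyr::bind_rows(parts, tibble::tibble(id = 151, area = 6000))
  expect_gte(topk_mean_area(bigger, k = 100)$mean_top_k_area,
             s$mean_top_k_area)
  expect_error(topk_mean_area(parts[0, ], k = 100), "empty")
})

test_that("condition summaries average wells within groups", {
  w <- tibble::tibble(donor = c("HC1", "HC1", "HC2"), oxygen = "2%",
                      condition = "DMSO",
                      mean_top_k_area = c(100, 200, 500))
  s <- summarize_condition(w)
  expect_equal(s$mean_top_k_area[s$donor == "HC1"], 150)
  expect_equal(s$mean_top_k_area[s$donor == "HC2"], 500)
  # spreadsheet-style oracle over a 3-donor synthetic grid
  set.seed(9)
  grid <- tidyr::expand_grid(donor = c("A", "B", "C"), oxygen = c("2%", "20%"),
                             condition = c("DMSO", "TOFA"), well = 1:3)
  grid$mean_top_k_area <- runif(nrow(grid), 500, 4000)
  got <- summarize_condition(grid)
  for (r in seq_len(nrow(got))) {
    sel <- grid$donor == got$donor[r] & grid$oxygen == got$oxygen[r] &
      grid$condition == got$condition[r]
    expect_equal(got$mean_top_k_area[r], mean(grid$mean_top_k_area[sel]))
  }
  w$calibration <- c(1, 2, 1)
  expect_error(summarize_condition(w), "calibration")
})

test_that("planted colonoid scenes are recovered exactly end to end", {
  g <- generate_brightfield_well(n_objects = 70, seed = 77)
  mask <- phansalkar_threshold(g$image, radius = 15)
  parts <- analyze_particles(mask, g$image$calibration, min_size = 10)
  truth <- dplyr::filter(g$truth, !touches_edge)
  expect_equal(nrow(parts), nrow(truth))
  idx <- match_to_truth(parts, truth)
  expect_equal(sort(idx), seq_len(nrow(truth)))   # one-to-one
  rel_err <- abs(parts$area_px - truth$area_px[idx]) / truth$area_px[idx]
  diam <- 2 * sqrt(truth$area_px[idx] / pi)
  expect_true(all(rel_err[diam >= 10] <= 0.05))
})
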