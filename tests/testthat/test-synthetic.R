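test_that("brightfield generator is deterministic and truthful", {
  g1 <- generate_brightfield_well(n_objects = 40, dim = c(500, 500), seed = 21)
  g2 <- generate_brightfield_well(n_objects = 40, dim = c(500, 500), seed = 21)
  expect_identical(g1$image$pixels$BF, g2$image$pixels$BF)
  expect_identical(g1$truth, g2$truth)

  g0 <- generate_brightfield_well(n_objects = 0, seed = 1)
  expect_equal(nrow(g0$truth), 0)
  expect_true(all(g0$image$pixels$BF == 220))

  # planted ellipse areas agree with the analytic pi*a*b within rasterization
  # tolerance for objects of equivalent diameter >= 10 px
  diam <- 2 * sqrt(g1$truth$area_px / pi)
  analytic <- pi * g1$truth$axis_a * g1$truth$axis_b
  inner <- !g1$truth$touches_edge & diam >= 10
  expect_true(all(abs(g1$truth$area_px[inner] - analytic[inner]) /
                    analytic[inner] <= 0.05))
  expect_error(generate_brightfield_well(calibration = 0), "> 0")
})

test_that("H-DAB generator plants exact positive fractions and valid OD", {
  g <- generate_ihc_section(n_cells = 200, dab_positive_fraction = 0.5,
                            seed = 13)
  expect_equal(sum(g$truth$dab_positive), 100)
  # zero-fraction section deconvolves to a near-zero DAB channel
  g0 <- generate_ihc_section(n_cells = 60, dab_positive_fraction = 0,
                             dim = c(450, 450), seed = 14)
  dec <- deconvolve_stains(rgb_to_od(g0$image), hdab_vectors())
  expect_lt(max(abs(dec$dab - g0$od_truth$dab)), 0.02)
  expect_lt(max(dec$dab), 0.05)
  expect_error(generate_ihc_section(n_cells = 10, dab_positive_fraction = 2),
               "\\[0, 1\\]")
})

test_that("fluorescence generator plants exact class counts and patch areas", {
  mix <- c(ki67_ck20 = 0.3, ki67_only = 0.2, ck20_only = 0.3,
           negative = 0.2, tunel = 0)
  g <- generate_fluorescence_section(n_cells = 300, class_mix = mix,
                                     seed = 31)
  expect_equal(sum(g$truth$ki67_pos & g$truth$ck20_pos), 90)
  expect_equal(nrow(g$truth), 300)
  expect_identical(g$image$channels, c("DAPI", "KI67", "CK20", "TUNEL"))

  gp <- generate_fluorescence_section(
    n_cells = 20, dim = c(700, 700), seed = 32,
    class_mix = c(ki67_ck20 = 0, ki67_only = 0, ck20_only = 0, negative = 1,
                  tunel = 0),
    tunel_patch_areas_um2 = 400)
  # rasterized patch area within rasterization tolerance of the request
  expect_equal(gp$tunel_truth$area_um2, 400, tolerance = 0.05)
  expect_equal(attr(gp$tunel_truth, "total_um2"),
               sum(gp$tunel_truth$area_um2))
  expect_error(generate_fluorescence_section(
    n_cells = 10, class_mix = c(ki67_ck20 = 0.9)), "sum to 1")
})

test_that("chemokine panel simulator matches its stated generative model", {
  # zero variance, zero effects: every value is exp(baseline)
  cfg0 <- panel_sim_config(n_donors = 2, analytes = "CXCL5", donor_sd = 0,
                           residual_sd = 0, seed = 7)
  p0 <- simulate_chemokine_panel(cfg0)
  expect_true(all(abs(p0$true_value - 200) < 1e-9))
  # censoring: lower limit above everything yields all OOR tokens
  cfgc <- panel_sim_config(n_donors = 2, analytes = "CXCL5",
                           lower_limit = 1e9, seed = 7)
  expect_true(all(simulate_chemokine_panel(cfgc)$token == "OOR <"))
  # Monte-Carlo: with effects 0 the mean log value sits at baseline
  cfg <- panel_sim_config(n_donors = 90, analytes = "CXCL5", donor_sd = 0.3,
                          residual_sd = 0.2, n_wells = 1, seed = 8)
  p <- simulate_chemokine_panel(cfg)
  se <- sqrt(0.3^2 / 90 + 0.2^2 / nrow(p))
  expect_lt(abs(mean(log(p$true_value)) - log(200)), 3 * se)
  # effects shift the targeted cells only
  cfge <- panel_sim_config(n_donors = 3, analytes = "CXCL5", donor_sd = 0,
                           residual_sd = 0,
                           condition_effects = c(TOFA = 0.5), seed = 9)
  pe <- simulate_chemokine_panel(cfge)
  expect_equal(unique(pe$true_value[pe$condition == "TOFA"]),
               exp(log(200) + 0.5))
  expect_equal(unique(pe$true_value[pe$condition == "DMSO"]), 200)
})

test_that("blot simulator reproduces planted folds through normalisation", {
  b <- simulate_blot_table(n_donors = 4, fold_changes = c(TOFA = 2),
                           noise_sd = 0, donor_sd = 0.5, seed = 5)
  nb <- normalize_blot(b)
  expect_equal(nb$fold[nb$condition == "TOFA"], rep(2, 4))
  expect_equal(nb$fold[nb$condition == "DMSO"], rep(1, 4))
  expect_error(simulate_blot_table(fold_changes = c(TOFA = -1)), "> 0")
  # fold recovery under noise: median over many donors within 5% of truth
  bn <- simulate_blot_table(n_donors = 200, fold_changes = c(BUD = 0.6),
                            noise_sd = 0.15, seed = 6)
  nbn <- normalize_blot(bn)
  expect_equal(median(nbn$fold[nbn$condition == "BUD"]), 0.6,
               tolerance = 0.05)
})
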