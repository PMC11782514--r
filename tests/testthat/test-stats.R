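test_that("token preprocessing strips asterisks and substitutes OOR lows", {
  raw <- tibble::tibble(analyte = "CXCL5",
                        token = c("OOR <", "12", "30"))
  out <- preprocess_panel(raw)
  expect_equal(out$value, c(6, 12, 30))   # 50% of the minimum detected value
  expect_equal(out$oor_low, c(TRUE, FALSE, FALSE))

  star <- preprocess_panel(tibble::tibble(analyte = "A", token = "45.2*"))
  expect_equal(star$value, 45.2)

  plain <- tibble::tibble(analyte = c("A", "A"), token = c("3.5", "7"))
  expect_equal(preprocess_panel(plain)$value, c(3.5, 7))

  high <- preprocess_panel(tibble::tibble(analyte = "A",
                                          token = c("OOR >", "5")))
  expect_true(high$oor_high[1])
  expect_true(is.na(high$value[1]))
  # substitution per analyte, not global
  two <- preprocess_panel(tibble::tibble(analyte = c("A", "A", "B", "B"),
                                         token = c("OOR <", "100",
                                                   "OOR <", "8")))
  expect_equal(two$value, c(50, 100, 4, 8))
  expect_error(preprocess_panel(tibble::tibble(analyte = "A",
                                               token = c("OOR <", "OOR <"))),
               "undefined")
  expect_error(preprocess_panel(tibble::tibble(analyte = "A", token = "abc")),
               "unparseable")
})

test_that("detection-range filter keeps analytes with in-range medians", {
  panel <- tibble::tibble(
    analyte = rep(c("low", "ok"), each = 4),
    value = c(2, 2, 2, 2, 100, 120, 90, 110),
    oor_high = FALSE)
  out <- filter_detection_range(panel, lower = 10, upper = 10000)
  expect_equal(attr(out, "retained"), "ok")

  # synthetic panel: 5 in-range + 3 out-of-range analytes -> exactly 5 kept
  base <- c(a1 = log(50), a2 = log(120), a3 = log(300), a4 = log(1000),
            a5 = log(80), b1 = log(1), b2 = log(2), b3 = log(0.5))
  cfg <- panel_sim_config(n_donors = 4, analytes = names(base),
                          baseline_log_mean = base, donor_sd = 0.1,
                          residual_sd = 0.1, seed = 12)
  pan <- preprocess_panel(simulate_chemokine_panel(cfg))
  kept <- filter_detection_range(pan, lower = 10)
  expect_setequal(attr(kept, "retained"), c("a1", "a2", "a3", "a4", "a5"))

  # analytes with too many above-range readings are dropped
  ph <- tibble::tibble(analyte = "sat", value = c(NA, NA, 100, 100),
                       oor_high = c(TRUE, TRUE, FALSE, FALSE))
  expect_length(attr(filter_detection_range(ph), "retained"), 0)
})

test_that("BH adjustment equals the step-up oracle and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.002)),
               c(0.02, 0.04, 0.04, 0.008))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.05, 3)), rep(0.05, 3))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p))
    # permutation stability
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
  expect_error(bh_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("Sidak adjustment matches its closed form", {
  expect_equal(sidak_adjust(0.05, m = 3), 0.142625)
  expect_equal(sidak_adjust(c(0.1, 0.2), m = 2),
               1 - (1 - c(0.1, 0.2))^2)
  expect_true(all(sidak_adjust(runif(10), m = 5) <= 1))
  p <- runif(6)
  expect_true(all(sidak_adjust(p) >= p))
})

test_that("paired t-test matches hand computation", {
  a <- c(1, 2, 3); b <- c(2, 2, 5)
  res <- paired_t(a, b)
  expect_equal(abs(res$statistic), sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p_raw, 2 * pt(sqrt(3), 2, lower.tail = FALSE))
  expect_equal(res$p_raw, 0.225, tolerance = 0.005)
  # symmetry
  rev <- paired_t(b, a)
  expect_equal(rev$statistic, -res$statistic)
  expect_equal(rev$p_raw, res$p_raw)
  expect_error(paired_t(a, a), "identical")
  expect_error(paired_t(1:2, 2:3), ">= 3")
})

test_that("RM ANOVA equals the brute-force sum-of-squares oracle", {
  set.seed(23)
  for (i in 1:5) {
    n <- sample(4:7, 1); k <- sample(3:5, 1)
    d <- tidyr::expand_grid(subject = paste0("S", 1:n),
                            condition = paste0("C", 1:k))
    d$value <- rnorm(nrow(d), rep(seq_len(k), n), 1)
    res <- rm_anova_sidak(d)
    orc <- oracle_rm_anova(d$value, d$subject, d$condition)
    expect_equal(res$anova$statistic, orc$F, tolerance = 1e-10)
    expect_equal(res$anova$p, orc$p, tolerance = 1e-10)
    expect_equal(res$anova$df1, orc$df1)
    expect_equal(res$anova$df2, orc$df2)
  }
})

test_that("RM ANOVA handles degenerate data and incomplete grids", {
  d <- tidyr::expand_grid(subject = paste0("S", 1:4),
                          condition = c("A", "B", "C"))
  d$value <- 5
  res <- rm_anova_sidak(d)
  expect_equal(res$anova$statistic, 0)
  expect_equal(res$anova$p, 1)
  expect_true(all(res$contrasts$p_adj == 1))
  expect_error(rm_anova_sidak(d[-1, ]), "incomplete")
})

test_that("RM ANOVA post-hoc contrasts use the pooled error term with Sidak", {
  set.seed(29)
  d <- tidyr::expand_grid(subject = paste0("S", 1:5),
                          condition = c("DMSO", "TOFA", "BUD"))
  d$value <- rnorm(nrow(d), ifelse(d$condition == "TOFA", 1, 0), 0.5)
  res <- rm_anova_sidak(d, contrasts = list(c("TOFA", "DMSO"),
                                            c("BUD", "DMSO")))
  expect_equal(nrow(res$contrasts), 2)
  expect_equal(res$contrasts$p_adj, sidak_adjust(res$contrasts$p_raw, 2))
  grand <- mean(d$value)
  ssc <- sum(5 * (tapply(d$value, d$condition, mean) - grand)^2)
  sss <- sum(3 * (tapply(d$value, d$subject, mean) - grand)^2)
  sse <- sum((d$value - grand)^2) - ssc - sss
  mse <- sse / 8
  est <- mean(d$value[d$condition == "TOFA"]) -
    mean(d$value[d$condition == "DMSO"])
  expect_equal(res$contrasts$statistic[1], est / sqrt(2 * mse / 5),
               tolerance = 1e-12)
})

test_that("log2 transform for ELISA values is exact and invertible", {
  expect_equal(log2_elisa(8), 3)
  expect_equal(log2_elisa(1), 0)
  set.seed(2)
  x <- runif(20, -5, 5)
  expect_equal(log2_elisa(2^x), x)
  expect_error(log2_elisa(c(4, 0)), "positive")
})

test_that("p-value reporting applies the 0.2 rule and star tiers", {
  res <- tibble::tibble(comparison = c("a", "b", "c", "d", "e"),
                        p_raw = c(0.19, 0.25, 0.0005, 0.04, 0.00005))
  rep <- report_pvalues(res)
  expect_setequal(rep$comparison, c("a", "c", "d", "e"))
  expect_equal(rep$tier[rep$comparison == "a"], "")
  expect_equal(rep$tier[rep$comparison == "d"], "*")
  expect_equal(rep$tier[rep$comparison == "c"], "***")
  expect_equal(rep$tier[rep$comparison == "e"], "****")
})

test_that("mixed model reduces to cell-mean contrasts without noise", {
  cfg <- panel_sim_config(n_donors = 3, analytes = "A", donor_sd = 0,
                          residual_sd = 0,
                          condition_effects = c(TOFA = 0.5, BUD = -0.25),
                          oxygen_effect = 0.1, seed = 3)
  d <- dplyr::mutate(simulate_chemokine_panel(cfg), value = true_value)
  f <- fit_lmm(d)
  td <- tidy(f)
  expect_equal(td$estimate[td$term == "conditionTOFA"], 0.5, tolerance = 1e-8)
  expect_equal(td$estimate[td$term == "conditionBUD"], -0.25,
               tolerance = 1e-8)
  expect_equal(td$estimate[td$term == "oxygen20%"], 0.1, tolerance = 1e-8)
  expect_equal(td$estimate[td$term == "(Intercept)"], log(200),
               tolerance = 1e-8)
})

test_that("mixed model recovers effects and flags singular fits", {
  cfg <- panel_sim_config(n_donors = 6, analytes = "A", donor_sd = 0.3,
                          residual_sd = 0.2,
                          condition_effects = c(TOFA = 0.5), seed = 101)
  ests <- vapply(1:15, function(s) {
    cfg$seed <- s
    d <- dplyr::mutate(simulate_chemokine_panel(cfg), value = true_value)
    td <- tidy(fit_lmm(d))
    td$estimate[td$term == "conditionTOFA"]
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.5), 0.1)

  # boundary fit (no donor variance in the data) is flagged, not an error
  cfg0 <- panel_sim_config(n_donors = 6, analytes = "A", donor_sd = 0,
                           residual_sd = 0.2, seed = 4)
  d0 <- dplyr::mutate(simulate_chemokine_panel(cfg0), value = true_value)
  f0 <- fit_lmm(d0)
  expect_true(glance(f0)$singular)
  expect_error(fit_lmm(dplyr::mutate(d0, value = -value)), "> 0")
})

test_that("doubling residual noise widens mixed-model standard errors", {
  se_at <- function(res_sd, seeds) {
    vapply(seeds, function(s) {
      cfg <- panel_sim_config(n_donors = 6, analytes = "A", donor_sd = 0.3,
                              residual_sd = res_sd, seed = s)
      d <- dplyr::mutate(simulate_chemokine_panel(cfg), value = true_value)
      td <- tidy(fit_lmm(d))
      td$std_error[td$term == "conditionTOFA"]
    }, numeric(1))
  }
  seeds <- 1:12
  expect_gt(mean(se_at(0.4, seeds)), mean(se_at(0.2, seeds)))
})

test_that("panel screening pools BH adjustment within terms", {
  cfg <- panel_sim_config(n_donors = 5, analytes = c("A", "B", "C"),
                          donor_sd = 0.2, residual_sd = 0.2,
                          condition_effects = c(TOFA = 1), seed = 44)
  pan <- dplyr::mutate(simulate_chemokine_panel(cfg), value = true_value)
  scr <- lmm_screen(pan)
  one_term <- dplyr::filter(scr, term == "conditionTOFA")
  expect_equal(one_term$p_adj, bh_adjust(one_term$p_value))
  expect_setequal(unique(scr$analyte), c("A", "B", "C"))
})
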