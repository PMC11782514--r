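# Panel statistics: multiplex token preprocessing (asterisk stripping,
# out-of-range substitution), detection-range filtering, the log-scale
# linear mixed model with donor random intercepts, Benjamini-Hochberg and
# Sidak adjustments, paired t-tests, repeated-measures one-way ANOVA, and
# the p < 0.2 reporting rule.

#' Preprocess raw multiplex panel tokens
#'
#' Cleans assay-software export tokens: trailing asterisks are stripped and
#' values parsed numeric; `"OOR <"` (below the calibration range) is
#' substituted with 50% of the minimum numerically detected value of that
#' analyte (across all its rows) and flagged `oor_low`; `"OOR >"` is flagged
#' `oor_high` with no substituted value.
#'
#' @param raw tibble with an `analyte` column and a `token` character
#'   column (plus any key columns, preserved).
#' @param token_col name of the token column (default `"token"`).
#' @return The input with `value` (numeric), `oor_low`, `oor_high` columns.
#' @export
preprocess_panel <- function(raw, token_col = "token") {
  if (!token_col %in% names(raw)) {
    stop("no `", token_col, "` column in the input", call. = FALSE)
  }
  if (!"analyte" %in% names(raw)) stop("no `analyte` column", call. = FALSE)
  tok <- trimws(as.character(raw[[token_col]]))
  oor_low <- grepl("^OOR\\s*<$", tok)
  oor_high <- grepl("^OOR\\s*>$", tok)
  num <- suppressWarnings(as.numeric(gsub("\\*+$", "", tok)))
  bad <- !oor_low & !oor_high & is.na(num)
  if (any(bad)) {
    stop("unparseable token(s): ",
         paste(utils::head(unique(tok[bad]), 3), collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::mutate(tibble::as_tibble(raw), value = num,
                       oor_low = oor_low, oor_high = oor_high)
  out <- out |>
    dplyr::group_by(.data$analyte) |>
    dplyr::mutate(.min_det = ifelse(all(is.na(.data$value)), NA_real_,
                                    min(.data$value, na.rm = TRUE))) |>
    dplyr::ungroup()
  undef <- unique(out$analyte[out$oor_low & is.na(out$.min_det)])
  if (length(undef)) {
    stop("analyte(s) with only below-range values; substitution undefined: ",
         paste(undef, collapse = ", "), call. = FALSE)
  }
  dplyr::mutate(out,
                value = ifelse(.data$oor_low, 0.5 * .data$.min_det, .data$value),
                .min_det = NULL)
}

#' Filter analytes to the usable detection range
#'
#' Retains an analyte when its median observed concentration is at least
#' `lower` (10 pg/mL by default) and at most its upper detection limit, and
#' when no more than `max_oor_high_frac` of its rows are above-range. The
#' per-analyte aggregation (median within range) is this package's
#' operationalisation of "concentrations within the detection range" and is
#' configurable.
#'
#' @param panel preprocessed panel from [preprocess_panel()].
#' @param lower lower limit, pg/mL (default 10).
#' @param upper single number or named vector (per analyte) of upper
#'   detection limits (default `Inf`).
#' @param max_oor_high_frac maximum tolerated fraction of above-range rows
#'   (default 0.1).
#' @return The panel restricted to retained analytes; the retained analyte
#'   names are attached as attribute `retained`.
#' @export
filter_detection_range <- function(panel, lower = 10, upper = Inf,
                                   max_oor_high_frac = 0.1) {
  up <- function(a) {
    if (is.null(names(upper))) upper[1]
    else ifelse(is.na(upper[a]), Inf, upper[a])
  }
  keep <- panel |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(med = stats::median(.data$value, na.rm = TRUE),
                     frac_high = mean(.data$oor_high), .groups = "drop") |>
    dplyr::mutate(upper_limit = vapply(.data$analyte, up, numeric(1))) |>
    dplyr::filter(.data$med >= lower, .data$med <= .data$upper_limit,
                  .data$frac_high <= max_oor_high_frac)
  out <- dplyr::filter(panel, .data$analyte %in% keep$analyte)
  attr(out, "retained") <- keep$analyte
  out
}

#' Fit the donor random-intercept mixed model for one analyte
#'
#' `log(Value) ~ Condition + Oxygen + Condition:Oxygen + (1 | Donor)`,
#' natural log, treatment coding with DMSO and 2% oxygen as reference
#' levels, REML estimation, per-coefficient t-tests with Satterthwaite
#' degrees of freedom. Above-range rows (`value` missing) are dropped. A
#' boundary fit with zero donor variance is returned flagged `singular`, not
#' an error; when the mixed fit is degenerate (e.g. noise-free data), the
#' fixed effects are estimated by ordinary least squares and flagged.
#'
#' @param data rows for one analyte: columns donor, oxygen, condition,
#'   `value` (> 0).
#' @param value_col value column name (default `"value"`).
#' @return An `lmm_fit` object; see [tidy.lmm_fit()] and
#'   [glance.lmm_fit()].
#' @export
fit_lmm <- function(data, value_col = "value") {
  v <- data[[value_col]]
  data <- data[!is.na(v), , drop = FALSE]
  v <- v[!is.na(v)]
  if (any(v <= 0)) stop("values must be > 0 for the log model", call. = FALSE)
  if (dplyr::n_distinct(data$donor) < 2) {
    stop("need >= 2 donors", call. = FALSE)
  }
  if (dplyr::n_distinct(data$condition) < 2) {
    stop("need >= 2 conditions", call. = FALSE)
  }
  df <- tibble::tibble(
    logv = log(v),
    condition = normalize_condition(data$condition),
    oxygen = factor(data$oxygen, levels = oxygen_levels()),
    donor = factor(data$donor))
  df$condition <- droplevels(df$condition)
  one_oxy <- dplyr::n_distinct(df$oxygen) < 2
  form <- if (one_oxy) logv ~ condition + (1 | donor) else
    logv ~ condition * oxygen + (1 | donor)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(lmerTest::lmer(form, data = df,
                                                     REML = TRUE))),
    error = function(e) NULL)
  co <- NULL
  if (!is.null(fit)) {
    co <- tryCatch(suppressWarnings(summary(fit)$coefficients),
                   error = function(e) NULL)
  }
  if (is.null(fit) || is.null(co) || any(!is.finite(co[, "Pr(>|t|)"]))) {
    # degenerate path: OLS fixed effects (identical point estimates on a
    # balanced design with no donor variance)
    lform <- if (one_oxy) logv ~ condition else logv ~ condition * oxygen
    lfit <- stats::lm(lform, data = df)
    co <- summary(lfit)$coefficients
    fixed <- tibble::tibble(term = rownames(co), estimate = unname(co[, 1]),
                            std_error = unname(co[, 2]),
                            df = lfit$df.residual,
                            statistic = unname(co[, 3]),
                            p_value = unname(co[, 4]))
    res <- stats::residuals(lfit)
    out <- list(model = lfit, fixed = fixed, donor_intercept_sd = 0,
                residual_sd = summary(lfit)$sigma, singular = TRUE,
                method = "ols-degenerate",
                residual_normality_p = safe_shapiro(res))
    class(out) <- "lmm_fit"
    return(out)
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  fixed <- tibble::tibble(term = rownames(co),
                          estimate = unname(co[, "Estimate"]),
                          std_error = unname(co[, "Std. Error"]),
                          df = unname(co[, "df"]),
                          statistic = unname(co[, "t value"]),
                          p_value = unname(co[, "Pr(>|t|)"]))
  out <- list(model = fit, fixed = fixed,
              donor_intercept_sd = vc$sdcor[vc$grp == "donor"],
              residual_sd = vc$sdcor[vc$grp == "Residual"],
              singular = lme4::isSingular(fit),
              method = "reml-satterthwaite",
              residual_normality_p = safe_shapiro(stats::residuals(fit)))
  class(out) <- "lmm_fit"
  out
}

safe_shapiro <- function(res) {
  if (length(res) < 3 || length(res) > 5000 || stats::sd(res) == 0) {
    return(NA_real_)
  }
  tryCatch(stats::shapiro.test(res)$p.value, error = function(e) NA_real_)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("log-scale donor random-intercept model (", x$method, ")\n", sep = "")
  cat(sprintf("donor intercept sd %.4f, residual sd %.4f%s\n",
              x$donor_intercept_sd, x$residual_sd,
              if (x$singular) " [singular fit]" else ""))
  print(x$fixed)
  invisible(x)
}

#' Tidy / summarise a mixed-model fit
#'
#' `tidy()` returns the fixed-effect table (term, estimate, std_error, df,
#' statistic, p_value); `glance()` a one-row model summary (variance
#' components, singularity flag, residual-normality diagnostic, n).
#'
#' @param x an `lmm_fit`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.lmm_fit <- function(x, ...) x$fixed

#' @rdname tidy.lmm_fit
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(donor_intercept_sd = x$donor_intercept_sd,
                 residual_sd = x$residual_sd, singular = x$singular,
                 method = x$method,
                 residual_normality_p = x$residual_normality_p,
                 nobs = stats::nobs(x$model))
}

#' Screen a panel with per-analyte mixed models
#'
#' Fits [fit_lmm()] per analyte and pools the per-term p-values across
#' analytes with Benjamini-Hochberg adjustment (within each term).
#'
#' @param panel preprocessed (and range-filtered) panel.
#' @return Tibble: analyte, term, estimate, std_error, df, statistic,
#'   p_value, `p_adj` (BH across analytes within term), `singular`.
#' @export
lmm_screen <- function(panel) {
  fits <- panel |>
    dplyr::group_by(.data$analyte) |>
    dplyr::group_map(function(d, key) {
      f <- fit_lmm(d)
      dplyr::mutate(tidy(f), analyte = key$analyte, singular = f$singular)
    }) |>
    dplyr::bind_rows()
  fits |>
    dplyr::group_by(.data$term) |>
    dplyr::mutate(p_adj = bh_adjust(.data$p_value)) |>
    dplyr::ungroup() |>
    dplyr::select("analyte", dplyr::everything())
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment,
#' `p_adj(i) = min_{j: rank >= rank(i)} p_(j) * m / j`, capped at 1; stable
#' under input permutation.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Sidak familywise adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for `m` comparisons (e.g.
#' `1 - (1 - 0.05)^3 = 0.142625`).
#'
#' @param p raw p-values.
#' @param m number of comparisons in the family (default `length(p)`).
#' @return Adjusted p-values, capped at 1 and never below `p`.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  pmin(1 - (1 - p)^m, 1)
}

#' Paired t-test between two matched groups
#'
#' Two-sided paired t-test, `t = mean(d) / (sd(d) / sqrt(n))`, `df = n - 1`.
#'
#' @param a,b numeric vectors paired by position (same sample keys).
#' @param comparison label for the result row.
#' @return One-row `test_result` tibble: comparison, statistic, df, `p_raw`,
#'   method.
#' @export
paired_t <- function(a, b, comparison = "A vs B") {
  if (length(a) != length(b)) stop("groups must be paired", call. = FALSE)
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(a - b) == 0) {
    stop("all paired differences identical; t statistic undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(comparison = comparison,
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_raw = tt$p.value, method = "paired t")
}

#' Repeated-measures one-way ANOVA with Sidak post-hoc contrasts
#'
#' Within-subject one-way ANOVA (subject as blocking factor):
#' `F = MS_condition / MS_error` with df `(k - 1)` and `(k - 1)(n - 1)`.
#' Pairwise condition contrasts use the pooled error mean square
#' (`se = sqrt(2 MS_error / n)`, error df) and Sidak adjustment over the `m`
#' requested comparisons.
#'
#' @param data tibble with subject, condition and value columns; the
#'   subject x condition grid must be complete.
#' @param value,subject,condition column names.
#' @param contrasts list of length-2 character vectors of condition levels
#'   to compare; `NULL` compares all pairs.
#' @return List: `anova` (one-row tibble: statistic, df1, df2, p), and
#'   `contrasts` (tibble with estimate, statistic, df, `p_raw`, `p_adj`).
#' @export
rm_anova_sidak <- function(data, value = "value", subject = "subject",
                           condition = "condition", contrasts = NULL) {
  y <- data[[value]]
  s <- factor(data[[subject]])
  g <- factor(data[[condition]])
  grid <- table(s, g)
  if (any(grid != 1)) {
    miss <- which(grid == 0, arr.ind = TRUE)
    msg <- if (nrow(miss)) {
      paste(apply(miss, 1, function(i) {
        paste0(levels(s)[i[1]], " x ", levels(g)[i[2]])
      }), collapse = ", ")
    } else "duplicated cells"
    stop("incomplete subject x condition grid: ", msg, call. = FALSE)
  }
  n <- nlevels(s); k <- nlevels(g)
  grand <- mean(y)
  cond_means <- tapply(y, g, mean)
  subj_means <- tapply(y, s, mean)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  if (ms_err <= .Machine$double.eps * max(1, abs(ss_tot))) {
    f <- if (ms_cond <= .Machine$double.eps * max(1, abs(ss_tot))) 0 else Inf
    p <- if (f == 0) 1 else 0
  } else {
    f <- ms_cond / ms_err
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  if (is.null(contrasts)) {
    contrasts <- utils::combn(levels(g), 2, simplify = FALSE)
  }
  m <- length(contrasts)
  rows <- purrr::map_dfr(contrasts, function(pr) {
    est <- cond_means[pr[1]] - cond_means[pr[2]]
    if (ms_err <= 0) {
      tstat <- if (est == 0) 0 else Inf * sign(est)
      praw <- if (est == 0) 1 else 0
    } else {
      tstat <- est / sqrt(2 * ms_err / n)
      praw <- 2 * stats::pt(abs(tstat), df2, lower.tail = FALSE)
    }
    tibble::tibble(comparison = paste(pr[1], "vs", pr[2]),
                   estimate = unname(est), statistic = unname(tstat),
                   df = df2, p_raw = praw)
  })
  rows$p_adj <- sidak_adjust(rows$p_raw, m)
  rows$method <- "RM one-way ANOVA + Sidak"
  list(anova = tibble::tibble(statistic = f, df1 = df1, df2 = df2, p = p),
       contrasts = rows)
}

#' Log2-transform ELISA values
#'
#' Downstream RM-ANOVA / Sidak testing of ELISA concentrations operates on
#' log2 values.
#'
#' @param values positive numeric vector.
#' @return `log2(values)`.
#' @export
log2_elisa <- function(values) {
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("ELISA values must be positive for the log2 transform",
         call. = FALSE)
  }
  log2(values)
}

#' Report comparisons below the p < 0.2 threshold
#'
#' Because of large inter-donor differences, every comparison with p below
#' 0.2 is reported; significance tiers follow the asterisk convention
#' `*` p < 0.05, `***` p < 0.001, `****` p < 0.0001 (comparisons between
#' 0.05 and 0.2 are listed without a star).
#'
#' @param results tibble with a p-value column.
#' @param threshold reporting threshold (default 0.2).
#' @param p_col p-value column name (default `"p_raw"`, falling back to
#'   `"p"` / `"p_value"`).
#' @return The reported rows with a `tier` column, sorted by p.
#' @export
report_pvalues <- function(results, threshold = 0.2, p_col = NULL) {
  if (is.null(p_col)) {
    p_col <- intersect(c("p_raw", "p", "p_value", "p_adj"), names(results))[1]
    if (is.na(p_col)) stop("no p-value column found", call. = FALSE)
  }
  p <- results[[p_col]]
  out <- results[!is.na(p) & p < threshold, , drop = FALSE]
  p <- out[[p_col]]
  out$tier <- dplyr::case_when(p < 1e-4 ~ "****", p < 1e-3 ~ "***",
                               p < 0.05 ~ "*", TRUE ~ "")
  dplyr::arrange(tibble::as_tibble(out), .data[[p_col]])
}
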