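#' Two-group comparison
#'
#' The study's baseline comparisons: either the classical unpaired
#' (pooled-variance) t-test or its nonparametric analogue, the two-sample
#' Wilcoxon rank-sum test with normal approximation and tie correction.
#' Both report a two-sided p value. The degenerate case of two groups with
#' zero variance and equal means returns statistic 0, p = 1.
#'
#' @param a,b Numeric vectors (each of length >= 2, finite).
#' @param method `"t_unpaired"` or `"rank_nonparametric"`.
#' @return One-row data frame: `effect, statistic, df, p_raw, estimate,
#'   conf_low, conf_high, n` (df/CI are `NA` for the rank test).
#' @export
two_group_test <- function(a, b, method = c("t_unpaired", "rank_nonparametric")) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("responses must be finite")
  n <- length(a) + length(b)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(data.frame(effect = method, statistic = 0,
                        df = if (method == "t_unpaired") n - 2 else NA_real_,
                        p_raw = 1, estimate = 0, conf_low = 0, conf_high = 0, n = n))
    }
    if (method == "t_unpaired") stop("zero variance in both groups with unequal means")
  }
  if (method == "t_unpaired") {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    data.frame(effect = "t_unpaired", statistic = unname(tt$statistic),
               df = unname(tt$parameter), p_raw = tt$p.value,
               estimate = mean(a) - mean(b),
               conf_low = tt$conf.int[1], conf_high = tt$conf.int[2], n = n)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = FALSE))
    data.frame(effect = "rank_nonparametric", statistic = unname(wt$statistic),
               df = NA_real_, p_raw = wt$p.value,
               estimate = NA_real_, conf_low = NA_real_, conf_high = NA_real_, n = n)
  }
}

#' Genotype-by-treatment factorial ANOVA
#'
#' Two-way fixed-effects ANOVA of a per-fish metric on population
#' (surface/cavefish), treatment, and their interaction. For unbalanced
#' cells, each effect is tested adjusted for all others (partial,
#' Type-III-style sums of squares with sum-to-zero contrasts), which
#' reduces to the textbook decomposition when cells are equal-sized.
#'
#' @param design Data frame with columns `response`, `factorA`, `factorB`
#'   (and optionally `subject_id`).
#' @return Data frame with rows `factorA`, `factorB`, `factorA:factorB`:
#'   `effect, statistic` (F), `df1, df2, p_raw`.
#' @export
two_way_anova <- function(design) {
  need <- c("response", "factorA", "factorB")
  if (!all(need %in% names(design))) stop("design needs columns response, factorA, factorB")
  d <- data.frame(response = as.numeric(design$response),
                  factorA = factor(design$factorA),
                  factorB = factor(design$factorB))
  if (any(!is.finite(d$response))) stop("responses must be finite")
  if (nlevels(d$factorA) < 2 || nlevels(d$factorB) < 2) stop("each factor needs >= 2 levels")
  cells <- table(d$factorA, d$factorB)
  if (any(cells == 0)) stop("every factorA x factorB cell must be non-empty")
  if (any(cells == 1)) stop("a cell with n = 1 leaves no within-cell error for the interaction")
  fit <- stats::lm(response ~ factorA * factorB, data = d,
                   contrasts = list(factorA = "contr.sum", factorB = "contr.sum"))
  ao <- car::Anova(fit, type = 3)
  rows <- c("factorA", "factorB", "factorA:factorB")
  df2 <- ao["Residuals", "Df"]
  data.frame(effect = rows,
             statistic = ao[rows, "F value"],
             df1 = ao[rows, "Df"],
             df2 = rep(df2, length(rows)),
             p_raw = ao[rows, "Pr(>F)"],
             row.names = NULL)
}

#' Holm-Sidak step-down adjusted p values
#'
#' The study's multiple-comparison post-test. Raw p values are sorted
#' ascending; the i-th smallest (of m) is adjusted to
#' `1 - (1 - p_(i))^(m - i + 1)`, adjusted values are forced monotone
#' non-decreasing along the sorted order, capped at 1, and returned in the
#' input order.
#'
#' @param p_raw Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, same length and order as the input.
#' @export
holm_sidak <- function(p_raw) {
  p <- as.numeric(p_raw)
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Regression of sleep on silenced-cell count
#'
#' Ordinary least squares of a per-fish sleep metric on the number of
#' silenced (or labeled) HCRT neurons, reporting slope, intercept, R^2 and
#' the two-sided p value of the slope — the analysis used to ask whether
#' sleep increases with the number of HCRT neurons silenced.
#'
#' @param cells Numeric/integer predictor (cell counts), not all equal.
#' @param sleep Numeric response (e.g. total sleep, minutes).
#' @return One-row data frame: `slope, intercept, r_squared, p_slope, n`.
#' @export
regress_sleep_on_cells <- function(cells, sleep) {
  cells <- as.numeric(cells); sleep <- as.numeric(sleep)
  if (length(cells) != length(sleep)) stop("cells and sleep must have equal length")
  if (length(cells) < 3) stop("need n >= 3")
  if (stats::var(cells) == 0) stop("constant predictor: regression undefined")
  fit <- stats::lm(sleep ~ cells)
  sm <- suppressWarnings(summary(fit))  # silence "essentially perfect fit"
  data.frame(slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             r_squared = sm$r.squared,
             p_slope = sm$coefficients["cells", "Pr(>|t|)"],
             n = length(cells))
}

#' Effects table with Holm-Sidak adjustment
#'
#' Convenience wrapper: runs [two_way_anova()] and appends Holm-Sidak
#' adjusted p values across the three effects (the comparison family used
#' when the omnibus test is followed up).
#'
#' @param design See [two_way_anova()].
#' @return The ANOVA table with an extra `p_adj` column.
#' @export
anova_with_adjustment <- function(design) {
  tab <- two_way_anova(design)
  tab$p_adj <- holm_sidak(tab$p_raw)
  tab
}
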