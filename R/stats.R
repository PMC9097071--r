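# Group statistics and power computations applied to pipeline outputs.

#' Repeated-measures ANOVA with 1-3 within-subject factors
#'
#' Standard within-subjects decomposition via `stats::aov` with an
#' `Error(subject/(A*B*...))` stratum per factor combination, on a
#' complete balanced long table. With all-constant responses the F ratio
#' is undefined; such effects are reported with `F = NA` and `p = 1`.
#'
#' @param data Long-format data frame.
#' @param dv Name of the response column.
#' @param subject Name of the subject identifier column.
#' @param within Character vector (length 1-3) of within-subject factor
#'   columns.
#' @return Data frame of class `rm_anova`: `effect`, `df1`, `df2`,
#'   `statistic` (F), `p`.
#' @export
#' @examples
#' d <- expand.grid(subj = factor(1:6), cond = factor(c("a", "b")))
#' d$y <- rnorm(nrow(d)) + (d$cond == "b")
#' rm_anova(d, "y", "subj", "cond")
rm_anova <- function(data, dv, subject, within) {
  stopifnot(length(within) >= 1, length(within) <= 3,
            all(c(dv, subject, within) %in% names(data)))
  d <- data
  d[[subject]] <- factor(d[[subject]])
  for (w in within) d[[w]] <- factor(d[[w]])
  cells <- interaction(d[within], drop = TRUE)
  tab <- table(d[[subject]], cells)
  if (any(tab != 1))
    stop("design must be complete and balanced (one observation per ",
         "subject and factor-level combination)", call. = FALSE)
  rhs <- paste(within, collapse = " * ")
  if (stats::sd(d[[dv]]) == 0) {
    # constant response: every sum of squares is zero, F is undefined
    effects <- attr(stats::terms(
      stats::as.formula(paste("~", rhs))), "term.labels")
    out <- data.frame(effect = effects, df1 = NA_real_, df2 = NA_real_,
                      statistic = NA_real_, p = 1,
                      stringsAsFactors = FALSE)
    class(out) <- c("rm_anova", "data.frame")
    return(out)
  }
  f <- stats::as.formula(sprintf("%s ~ %s + Error(%s/(%s))",
                                 dv, rhs, subject, rhs))
  fit <- suppressWarnings(stats::aov(f, data = d))
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    tb <- if (is.list(stratum)) stratum[[1]] else stratum
    tb <- as.data.frame(tb)
    eff <- trimws(rownames(tb))
    keep <- eff != "Residuals"
    if (!any(keep)) next
    resid_df <- tb$Df[eff == "Residuals"]
    for (i in which(keep)) {
      rows[[length(rows) + 1]] <- data.frame(
        effect = gsub(" ", "", eff[i]),
        df1 = tb$Df[i],
        df2 = if (length(resid_df)) resid_df else NA_real_,
        statistic = if (is.finite(tb$`F value`[i])) tb$`F value`[i]
                    else NA_real_,
        p = if (is.finite(tb$`Pr(>F)`[i])) tb$`Pr(>F)`[i] else 1,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' Kruskal-Wallis with pairwise Wilcoxon follow-up
#'
#' Omnibus Kruskal-Wallis H (tie-corrected) across groups, followed by
#' pairwise Wilcoxon comparisons (signed-rank when `paired`, rank-sum
#' otherwise), Bonferroni-corrected across the pairs compared. Effect
#' sizes: eta-squared `(H - k + 1)/(n - k)` for the omnibus;
#' `r = Z / sqrt(n)` per pair (Z recovered from the two-sided p-value).
#'
#' @param groups Named list of numeric vectors (>= 2 groups).
#' @param paired Treat pairwise comparisons as paired (signed-rank);
#'   requires equal lengths.
#' @param bonferroni_m Correction family size; default the number of
#'   pairwise comparisons.
#' @return List: `kruskal` (`statistic` H, `df`, `p`, `effect_size`) and
#'   `pairwise` (data frame `group_a`, `group_b`, `statistic` W/V, `p`,
#'   `p_corrected`, `effect_size`).
#' @export
nonparam_tests <- function(groups, paired = FALSE, bonferroni_m = NULL) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  kw <- stats::kruskal.test(groups)
  k <- length(groups)
  n <- sum(lengths(groups))
  eta2 <- (unname(kw$statistic) - k + 1) / (n - k)
  pairs <- utils::combn(names(groups), 2)
  m <- if (is.null(bonferroni_m)) ncol(pairs) else bonferroni_m
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- groups[[pairs[1, j]]]; b <- groups[[pairs[2, j]]]
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                              exact = FALSE))
    np <- if (paired) length(a) else length(a) + length(b)
    z <- stats::qnorm(wt$p.value / 2, lower.tail = FALSE)
    data.frame(group_a = pairs[1, j], group_b = pairs[2, j],
               statistic = unname(wt$statistic), p = wt$p.value,
               p_corrected = min(1, m * wt$p.value),
               effect_size = z / sqrt(np),
               stringsAsFactors = FALSE)
  }))
  list(kruskal = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p = kw$p.value,
                      effect_size = eta2),
       pairwise = pw)
}

#' Two-tailed paired t test
#'
#' Student's t on paired differences, with an optional Bonferroni
#' multiplier (e.g. the number of frequency bands when applied band-wise).
#' Effect size is Cohen's d on the differences. Identical samples return
#' `t = 0`, `p = 1`; a constant non-zero difference has zero variance and
#' raises an error.
#'
#' @param x,y Paired samples of equal length (n >= 2).
#' @param bonferroni_m Correction multiplier (default 1).
#' @return List: `statistic` (t), `df`, `p`, `p_corrected`,
#'   `effect_size`.
#' @export
paired_t <- function(x, y, bonferroni_m = 1) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  scale <- max(abs(d), 1)
  if (stats::sd(d) <= 1e-10 * scale) {
    if (all(abs(d) <= 1e-10))  # identical samples: no difference at all
      return(list(statistic = 0, df = length(d) - 1, p = 1,
                  p_corrected = 1, effect_size = 0))
    stop("zero-variance differences: t undefined", call. = FALSE)
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, p_corrected = min(1, bonferroni_m * tt$p.value),
       effect_size = mean(d) / stats::sd(d))
}

#' Power of the two-tailed paired t test
#'
#' Exact power from the noncentral t distribution with noncentrality
#' `d * sqrt(n)` and `n - 1` degrees of freedom. A "medium" effect size in
#' Cohen's convention is `d = 0.5`.
#'
#' @param d Effect size (Cohen's d of the paired differences), > 0 (0
#'   returns the type-I rate `alpha`).
#' @param n Number of pairs (>= 2).
#' @param alpha Two-tailed significance level.
#' @return List of class `power_result`: `power`, `ncp`, `df`, plus the
#'   inputs.
#' @export
#' @examples
#' power_paired_t(0.5, 122)$power  # > 0.99
power_paired_t <- function(d, n, alpha = 0.05) {
  stopifnot(d >= 0, n >= 2)
  if (alpha <= 0 || alpha >= 1) stop("invalid alpha", call. = FALSE)
  df <- n - 1
  ncp <- d * sqrt(n)
  crit <- stats::qt(1 - alpha / 2, df)
  power <- stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-crit, df, ncp = ncp)
  structure(list(design = "paired t, two-tailed", d = d, n = n,
                 alpha = alpha, df = df, ncp = ncp, power = power),
            class = "power_result")
}

#' Power of a one-way repeated-measures ANOVA
#'
#' Noncentral-F power under the common design-software convention:
#' noncentrality `f^2 * n * m / (1 - rho)` with numerator df `m - 1` and
#' denominator df `(n - 1)(m - 1)` (sphericity assumed). A "medium" effect
#' size in Cohen's convention is `f = 0.25`; `rho` is the assumed
#' correlation among repeated measures.
#'
#' @param f Cohen's f effect size (>= 0).
#' @param n Number of subjects (>= 2).
#' @param m Number of repeated measurements (>= 2).
#' @param rho Correlation among repeated measures, `0 <= rho < 1`.
#' @param alpha Significance level.
#' @return List of class `power_result`.
#' @export
power_rm_anova <- function(f, n, m, rho = 0.5, alpha = 0.05) {
  stopifnot(f >= 0, n >= 2, m >= 2)
  if (rho < 0 || rho >= 1) stop("invalid rho", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("invalid alpha", call. = FALSE)
  df1 <- m - 1
  df2 <- (n - 1) * (m - 1)
  ncp <- f^2 * n * m / (1 - rho)
  crit <- stats::qf(1 - alpha, df1, df2)
  power <- stats::pf(crit, df1, df2, ncp = ncp, lower.tail = FALSE)
  structure(list(design = "one-way repeated-measures ANOVA", f = f, n = n,
                 m = m, rho = rho, alpha = alpha, df1 = df1, df2 = df2,
                 ncp = ncp, power = power),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("<power_result> %s: power = %.4f (n = %d, alpha = %g)\n",
              x$design, x$power, x$n, x$alpha))
  invisible(x)
}

#' Bonferroni correction
#'
#' `min(1, m * p)`, vectorized; preserves the ordering of raw p-values.
#'
#' @param p Raw p-values.
#' @param m Family size.
#' @return Corrected p-values.
#' @export
bonferroni <- function(p, m) pmin(1, m * p)
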