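#' Normality-gated two-group comparison (or ANOVA + Tukey for > 2 groups)
#'
#' Implements the study-style test-selection rule: for two groups, a
#' Shapiro-Wilk test is run on each group at `normality_alpha`; if both
#' groups pass, an unpaired two-tailed Student t-test (equal variances by
#' default) is used, otherwise a Mann-Whitney (Wilcoxon rank-sum) test.
#' For more than two groups a one-way ANOVA with Tukey HSD post-hoc is
#' used. Groups with fewer than 3 values, or with zero variance, cannot be
#' gated and force the nonparametric branch (two-group case).
#'
#' @param values numeric vector of observations.
#' @param groups factor or character vector of group labels, same length.
#' @param normality_alpha alpha for the Shapiro-Wilk gate (default 0.05).
#' @param welch use Welch's unequal-variance t-test instead of Student's.
#'
#' @return An object of class `group_comparison`: a list with `test_name`
#'   (`"t-test"`, `"Mann-Whitney"` or `"ANOVA+Tukey"`), `statistic`, `p`,
#'   `mean_difference` (group 2 minus group 1), `conf_int` (95% CI of the
#'   difference, parametric branch only), `normality_p` per group,
#'   `gate_note`, and for the ANOVA branch a `tukey` data frame of pairwise
#'   contrasts.
#' @export
compare_groups <- function(values, groups,
                           normality_alpha = 0.05, welch = FALSE) {
  stopifnot(length(values) == length(groups))
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  lev <- levels(groups)
  if (length(lev) < 2L)
    stop("compare_groups() needs at least 2 groups, got ", length(lev))

  if (length(lev) > 2L) {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1L]]
    tk <- stats::TukeyHSD(fit)$groups
    tukey <- data.frame(contrast = rownames(tk),
                        difference = tk[, "diff"],
                        lwr = tk[, "lwr"], upr = tk[, "upr"],
                        p_adj = tk[, "p adj"], row.names = NULL)
    return(structure(list(test_name = "ANOVA+Tukey",
                          statistic = an[["F value"]][1L],
                          p = an[["Pr(>F)"]][1L],
                          mean_difference = NA_real_,
                          conf_int = NULL,
                          normality_p = NULL,
                          gate_note = "multi-group: ANOVA branch",
                          tukey = tukey),
                     class = "group_comparison"))
  }

  x <- values[groups == lev[1L]]
  y <- values[groups == lev[2L]]
  gate <- gate_normality(x, y, normality_alpha)

  if (gate$parametric) {
    tt <- stats::t.test(y, x, var.equal = !welch)
    res <- list(test_name = "t-test", statistic = unname(tt$statistic),
                p = tt$p.value, mean_difference = mean(y) - mean(x),
                conf_int = as.numeric(tt$conf.int))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(y, x,
      exact = (length(x) <= 8 && length(y) <= 8 &&
               !anyDuplicated(c(x, y))), correct = TRUE))
    res <- list(test_name = "Mann-Whitney", statistic = unname(wt$statistic),
                p = wt$p.value, mean_difference = mean(y) - mean(x),
                conf_int = NULL)
  }
  res$normality_p <- gate$normality_p
  res$gate_note <- gate$note
  structure(res, class = "group_comparison")
}

gate_normality <- function(x, y, alpha) {
  sw_p <- function(v) {
    if (length(v) < 3L) return(NA_real_)
    if (stats::sd(v) == 0) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }
  px <- sw_p(x); py <- sw_p(y)
  if (is.na(px) || is.na(py)) {
    list(parametric = FALSE, normality_p = c(px, py),
         note = "gate skipped (n < 3 or zero variance); nonparametric forced")
  } else if (px >= alpha && py >= alpha) {
    list(parametric = TRUE, normality_p = c(px, py),
         note = "both groups pass Shapiro-Wilk")
  } else {
    list(parametric = FALSE, normality_p = c(px, py),
         note = "Shapiro-Wilk rejected normality in at least one group")
  }
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(x$test_name, ": statistic = ", format(x$statistic, digits = 4),
      ", p = ", format(x$p, digits = 4), "\n", sep = "")
  if (is.finite(x$mean_difference))
    cat("mean difference:", format(x$mean_difference, digits = 4), "\n")
  if (!is.null(x$conf_int))
    cat("95% CI: [", format(x$conf_int[1], digits = 4), ", ",
        format(x$conf_int[2], digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validated wrapper around [stats::p.adjust()] with `method = "BH"`:
#' input order is preserved and p-values outside `[0, 1]` are rejected
#' rather than propagated as `NA`.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return numeric vector of BH-adjusted q-values, same order as input.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pearson correlation as R-squared with a slope test
#'
#' @param x,y paired numeric vectors, n >= 3 finite pairs required.
#' @return list with `r_squared`, `p` (two-sided, zero-slope), `r`, `n`.
#' @export
correlate <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("correlate() needs at least 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlate() undefined for zero-variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r_squared = unname(ct$estimate)^2, p = ct$p.value,
       r = unname(ct$estimate), n = length(x))
}
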