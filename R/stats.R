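#' Density-adjusted group comparison of a graph measure (ANCOVA)
#'
#' Fits `value ~ group + density` by least squares over the pooled pre/post
#' observations (group coded 0 = pre, 1 = post) and tests the group
#' coefficient, mirroring the treatment of the paired sessions as two
#' groups with network density as the nuisance covariate. A paired
#' alternative (`paired = TRUE`) regresses the within-subject differences on
#' the within-subject density differences and tests the intercept.
#'
#' @param values_pre,values_post measure values per subject (equal
#'   lengths of at least 3).
#' @param density_pre,density_post the corresponding network densities.
#' @param paired use the within-subject difference formulation.
#' @return object of class `ancova_result`: `estimate` (group effect), `F`,
#'   `p`, `density_coef`, `n_per_group`, `df`, `method`.
#' @export
ancova_group_density <- function(values_pre, values_post, density_pre,
                                 density_post, paired = FALSE) {
  n <- length(values_pre)
  if (length(values_post) != n || length(density_pre) != n ||
      length(density_post) != n)
    stop_param("all inputs must have the same length")
  if (n < 3) stop_param("need at least 3 subjects per group")
  if (paired) {
    d <- values_post - values_pre
    dd <- density_post - density_pre
    fit <- if (var(dd) > 0) lm(d ~ dd) else lm(d ~ 1)
    sm <- summary(fit)$coefficients
    tval <- sm["(Intercept)", "t value"]
    return(structure(list(
      estimate = sm["(Intercept)", "Estimate"], F = tval^2,
      p = sm["(Intercept)", "Pr(>|t|)"],
      density_coef = if (nrow(sm) > 1) sm["dd", "Estimate"] else 0,
      n_per_group = n, df = fit$df.residual, method = "paired"),
      class = "ancova_result"))
  }
  y <- c(values_pre, values_post)
  grp <- rep(c(0, 1), each = n)
  dens <- c(density_pre, density_post)
  if (var(dens) == 0)
    stop_param("density covariate has zero variance")
  X <- cbind(1, grp, dens)
  qrX <- qr(X)
  if (qrX$rank < 3)
    stop_param("density is collinear with group (condition number %.3g)",
               kappa(X))
  fit <- lm(y ~ grp + dens)
  sm <- summary(fit)$coefficients
  tval <- sm["grp", "t value"]
  structure(list(estimate = sm["grp", "Estimate"], F = tval^2,
                 p = sm["grp", "Pr(>|t|)"],
                 density_coef = sm["dens", "Estimate"],
                 n_per_group = n, df = fit$df.residual,
                 method = "pooled"),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf(
    "<ancova_result> group effect %.4g, F(1, %d) = %.4g, p = %.4g (%s; density coef %.4g)\n",
    x$estimate, x$df, x$F, x$p, x$method, x$density_coef))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level `q`: adjusted p-values are the usual monotone
#' BH values and the mask marks hypotheses with adjusted p <= q.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param q FDR level.
#' @return list with `mask` (logical) and `adjusted` (numeric).
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (!is.numeric(p_values) || any(is.na(p_values)) ||
      any(p_values < 0 | p_values > 1))
    stop_param("p-values must lie in [0, 1]")
  check_scalar(q, "q", lower = 1e-12, upper = 1)
  adjusted <- p.adjust(p_values, method = "BH")
  list(mask = adjusted <= q, adjusted = adjusted)
}

#' Paired behavioral score comparison
#'
#' Wilcoxon signed-rank (zero differences dropped; exact distribution for
#' n <= 25 without ties, normal approximation with continuity correction
#' otherwise) or paired t test, reporting the statistic, p-value and mean
#' post - pre difference.
#'
#' @param scores_pre,scores_post paired score vectors (equal length >= 2).
#' @param method `"wilcoxon"` or `"paired_t"`.
#' @param test_name label carried into the result.
#' @return object of class `behavioral_result`.
#' @export
behavioral_compare <- function(scores_pre, scores_post,
                               method = c("wilcoxon", "paired_t"),
                               test_name = "") {
  method <- match.arg(method)
  n <- length(scores_pre)
  if (length(scores_post) != n || n < 2)
    stop_param("need paired score vectors of equal length >= 2")
  d <- scores_post - scores_pre
  if (method == "wilcoxon") {
    dnz <- d[d != 0]
    if (!length(dnz))
      stop_param("all differences are zero: signed-rank test undefined")
    exact <- length(dnz) <= 25 && !any(duplicated(abs(dnz)))
    wt <- suppressWarnings(wilcox.test(dnz, exact = exact, correct = TRUE))
    stat <- unname(wt$statistic)
    p <- wt$p.value
  } else {
    if (sd(d) == 0) {
      stat <- 0
      p <- 1
    } else {
      tt <- t.test(scores_post, scores_pre, paired = TRUE)
      stat <- unname(tt$statistic)
      p <- tt$p.value
    }
  }
  structure(list(test = test_name, method = method, statistic = stat,
                 p = p, mean_difference = mean(d)),
            class = "behavioral_result")
}

#' @export
print.behavioral_result <- function(x, ...) {
  cat(sprintf("<behavioral_result> %s%s: statistic %.4g, p = %.4g, mean diff %.4g\n",
              x$method,
              if (nzchar(x$test)) paste0(" (", x$test, ")") else "",
              x$statistic, x$p, x$mean_difference))
  invisible(x)
}
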