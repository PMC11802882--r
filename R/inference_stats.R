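#' Independent-samples pooled-variance t-test
#'
#' Student's t with pooled variance and df = nA + nB - 2, matching the
#' degrees of freedom convention of listwise-deleted group contrasts.
#' One-tailed tests honor a pre-registered direction for the mean
#' difference A - B; the effect size is d = t * sqrt(1/nA + 1/nB).
#'
#' @param groupA,groupB Numeric vectors (each n >= 2).
#' @param sided \code{"one"} or \code{"two"}.
#' @param direction For one-tailed tests, hypothesized sign of
#'   mean(A) - mean(B): \code{"greater"} or \code{"less"}.
#' @return A \code{group_test} list: t, df, p, sided, direction, d,
#'   means, sds, n.
#' @export
independent_t <- function(groupA, groupB, sided = c("two", "one"),
                          direction = c("greater", "less")) {
  sided <- match.arg(sided)
  direction <- match.arg(direction)
  groupA <- groupA[is.finite(groupA)]
  groupB <- groupB[is.finite(groupB)]
  nA <- length(groupA); nB <- length(groupB)
  if (nA < 2L || nB < 2L) stop("each group needs n >= 2")
  sp2 <- ((nA - 1) * stats::var(groupA) + (nB - 1) * stats::var(groupB)) /
    (nA + nB - 2)
  if (sp2 == 0) stop("zero pooled variance")
  tval <- (mean(groupA) - mean(groupB)) / sqrt(sp2 * (1 / nA + 1 / nB))
  df <- nA + nB - 2
  p <- if (sided == "two") {
    2 * stats::pt(-abs(tval), df)
  } else if (direction == "greater") {
    stats::pt(tval, df, lower.tail = FALSE)
  } else {
    stats::pt(tval, df)
  }
  structure(list(t = tval, df = df, p = p, sided = sided,
                 direction = if (sided == "one") direction else NA,
                 d = tval * sqrt(1 / nA + 1 / nB),
                 means = c(A = mean(groupA), B = mean(groupB)),
                 sds = c(A = stats::sd(groupA), B = stats::sd(groupB)),
                 n = c(A = nA, B = nB)),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g (%s-tailed%s), d = %.3f\n",
              x$df, x$t, x$p, x$sided,
              if (x$sided == "one") paste0(", ", x$direction) else "",
              x$d))
  cat(sprintf("  A: M = %.3f SD = %.3f (n = %d); B: M = %.3f SD = %.3f (n = %d)\n",
              x$means[1], x$sds[1], x$n[1], x$means[2], x$sds[2], x$n[2]))
  invisible(x)
}

#' Pearson correlation with t-distributed test
#'
#' @param x,y Numeric vectors (finite, n >= 3).
#' @param sided \code{"two"} or \code{"one"}.
#' @param direction For one-tailed tests, hypothesized sign of r.
#' @return List with r, df (n - 2), p, n.
#' @export
pearson_r <- function(x, y, sided = c("two", "one"),
                      direction = c("positive", "negative")) {
  sided <- match.arg(sided)
  direction <- match.arg(direction)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need n >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined")
  alt <- if (sided == "two") "two.sided" else
    if (direction == "positive") "greater" else "less"
  ct <- stats::cor.test(x, y, alternative = alt, method = "pearson")
  list(r = unname(ct$estimate), df = unname(ct$parameter),
       p = ct$p.value, n = length(x))
}

#' Covariate-adjusted group effect (ANCOVA)
#'
#' F-test of the group factor after adjusting for covariates, as in
#' "group effect after entering gender, age, and income in an ANOVA
#' model". Partial (type-III style) test via \code{car::Anova}; listwise
#' deletion of incomplete rows.
#'
#' @param data Data.frame holding all columns.
#' @param outcome,group Column names (group is coerced to factor).
#' @param covariates Character vector of covariate column names.
#' @return List with F, df1, df2, p, n.
#' @export
ancova_group_effect <- function(data, outcome, group,
                                covariates = character(0)) {
  cols <- c(outcome, group, covariates)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  d[[group]] <- factor(d[[group]])
  is_fac <- vapply(d[c(group, covariates)],
                   function(v) is.factor(v) || is.character(v), logical(1))
  for (nm in names(is_fac)[is_fac]) d[[nm]] <- factor(d[[nm]])
  ctr <- stats::setNames(rep(list("contr.sum"), sum(is_fac)),
                         names(is_fac)[is_fac])
  mod <- stats::lm(stats::reformulate(c(group, covariates), outcome),
                   data = d, contrasts = ctr)
  if (any(is.na(stats::coef(mod)))) {
    al <- names(stats::coef(mod))[is.na(stats::coef(mod))]
    stop("rank-deficient design; aliased: ", paste(al, collapse = ", "))
  }
  aov3 <- car::Anova(mod, type = 3)
  row <- which(rownames(aov3) == group)
  list(F = aov3[row, "F value"], df1 = aov3[row, "Df"],
       df2 = aov3["Residuals", "Df"], p = aov3[row, "Pr(>F)"],
       n = nrow(d))
}

#' Simultaneous (multiple) OLS regression
#'
#' Ordinary least squares with conventional standard errors; errors on a
#' rank-deficient design rather than silently dropping terms.
#'
#' @param data Data.frame.
#' @param outcome Outcome column name.
#' @param predictors Character vector of predictor column names.
#' @return Data.frame of coefficients: estimate, se, t, p.
#' @export
simultaneous_regression <- function(data, outcome, predictors) {
  cols <- c(outcome, predictors)
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  mod <- stats::lm(stats::reformulate(predictors, outcome), data = d)
  if (any(is.na(stats::coef(mod)))) {
    al <- names(stats::coef(mod))[is.na(stats::coef(mod))]
    stop("collinear design; aliased: ", paste(al, collapse = ", "))
  }
  cf <- summary(mod)$coefficients
  data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
             t = cf[, 3], p = cf[, 4], row.names = NULL)
}
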