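#' OLS mediation with percentile bootstrap of the partially standardized
#' indirect effect
#'
#' Simple mediation X -> M -> Y estimated by ordinary least squares, in
#' the style of the PROCESS macro: the a path regresses the mediator on
#' the (binary) predictor plus covariates; b and the direct effect c'
#' come from the outcome on mediator, predictor and covariates; the total
#' effect c from the outcome on predictor and covariates. Because the
#' predictor is a group indicator it is left unstandardized, and effects
#' are reported partially standardized, i.e. in outcome-SD units with the
#' mediator standardized: a* = a/SD(M), b* = b SD(M)/SD(Y),
#' indirect = a* b* = a b / SD(Y). The OLS identity c = c' + a b makes
#' total = direct + indirect hold exactly. Inference for the indirect
#' effect uses a percentile bootstrap over participants.
#'
#' @param x Binary group vector coded 0/1 (or a 2-level factor).
#' @param m,y Mediator and outcome vectors.
#' @param covariates Optional data.frame of covariates, entered in both
#'   the mediator and outcome equations.
#' @param n_boot Bootstrap resamples (default 10,000; fewer than 1,000
#'   triggers a recorded warning).
#' @param seed Integer seed (mandatory, for reproducibility).
#' @param conf Confidence level of the percentile interval.
#' @return A \code{mediation_fit}: standardized paths \code{a_path},
#'   \code{b_path}, \code{direct}, \code{total}, \code{indirect}, their
#'   unstandardized counterparts, bootstrap \code{ci}, \code{boot_se},
#'   \code{n}, \code{n_boot}, \code{seed}, \code{covariates},
#'   \code{warnings}.
#' @export
fit_mediation <- function(x, m, y, covariates = NULL, n_boot = 10000L,
                          seed, conf = 0.95) {
  if (missing(seed)) stop("seed is required for the bootstrap")
  if (is.factor(x)) x <- as.integer(x) - 1L
  if (!all(x %in% c(0, 1))) stop("x must be coded {0, 1}")
  cov_df <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  cov_mat <- if (is.null(cov_df)) {
    matrix(numeric(0), nrow = length(x), ncol = 0)
  } else {
    stats::model.matrix(~ ., data = cov_df)[, -1, drop = FALSE]
  }
  ok <- is.finite(x) & is.finite(m) & is.finite(y) &
    (if (ncol(cov_mat)) apply(is.finite(cov_mat), 1, all) else TRUE)
  x <- x[ok]; m <- m[ok]; y <- y[ok]
  cov_mat <- cov_mat[ok, , drop = FALSE]
  n <- length(x)
  # canonical row order: the bootstrap draws index sets, so sorting makes
  # the CI invariant to the caller's row order under a fixed seed
  ord <- do.call(order, c(list(x, m, y),
                          if (ncol(cov_mat)) asplit(cov_mat, 2) else NULL))
  x <- x[ord]; m <- m[ord]; y <- y[ord]
  cov_mat <- cov_mat[ord, , drop = FALSE]
  if (length(unique(x)) < 2L) stop("x is constant after listwise deletion")
  if (stats::sd(m) == 0) stop("degenerate mediator (zero variance)")
  warnings <- character(0)
  if (n_boot < 1000L)
    warnings <- c(warnings, "n_boot < 1000: bootstrap CI is unstable")

  Xa <- cbind(1, x, cov_mat)              # m ~ x (+cov)
  Xb <- cbind(1, m, x, cov_mat)           # y ~ m + x (+cov)
  Xc <- Xa                                # y ~ x (+cov)
  paths <- function(Xa, Xb, Xc, m, y) {
    a <- .lm.fit(Xa, m)$coefficients[2L]
    cf <- .lm.fit(Xb, y)$coefficients
    b <- cf[2L]; cprime <- cf[3L]
    ctot <- .lm.fit(Xc, y)$coefficients[2L]
    c(a = a, b = b, cprime = cprime, ctot = ctot)
  }
  est <- paths(Xa, Xb, Xc, m, y)
  sdm <- stats::sd(m); sdy <- stats::sd(y)

  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  boot_ind <- numeric(n_boot)
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    mb <- m[idx]; yb <- y[idx]
    Xab <- Xa[idx, , drop = FALSE]
    Xbb <- cbind(1, mb, Xab[, -1, drop = FALSE])
    ab <- .lm.fit(Xab, mb)$coefficients[2L]
    bb <- .lm.fit(Xbb, yb)$coefficients[2L]
    boot_ind[i] <- ab * bb / stats::sd(yb)
  }
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot_ind, c(alpha, 1 - alpha), type = 6))

  structure(list(
    a_path = unname(est["a"] / sdm),
    b_path = unname(est["b"] * sdm / sdy),
    direct = unname(est["cprime"] / sdy),
    total = unname(est["ctot"] / sdy),
    indirect = unname(est["a"] * est["b"] / sdy),
    unstandardized = as.list(est),
    ci = ci, conf = conf,
    boot_se = stats::sd(boot_ind),
    n = n, n_boot = n_boot, seed = seed,
    covariates = if (is.null(cov_df)) character(0) else names(cov_df),
    warnings = warnings), class = "mediation_fit")
}

#' Indirect effect implied by two standardized paths
#'
#' The product rule of simple OLS mediation: the (partially) standardized
#' indirect effect is the product of the X -> M and M -> Y | X paths, and
#' the total effect decomposes as direct + indirect. Handy for checking a
#' published path diagram's internal consistency.
#'
#' @param a_path Standardized X -> M path.
#' @param b_path Standardized M -> Y (given X) path.
#' @param direct Optional direct (c') effect; when supplied the implied
#'   total effect is also returned.
#' @return List with \code{indirect} and (if \code{direct} given)
#'   \code{total}.
#' @export
indirect_from_paths <- function(a_path, b_path, direct = NULL) {
  out <- list(indirect = a_path * b_path)
  if (!is.null(direct)) out$total <- direct + out$indirect
  out
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat("<mediation_fit> n =", x$n, "\n")
  cat(sprintf("  a = %.3f, b = %.3f (standardized paths)\n",
              x$a_path, x$b_path))
  cat(sprintf("  indirect = %.3f, direct = %.3f, total = %.3f (Y-SD units)\n",
              x$indirect, x$direct, x$total))
  cat(sprintf("  %.0f%% percentile bootstrap CI (%d resamples): [%.3f, %.3f]\n",
              100 * x$conf, x$n_boot, x$ci[1], x$ci[2]))
  if (length(x$covariates))
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
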