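#' Single-component PCA latent factor
#'
#' Extracts the first principal component of the (by default) correlation
#' matrix of a participants-by-variables score matrix, the construction
#' used for the future-orientation and dispositional-negativity latent
#' factors. Loadings are the eigenvector scaled by the square root of its
#' eigenvalue, signed so the majority of loadings are positive; the
#' proportion of variance explained is sum(loading^2)/p. With a single
#' retained component a varimax rotation is the identity, so the rotation
#' step is a no-op (asserted, not assumed). Factor scores use the
#' regression method on standardized variables (unit-variance scores);
#' \code{scores = "component"} returns the unscaled loading-weighted sum.
#'
#' @param score_matrix Numeric matrix or data.frame, participants x
#'   variables; no missing cells (filter listwise upstream).
#' @param standardize Use the correlation (TRUE) or covariance matrix.
#' @param scores Factor-score method.
#' @return A \code{factor_solution}: list with \code{loadings},
#'   \code{proportion_variance}, \code{scores}, \code{n_components}.
#' @export
fit_single_factor <- function(score_matrix, standardize = TRUE,
                              scores = c("regression", "component")) {
  scores <- match.arg(scores)
  x <- as.matrix(score_matrix)
  if (nrow(x) < 3L) stop("at least 3 participants required")
  if (ncol(x) < 2L) stop("at least 2 variables required")
  if (anyNA(x))
    stop("score matrix contains missing cells; filter rows listwise ",
         "before fitting")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance variable(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  xc <- scale(x, center = TRUE, scale = standardize)
  cmat <- stats::cov(xc)
  eig <- eigen(cmat, symmetric = TRUE)
  v <- eig$vectors[, 1]
  lambda1 <- eig$values[1]
  loadings <- v * sqrt(lambda1)
  # deterministic orientation: majority of loadings positive
  if (sum(loadings > 0) < sum(loadings < 0) ||
      (sum(loadings > 0) == sum(loadings < 0) && sum(loadings) < 0)) {
    loadings <- -loadings
    v <- -v
  }
  names(loadings) <- colnames(x)
  # single-component varimax is the identity; keep the assertion live
  rot <- stats::varimax(matrix(loadings, ncol = 1))
  rot_load <- if (is.list(rot)) c(rot$loadings) else c(rot)
  stopifnot(max(abs(rot_load - loadings)) < 1e-8)
  fs <- if (scores == "regression") {
    drop(xc %*% v) / sqrt(lambda1)
  } else {
    drop(xc %*% loadings)
  }
  structure(list(
    variables = colnames(x),
    loadings = loadings,
    proportion_variance = lambda1 / sum(diag(cmat)),
    scores = fs,
    score_method = scores,
    n_components = 1L), class = "factor_solution")
}

#' Variance explained implied by a standardized loading vector
#'
#' For a single-component solution on standardized variables the
#' proportion of total variance carried by the component is
#' sum(loading^2)/p. Useful for checking a printed loading table against
#' its printed variance-explained figure.
#'
#' @param loadings Numeric vector of component loadings.
#' @return Fraction of variance explained.
#' @export
variance_from_loadings <- function(loadings) {
  if (!length(loadings)) stop("loadings must be nonempty")
  sum(loadings^2) / length(loadings)
}

#' @export
print.factor_solution <- function(x, ...) {
  cat("<factor_solution> 1 component,",
      format(100 * x$proportion_variance, digits = 3),
      "% variance explained\n")
  print(round(x$loadings, 3))
  invisible(x)
}
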