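# The radiomic signature: principal components of the standardized feature
# set, retained by the Kaiser criterion (eigenvalue > 1).

#' Fit the radiomic signature
#'
#' Z-scores every feature, eigendecomposes the feature correlation matrix
#' and retains the components with eigenvalue greater than one. Correlation
#' (not covariance) PCA is used because the features live on wildly
#' different scales (SUV units vs fourth-moment cluster prominence). The
#' decomposition is closed-form and deterministic up to column sign; signs
#' are fixed so each loading column's largest-magnitude entry is positive.
#'
#' @param features numeric samples x features table, no missing values, no
#'   zero-variance columns; a warning is emitted when `n <= p` or when the
#'   spectrum is near-flat (all eigenvalues close to 1), where the retained
#'   count is unstable.
#' @return an object of class `radiomic_signature`: `center`, `scale` (per
#'   feature), `loadings` (features x retained, orthonormal), `eigenvalues`
#'   (all, descending), `n_retained`, `features`.
#' @export
fit_signature <- function(features) {
  X <- as.matrix(features)
  if (anyNA(X)) stop("missing values in features")
  fn <- colnames(X)
  if (is.null(fn)) fn <- paste0("f", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("zero-variance feature: ", fn[which(sds == 0)[1]])
  if (nrow(X) <= ncol(X))
    warning("n_samples <= n_features; component retention may be unstable")
  ctr <- colMeans(X)
  Z <- sweep(sweep(X, 2, ctr, "-"), 2, sds, "/")
  C <- stats::cor(X)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  keep <- which(ev > 1)
  if (!length(keep)) keep <- 1L  # degenerate: keep the leading component
  if (max(ev) < 1.15)
    warning("near-identity correlation spectrum; Kaiser retention unstable")
  L <- e$vectors[, keep, drop = FALSE]
  # fix signs: largest-|loading| entry of each column positive
  for (j in seq_len(ncol(L))) {
    k <- which.max(abs(L[, j]))
    if (L[k, j] < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(fn, paste0("PC", seq_along(keep)))
  structure(list(center = stats::setNames(ctr, fn),
                 scale = stats::setNames(sds, fn),
                 loadings = L,
                 eigenvalues = ev,
                 n_retained = length(keep),
                 features = fn),
            class = "radiomic_signature")
}

#' Project features onto the radiomic signature
#'
#' `scores = standardized features \%*\% loadings`, using the fit-time
#' center and scale. On the fit data the scores have zero mean per
#' component and are mutually uncorrelated.
#'
#' @param features table containing the fitted feature columns.
#' @param sig a [fit_signature()] result.
#' @return data frame of component scores (`PC1`, `PC2`, ...).
#' @export
apply_signature <- function(features, sig) {
  stopifnot(inherits(sig, "radiomic_signature"))
  X <- as.matrix(features)
  miss <- setdiff(sig$features, colnames(X))
  if (length(miss)) stop("missing feature column(s): ", paste(miss, collapse = ", "))
  X <- X[, sig$features, drop = FALSE]
  Z <- sweep(sweep(X, 2, sig$center, "-"), 2, sig$scale, "/")
  S <- Z %*% sig$loadings
  out <- as.data.frame(S)
  rownames(out) <- NULL
  out
}

#' @export
predict.radiomic_signature <- function(object, newdata, ...) {
  apply_signature(newdata, object)
}

#' @export
print.radiomic_signature <- function(x, ...) {
  cat("Radiomic signature:", x$n_retained, "of", length(x$eigenvalues),
      "components retained (eigenvalue > 1)\n")
  cat("  eigenvalues:", paste(signif(x$eigenvalues[seq_len(min(6, length(x$eigenvalues)))], 3),
                              collapse = ", "),
      if (length(x$eigenvalues) > 6) "..." else "", "\n")
  cat("  variance explained by retained components:",
      sprintf("%.1f%%", 100 * sum(x$eigenvalues[seq_len(x$n_retained)]) /
                sum(x$eigenvalues)), "\n")
  invisible(x)
}
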