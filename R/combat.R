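# Parametric empirical-Bayes location/scale batch harmonization (ComBat)
# for the extracted feature table, with an explicit fit/apply split so the
# model can be serialized, audited, and applied to held-out samples.

#' Fit a ComBat harmonization model
#'
#' Per feature g: estimate the batch-weighted grand mean `alpha_g` and the
#' pooled residual scale `sigma_g`; standardize `z = (y - alpha_g)/sigma_g`;
#' estimate per-batch location `gamma_ig` and scale `delta_ig` on z; shrink
#' them toward normal (location) and inverse-gamma (scale) priors whose
#' hyperparameters are moment-matched across features, by the standard
#' iterative parametric empirical-Bayes solver (convergence when the largest
#' parameter change falls below `tol`).
#'
#' Laboratory covariates are not features of the scanner and must not be
#' passed here; harmonize only image-derived columns.
#'
#' @param features numeric data frame / matrix, samples x features, no
#'   missing values.
#' @param batch vector of batch labels, one per sample; every batch needs at
#'   least 2 samples.
#' @param tol convergence tolerance of the EB solver (default 1e-6).
#' @param max_iter iteration cap (default 100).
#' @return an object of class `combat_model` with elements `alpha`, `sigma`
#'   (per feature), `gamma_star`, `delta_star` (batch x feature matrices;
#'   `delta_star` is a scale, not a variance), `batches`, `features`.
#' @export
combat_fit <- function(features, batch, tol = 1e-6, max_iter = 100L) {
  X <- as.matrix(features)
  if (!is.numeric(X)) stop("features must be numeric")
  if (anyNA(X)) stop("missing values in features")
  batch <- as.character(batch)
  if (length(batch) != nrow(X)) stop("batch length must match rows")
  tabs <- table(batch)
  if (length(tabs) < 2L) stop("need at least 2 batches")
  if (any(tabs < 2L))
    stop("singleton batch: ", names(tabs)[which(tabs < 2L)[1]])
  fn <- colnames(X)
  if (is.null(fn)) fn <- paste0("f", seq_len(ncol(X)))
  zv <- which(apply(X, 2, stats::sd) == 0)
  if (length(zv)) stop("zero-variance feature: ", fn[zv[1]])

  bl <- names(tabs)
  nb <- length(bl)
  n <- nrow(X); p <- ncol(X)
  ni <- as.numeric(tabs[bl])

  # batch means and batch-size-weighted grand mean
  bmean <- t(vapply(bl, function(b) colMeans(X[batch == b, , drop = FALSE]),
                    numeric(p)))
  alpha <- as.numeric(crossprod(ni / n, bmean))
  # pooled residual variance about batch means (divide by n, ComBat form)
  R <- X - bmean[match(batch, bl), , drop = FALSE]
  sigma <- sqrt(colSums(R^2) / n)
  Z <- sweep(sweep(X, 2, alpha, "-"), 2, sigma, "/")

  gamma_hat <- t(vapply(bl, function(b) colMeans(Z[batch == b, , drop = FALSE]),
                        numeric(p)))
  delta2_hat <- t(vapply(bl, function(b) apply(Z[batch == b, , drop = FALSE], 2, stats::var),
                         numeric(p)))

  # moment-matched prior hyperparameters per batch
  gamma_bar <- rowMeans(gamma_hat)
  tau2_bar <- apply(gamma_hat, 1, stats::var)
  a_prior <- function(d) { m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2 }
  b_prior <- function(d) { m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2 }

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  for (ib in seq_len(nb)) {
    zb <- Z[batch == bl[ib], , drop = FALSE]
    nbatch <- ni[ib]
    g_hat <- gamma_hat[ib, ]; d2_hat <- delta2_hat[ib, ]
    g_bar <- gamma_bar[ib]; t2 <- tau2_bar[ib]
    ap <- a_prior(d2_hat); bp <- b_prior(d2_hat)
    g_old <- g_hat; d2_old <- d2_hat
    for (it in seq_len(max_iter)) {
      g_new <- (nbatch * t2 * g_hat + d2_old * g_bar) / (nbatch * t2 + d2_old)
      ss <- colSums((zb - matrix(g_new, nbatch, p, byrow = TRUE))^2)
      d2_new <- (0.5 * ss + bp) / (nbatch / 2 + ap - 1)
      change <- max(abs(g_new - g_old) / abs(g_old + 1e-12),
                    abs(d2_new - d2_old) / d2_old)
      g_old <- g_new; d2_old <- d2_new
      if (change < tol) break
    }
    gamma_star[ib, ] <- g_old
    delta2_star[ib, ] <- d2_old
  }

  structure(list(alpha = stats::setNames(alpha, fn),
                 sigma = stats::setNames(sigma, fn),
                 gamma_star = gamma_star,
                 delta_star = sqrt(delta2_star),
                 batches = bl,
                 features = fn),
            class = "combat_model")
}

#' Apply a fitted ComBat model
#'
#' `y* = sigma_g * (z - gamma*_ig) / delta*_ig + alpha_g` with
#' `z = (y - alpha_g)/sigma_g`. Monotone per batch x feature, so
#' within-batch feature ranks are preserved.
#'
#' @param features samples x features table with the fitted feature columns.
#' @param model a [combat_fit()] result.
#' @param batch batch label per sample; every label must have been seen at
#'   fit time.
#' @return the harmonized table, same shape and column order as the input.
#' @export
combat_apply <- function(features, model, batch) {
  stopifnot(inherits(model, "combat_model"))
  X <- as.matrix(features)
  miss <- setdiff(model$features, colnames(X))
  if (length(miss)) stop("missing feature column(s): ", paste(miss, collapse = ", "))
  X <- X[, model$features, drop = FALSE]
  batch <- as.character(batch)
  if (length(batch) != nrow(X)) stop("batch length must match rows")
  unseen <- setdiff(unique(batch), model$batches)
  if (length(unseen)) stop("unseen batch label: ", unseen[1])
  Z <- sweep(sweep(X, 2, model$alpha, "-"), 2, model$sigma, "/")
  ib <- match(batch, model$batches)
  Zs <- (Z - model$gamma_star[ib, , drop = FALSE]) /
    model$delta_star[ib, , drop = FALSE]
  Y <- sweep(sweep(Zs, 2, model$sigma, "*"), 2, model$alpha, "+")
  out <- as.data.frame(Y)
  rownames(out) <- NULL
  out
}

#' Identity ComBat model
#'
#' A model with `gamma* = 0`, `delta* = 1` for every batch x feature;
#' applying it returns the input unchanged. Useful as a null in tests and
#' pipelines with harmonization switched off.
#'
#' @param features feature table defining names and standardization.
#' @param batches character vector of batch labels the model accepts.
#' @return a `combat_model`.
#' @export
combat_identity <- function(features, batches) {
  X <- as.matrix(features)
  fn <- colnames(X)
  p <- length(fn); nb <- length(batches)
  structure(list(alpha = stats::setNames(colMeans(X), fn),
                 sigma = stats::setNames(apply(X, 2, stats::sd), fn),
                 gamma_star = matrix(0, nb, p, dimnames = list(batches, fn)),
                 delta_star = matrix(1, nb, p, dimnames = list(batches, fn)),
                 batches = batches,
                 features = fn),
            class = "combat_model")
}

#' @export
print.combat_model <- function(x, ...) {
  cat("ComBat model:", length(x$features), "features,",
      length(x$batches), "batches (", paste(x$batches, collapse = ", "), ")\n")
  cat("  shrunken batch locations (mean |gamma*|):",
      signif(mean(abs(x$gamma_star)), 3), "\n")
  invisible(x)
}
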