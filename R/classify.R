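# Repeated 70/30 MLP classification with Mann-Whitney AUC reporting.
#
# The network is a small feed-forward perceptron (tanh hidden layers,
# 2-unit softmax output, cross-entropy loss) trained by full-batch
# backpropagation gradient descent with a backtracking line search: a step
# is accepted only if it lowers the loss, so the recorded loss trace is
# non-increasing by construction and a run is fully determined by its seed.

#' Stratified train/test split
#'
#' The training size is `round-half-up(n * train_fraction)`; it is allocated
#' to the classes by largest remainder, so per-class proportions are
#' preserved within one sample. The split is disjoint, exhaustive, keeps at
#' least one member of each class on both sides, and is deterministic given
#' the seed.
#'
#' @param labels logical/two-level vector; both classes need >= 2 members.
#' @param train_fraction default 0.70.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.70, seed = 1L) {
  y <- as.logical(labels)
  if (anyNA(y)) stop("labels must be two-level / logical")
  if (min(table(y)) < 2L || length(unique(y)) < 2L)
    stop("both classes need at least 2 members")
  n <- length(y)
  ntr_total <- as.integer(floor(n * train_fraction + 0.5))
  nc <- c(sum(!y), sum(y))
  quota <- nc * train_fraction
  ntr <- floor(quota)
  extra <- ntr_total - sum(ntr)
  if (extra > 0) {
    give <- order(quota - ntr, decreasing = TRUE)[seq_len(extra)]
    ntr[give] <- ntr[give] + 1L
  }
  ntr <- pmin(pmax(ntr, 1L), nc - 1L)
  with_seed(seed, {
    train <- c(sample(which(!y), ntr[1]), sample(which(y), ntr[2]))
    train <- sort(train)
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' MLP configuration
#'
#' @param n_hidden_layers number of hidden layers, `>= 1` (default 1).
#' @param units_per_layer neurons per hidden layer, `>= 3` (default 3).
#' @param max_epochs full-batch gradient steps (default 500).
#' @param learning_rate initial step size (adapted by backtracking).
#' @param weight_decay L2 penalty on weights. The default (0.02) is sized
#'   for the regime this pipeline works in — around a hundred training
#'   cases and at most eight inputs — where an unpenalized network of even
#'   three tanh units can fit the training split perfectly and generalize
#'   poorly.
#' @param init_scale SD of the random weight initialization.
#' @return an object of class `mlp_config`.
#' @export
mlp_config <- function(n_hidden_layers = 1L, units_per_layer = 3L,
                       max_epochs = 500L, learning_rate = 0.5,
                       weight_decay = 0.02, init_scale = 0.5) {
  stopifnot(n_hidden_layers >= 1L, units_per_layer >= 3L, max_epochs >= 1L,
            learning_rate > 0, weight_decay >= 0, init_scale > 0)
  structure(list(n_hidden_layers = as.integer(n_hidden_layers),
                 units_per_layer = as.integer(units_per_layer),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 init_scale = init_scale),
            class = "mlp_config")
}

mlp_forward <- function(W, b, X) {
  A <- list(X)
  nl <- length(W)
  for (l in seq_len(nl - 1L))
    A[[l + 1L]] <- tanh(A[[l]] %*% W[[l]] + matrix(b[[l]], nrow(X), length(b[[l]]), byrow = TRUE))
  S <- A[[nl]] %*% W[[nl]] + matrix(b[[nl]], nrow(X), 2, byrow = TRUE)
  S <- S - apply(S, 1, max)
  E <- exp(S)
  P <- E / rowSums(E)
  list(activations = A, prob = P)
}

mlp_loss <- function(W, b, X, Y, decay) {
  fw <- mlp_forward(W, b, X)
  ce <- -mean(log(pmax(fw$prob[cbind(seq_len(nrow(X)), Y + 1L)], 1e-12)))
  ce + 0.5 * decay * sum(vapply(W, function(w) sum(w^2), 0))
}

mlp_grad <- function(W, b, X, Y, decay) {
  n <- nrow(X); nl <- length(W)
  fw <- mlp_forward(W, b, X)
  A <- fw$activations
  T_ <- matrix(0, n, 2); T_[cbind(seq_len(n), Y + 1L)] <- 1
  D <- (fw$prob - T_) / n                 # softmax + cross-entropy
  gW <- vector("list", nl); gb <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    gW[[l]] <- crossprod(A[[l]], D) + decay * W[[l]]
    gb[[l]] <- colSums(D)
    if (l > 1L) D <- (D %*% t(W[[l]])) * (1 - A[[l]]^2)  # tanh'
  }
  list(W = gW, b = gb)
}

#' Train the multi-layer perceptron
#'
#' Inputs are standardized internally with the training data's mean/SD
#' (stored in the fit and re-used at prediction time, so a test split is
#' never standardized with its own statistics). Training is full-batch
#' backpropagation with backtracking: each epoch's step is accepted only if
#' it decreases the penalized cross-entropy, halving the step size up to 30
#' times before giving up, so `$loss` is non-increasing.
#'
#' @param features numeric samples x inputs table.
#' @param labels logical/0-1 vector, both classes present.
#' @param config an [mlp_config()].
#' @param seed integer seed for the weight initialization.
#' @return an object of class `mlp_fit` with `weights`, `biases`, `center`,
#'   `scale`, `loss` (accepted-epoch trace), `config`, `seed`.
#' @export
train_mlp <- function(features, labels, config = mlp_config(), seed = 1L) {
  X <- as.matrix(features)
  if (!all(is.finite(X))) stop("non-finite values in features")
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2L) stop("degenerate single-class training split")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  sizes <- c(ncol(X), rep(config$units_per_layer, config$n_hidden_layers), 2L)
  nl <- length(sizes) - 1L
  fit <- with_seed(seed, {
    W <- lapply(seq_len(nl), function(l)
      matrix(stats::rnorm(sizes[l] * sizes[l + 1L], 0, config$init_scale / sqrt(sizes[l])),
             sizes[l], sizes[l + 1L]))
    b <- lapply(seq_len(nl), function(l) numeric(sizes[l + 1L]))
    lr <- config$learning_rate
    loss <- mlp_loss(W, b, Xs, y, config$weight_decay)
    trace <- loss
    for (ep in seq_len(config$max_epochs)) {
      g <- mlp_grad(W, b, Xs, y, config$weight_decay)
      step <- lr
      accepted <- FALSE
      for (tr in 1:30) {
        Wn <- Map(function(w, gw) w - step * gw, W, g$W)
        bn <- Map(function(bb, gb) bb - step * gb, b, g$b)
        newloss <- mlp_loss(Wn, bn, Xs, y, config$weight_decay)
        if (newloss < loss) { accepted <- TRUE; break }
        step <- step / 2
      }
      if (!accepted) break
      W <- Wn; b <- bn; loss <- newloss
      trace <- c(trace, loss)
      lr <- min(step * 2, config$learning_rate * 4)  # gentle re-expansion
      if (length(trace) > 1 &&
          abs(trace[length(trace) - 1] - loss) < 1e-10) break
    }
    list(W = W, b = b, trace = trace)
  })
  structure(list(weights = fit$W, biases = fit$b,
                 center = ctr, scale = scl,
                 loss = fit$trace, config = config, seed = seed),
            class = "mlp_fit")
}

#' Predicted class-1 probabilities
#'
#' @param object an [train_mlp()] fit.
#' @param newdata samples x inputs table (fit-time standardization applied).
#' @param ... unused.
#' @return numeric vector of probabilities for the positive class.
#' @export
predict.mlp_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  Xs <- sweep(sweep(X, 2, object$center, "-"), 2, object$scale, "/")
  mlp_forward(object$weights, object$biases, Xs)$prob[, 2]
}

#' @export
print.mlp_fit <- function(x, ...) {
  cat("MLP:", length(x$center), "inputs ->",
      paste(rep(x$config$units_per_layer, x$config$n_hidden_layers), collapse = "-"),
      "tanh -> 2 softmax;", length(x$loss) - 1L, "accepted epochs, final loss",
      signif(x$loss[length(x$loss)], 4), "\n")
  invisible(x)
}

#' Mann-Whitney AUC
#'
#' Area under the ROC curve via the rank (Mann-Whitney) formulation:
#' `(concordant pairs + 0.5 * tied pairs) / (n_pos * n_neg)`, computed with
#' midranks.
#'
#' @param prob numeric scores.
#' @param labels logical/0-1 outcome, both classes present.
#' @return a value in \[0,1\].
#' @export
auc_mw <- function(prob, labels) {
  y <- as.logical(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(prob)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ---- repeated-runs experiment -------------------------------------------

endpoint_names <- c("involved", "rel5", "rel10", "abs5", "abs10", "ki67")

# make_xy(split) -> list(tr, te); indirection so train-only PCA fits can
# rebuild the design matrices inside each split
one_run <- function(make_xy, y, config, split_seed, weight_seed, auc_on = "test") {
  sp <- stratified_split(y, 0.70, seed = split_seed)
  xy <- make_xy(sp)
  fit <- train_mlp(xy$tr, y[sp$train], config = config, seed = weight_seed)
  p_tr <- predict(fit, xy$tr)
  p_te <- predict(fit, xy$te)
  acc <- function(p, yy) 100 * mean((p >= 0.5) == yy)
  auc_scores <- if (auc_on == "test") auc_mw(p_te, y[sp$test])
                else auc_mw(c(p_tr, p_te), c(y[sp$train], y[sp$test]))
  c(train_accuracy = acc(p_tr, y[sp$train]),
    test_accuracy = acc(p_te, y[sp$test]),
    auc = auc_scores)
}

#' Run the repeated-splits classification experiment
#'
#' For every endpoint x feature set, performs `n_runs` (default 5) seeded
#' runs of split -> train -> evaluate, and reports the median and range of
#' training accuracy, test accuracy, and test AUC. Feature sets: `"suv"`
#' (the three SUV metrics), `"signature"` (the retained principal radiomic
#' components), `"signature+labs"` (components plus continuous WBC and LDH;
#' marrow-involvement endpoints only, not Ki-67). The Ki-67 endpoint is
#' evaluated in involved patients only. By default the five repetitions
#' re-randomize only the weight initialization, with one shared 70/30 split
#' per endpoint (`vary = "weights"`); `vary = "both"` re-randomizes the
#' split as well.
#'
#' @param cohort cohort data frame (see [read_cohort()]).
#' @param features harmonized feature table aligned row-wise with `cohort`
#'   (must contain the 19 radiomic columns).
#' @param signature optional pre-fit [fit_signature()]; fit on `features`
#'   when `NULL`.
#' @param endpoints subset of
#'   `c("involved","rel5","rel10","abs5","abs10","ki67")`.
#' @param feature_sets subset of `c("suv","signature","signature+labs")`.
#' @param config an [mlp_config()].
#' @param n_runs repetitions per cell (default 5).
#' @param master_seed seed from which all split/weight seeds derive.
#' @param vary `"weights"` (default) or `"both"`.
#' @param auc_on `"test"` (default) or `"all"` cases.
#' @param pca_fit `"full"` (default): signature scores come from the
#'   full-cohort fit; `"train"`: the signature is refit on each run's
#'   training split only (no fit-time leakage into the test split).
#' @return an object of class `run_report`: `runs` (long per-run data
#'   frame) and `summary` (median and range per endpoint x feature set x
#'   outcome).
#' @export
run_experiment <- function(cohort, features, signature = NULL,
                           endpoints = endpoint_names,
                           feature_sets = c("suv", "signature", "signature+labs"),
                           config = mlp_config(), n_runs = 5L,
                           master_seed = 1L, vary = c("weights", "both"),
                           auc_on = c("test", "all"),
                           pca_fit = c("full", "train")) {
  vary <- match.arg(vary)
  auc_on <- match.arg(auc_on)
  pca_fit <- match.arg(pca_fit)
  endpoints <- match.arg(endpoints, endpoint_names, several.ok = TRUE)
  fs_all <- c("suv", "signature", "signature+labs")
  feature_sets <- match.arg(feature_sets, fs_all, several.ok = TRUE)
  fmat <- as.matrix(features[, feature_columns(), drop = FALSE])
  if (is.null(signature)) signature <- fit_signature(fmat)
  scores <- as.matrix(apply_signature(fmat, signature))
  rows <- list()
  for (ep in endpoints) {
    st <- stratify(cohort, ep)
    sel <- st$subset
    y <- st$labels
    if (min(table(y)) < 2L) stop("endpoint ", ep, ": a class has < 2 members")
    for (fset in feature_sets) {
      if (fset == "signature+labs" && ep == "ki67") next
      with_labs <- fset == "signature+labs"
      labs <- cbind(wbc = cohort$wbc[sel], ldh = cohort$ldh[sel])
      make_xy <- if (fset == "suv" || pca_fit == "full") {
        X <- switch(fset,
                    "suv" = fmat[sel, c("suv_max", "suv_mean", "suv_peak"), drop = FALSE],
                    "signature" = scores[sel, , drop = FALSE],
                    "signature+labs" = cbind(scores[sel, , drop = FALSE], labs))
        function(sp) list(tr = X[sp$train, , drop = FALSE],
                          te = X[sp$test, , drop = FALSE])
      } else {
        fsub <- fmat[sel, , drop = FALSE]
        function(sp) {
          sig_r <- fit_signature(fsub[sp$train, , drop = FALSE])
          str <- as.matrix(apply_signature(fsub[sp$train, , drop = FALSE], sig_r))
          ste <- as.matrix(apply_signature(fsub[sp$test, , drop = FALSE], sig_r))
          if (with_labs) {
            str <- cbind(str, labs[sp$train, , drop = FALSE])
            ste <- cbind(ste, labs[sp$test, , drop = FALSE])
          }
          list(tr = str, te = ste)
        }
      }
      base_seed <- derive_seed(master_seed, match(ep, endpoint_names) * 100 +
                                 match(fset, fs_all) * 10)
      for (r in seq_len(n_runs)) {
        split_seed <- if (vary == "both") derive_seed(base_seed, 1000 + r)
                      else derive_seed(base_seed, 1000)
        weight_seed <- derive_seed(base_seed, 2000 + r)
        res <- one_run(make_xy, y, config, split_seed, weight_seed, auc_on)
        rows[[length(rows) + 1L]] <- data.frame(
          endpoint = ep, feature_set = fset, run = r,
          train_accuracy = res["train_accuracy"],
          test_accuracy = res["test_accuracy"],
          auc = res["auc"], row.names = NULL)
      }
    }
  }
  runs <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(runs, list(runs$endpoint, runs$feature_set),
                                      drop = TRUE), function(g) {
    data.frame(endpoint = g$endpoint[1], feature_set = g$feature_set[1],
               train_accuracy_median = stats::median(g$train_accuracy),
               train_accuracy_min = min(g$train_accuracy),
               train_accuracy_max = max(g$train_accuracy),
               test_accuracy_median = stats::median(g$test_accuracy),
               test_accuracy_min = min(g$test_accuracy),
               test_accuracy_max = max(g$test_accuracy),
               auc_median = stats::median(g$auc),
               auc_min = min(g$auc), auc_max = max(g$auc),
               row.names = NULL)
  }))
  rownames(summ) <- NULL
  structure(list(runs = runs, summary = summ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$summary
  cat("Repeated-splits MLP report (median (range) over",
      max(x$runs$run), "runs):\n")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %-15s train %5.1f (%5.1f-%5.1f)  test %5.1f (%5.1f-%5.1f)  AUC %.2f (%.2f-%.2f)\n",
                s$endpoint[i], s$feature_set[i],
                s$train_accuracy_median[i], s$train_accuracy_min[i], s$train_accuracy_max[i],
                s$test_accuracy_median[i], s$test_accuracy_min[i], s$test_accuracy_max[i],
                s$auc_median[i], s$auc_min[i], s$auc_max[i]))
  }
  invisible(x)
}
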