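make_batch_table <- function(n_per_batch, p = 19, gamma = 0, delta = 1,
                             seed = 1) {
  # batch B gets an additive gamma (in SD units) and scale delta
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_batch * p), n_per_batch, p),
             matrix(rnorm(n_per_batch * p, gamma, delta), n_per_batch, p))
  colnames(X) <- paste0("f", seq_len(p))
  list(X = as.data.frame(X),
       batch = rep(c("A", "B"), each = n_per_batch))
}

test_that("a duplicated single batch fits near-null batch parameters", {
  set.seed(4)
  half <- matrix(rnorm(60 * 6), 60, 6)
  X <- rbind(half, half)
  colnames(X) <- paste0("f", 1:6)
  m <- combat_fit(X, rep(c("A", "B"), each = 60))
  expect_lt(max(abs(m$gamma_star)), 0.05)
  expect_lt(max(abs(m$delta_star - 1)), 0.05)
})

test_that("a large additive batch shift is essentially removed", {
  # +5 SD on every feature: a worst case for empirical-Bayes shrinkage,
  # because the across-feature spread of batch effects (the location prior
  # variance) is then just sampling noise, so per-feature deviations are
  # shrunk hard and small residuals remain. The reference implementation
  # behaves identically (see the cross-check below); we assert the shift is
  # removed up to those shrinkage residuals.
  d <- make_batch_table(100, gamma = 5, seed = 2)
  m <- combat_fit(d$X, d$batch)
  Y <- combat_apply(d$X, m, d$batch)
  gap <- abs(colMeans(Y[d$batch == "A", ]) - colMeans(Y[d$batch == "B", ])) /
    apply(Y, 2, sd)
  expect_lt(max(gap), 0.3)       # raw gap was 5 SD
  expect_lt(median(gap), 0.1)
})

test_that("preconditions are enforced with named errors", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(combat_fit(X, c(rep("A", 9), "B")), "singleton batch: B")
  expect_error(combat_fit(X, rep("A", 10)), "at least 2 batches")
  Xz <- X; Xz[, 2] <- 7
  expect_error(combat_fit(Xz, rep(c("A", "B"), 5)), "zero-variance feature: b")
  m <- combat_fit(X, rep(c("A", "B"), 5))
  expect_error(combat_apply(X, m, rep("C", 10)), "unseen batch")
  expect_error(combat_apply(X[, 1, drop = FALSE], m, rep("A", 10)),
               "missing feature")
})

test_that("the identity model returns its input", {
  d <- make_batch_table(30, seed = 3)
  m0 <- combat_identity(d$X, unique(d$batch))
  Y <- combat_apply(d$X, m0, d$batch)
  expect_equal(as.matrix(Y), as.matrix(d$X), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("the adjustment formula matches a hand-computed value", {
  # one feature, alpha = 2, sigma = 3; batch A with gamma* = 1, delta* = 2
  m <- structure(list(alpha = c(f = 2), sigma = c(f = 3),
                      gamma_star = matrix(1, 1, 1, dimnames = list("A", "f")),
                      delta_star = matrix(2, 1, 1, dimnames = list("A", "f")),
                      batches = "A", features = "f"),
                 class = "combat_model")
  y <- 8  # z = (8-2)/3 = 2 -> (2-1)/2 = 0.5 -> 3*0.5 + 2 = 3.5
  out <- combat_apply(data.frame(f = y), m, "A")
  expect_equal(out$f, 3.5)
})

test_that("mixed-sign location and scale effects are jointly recovered", {
  # sign-varying gamma keeps the location prior variance honest, which is
  # the regime empirical-Bayes adjustment is designed for
  pass <- 0; total <- 0
  for (s in 1:4) {
    set.seed(10 + s)
    p <- 19; n <- 100
    gam <- sample(c(-1, 1), p, TRUE)
    del <- sample(c(0.5, 2), p, TRUE)
    A <- matrix(rnorm(n * p), n, p)
    B <- sweep(sweep(matrix(rnorm(n * p), n, p), 2, del, "*"), 2, gam, "+")
    X <- rbind(A, B); colnames(X) <- paste0("f", 1:p)
    batch <- rep(c("A", "B"), each = n)
    Y <- combat_apply(X, combat_fit(X, batch), batch)
    gap <- abs(colMeans(Y[1:n, ]) - colMeans(Y[(n + 1):(2 * n), ])) /
      apply(Y, 2, sd)
    vr <- apply(Y[1:n, ], 2, var) / apply(Y[(n + 1):(2 * n), ], 2, var)
    pass <- pass + sum(gap < 0.1 & vr > 0.8 & vr < 1.25)
    total <- total + p
  }
  expect_gte(pass / total, 0.9)
})

test_that("harmonization is monotone within batch (rank preserving)", {
  d <- make_batch_table(40, gamma = 2, delta = 0.5, seed = 5)
  m <- combat_fit(d$X, d$batch)
  Y <- combat_apply(d$X, m, d$batch)
  for (b in c("A", "B")) for (j in 1:3)
    expect_equal(rank(Y[d$batch == b, j]), rank(d$X[d$batch == b, j]))
})

test_that("harmonizing label-independent batches barely moves per-feature AUCs", {
  set.seed(6)
  n <- 400; p <- 10
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- matrix(rnorm(n * p), n, p) + outer(as.numeric(y), runif(p, 0, 1))
  colnames(X) <- paste0("f", seq_len(p))
  batch <- sample(c("A", "B", "C", "D"), n, replace = TRUE)  # label-independent
  m <- combat_fit(X, batch)
  Y <- as.matrix(combat_apply(X, m, batch))
  for (j in seq_len(p))
    expect_lt(abs(auc_mw(Y[, j], y) - auc_mw(X[, j], y)), 0.03)
})

test_that("fit agrees with the reference empirical-Bayes implementation", {
  skip_if_not_installed("sva")
  d <- make_batch_table(40, p = 5, gamma = 1.5, delta = 1.7, seed = 9)
  m <- combat_fit(d$X, d$batch)
  ours <- combat_apply(d$X, m, d$batch)
  ref <- t(sva::ComBat(dat = t(as.matrix(d$X)), batch = d$batch,
                       par.prior = TRUE, prior.plots = FALSE))
  expect_equal(as.matrix(ours), ref, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("scanner batch effects in phantom features exist and are removed", {
  f <- batch_only_features()
  X <- f[, feature_columns()]
  pvals_pre <- vapply(glcm_feature_names, function(cn)
    stats::kruskal.test(f[[cn]], factor(f$scanner_id))$p.value, 0)
  expect_lt(min(pvals_pre), 0.01)  # batch effect present before harmonization
  m <- combat_fit(X, f$scanner_id)
  Y <- combat_apply(X, m, f$scanner_id)
  worst <- names(which.min(pvals_pre))
  gaps <- abs(tapply(Y[[worst]], f$scanner_id, mean) - mean(Y[[worst]]))
  expect_true(all(gaps < 0.5 * sd(Y[[worst]])))
})
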