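test_that("SUV metrics: constant field, two-voxel mean, sphere-oracle peak", {
  dm <- c(9, 9, 9)
  v <- vol_from_array(array(3, dim = dm))
  m <- full_mask(dm)
  expect_equal(unname(suv_metrics(v, m)), c(3, 3, 3))

  a <- array(0, dim = dm); a[1, 1, 1] <- 2; a[2, 1, 1] <- 4
  msk <- array(0L, dim = dm); msk[1:2, 1, 1] <- 1L
  sm <- suv_metrics(vol_from_array(a), binary_mask(msk, c(5.5, 5.5, 3.3)))
  expect_equal(unname(sm["suv_mean"]), 3)
  expect_equal(unname(sm["suv_max"]), 4)

  # single hot voxel in uniform background: peak equals explicit enumeration
  b <- array(1, dim = dm); b[5, 5, 5] <- 5
  mt <- array(0L, dim = dm); mt[5, 5, 5] <- 1L
  sm2 <- suv_metrics(vol_from_array(b), binary_mask(mt, c(5.5, 5.5, 3.3)))
  expect_equal(unname(sm2["suv_peak"]),
               oracle_suv_peak(b, mt, c(5.5, 5.5, 3.3)))

  # and on random data with a random MTV
  set.seed(12)
  r <- array(runif(prod(dm), 0, 6), dim = dm)
  mr <- array(rbinom(prod(dm), 1, 0.4), dim = dm)
  mr[4, 4, 4] <- 1L
  sm3 <- suv_metrics(vol_from_array(r), binary_mask(mr, c(5.5, 5.5, 3.3)))
  expect_equal(unname(sm3["suv_peak"]),
               oracle_suv_peak(r, mr, c(5.5, 5.5, 3.3)))
  expect_lte(sm3["suv_mean"], sm3["suv_max"])
  expect_lte(sm3["suv_peak"], sm3["suv_max"])
})

test_that("discretization follows the uniform-partition and floor rules", {
  dm <- c(4, 1, 1)
  v <- vol_from_array(array(c(0, 1, 2, 3), dim = dm))
  d <- discretize(v, full_mask(dm), "fixed-bin-number", 4)
  expect_equal(as.vector(d$levels), c(1, 2, 3, 4))

  v2 <- vol_from_array(array(c(1.0, 1.2, 2.6, 2.6), dim = dm))
  d2 <- discretize(v2, full_mask(dm), "fixed-bin-width", 1.0)
  expect_equal(as.vector(d2$levels)[1:3], c(1, 1, 2))

  # constant region: a single level, not an error
  d3 <- discretize(vol_from_array(array(2, dim = dm)), full_mask(dm),
                   "fixed-bin-number", 25)
  expect_true(all(d3$levels == 1L))

  # property: levels within [1, Ng] and monotone in value
  set.seed(5)
  dm4 <- c(6, 6, 4)
  x <- array(runif(prod(dm4), 0, 10), dim = dm4)
  d4 <- discretize(vol_from_array(x), full_mask(dm4), "fixed-bin-number", 25)
  lv <- as.vector(d4$levels)
  expect_true(all(lv >= 1 & lv <= 25))
  o <- order(as.vector(x))
  expect_true(all(diff(lv[o]) >= 0))
})

test_that("GLCM construction matches exhaustive pair enumeration", {
  # constant 2x2x2 block: single entry
  dm <- c(2, 2, 2)
  d <- discretize(vol_from_array(array(1, dim = dm)), full_mask(dm),
                  "fixed-bin-number", 4)
  P <- build_glcm(d, c(1, 0, 0))
  expect_equal(unclass(P)[1, 1], 1)

  # alternating strip
  dm2 <- c(4, 1, 1)
  v <- vol_from_array(array(c(0, 1, 0, 1), dim = dm2))
  d2 <- discretize(v, full_mask(dm2), "fixed-bin-number", 2)
  P2 <- unclass(build_glcm(d2, c(1, 0, 0)))
  expect_equal(P2[1, 2], 0.5)
  expect_equal(P2[2, 1], 0.5)
  expect_equal(P2[1, 1] + P2[2, 2], 0)

  # random labelings vs the brute-force oracle, all 13 directions
  offs <- glcm_offsets()
  for (s in 1:5) {
    set.seed(s)
    dm3 <- c(4, 4, 3)
    lev <- array(sample(0:5, prod(dm3), replace = TRUE), dim = dm3)
    dd <- structure(list(levels = lev, n_levels = 5L,
                         mode = "fixed-bin-number", bin_param = 5,
                         spacing_mm = c(5.5, 5.5, 3.3)),
                    class = "discretized_volume")
    for (r in seq_len(nrow(offs))) {
      po <- oracle_glcm(lev, offs[r, ], 5L)
      if (is.null(po)) {
        expect_error(build_glcm(dd, offs[r, ]), "empty co-occurrence")
      } else {
        P <- unclass(build_glcm(dd, offs[r, ]))
        expect_equal(P, po, tolerance = 1e-14)
        expect_equal(sum(P), 1, tolerance = 1e-12)
        expect_equal(P, t(P), tolerance = 0)
      }
    }
  }
  expect_error(build_glcm(d, c(2, 0, 0)), "Chebyshev")
  expect_error(build_glcm(d, c(0, 0, 0)), "Chebyshev")
})

test_that("Haralick features: degenerate limits and hand-computed two-level case", {
  P1 <- matrix(1, 1, 1)
  f1 <- haralick_features(P1)
  expect_equal(unname(f1["angular_second_moment"]), 1)
  expect_equal(unname(f1["entropy"]), 0)
  expect_equal(unname(f1["contrast"]), 0)
  expect_equal(unname(f1["homogeneity"]), 1)
  expect_equal(unname(f1["inverse_difference_moment"]), 1)
  expect_equal(unname(f1["maximum_probability"]), 1)
  expect_equal(unname(f1["cluster_shade"]), 0)
  expect_equal(unname(f1["imc2"]), 0)
  expect_equal(unname(f1["correlation"]), 1)  # single level is predictable

  P2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  f2 <- haralick_features(P2)
  expect_equal(unname(f2["contrast"]), 1)
  expect_equal(unname(f2["angular_second_moment"]), 0.5)
  expect_equal(unname(f2["entropy"]), log(2))
  expect_equal(unname(f2["sum_average"]), 3)
  expect_equal(unname(f2["maximum_probability"]), 0.5)
})

test_that("all 16 features agree with the naive double-loop oracle", {
  for (s in 1:10) {
    set.seed(100 + s)
    P <- random_symmetric_stochastic(6)
    expect_equal(haralick_features(P), oracle_haralick(P)[glcm_feature_names],
                 tolerance = 1e-10)
  }
})

test_that("entropy-family features can use base-2 logarithms", {
  set.seed(1)
  P <- random_symmetric_stochastic(4)
  fn <- haralick_features(P)
  f2 <- haralick_features(P, base = 2)
  expect_equal(unname(f2["entropy"]), unname(fn["entropy"]) / log(2))
  expect_equal(unname(f2["contrast"]), unname(fn["contrast"]))  # unaffected
})

test_that("relabeling that preserves the co-occurrence multiset preserves entropy/ASM/max-prob", {
  set.seed(8)
  dm <- c(5, 5, 4)
  lev <- array(sample(1:2, prod(dm), replace = TRUE), dim = dm)
  dd <- structure(list(levels = lev, n_levels = 2L, mode = "fixed-bin-number",
                       bin_param = 2, spacing_mm = c(5.5, 5.5, 3.3)),
                  class = "discretized_volume")
  swapped <- dd
  swapped$levels <- array(3L - lev, dim = dm)  # 1 <-> 2
  fa <- haralick_features(build_glcm(dd, c(1, 0, 0)))
  fb <- haralick_features(build_glcm(swapped, c(1, 0, 0)))
  for (k in c("entropy", "angular_second_moment", "maximum_probability"))
    expect_equal(fa[[k]], fb[[k]], tolerance = 1e-14)
})

test_that("feature record has the full 19-feature schema and guards tiny MTVs", {
  spec <- phantom_spec(grid_shape = c(24, 24, 12))
  v <- generate_patient_volume(spec, TRUE, 30, default_scanner_effects()[[1]], 3)
  m <- generate_pelvis_mask(spec)
  mtv <- segment_mtv(v, m)
  rec <- extract_features(v, mtv$mtv_mask, patient_id = "P1", scanner_id = "S1")
  expect_equal(nrow(rec), 1L)
  expect_true(all(feature_columns() %in% names(rec)))
  expect_equal(sum(vapply(rec[feature_columns()], is.numeric, TRUE)), 19L)

  one <- array(0L, dim = dim(v$values)); one[12, 12, 6] <- 1L
  expect_error(extract_features(v, binary_mask(one, v$spacing_mm)),
               "MTV too small")
})

test_that("direction-averaged features equal the mean of per-direction features", {
  set.seed(21)
  dm <- c(8, 8, 6)
  stripes <- array(rep(c(0, 3), length.out = dm[1]), dim = dm)  # x stripes
  a <- stripes + array(runif(prod(dm), 0, 0.5), dim = dm)
  v <- vol_from_array(a); m <- full_mask(dm)
  rec <- extract_features(v, m)
  d <- discretize(v, m, "fixed-bin-number", 25)
  offs <- glcm_offsets()
  per_dir <- vapply(seq_len(nrow(offs)), function(r)
    haralick_features(build_glcm(d, offs[r, ])), numeric(16))
  expect_equal(unlist(rec[glcm_feature_names]),
               rowMeans(per_dir)[glcm_feature_names], tolerance = 1e-12,
               ignore_attr = TRUE)
  # anisotropy is visible per direction
  expect_gt(max(per_dir["contrast", ]) / min(per_dir["contrast", ]), 1.5)
})

test_that("90-degree axial rotation leaves the 13-direction average unchanged", {
  set.seed(33)
  dm <- c(10, 10, 6)
  a <- array(runif(prod(dm), 0, 4), dim = dm)
  sp <- c(5.5, 5.5, 3.3)  # in-plane isotropic, so the rotation is exact
  v1 <- suv_volume(a, sp)
  rot <- aperm(a, c(2, 1, 3))[dm[2]:1, , , drop = FALSE]  # 90 deg about z
  v2 <- suv_volume(rot, sp)
  f1 <- extract_features(v1, full_mask(dm, sp))
  f2 <- extract_features(v2, binary_mask(array(1L, dim = dim(rot)), sp))
  expect_equal(unlist(f1[glcm_feature_names]), unlist(f2[glcm_feature_names]),
               tolerance = 1e-9)
})

test_that("entropy rises and ASM falls when field amplitude doubles (fixed bin width)", {
  spec_lo <- phantom_spec(grid_shape = c(24, 24, 12), texture_sd = c(0.15, 0.15),
                          noise_sd = 0)
  spec_hi <- phantom_spec(grid_shape = c(24, 24, 12), texture_sd = c(0.3, 0.3),
                          noise_sd = 0)
  m <- generate_pelvis_mask(spec_lo)
  ent <- matrix(0, 50, 2); asm <- matrix(0, 50, 2)
  for (s in 1:50) {
    for (ci in 1:2) {
      spec <- list(spec_lo, spec_hi)[[ci]]
      v <- generate_patient_volume(spec, FALSE, 0, identity_effect(), seed = s)
      rec <- extract_features(v, m, mode = "fixed-bin-width", bin_param = 0.05)
      ent[s, ci] <- rec$entropy; asm[s, ci] <- rec$angular_second_moment
    }
  }
  expect_gt(mean(ent[, 2]), mean(ent[, 1]))
  expect_lt(mean(asm[, 2]), mean(asm[, 1]))
})
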