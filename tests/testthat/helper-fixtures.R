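# Programmatic fixtures. Expensive shared objects (phantom cohorts with
# feature extraction) are built lazily once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a small volume + full-grid search mask from an explicit array
vol_from_array <- function(a, spacing = c(5.5, 5.5, 3.3)) {
  suv_volume(a, spacing)
}
full_mask <- function(dm, spacing = c(5.5, 5.5, 3.3)) {
  binary_mask(array(1L, dim = dm), spacing)
}

# phantom spec with the scanner chain switched off (identity acquisition)
identity_effect <- function() {
  scanner_effect("ID", psf_fwhm_mm = 0, gain = 1, offset = 0, noise_scale = 0)
}

# texture-only class contrast: equal marrow mean SUV and field amplitude,
# no lesions; the classes differ only in texture architecture (coarse
# diffuse field vs REL-weighted fine infiltration field)
texture_only_spec <- function() {
  phantom_spec(suv_shift_per_rel = 0, lesion_rate_per_rel = 0,
               texture_sd_per_rel = 0,
               texture_corr_length_mm = c(30, 8),
               texture_sd = c(0.2, 0.2),
               texture_mix_rel_saturation = 30,
               marrow_suv_jitter_sd = 0.15)
}

# n = 200 texture-contrast cohort with extracted features (shared by the
# end-to-end discrimination and permutation-null checks)
texture_cohort_features <- function() {
  cached("texture_cohort", function() {
    cs <- cohort_spec(n_patients = 200L, seed = 424243L)
    cd <- generate_cohort(cs, texture_only_spec())
    feats <- extract_cohort_features(cd)
    cb <- combat_fit(feats[, feature_columns()], feats$scanner_id)
    harmonized <- feats
    harmonized[, feature_columns()] <-
      combat_apply(feats[, feature_columns()], cb, feats$scanner_id)
    list(cohort = cd$cohort, features = feats, harmonized = harmonized)
  })
}

# n = 48 single-class (uninvolved) cohort: any feature difference across
# scanners is pure batch effect
batch_only_features <- function() {
  cached("batch_only", function() {
    cs <- cohort_spec(n_patients = 48L, involvement_prevalence = 0, seed = 777L)
    cd <- generate_cohort(cs, phantom_spec())
    extract_cohort_features(cd)
  })
}

# a cohort table realizing the published per-endpoint counts: 97 patients,
# 67 involved, 46 with REL > 5, 41 with REL > 10, 43 with ABS > 5,
# 35 with ABS > 10, 33 of the involved with Ki-67 >= 30
printed_counts_cohort <- function() {
  n <- 97L
  involved <- rep(c(TRUE, FALSE), c(67L, 30L))
  rel <- numeric(n)
  rel[1:41] <- 60          # REL > 10 (and > 5)
  rel[42:46] <- 8          # 5 < REL <= 10
  rel[47:67] <- 3          # 0 < REL <= 5
  cellularity <- rep(50, n)
  cellularity[1:35] <- 80  # ABS = 48 > 10   (35 patients)
  cellularity[36:41] <- 15 # ABS = 9  in (5, 10]  -> ABS > 5 count 35 + 6 = 41
  cellularity[42:43] <- 90 # ABS = 7.2 > 5        -> ABS > 5 count 43
  cellularity[44:46] <- 50 # ABS = 4 <= 5
  ki67 <- rep(10, n)
  ki67[1:33] <- 45         # involved patients with high Ki-67
  data.frame(patient_id = sprintf("P%03d", 1:n),
             scanner_id = rep(c("S1", "S2", "S3", "S4"), length.out = n),
             involved = involved, rel = rel, cellularity = cellularity,
             abs = cellularity * rel / 100,
             wbc = rep(10, n), ldh = rep(230, n), ki67 = ki67,
             stringsAsFactors = FALSE)
}

# p observed features built from k latent factors plus independent noise;
# orthogonal loading columns so every factor carries comparable signal
factor_model_features <- function(n, p = 19, k = 5, noise = 0.55, seed = 1) {
  set.seed(seed)
  F <- matrix(rnorm(n * k), n, k)
  L <- qr.Q(qr(matrix(rnorm(p * k), p, k))) * sqrt(p * 0.6 / k)
  X <- F %*% t(L) + noise * matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", seq_len(p))
  as.data.frame(X)
}

# synthetic 19-column feature table + matching cohort rows, for classifier
# schema tests that do not need imaging
synthetic_feature_table <- function(n, seed = 1L) {
  set.seed(seed)
  f <- as.data.frame(matrix(rnorm(n * 19), n, 19))
  names(f) <- feature_columns()
  f$patient_id <- sprintf("P%03d", seq_len(n))
  f$scanner_id <- sample(c("S1", "S2", "S3", "S4"), n, replace = TRUE)
  f
}
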