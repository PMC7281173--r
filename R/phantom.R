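# Synthetic pelvic PET phantom and cohort generator.
#
# The uptake model is a stationary Gaussian random field (periodic spectral
# synthesis) over a marrow compartment, with class-conditional correlation
# length and amplitude, a diffuse mean shift and Poisson-count focal
# spherical lesions in involved patients, and per-scanner blur / gain /
# offset / noise applied last. It emulates the class structure, covariate
# distributions and batch effects the downstream analysis assumes; it makes
# no claim of anatomical or reconstruction-physics realism.

#' Phantom specification
#'
#' Parameters of the synthetic pelvic PET volume generator. Class-conditional
#' parameters (`texture_corr_length_mm`, `texture_sd`) are length-2 vectors
#' ordered (uninvolved, involved).
#'
#' @param grid_shape voxels per axis, default `c(64, 64, 32)`.
#' @param voxel_spacing_mm voxel size in mm, default `c(5.5, 5.5, 3.3)`.
#' @param background_suv mean soft-tissue SUV outside the marrow.
#' @param marrow_suv_mean baseline marrow SUV (uninvolved).
#' @param marrow_suv_jitter_sd SD of the per-patient random offset of the
#'   marrow baseline (inter-patient metabolic variability, independent of
#'   class). Intensity summaries see this as noise; min-max-discretized
#'   texture features are invariant to it.
#' @param suv_shift_per_rel additive marrow SUV per percentage point of REL
#'   in involved patients (diffuse-infiltration contrast; set 0 for
#'   texture-only class contrast).
#' @param texture_corr_length_mm Gaussian-random-field correlation length per
#'   class, mm.
#' @param texture_sd random-field SD per class, SUV units.
#' @param texture_sd_per_rel relative increase of the involved-class field SD
#'   per percentage point of REL (extra heterogeneity with infiltration).
#' @param texture_mix_rel_saturation REL (\%) at which the involved-class
#'   texture fully replaces the uninvolved one. Involved marrow texture is a
#'   variance-preserving mixture of the two class random fields with weight
#'   `min(1, rel / saturation)`, so minimal infiltration looks like normal
#'   marrow and texture changes grow monotonically with REL.
#' @param lesion_rate_per_rel expected number of focal lesions per percentage
#'   point of REL.
#' @param lesion_radius_mm radius of focal spherical lesions.
#' @param lesion_suv_boost additive SUV inside lesions.
#' @param noise_sd additive acquisition noise SD (before scanner
#'   `noise_scale`).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 32L),
                         voxel_spacing_mm = c(5.5, 5.5, 3.3),
                         background_suv = 0.4,
                         marrow_suv_mean = 1.2,
                         marrow_suv_jitter_sd = 0.1,
                         suv_shift_per_rel = 0.008,
                         texture_corr_length_mm = c(18, 10),
                         texture_sd = c(0.15, 0.25),
                         texture_sd_per_rel = 0.01,
                         texture_mix_rel_saturation = 40,
                         lesion_rate_per_rel = 0.05,
                         lesion_radius_mm = 11,
                         lesion_suv_boost = 1.5,
                         noise_sd = 0.05) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0),
            length(voxel_spacing_mm) == 3L, all(voxel_spacing_mm > 0),
            background_suv >= 0, marrow_suv_mean >= 0,
            marrow_suv_jitter_sd >= 0, suv_shift_per_rel >= 0,
            length(texture_corr_length_mm) == 2L,
            all(texture_corr_length_mm >= 0),
            length(texture_sd) == 2L, all(texture_sd >= 0),
            texture_sd_per_rel >= 0, texture_mix_rel_saturation > 0,
            lesion_rate_per_rel >= 0,
            lesion_radius_mm > 0, lesion_suv_boost >= 0, noise_sd >= 0)
  structure(list(grid_shape = grid_shape,
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 background_suv = background_suv,
                 marrow_suv_mean = marrow_suv_mean,
                 marrow_suv_jitter_sd = marrow_suv_jitter_sd,
                 suv_shift_per_rel = suv_shift_per_rel,
                 texture_corr_length_mm = as.numeric(texture_corr_length_mm),
                 texture_sd = as.numeric(texture_sd),
                 texture_sd_per_rel = texture_sd_per_rel,
                 texture_mix_rel_saturation = texture_mix_rel_saturation,
                 lesion_rate_per_rel = lesion_rate_per_rel,
                 lesion_radius_mm = lesion_radius_mm,
                 lesion_suv_boost = lesion_suv_boost,
                 noise_sd = noise_sd),
            class = "phantom_spec")
}

#' Scanner effect
#'
#' Per-scanner acquisition characteristics applied to a phantom volume:
#' isotropic Gaussian point-spread blur, multiplicative SUV gain, additive
#' SUV offset, and a multiplier on the acquisition noise SD.
#'
#' @param scanner_id character scanner label.
#' @param psf_fwhm_mm blur FWHM in mm, `>= 0`.
#' @param gain multiplicative SUV factor, `> 0`.
#' @param offset additive SUV shift.
#' @param noise_scale multiplier on the phantom `noise_sd`.
#' @return an object of class `scanner_effect`.
#' @export
scanner_effect <- function(scanner_id, psf_fwhm_mm = 5, gain = 1,
                           offset = 0, noise_scale = 1) {
  stopifnot(psf_fwhm_mm >= 0, gain > 0, noise_scale >= 0)
  structure(list(scanner_id = as.character(scanner_id),
                 psf_fwhm_mm = psf_fwhm_mm, gain = gain,
                 offset = offset, noise_scale = noise_scale),
            class = "scanner_effect")
}

#' Default four-scanner batch
#'
#' Four mildly different scanners (blur 4-8 mm FWHM, gain 0.9-1.1), strong
#' enough that texture features show a scanner main effect before
#' harmonization, mild enough that class signal survives.
#'
#' @return a named list of four [scanner_effect()] objects.
#' @export
default_scanner_effects <- function() {
  list(S1 = scanner_effect("S1", psf_fwhm_mm = 4.0, gain = 0.95, offset = 0.00, noise_scale = 1.0),
       S2 = scanner_effect("S2", psf_fwhm_mm = 5.0, gain = 1.05, offset = 0.05, noise_scale = 1.2),
       S3 = scanner_effect("S3", psf_fwhm_mm = 6.5, gain = 0.90, offset = -0.05, noise_scale = 0.9),
       S4 = scanner_effect("S4", psf_fwhm_mm = 8.0, gain = 1.10, offset = 0.02, noise_scale = 1.1))
}

#' Cohort specification
#'
#' Distributional parameters of the synthetic cohort. Continuous covariates
#' are truncated normals whose underlying parameters are moment-calibrated so
#' the truncated variable matches the requested (mean, sd). Class-conditional
#' entries are `c(location, scale)`; `rel_distribution` applies to involved
#' patients only (uninvolved REL is identically 0).
#'
#' @param n_patients cohort size, `>= 4`.
#' @param involvement_prevalence probability of biopsy-positive marrow.
#' @param rel_distribution `c(mean, sd)` of REL (%) among involved, truncated
#'   to \[0,100\].
#' @param rel_model `"truncnorm"` (default) or `"beta"` (moment-matched beta
#'   on \[0,100\]).
#' @param cellularity_distribution `c(mean, sd)` of marrow cellularity (%).
#' @param wbc_distribution 2x2 matrix, rows (uninvolved, involved), columns
#'   (mean, sd), of white-blood-cell count (1e9/L); drawn from a
#'   moment-matched lognormal (lab values are right-skewed and may have
#'   cv > 1, which a 0-truncated normal cannot represent).
#' @param ldh_distribution same layout for lactate dehydrogenase (U/L),
#'   also lognormal.
#' @param ki67_distribution same layout for the Ki-67 index (%), truncated to
#'   \[0,100\].
#' @param seed master integer seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 97L,
                        involvement_prevalence = 0.691,
                        rel_distribution = c(33.0, 29.1),
                        rel_model = c("truncnorm", "beta"),
                        cellularity_distribution = c(68, 15),
                        wbc_distribution = rbind(uninvolved = c(7.2, 7.0),
                                                 involved = c(12.0, 13.0)),
                        ldh_distribution = rbind(uninvolved = c(204, 70),
                                                 involved = c(245, 90)),
                        ki67_distribution = rbind(uninvolved = c(22.1, 18.0),
                                                  involved = c(31.95, 20.0)),
                        seed = 1L) {
  rel_model <- match.arg(rel_model)
  stopifnot(n_patients >= 4,
            involvement_prevalence >= 0, involvement_prevalence <= 1,
            length(rel_distribution) == 2L, rel_distribution[2] > 0,
            all(dim(wbc_distribution) == c(2, 2)),
            all(dim(ldh_distribution) == c(2, 2)),
            all(dim(ki67_distribution) == c(2, 2)))
  structure(list(n_patients = as.integer(n_patients),
                 involvement_prevalence = involvement_prevalence,
                 rel_distribution = as.numeric(rel_distribution),
                 rel_model = rel_model,
                 cellularity_distribution = as.numeric(cellularity_distribution),
                 wbc_distribution = wbc_distribution,
                 ldh_distribution = ldh_distribution,
                 ki67_distribution = ki67_distribution,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate the pelvic-bone search mask
#'
#' A deterministic stand-in for the bony-pelvis search region: two mirrored
#' posterior half-annuli (iliac-wing-like slabs) spanning the middle axial
#' band of the grid.
#'
#' @param spec a [phantom_spec()].
#' @return a [binary_mask()].
#' @export
generate_pelvis_mask <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  if (any(d < 8L)) stop("degenerate grid: every axis needs >= 8 voxels")
  sp <- spec$voxel_spacing_mm
  # world coordinates of voxel centers
  x <- (seq_len(d[1]) - 0.5) * sp[1]
  y <- (seq_len(d[2]) - 0.5) * sp[2]
  z <- (seq_len(d[3]) - 0.5) * sp[3]
  ex <- d[1] * sp[1]; ey <- d[2] * sp[2]; ez <- d[3] * sp[3]
  r_out <- 0.18 * min(ex, ey)
  r_in <- 0.55 * r_out
  centers_x <- c(0.30, 0.70) * ex
  cy <- 0.5 * ey
  zlo <- 0.30 * ez; zhi <- 0.70 * ez
  m <- array(0L, dim = d)
  zin <- which(z >= zlo & z <= zhi)
  for (cx in centers_x) {
    r2 <- outer((x - cx)^2, (y - cy)^2, "+")
    ring <- r2 >= r_in^2 & r2 <= r_out^2
    ring <- ring & outer(rep(TRUE, d[1]), y >= cy)  # posterior arc
    m[, , zin] <- m[, , zin] | as.integer(ring)
  }
  if (!any(m == 1L)) stop("degenerate grid: empty pelvis mask")
  binary_mask(m, sp)
}

# expected focal-lesion count: linear in REL
lesion_rate <- function(spec, rel_percent) spec$lesion_rate_per_rel * rel_percent

# place n spherical lesions at marrow voxels (uses current RNG stream)
add_lesions <- function(vol_arr, marrow_idx, d, sp, n, radius_mm, boost) {
  if (n == 0L) return(vol_arr)
  centers <- sample(marrow_idx, n, replace = TRUE)
  ci <- arrayInd(centers, d)
  x <- (seq_len(d[1]) - 0.5) * sp[1]
  y <- (seq_len(d[2]) - 0.5) * sp[2]
  z <- (seq_len(d[3]) - 0.5) * sp[3]
  inmask <- logical(prod(d)); inmask[marrow_idx] <- TRUE
  dim(inmask) <- d
  for (l in seq_len(n)) {
    cx <- x[ci[l, 1]]; cyy <- y[ci[l, 2]]; cz <- z[ci[l, 3]]
    ix <- which(abs(x - cx) <= radius_mm)
    iy <- which(abs(y - cyy) <= radius_mm)
    iz <- which(abs(z - cz) <= radius_mm)
    for (k in iz) {
      dz2 <- (z[k] - cz)^2
      sub <- outer((x[ix] - cx)^2, (y[iy] - cyy)^2, "+") + dz2 <= radius_mm^2
      sub <- sub & inmask[ix, iy, k]
      vol_arr[ix, iy, k][sub] <- vol_arr[ix, iy, k][sub] + boost
    }
  }
  vol_arr
}

#' Generate one synthetic patient volume
#'
#' Marrow uptake is `marrow_suv_mean` plus a Gaussian random field; involved
#' patients additionally receive a diffuse mean shift and extra field
#' amplitude, both monotone in REL, plus Poisson-count focal spherical
#' lesions with expectation `lesion_rate_per_rel * rel_percent`. The scanner
#' blur, gain, offset and noise are applied last and the result is clamped at
#' zero.
#'
#' @param spec a [phantom_spec()].
#' @param involved logical biopsy status.
#' @param rel_percent REL in \[0,100\]; must be 0 when `involved` is `FALSE`.
#' @param effect a [scanner_effect()].
#' @param seed integer seed; the volume is reproducible given
#'   `(spec, involved, rel_percent, effect, seed)`.
#' @return a [suv_volume()].
#' @export
generate_patient_volume <- function(spec, involved, rel_percent, effect, seed) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(effect, "scanner_effect"))
  if (rel_percent < 0 || rel_percent > 100)
    stop("rel_percent outside [0,100]")
  if (!involved && rel_percent != 0)
    stop("rel_percent must be 0 for uninvolved patients")
  d <- spec$grid_shape; sp <- spec$voxel_spacing_mm
  mask <- generate_pelvis_mask(spec)
  midx <- which(mask$values == 1L)
  cls <- if (involved) 2L else 1L
  with_seed(seed, {
    v <- array(spec$background_suv, dim = d)
    mean_suv <- spec$marrow_suv_mean +
      (if (involved) spec$suv_shift_per_rel * rel_percent else 0) +
      (if (spec$marrow_suv_jitter_sd > 0)
        stats::rnorm(1, 0, spec$marrow_suv_jitter_sd) else 0)
    mean_suv <- max(mean_suv, 0)
    sd_suv <- spec$texture_sd[cls] *
      (1 + if (involved) spec$texture_sd_per_rel * rel_percent else 0)
    v[midx] <- mean_suv
    if (sd_suv > 0) {
      # involved texture: variance-preserving mix of the normal-marrow field
      # and the infiltration field, weighted by REL (saturating)
      w <- if (involved)
        min(1, rel_percent / spec$texture_mix_rel_saturation) else 0
      f <- sqrt(1 - w) * grf3d(d, sp, spec$texture_corr_length_mm[1])
      if (w > 0)
        f <- f + sqrt(w) * grf3d(d, sp, spec$texture_corr_length_mm[2])
      v[midx] <- v[midx] + sd_suv * f[midx]
    }
    if (involved && spec$lesion_rate_per_rel > 0) {
      nles <- stats::rpois(1, lesion_rate(spec, rel_percent))
      v <- add_lesions(v, midx, d, sp, nles,
                       spec$lesion_radius_mm, spec$lesion_suv_boost)
    }
    if (effect$psf_fwhm_mm > 0) {
      sigma_vox <- effect$psf_fwhm_mm / 2.35482 / sp
      v <- gauss_smooth3d(v, sigma_vox)
    }
    v <- v * effect$gain + effect$offset
    ns <- spec$noise_sd * effect$noise_scale
    if (ns > 0) v <- v + array(stats::rnorm(prod(d), 0, ns), dim = d)
    v[v < 0] <- 0
    suv_volume(v, sp)
  })
}

# draw one class-conditional covariate column; lab values (dist =
# "lognormal") are right-skewed with cv possibly > 1, which a 0-truncated
# normal cannot represent, so they use a moment-matched lognormal instead
draw_cc <- function(n, involved, distmat, lo, hi, dist = "truncnorm") {
  out <- numeric(n)
  for (cls in 1:2) {
    idx <- which(involved == (cls == 2L))
    if (!length(idx)) next
    if (dist == "lognormal") {
      p <- lognormal_params(distmat[cls, 1], distmat[cls, 2])
      out[idx] <- stats::rlnorm(length(idx), p["meanlog"], p["sdlog"])
    } else {
      p <- truncnorm_calibrate(distmat[cls, 1], distmat[cls, 2], lo, hi)
      out[idx] <- rtruncnorm(length(idx), p["mu"], p["sigma"], lo, hi)
    }
  }
  out
}

#' Generate a synthetic cohort
#'
#' Draws per-patient involvement, REL, cellularity, WBC, LDH and Ki-67 from
#' the cohort specification, assigns the four scanners uniformly, and
#' (optionally) synthesizes one PET volume per patient. `abs` is derived as
#' `cellularity * rel / 100`.
#'
#' @param cspec a [cohort_spec()].
#' @param pspec a [phantom_spec()].
#' @param effects list of four [scanner_effect()]s, default
#'   [default_scanner_effects()].
#' @param volumes if `FALSE`, only the cohort table is generated (fast; used
#'   for covariate-level analyses).
#' @param dir if non-`NULL`, volumes/masks are written as NIfTI and the table
#'   as CSV under this directory, with a JSON manifest of all parameters.
#' @return a list with `cohort` (data frame), `volumes` (list of
#'   [suv_volume()] or `NULL`), `mask` (the shared [binary_mask()]), and
#'   `manifest`.
#' @export
generate_cohort <- function(cspec, pspec = phantom_spec(),
                            effects = default_scanner_effects(),
                            volumes = TRUE, dir = NULL) {
  stopifnot(inherits(cspec, "cohort_spec"), inherits(pspec, "phantom_spec"))
  if (length(effects) != 4L)
    stop("exactly 4 scanner effects required")
  n <- cspec$n_patients
  tab <- with_seed(derive_seed(cspec$seed, 0L), {
    involved <- stats::runif(n) < cspec$involvement_prevalence
    rel <- numeric(n)
    ninv <- sum(involved)
    if (ninv > 0) {
      rd <- cspec$rel_distribution
      if (cspec$rel_model == "truncnorm") {
        p <- truncnorm_calibrate(rd[1], rd[2], 0, 100)
        rel[involved] <- rtruncnorm(ninv, p["mu"], p["sigma"], 0, 100)
      } else {
        # beta on [0,100] moment-matched to (mean, sd)
        m <- rd[1] / 100; v <- (rd[2] / 100)^2
        k <- m * (1 - m) / v - 1
        rel[involved] <- 100 * stats::rbeta(ninv, max(m * k, 0.05),
                                            max((1 - m) * k, 0.05))
      }
    }
    cp <- truncnorm_calibrate(cspec$cellularity_distribution[1],
                              cspec$cellularity_distribution[2], 0, 100)
    cellularity <- rtruncnorm(n, cp["mu"], cp["sigma"], 0, 100)
    wbc <- draw_cc(n, involved, cspec$wbc_distribution, 0, Inf, "lognormal")
    ldh <- draw_cc(n, involved, cspec$ldh_distribution, 0, Inf, "lognormal")
    ki67 <- draw_cc(n, involved, cspec$ki67_distribution, 0, 100)
    scanner <- vapply(effects, `[[`, "", "scanner_id")[
      sample.int(4L, n, replace = TRUE)]
    data.frame(patient_id = sprintf("P%04d", seq_len(n)),
               scanner_id = scanner,
               involved = involved,
               rel = rel,
               cellularity = cellularity,
               abs = cellularity * rel / 100,
               wbc = wbc, ldh = ldh, ki67 = ki67,
               stringsAsFactors = FALSE)
  })
  mask <- generate_pelvis_mask(pspec)
  vols <- NULL
  if (volumes) {
    eff_by_id <- stats::setNames(effects, vapply(effects, `[[`, "", "scanner_id"))
    vols <- vector("list", n)
    for (i in seq_len(n)) {
      vols[[i]] <- generate_patient_volume(
        pspec, tab$involved[i], tab$rel[i],
        eff_by_id[[tab$scanner_id[i]]],
        seed = derive_seed(cspec$seed, i))
    }
    names(vols) <- tab$patient_id
  }
  manifest <- list(cohort_spec = unclass(cspec),
                   phantom_spec = unclass(pspec),
                   scanner_effects = lapply(effects, unclass),
                   master_seed = cspec$seed)
  if (!is.null(dir)) {
    ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot write to output directory: ", dir)
    write_cohort(tab, file.path(dir, "cohort.csv"))
    write_mask(mask, file.path(dir, "pelvis_mask.nii.gz"))
    if (volumes)
      for (i in seq_len(n))
        write_volume(vols[[i]], file.path(dir, paste0(tab$patient_id[i], ".nii.gz")))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(cohort = tab, volumes = vols, mask = mask, manifest = manifest)
}
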