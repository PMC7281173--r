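# SUV metrics and 3D GLCM (Haralick) texture features over the MTV.

#' The 16 GLCM feature names
#'
#' Fixed order used throughout the package.
#' @export
glcm_feature_names <- c(
  "entropy", "homogeneity", "contrast", "correlation",
  "angular_second_moment", "difference_entropy", "difference_variance",
  "inverse_difference_moment", "sum_average", "sum_entropy", "sum_variance",
  "cluster_prominence", "cluster_shade", "maximum_probability",
  "imc1", "imc2")

#' SUV metrics over a region
#'
#' SUVmax and SUVmean are the maximum and arithmetic mean over the MTV.
#' SUVpeak is the mean SUV within a 1 cm^3 sphere of voxel centers (radius
#' 6.2 mm in world millimetres, clipped to the image bounds) centered on the
#' hottest MTV voxel.
#'
#' @param volume a [suv_volume()].
#' @param mtv a [binary_mask()] on the same grid, non-empty.
#' @param peak_radius_mm sphere radius for SUVpeak; default 6.2 mm (1 cm^3).
#' @return named numeric vector `c(suv_max, suv_mean, suv_peak)`.
#' @export
suv_metrics <- function(volume, mtv, peak_radius_mm = 6.2) {
  stopifnot(inherits(volume, "suv_volume"), inherits(mtv, "binary_mask"))
  check_same_grid(volume, mtv)
  idx <- which(mtv$values == 1L)
  if (!length(idx)) stop("empty MTV")
  vals <- volume$values[idx]
  imax <- idx[which.max(vals)]
  d <- dim(volume$values); sp <- volume$spacing_mm
  c0 <- arrayInd(imax, d)
  # voxel-center offsets within the sphere, in index space
  noff <- floor(peak_radius_mm / sp)
  off <- expand.grid(i = -noff[1]:noff[1], j = -noff[2]:noff[2],
                     k = -noff[3]:noff[3])
  keep <- (off$i * sp[1])^2 + (off$j * sp[2])^2 + (off$k * sp[3])^2 <=
    peak_radius_mm^2
  off <- off[keep, , drop = FALSE]
  pi_ <- c0[1] + off$i; pj <- c0[2] + off$j; pk <- c0[3] + off$k
  inb <- pi_ >= 1 & pi_ <= d[1] & pj >= 1 & pj <= d[2] & pk >= 1 & pk <= d[3]
  peak_vals <- volume$values[cbind(pi_[inb], pj[inb], pk[inb])]
  c(suv_max = max(vals), suv_mean = mean(vals), suv_peak = mean(peak_vals))
}

#' Discretize SUVs inside the MTV to gray levels
#'
#' Two schemes:
#' \describe{
#'   \item{fixed-bin-number}{`level = min(Ng, floor(Ng * (x - min)/(max - min)) + 1)`;
#'     a constant region maps to level 1 everywhere.}
#'   \item{fixed-bin-width}{`level = floor((x - min)/w) + 1`.}
#' }
#' Out-of-mask voxels carry level 0.
#'
#' @param volume a [suv_volume()].
#' @param mtv a non-empty [binary_mask()].
#' @param mode `"fixed-bin-number"` or `"fixed-bin-width"`.
#' @param bin_param the number of gray levels Ng (default 25) or the bin
#'   width in SUV units, depending on `mode`.
#' @return an object of class `discretized_volume` with `levels` (integer 3D
#'   array), `n_levels`, `mode`, `bin_param`, `spacing_mm`.
#' @export
discretize <- function(volume, mtv, mode = c("fixed-bin-number", "fixed-bin-width"),
                       bin_param = 25) {
  mode <- match.arg(mode)
  stopifnot(inherits(volume, "suv_volume"), inherits(mtv, "binary_mask"),
            bin_param > 0)
  check_same_grid(volume, mtv)
  idx <- which(mtv$values == 1L)
  if (!length(idx)) stop("empty MTV")
  x <- volume$values[idx]
  lev <- array(0L, dim = dim(volume$values))
  if (mode == "fixed-bin-number") {
    ng <- as.integer(bin_param)
    rng <- max(x) - min(x)
    if (rng <= 0) l <- rep(1L, length(x))
    else l <- pmin(ng, as.integer(floor(ng * (x - min(x)) / rng)) + 1L)
  } else {
    l <- as.integer(floor((x - min(x)) / bin_param)) + 1L
    ng <- max(l)
  }
  lev[idx] <- l
  structure(list(levels = lev, n_levels = as.integer(ng), mode = mode,
                 bin_param = bin_param, spacing_mm = volume$spacing_mm),
            class = "discretized_volume")
}

#' The 13 unique 3D co-occurrence directions
#'
#' Half of the 26-voxel Chebyshev-1 neighbourhood: one representative per
#' +/- direction pair.
#'
#' @return a 13 x 3 integer matrix of offsets.
#' @export
glcm_offsets <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  # keep one of each +/- pair: first nonzero component positive
  keep <- apply(g, 1, function(o) {
    nz <- o[o != 0]
    nz[1] > 0
  })
  m <- unname(g[keep, , drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

#' Build the gray-level co-occurrence matrix for one offset
#'
#' Counts are accumulated over every voxel pair `(v, v + offset)` with both
#' endpoints inside the mask (level > 0), in both orderings, then normalized
#' so the entries sum to one. The result is symmetric by construction.
#'
#' @param d a [discretize()]d volume.
#' @param offset integer 3-vector, nonzero, Chebyshev norm 1.
#' @return an Ng x Ng matrix of class `glcm` (joint probabilities).
#' @export
build_glcm <- function(d, offset) {
  stopifnot(inherits(d, "discretized_volume"))
  offset <- as.integer(offset)
  if (length(offset) != 3L || all(offset == 0L) || max(abs(offset)) != 1L)
    stop("offset must be a nonzero 3-vector with Chebyshev norm 1")
  L <- d$levels; dm <- dim(L); ng <- d$n_levels
  rg <- function(n, o) if (o >= 0) seq_len(n - o) else seq(1 - o, n)
  i1 <- rg(dm[1], offset[1]); j1 <- rg(dm[2], offset[2]); k1 <- rg(dm[3], offset[3])
  A <- L[i1, j1, k1, drop = FALSE]
  B <- L[i1 + offset[1], j1 + offset[2], k1 + offset[3], drop = FALSE]
  ok <- A > 0L & B > 0L
  if (!any(ok)) stop("empty co-occurrence for offset (",
                     paste(offset, collapse = ","), ")")
  a <- A[ok]; b <- B[ok]
  cnt <- tabulate(a + (b - 1L) * ng, nbins = ng * ng)
  P <- matrix(cnt, ng, ng)
  P <- P + t(P)
  P <- P / sum(P)
  class(P) <- c("glcm", class(P))
  P
}

#' Haralick features of a GLCM
#'
#' Computes the 16 second-order texture features from a symmetric,
#' normalized co-occurrence matrix: entropy, homogeneity, contrast,
#' correlation, angular second moment, difference entropy, difference
#' variance, inverse difference moment, sum average, sum entropy, sum
#' variance, cluster prominence, cluster shade, maximum probability, and the
#' two informational measures of correlation. The `0 log 0 = 0` convention
#' holds throughout. Degeneracies: a single-gray-level matrix has
#' correlation 1 (perfectly predictable), IMC1 is 0 when `max(HX, HY) = 0`,
#' and IMC2 clamps `1 - exp(.)` at 0 before the square root. Sum variance is
#' centered on sum average (the standard erratum correction).
#'
#' @param g a [build_glcm()] matrix (or any symmetric stochastic matrix).
#' @param base logarithm base for the entropy family; default natural log.
#' @return named numeric vector of the 16 features, in the order of
#'   [glcm_feature_names].
#' @export
haralick_features <- function(g, base = exp(1)) {
  P <- unclass(g)
  ng <- nrow(P)
  stopifnot(ncol(P) == ng, abs(sum(P) - 1) < 1e-8, all(P >= 0))
  i <- seq_len(ng)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(i * px); muy <- sum(i * py)
  sdx <- sqrt(sum((i - mux)^2 * px)); sdy <- sqrt(sum((i - muy)^2 * py))
  I <- matrix(i, ng, ng); J <- t(I)

  # p_{x+y}(k), k = 2..2Ng  and  p_{x-y}(k), k = 0..Ng-1
  pxy_sum <- vapply(2:(2 * ng), function(k) sum(P[I + J == k]), 0)
  pxy_dif <- vapply(0:(ng - 1), function(k) sum(P[abs(I - J) == k]), 0)
  ks <- 2:(2 * ng); kd <- 0:(ng - 1)

  HX <- -sum(xlogx(px, base)); HY <- -sum(xlogx(py, base))
  HXY <- -sum(xlogx(P, base))
  pxpy <- outer(px, py)
  lp <- matrix(0, ng, ng); pos <- pxpy > 0
  lp[pos] <- log(pxpy[pos], base = base)
  HXY1 <- -sum(P * lp)
  HXY2 <- -sum(xlogx(pxpy, base))

  corr <- if (sdx * sdy == 0) 1 else (sum(I * J * P) - mux * muy) / (sdx * sdy)
  sa <- sum(ks * pxy_sum)
  mud <- sum(kd * pxy_dif)
  denom <- max(HX, HY)
  imc1 <- if (denom == 0) 0 else (HXY - HXY1) / denom
  imc2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))

  c(entropy = HXY,
    homogeneity = sum(P / (1 + abs(I - J))),
    contrast = sum((I - J)^2 * P),
    correlation = corr,
    angular_second_moment = sum(P^2),
    difference_entropy = -sum(xlogx(pxy_dif, base)),
    difference_variance = sum((kd - mud)^2 * pxy_dif),
    inverse_difference_moment = sum(P / (1 + (I - J)^2)),
    sum_average = sa,
    sum_entropy = -sum(xlogx(pxy_sum, base)),
    sum_variance = sum((ks - sa)^2 * pxy_sum),
    cluster_prominence = sum((I + J - mux - muy)^4 * P),
    cluster_shade = sum((I + J - mux - muy)^3 * P),
    maximum_probability = max(P),
    imc1 = imc1,
    imc2 = imc2)[glcm_feature_names]
}

#' Extract the full per-patient feature record
#'
#' Combines the three SUV metrics with the 16 GLCM features. Texture is
#' computed in 3D: one co-occurrence matrix per unique distance-1 direction
#' (13 of them), features per direction, then the unweighted mean over
#' non-empty directions (`aggregate = "average"`); alternatively all
#' direction counts are merged into a single matrix before feature
#' computation (`aggregate = "merge"`). No voxel resampling is performed;
#' the in-plane/axial anisotropy of the acquisition grid is retained.
#'
#' @param volume a [suv_volume()].
#' @param mtv a non-empty [binary_mask()] (the segmented MTV).
#' @param mode,bin_param discretization settings, see [discretize()].
#' @param base logarithm base for entropy-family features.
#' @param aggregate `"average"` (default) or `"merge"`.
#' @param patient_id,scanner_id optional identifiers carried into the record.
#' @return one-row data frame: ids, `suv_max`, `suv_mean`, `suv_peak`, and
#'   the 16 texture features (19 numeric features in total).
#' @export
extract_features <- function(volume, mtv,
                             mode = "fixed-bin-number", bin_param = 25,
                             base = exp(1), aggregate = c("average", "merge"),
                             patient_id = NA_character_,
                             scanner_id = NA_character_) {
  aggregate <- match.arg(aggregate)
  if (sum(mtv$values) < 2L) stop("MTV too small for texture")
  suv <- suv_metrics(volume, mtv)
  d <- discretize(volume, mtv, mode = mode, bin_param = bin_param)
  offs <- glcm_offsets()
  mats <- list()
  for (r in seq_len(nrow(offs))) {
    P <- tryCatch(build_glcm(d, offs[r, ]), error = function(e) NULL)
    if (!is.null(P)) mats[[length(mats) + 1L]] <- P
  }
  if (!length(mats)) stop("MTV too small for texture")
  if (aggregate == "average") {
    fm <- vapply(mats, haralick_features, numeric(16), base = base)
    tex <- rowMeans(fm)
  } else {
    M <- Reduce(`+`, lapply(mats, unclass)) / length(mats)
    tex <- haralick_features(M / sum(M), base = base)
  }
  out <- data.frame(patient_id = patient_id, scanner_id = scanner_id,
                    suv_max = unname(suv["suv_max"]),
                    suv_mean = unname(suv["suv_mean"]),
                    suv_peak = unname(suv["suv_peak"]),
                    stringsAsFactors = FALSE)
  out[glcm_feature_names] <- as.list(unname(tex))
  out
}

#' Segment and extract features for a whole synthetic cohort
#'
#' Runs [segment_mtv()] and [extract_features()] on every patient of a
#' [generate_cohort()] result.
#'
#' @param cohort_data the list returned by [generate_cohort()] (with
#'   volumes).
#' @param fraction MTV threshold fraction, see [segment_mtv()].
#' @param ... further arguments passed to [extract_features()].
#' @return a data frame with one row per patient (ids + 19 features).
#' @export
extract_cohort_features <- function(cohort_data, fraction = 0.41, ...) {
  if (is.null(cohort_data$volumes))
    stop("cohort was generated without volumes")
  tab <- cohort_data$cohort
  rows <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    mtv <- segment_mtv(cohort_data$volumes[[i]], cohort_data$mask, fraction)
    rows[[i]] <- extract_features(cohort_data$volumes[[i]], mtv$mtv_mask,
                                  patient_id = tab$patient_id[i],
                                  scanner_id = tab$scanner_id[i], ...)
  }
  do.call(rbind, rows)
}

#' Names of the 19 radiomic feature columns
#' @export
feature_columns <- function() c("suv_max", "suv_mean", "suv_peak", glcm_feature_names)
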