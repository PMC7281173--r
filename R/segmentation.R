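# Metabolic tumor volume by relative-SUVmax thresholding.

#' Segment the metabolic tumor volume
#'
#' Thresholds the search region at a fraction of its hottest voxel: the MTV
#' is every search-region voxel with SUV at or above
#' `fraction * max(SUV over search region)`. Ties at exactly the threshold
#' are included, so the maximum voxel is always a member. The whole search
#' region is treated as one region with a single global SUVmax, and no
#' connected-component filtering is applied: disconnected supra-threshold
#' marrow uptake is biologically expected and retained.
#'
#' @param volume a [suv_volume()].
#' @param search a [binary_mask()] on the same grid (e.g. the bony pelvis).
#' @param fraction relative threshold in (0,1); default 0.41 (the standard
#'   41\% SUVmax rule for FDG-avid disease).
#' @return an object of class `mtv_result`: `mtv_mask` ([binary_mask()]),
#'   `suv_max`, `threshold_suv`, `mtv_ml` (volume in millilitres),
#'   `fraction`.
#' @export
segment_mtv <- function(volume, search, fraction = 0.41) {
  stopifnot(inherits(volume, "suv_volume"), inherits(search, "binary_mask"))
  check_same_grid(volume, search)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0,1)")
  idx <- which(search$values == 1L)
  if (!length(idx)) stop("empty search mask")
  suv_max <- max(volume$values[idx])
  if (suv_max <= 0) stop("degenerate region: SUVmax is 0")
  thr <- fraction * suv_max
  m <- array(0L, dim = dim(volume$values))
  m[idx[volume$values[idx] >= thr]] <- 1L
  voxel_ml <- prod(volume$spacing_mm) / 1000
  structure(list(mtv_mask = binary_mask(m, volume$spacing_mm),
                 suv_max = suv_max,
                 threshold_suv = thr,
                 mtv_ml = sum(m) * voxel_ml,
                 fraction = fraction),
            class = "mtv_result")
}

#' @export
print.mtv_result <- function(x, ...) {
  cat(sprintf("MTV: %d voxels (%.2f mL), SUVmax %.3f, threshold %.3f (%.0f%% SUVmax)\n",
              sum(x$mtv_mask$values), x$mtv_ml, x$suv_max, x$threshold_suv,
              100 * x$fraction))
  invisible(x)
}
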