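# Containers and NIfTI / CSV input-output.
#
# All geometry inside the package is 0-based-free index space with the voxel
# spacing carried alongside; world coordinates exist only through the NIfTI
# affine at the I/O boundary.

#' SUV volume container
#'
#' A 3D array of standardized uptake values (SUV, unitless, non-negative)
#' together with its per-axis voxel spacing in millimetres.
#'
#' @param values numeric 3D array of finite, non-negative SUVs.
#' @param spacing_mm numeric length-3 vector of positive voxel sizes (mm).
#' @return an object of class `suv_volume`.
#' @export
suv_volume <- function(values, spacing_mm) {
  if (length(dim(values)) != 3L) stop("expected 3D array of SUV values")
  if (!all(is.finite(values))) stop("SUV values must be finite")
  if (any(values < 0)) stop("negative SUV values are not allowed")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive values")
  structure(list(values = values, spacing_mm = spacing_mm),
            class = "suv_volume")
}

#' Binary mask container
#'
#' A voxel-aligned \{0,1\} region: either a search region (e.g. the bony
#' pelvis) or a segmented metabolic tumor volume.
#'
#' @param values integer/numeric 3D array containing only 0 and 1.
#' @param spacing_mm numeric length-3 vector of positive voxel sizes (mm).
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing_mm) {
  if (length(dim(values)) != 3L) stop("expected 3D mask array")
  u <- unique(as.vector(values))
  if (!all(u %in% c(0, 1))) stop("mask values must be 0/1")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive values")
  structure(list(values = array(as.integer(values), dim = dim(values)),
                 spacing_mm = spacing_mm),
            class = "binary_mask")
}

#' @export
print.suv_volume <- function(x, ...) {
  cat("SUV volume:", paste(dim(x$values), collapse = " x "),
      "voxels, spacing", paste(x$spacing_mm, collapse = " x "), "mm\n")
  cat("  SUV range: [", signif(min(x$values), 4), ",",
      signif(max(x$values), 4), "]\n")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("Binary mask:", paste(dim(x$values), collapse = " x "),
      "voxels,", sum(x$values), "set\n")
  invisible(x)
}

# shared geometry check
check_same_grid <- function(vol, mask) {
  if (!identical(dim(vol$values), dim(mask$values)))
    stop("volume and mask shapes differ")
  if (max(abs(vol$spacing_mm - mask$spacing_mm)) > 1e-6)
    stop("volume and mask voxel spacings differ")
  invisible(TRUE)
}

#' Read an SUV volume from a NIfTI file
#'
#' @param path path to a 3D NIfTI-1 image of non-negative SUVs.
#' @return a [suv_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected 3D image, got ", length(d), "D: ", path)
  vals <- array(as.numeric(img), dim = d)
  if (any(vals < 0)) stop("negative SUVs in ", path)
  suv_volume(vals, RNifti::pixdim(img)[1:3])
}

#' Write an SUV volume as float32 NIfTI
#'
#' @param vol a [suv_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "suv_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing_mm
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a binary mask from a NIfTI file
#'
#' @param path path to a 3D NIfTI label image with values in \{0,1\}.
#' @return a [binary_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected 3D image, got ", length(d), "D: ", path)
  vals <- array(as.numeric(img), dim = d)
  if (!all(vals %in% c(0, 1)))
    stop("mask contains values other than 0/1: ", path)
  binary_mask(vals, RNifti::pixdim(img)[1:3])
}

#' Write a binary mask as uint8 NIfTI
#'
#' @param mask a [binary_mask()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$values), dim = dim(mask$values)))
  RNifti::pixdim(img) <- mask$spacing_mm
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

# ---- cohort tables -------------------------------------------------------

cohort_columns <- c("patient_id", "scanner_id", "involved", "rel",
                    "cellularity", "abs", "wbc", "ldh", "ki67")

validate_cohort <- function(df) {
  miss <- setdiff(cohort_columns, names(df))
  if (length(miss)) stop("missing cohort column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("no records")
  df$involved <- as.logical(df$involved)
  for (cn in c("rel", "cellularity", "abs", "ki67")) {
    bad <- which(df[[cn]] < 0 | df[[cn]] > 100)
    if (length(bad))
      stop("row ", bad[1], ": ", cn, " outside [0,100]")
  }
  bad <- which(abs(df$abs - df$cellularity * df$rel / 100) > 0.1)
  if (length(bad))
    stop("row ", bad[1], ": abs inconsistent with cellularity x rel / 100")
  bad <- which(!df$involved & df$rel != 0)
  if (length(bad))
    stop("row ", bad[1], ": uninvolved patient with nonzero REL")
  df
}

#' Read a cohort table
#'
#' Reads a CSV of per-patient biopsy and laboratory data and validates the
#' invariants that downstream endpoints rely on: `rel`, `cellularity`, `abs`,
#' `ki67` in \[0,100\]; `abs = cellularity * rel / 100` within 0.1;
#' uninvolved patients have `rel = 0`.
#'
#' @param path CSV with header
#'   `patient_id,scanner_id,involved,rel,cellularity,abs,wbc,ldh,ki67`.
#' @return a validated data frame, row order preserved.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' Write a cohort table
#'
#' @param records a cohort data frame (validated before writing).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_cohort <- function(records, path) {
  records <- validate_cohort(as.data.frame(records))
  utils::write.csv(records[, cohort_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
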