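#' Scalar volume container
#'
#' A minimal 3D image container: a numeric array plus per-axis voxel spacing
#' in mm, an intensity unit and a modality tag. The axial (slice) axis is the
#' third array dimension throughout the package; slice indices are 1-based
#' and axial extents are inclusive on both ends.
#'
#' @param values numeric 3D array of voxel intensities.
#' @param spacing_mm numeric length-3 vector of voxel spacings in mm
#'   (x, y, z), all strictly positive.
#' @param intensity_unit one of `"HU"`, `"attenuation_per_cm"`,
#'   `"grayscale_8bit"`, `"density_mgcm3"`.
#' @param modality free-form modality tag, typically `"clinical_ct"` or
#'   `"micro_ct"`.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, spacing_mm,
                          intensity_unit = c("HU", "attenuation_per_cm",
                                             "grayscale_8bit",
                                             "density_mgcm3"),
                          modality = "clinical_ct") {
  intensity_unit <- match.arg(intensity_unit)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be three strictly positive finite values")
  if (any(dim(values) < 1L)) stop("volume must have extent >= 1 in every axis")
  structure(
    list(values = values, spacing_mm = spacing_mm,
         intensity_unit = intensity_unit, modality = modality,
         axial_axis = 3L),
    class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<scalar_volume> %d x %d x %d voxels, spacing %s mm, %s [%s]\n",
              d[1], d[2], d[3],
              paste(format(x$spacing_mm, digits = 4), collapse = " x "),
              x$modality, x$intensity_unit))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.scalar_volume <- function(x) dim(x$values)

is_cubic <- function(vol, tol = 1e-9) {
  s <- vol$spacing_mm
  max(s) - min(s) <= tol * max(s)
}

n_slices <- function(vol) dim(vol$values)[3L]

assert_volume <- function(vol) {
  if (!inherits(vol, "scalar_volume"))
    stop("expected a `scalar_volume` object")
  invisible(vol)
}
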