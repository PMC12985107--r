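#' Read a volume from disk
#'
#' NIfTI volumes are read with spacing taken from the header; an explicit
#' error is raised when spacing metadata is missing rather than assuming a
#' default. DICOM series are not parsed by this package: convert a series
#' to NIfTI first (any standard converter preserves spacing and rescale).
#'
#' @param path file path.
#' @param format `"auto"`, `"nifti"` or `"dicom_series"`.
#' @param intensity_unit,modality metadata tags for the returned volume.
#' @return A [scalar_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom_series"),
                        intensity_unit = "HU", modality = "clinical_ct") {
  format <- match.arg(format)
  if (format == "dicom_series")
    stop("DICOM series input is not supported; convert the series to NIfTI")
  if (!file.exists(path)) stop("input not found: ", path)
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img)[1:3])
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("volume has missing or invalid spacing metadata: ", path)
  scalar_volume(vals, sp, intensity_unit = intensity_unit,
                modality = modality)
}

#' Write a volume to NIfTI
#' @param vol a [scalar_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  assert_volume(vol)
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' 3D median filter
#'
#' Each voxel is replaced by the median of its `kernel`^3 neighborhood;
#' borders are handled by nearest-border replication.
#'
#' @param vol a [scalar_volume()].
#' @param kernel odd integer kernel edge length (default 3).
#' @return The filtered [scalar_volume()].
#' @export
median_filter_3d <- function(vol, kernel = 3L) {
  assert_volume(vol)
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L)
    stop("kernel must be an odd integer >= 1")
  if (kernel == 1L) return(vol)
  d <- dim(vol$values)
  vol$values <- array(cpp_median_filter3(vol$values, d, kernel), d)
  vol
}

#' Resample a volume to isotropic (cubic) voxels
#'
#' Trilinear interpolation onto an isotropic grid covering the input
#' physical extent. With no `target_spacing_mm` the smallest input spacing
#' is used ("force cubic"). A volume already isotropic at the target
#' spacing is returned unchanged.
#'
#' @param vol a [scalar_volume()].
#' @param target_spacing_mm optional isotropic output spacing in mm.
#' @return The resampled [scalar_volume()].
#' @export
resample_cubic <- function(vol, target_spacing_mm = NULL) {
  assert_volume(vol)
  target <- target_spacing_mm %||% min(vol$spacing_mm)
  if (target <= 0) stop("target_spacing_mm must be > 0")
  if (is_cubic(vol) && abs(vol$spacing_mm[1] - target) <
        1e-9 * max(target, 1))
    return(vol)
  d <- dim(vol$values)
  s <- vol$spacing_mm
  n_out <- pmax(1L, as.integer(round(d * s / target)))
  # voxel-center convention: input center i at (i - 0.5) * s_in
  qx <- (((seq_len(n_out[1]) - 0.5) * target) / s[1]) + 0.5
  qy <- (((seq_len(n_out[2]) - 0.5) * target) / s[2]) + 0.5
  qz <- (((seq_len(n_out[3]) - 0.5) * target) / s[3]) + 0.5
  vals <- array(cpp_trilinear_grid(vol$values, d, qx, qy, qz), n_out)
  scalar_volume(vals, target, intensity_unit = vol$intensity_unit,
                modality = vol$modality)
}

#' Axial extent of the bony region
#'
#' First slice = first axial slice containing any voxel above
#' `bone_threshold`; last slice = the supplied surgical-neck landmark when
#' given, otherwise the last slice containing bone. Extents are inclusive,
#' 1-based.
#'
#' @param vol a [scalar_volume()].
#' @param bone_threshold intensity threshold marking bone.
#' @param neck_landmark optional distal landmark slice index.
#' @return An object of class `axial_extent` with `first_slice`,
#'   `last_slice`, `landmark_source`.
#' @export
detect_extent <- function(vol, bone_threshold, neck_landmark = NULL) {
  assert_volume(vol)
  nz <- n_slices(vol)
  slice_max <- apply(vol$values, 3L, max)
  hit <- which(slice_max > bone_threshold)
  if (length(hit) == 0L) stop("no bone found above threshold ",
                              bone_threshold)
  first <- hit[1L]
  if (!is.null(neck_landmark)) {
    neck_landmark <- as.integer(neck_landmark)
    if (neck_landmark < first || neck_landmark > nz)
      stop("neck landmark outside volume/bone extent")
    last <- neck_landmark
    src <- "config"
  } else {
    last <- hit[length(hit)]
    src <- "auto_threshold"
  }
  axial_extent(first, last, src)
}

#' @rdname detect_extent
#' @param first_slice,last_slice inclusive 1-based slice indices.
#' @param landmark_source `"auto_threshold"` or `"config"`.
#' @export
axial_extent <- function(first_slice, last_slice,
                         landmark_source = "config") {
  first_slice <- as.integer(first_slice)
  last_slice <- as.integer(last_slice)
  if (first_slice < 1L || last_slice < first_slice)
    stop("invalid axial extent")
  structure(list(first_slice = first_slice, last_slice = last_slice,
                 landmark_source = landmark_source),
            class = "axial_extent")
}

extent_n <- function(extent) extent$last_slice - extent$first_slice + 1L

#' Crop a volume (or mask) to an axial extent
#' @param vol a [scalar_volume()] or a logical 3D array.
#' @param extent an [axial_extent()].
#' @return The cropped object of the same type.
#' @export
crop_subregion <- function(vol, extent) {
  stopifnot(inherits(extent, "axial_extent"))
  if (is.array(vol) && !inherits(vol, "scalar_volume")) {
    if (extent$last_slice > dim(vol)[3]) stop("extent exceeds volume")
    return(vol[, , extent$first_slice:extent$last_slice, drop = FALSE])
  }
  assert_volume(vol)
  if (extent$last_slice > n_slices(vol)) stop("extent exceeds volume")
  vol$values <- vol$values[, , extent$first_slice:extent$last_slice,
                           drop = FALSE]
  vol
}
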