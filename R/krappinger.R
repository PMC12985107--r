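#' Configuration for the HU-calibrated cancellous vBMD measurement
#'
#' @param diameter_reduction fractional ROI diameter reduction that keeps
#'   the ROI clear of cortical bone (default 0.15).
#' @param water_hu water-equivalent reference intensity; measured values
#'   below it are corrected (default 0, i.e. the HU of water).
#' @param roi_fractions three strictly increasing axial positions as
#'   fractions of the head extent ("equidistant" quarter positions by
#'   default).
#' @return An object of class `krappinger_config`.
#' @export
krappinger_config <- function(diameter_reduction = 0.15, water_hu = 0,
                              roi_fractions = c(0.25, 0.5, 0.75)) {
  if (diameter_reduction <= 0 || diameter_reduction >= 1)
    stop("diameter_reduction must lie in (0, 1)")
  if (length(roi_fractions) != 3L || any(diff(roi_fractions) <= 0) ||
      any(roi_fractions <= 0) || any(roi_fractions >= 1))
    stop("roi_fractions must be three increasing fractions in (0, 1)")
  structure(list(diameter_reduction = diameter_reduction,
                 water_hu = water_hu, roi_fractions = roi_fractions),
            class = "krappinger_config")
}

#' Three equidistant axial ROIs in the cancellous compartment
#'
#' Slices sit at `roi_fractions` of the head extent. At each slice the ROI
#' is a disk at the cancellous centroid whose diameter is the maximal
#' inscribed cancellous diameter reduced by `diameter_reduction` (radius
#' floored to whole pixels).
#'
#' @param vol a [scalar_volume()] (used for grid dimensions only).
#' @param extent an [axial_extent()] of the head (>= 3 slices).
#' @param interior_mask logical 3D array marking cancellous voxels.
#' @param config a [krappinger_config()].
#' @return List of three [central_roi_disk()]-style `roi_disk` objects.
#' @export
krappinger_rois <- function(vol, extent, interior_mask,
                            config = krappinger_config()) {
  assert_volume(vol)
  stopifnot(inherits(extent, "axial_extent"),
            inherits(config, "krappinger_config"))
  if (extent_n(extent) < 3L) stop("extent must span at least 3 slices")
  slices <- as.integer(round(extent$first_slice +
    config$roi_fractions * (extent$last_slice - extent$first_slice)))
  lapply(slices, function(s) {
    msk <- interior_mask[, , s]
    if (!any(msk))
      stop("degenerate cancellous region at slice ", s)
    idx <- which(msk, arr.ind = TRUE)
    ctr <- colMeans(idx)
    dm <- EBImage::distmap(EBImage::Image(msk * 1))
    cpx <- pmin(pmax(round(ctr), 1), dim(msk))
    rmax <- as.numeric(dm[cpx[1], cpx[2]])
    radius <- floor((1 - config$diameter_reduction) * rmax)
    if (radius < 1)
      stop("degenerate cancellous region at slice ", s)
    structure(list(center = ctr, radius_px = radius, slice_id = s),
              class = "roi_disk")
  })
}

#' Water-equivalent correction
#'
#' Values below the water-equivalent reference are raised to it
#' (clamping); values at or above it pass unchanged. This counters the
#' negative bias of fatty marrow: the output mean is never below the input
#' mean.
#'
#' @param hu_values numeric vector.
#' @param water_hu water-equivalent reference intensity.
#' @return Corrected vector `pmax(hu_values, water_hu)`.
#' @export
water_correction <- function(hu_values, water_hu) {
  if (!is.finite(water_hu) && water_hu != -Inf)
    stop("water_hu must be finite (or -Inf to disable)")
  pmax(hu_values, water_hu)
}

#' Calibrated cancellous vBMD from three axial ROIs
#'
#' Per-ROI mean of water-corrected intensities; the specimen value is the
#' mean of the three ROI means, converted to mg/cm3 by the linear phantom
#' calibration.
#'
#' @param vol a [scalar_volume()].
#' @param rois list of three `roi_disk` objects (see [krappinger_rois()]).
#' @param water_hu water-equivalent reference intensity.
#' @param model a [fit_calibration()] model.
#' @return List of class `krappinger_result`: `roi_means` (corrected
#'   intensity per ROI), `specimen_hu`, `bmd_mgcm3`.
#' @export
krappinger_bmd <- function(vol, rois, water_hu, model) {
  assert_volume(vol)
  stopifnot(inherits(model, "calibration_model"), length(rois) == 3L)
  roi_means <- vapply(rois, function(roi) {
    img <- vol$values[, , roi$slice_id]
    px <- img[disk_mask(dim(img), roi$center, roi$radius_px)]
    if (length(px) == 0L) stop("empty ROI at slice ", roi$slice_id)
    mean(water_correction(px, water_hu))
  }, numeric(1))
  hu <- mean(roi_means)
  structure(list(roi_means = roi_means, specimen_hu = hu,
                 bmd_mgcm3 = apply_calibration(hu, model)),
            class = "krappinger_result")
}
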