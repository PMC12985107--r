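#' Threshold segmentation of cortical and trabecular compartments
#'
#' The upper threshold is determined automatically as the volume maximum.
#' The cortical compartment is the largest 6-connected component of voxels
#' at or above `cortical_min`; the trabecular compartment comprises voxels
#' in `[trabecular_min, cortical_min)` lying inside the filled cortical
#' envelope (hole-filled per axial slice, matching the slice-wise workflow
#' the segmentation emulates) and outside the cortical mask.
#'
#' @param vol a [scalar_volume()].
#' @param config a [modality_config()] supplying `cortical_min` and
#'   `trabecular_min`.
#' @return A list of class `compartment_map`: `cortical_mask`,
#'   `trabecular_mask` (disjoint logical arrays), `provenance`.
#' @export
segment_compartments <- function(vol, config) {
  assert_volume(vol)
  stopifnot(inherits(config, "modality_config"))
  upper <- max(vol$values)
  cand <- vol$values >= config$cortical_min & vol$values <= upper
  if (!any(cand)) stop("no cortex found above threshold ",
                       config$cortical_min)
  cort <- largest_component(cand)
  envelope <- fill_envelope(cort)
  trab <- vol$values >= config$trabecular_min &
    vol$values < config$cortical_min & envelope & !cort
  if (!any(trab)) stop("empty trabecular compartment")
  compartment_map(cort, trab, "auto")
}

compartment_map <- function(cortical, trabecular, provenance) {
  if (any(cortical & trabecular))
    stop("compartments must be disjoint")
  structure(list(cortical_mask = cortical, trabecular_mask = trabecular,
                 provenance = provenance),
            class = "compartment_map")
}

largest_component <- function(mask) {
  lab <- array(cpp_label6(mask, dim(mask)), dim(mask))
  sizes <- tabulate(lab)
  array(lab == which.max(sizes), dim(mask))
}

# hole-fill the cortical shell per axial slice (2D, slice-wise)
fill_envelope <- function(mask) {
  d <- dim(mask)
  filled <- EBImage::fillHull(EBImage::Image(mask * 1, dim = d))
  array(EBImage::imageData(filled) > 0.5, d)
}

#' Morphological refinement of a compartment map
#'
#' Deterministic stand-in for manual slice-wise object-map editing: the
#' cortical mask is closed (disc of `closing_radius_px`, per axial slice)
#' and reduced to its largest 3D component; the trabecular mask is opened
#' (disc radius 1) and components smaller than `min_component_voxels` are
#' removed. Disjointness is re-enforced with cortex winning ties.
#'
#' @param map a [segment_compartments()] result.
#' @param closing_radius_px disc radius for cortical closing.
#' @param min_component_voxels minimum retained trabecular component size.
#' @return The refined `compartment_map` (provenance `"refined"`).
#' @export
refine_map <- function(map, closing_radius_px = 2,
                       min_component_voxels = 5) {
  stopifnot(inherits(map, "compartment_map"))
  d <- dim(map$cortical_mask)
  brush <- EBImage::makeBrush(2 * closing_radius_px + 1, "disc")
  cort <- EBImage::closing(EBImage::Image(map$cortical_mask * 1, dim = d),
                           brush)
  cort <- largest_component(array(EBImage::imageData(cort) > 0.5, d))
  trab <- EBImage::opening(
    EBImage::Image(map$trabecular_mask * 1, dim = d),
    EBImage::makeBrush(3, "disc"))
  trab <- array(EBImage::imageData(trab) > 0.5, d)
  lab <- array(cpp_label6(trab, d), d)
  sizes <- tabulate(lab)
  if (length(sizes) > 0) {
    keep <- which(sizes >= min_component_voxels)
    trab <- array(lab %in% keep & lab > 0, d)
  }
  trab <- trab & !cort
  if (!any(cort)) stop("refinement emptied the cortical compartment")
  if (!any(trab)) stop("refinement emptied the trabecular compartment")
  compartment_map(cort, trab, "refined")
}

#' Trabecular density from a compartment map
#'
#' Mean intensity over the trabecular mask mapped through the calibration
#' model; pass [identity_calibration()] for acquisitions that already
#' store calibrated densities (micro-CT mg HA/cm3).
#'
#' @param vol a [scalar_volume()].
#' @param map a `compartment_map`.
#' @param model a `calibration_model` (default identity).
#' @return Numeric density (mg/cm3, or pass-through units).
#' @export
trabecular_density <- function(vol, map, model = identity_calibration()) {
  assert_volume(vol)
  stopifnot(inherits(map, "compartment_map"))
  if (!any(map$trabecular_mask)) stop("empty trabecular mask")
  apply_calibration(mean(vol$values[map$trabecular_mask]), model)
}

#' Dice overlap between two masks
#' @param a,b logical arrays of equal dimension.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}
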