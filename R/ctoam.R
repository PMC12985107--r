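#' Per-modality analysis constants
#'
#' Bundles the modality-specific constants used across the workflows: the
#' display window (whose upper bound `hu_max` is also the scale of the
#' ROI-mean index), the MIP slab thickness in slices, the segmentation
#' lower bounds, and the bone-detection threshold. Defaults: clinical CT
#' window 0-1500 with 2-slice MIP slabs, cortical/trabecular lower bounds
#' 300/200; micro-CT window 0-3000 with 7-slice slabs, bounds 600/200.
#'
#' @param modality `"clinical_ct"` or `"micro_ct"`.
#' @param hu_max,hu_min display window bounds (index scale).
#' @param mip_slab_slices slices per MIP slab (>= 1).
#' @param cortical_min,trabecular_min segmentation lower bounds.
#' @param bone_threshold intensity marking "bone present" for extent
#'   detection (not stated by any workflow; config-exposed).
#' @return An object of class `modality_config`.
#' @export
modality_config <- function(modality = c("clinical_ct", "micro_ct"),
                            hu_max = NULL, hu_min = 0,
                            mip_slab_slices = NULL,
                            cortical_min = NULL, trabecular_min = 200,
                            bone_threshold = NULL) {
  modality <- match.arg(modality)
  def <- switch(modality,
    clinical_ct = list(hu_max = 1500, slab = 2L, cort = 300, bone = 150),
    micro_ct    = list(hu_max = 3000, slab = 7L, cort = 600, bone = 300))
  hu_max <- hu_max %||% def$hu_max
  mip_slab_slices <- as.integer(mip_slab_slices %||% def$slab)
  cortical_min <- cortical_min %||% def$cort
  bone_threshold <- bone_threshold %||% def$bone
  if (hu_max <= hu_min) stop("hu_max must exceed hu_min")
  if (mip_slab_slices < 1L) stop("mip_slab_slices must be >= 1")
  if (cortical_min <= trabecular_min)
    stop("cortical_min must exceed trabecular_min")
  structure(
    list(modality = modality, hu_max = hu_max, hu_min = hu_min,
         mip_slab_slices = mip_slab_slices, cortical_min = cortical_min,
         trabecular_min = trabecular_min, bone_threshold = bone_threshold),
    class = "modality_config")
}

# round half away from zero (fixed rule; R's round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Select the three central measurement levels
#'
#' The axial extent is divided into five equal bands and the centers of the
#' three middle bands are the measurement levels: with `n` slices, level
#' `k` sits at `first + round((k - 0.5) * n / 5)` for `k = 2, 3, 4`
#' (rounding half away from zero, clamped to the extent).
#'
#' @param extent an [axial_extent()] spanning at least 5 slices.
#' @return Integer vector of three strictly increasing slice indices.
#' @export
select_levels <- function(extent) {
  stopifnot(inherits(extent, "axial_extent"))
  n <- extent_n(extent)
  if (n < 5L) stop("extent too short: need at least 5 slices, got ", n)
  lev <- extent$first_slice + round_half_away((c(2, 3, 4) - 0.5) * n / 5)
  lev <- pmin(pmax(as.integer(lev), extent$first_slice), extent$last_slice)
  if (any(diff(lev) <= 0L)) stop("degenerate level selection")
  lev
}

#' Maximum-intensity projection over a slice slab
#'
#' Pixelwise maximum over slices `[center - floor((m-1)/2),
#' center + ceiling((m-1)/2)]`, clipped to the volume; an even slab
#' extends distally (for `m = 2` the slab is `[center, center + 1]`).
#'
#' @param vol a [scalar_volume()].
#' @param center_slice slab center slice index.
#' @param slab_slices slab thickness in slices (>= 1).
#' @return A 2D numeric matrix.
#' @export
make_mip <- function(vol, center_slice, slab_slices) {
  assert_volume(vol)
  m <- as.integer(slab_slices)
  if (m < 1L) stop("slab_slices must be >= 1")
  lo <- center_slice - floor((m - 1) / 2)
  hi <- center_slice + ceiling((m - 1) / 2)
  lo <- max(lo, 1L); hi <- min(hi, n_slices(vol))
  if (lo > hi) stop("MIP slab does not intersect the volume")
  out <- vol$values[, , lo]
  if (hi > lo) for (s in (lo + 1L):hi) out <- pmax(out, vol$values[, , s])
  out
}

#' Map an image to 8-bit under a display window
#'
#' `g = round(255 * clamp((v - hu_min) / (hu_max - hu_min), 0, 1))`,
#' rounding half away from zero; monotone non-decreasing in `v`.
#'
#' @param image numeric matrix.
#' @param window length-2 numeric `(hu_min, hu_max)`.
#' @return Integer-valued matrix in `[0, 255]`.
#' @export
to_8bit <- function(image, window) {
  if (window[2] <= window[1]) stop("window upper bound must exceed lower")
  f <- (image - window[1]) / (window[2] - window[1])
  g <- round_half_away(255 * pmin(pmax(f, 0), 1))
  matrix(as.integer(g), nrow(image), ncol(image))
}

#' Central cancellous disk ROI
#'
#' The disk is centered at the centroid of the cancellous (interior) mask;
#' its radius is the largest radius for which the disk stays inside the
#' mask, reduced by `margin_px`. The Euclidean distance transform of the
#' mask supplies that largest in-mask radius at the centroid.
#'
#' @param interior_mask logical matrix marking cancellous pixels.
#' @param margin_px safety margin subtracted from the radius.
#' @param slice_id optional slice label carried in the result.
#' @return An object of class `roi_disk` with `center` (row, col),
#'   `radius_px`, `slice_id`.
#' @export
central_roi_disk <- function(interior_mask, margin_px = 2, slice_id = NA) {
  if (!any(interior_mask)) stop("interior mask is empty")
  idx <- which(interior_mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  dm <- EBImage::distmap(EBImage::Image(interior_mask * 1))
  cpx <- pmin(pmax(round(ctr), 1), dim(interior_mask))
  rmax <- as.numeric(dm[cpx[1], cpx[2]])
  radius <- floor(rmax - margin_px)
  if (radius < 1) stop("specimen too small: no admissible ROI disk")
  structure(list(center = ctr, radius_px = radius, slice_id = slice_id),
            class = "roi_disk")
}

disk_mask <- function(dim2, center, radius) {
  rr <- (seq_len(dim2[1]) - center[1])^2
  cc <- (seq_len(dim2[2]) - center[2])^2
  outer(rr, cc, "+") <= radius^2
}

#' Grayscale statistics over a disk ROI (non-black pixels)
#'
#' Descriptive statistics of the 8-bit pixels inside the disk, excluding
#' black pixels (value 0). Quartiles use linear interpolation between
#' order statistics; the SD uses the n-1 denominator.
#'
#' @param image8 8-bit image matrix.
#' @param roi a [central_roi_disk()] result.
#' @return A list of class `grayscale_stats`: `n_pixels`, `min`, `q1`,
#'   `median`, `q3`, `max`, `mean`, `sd`.
#' @export
roi_grayscale_stats <- function(image8, roi) {
  stopifnot(inherits(roi, "roi_disk"))
  m <- disk_mask(dim(image8), roi$center, roi$radius_px)
  px <- image8[m]
  px <- px[px > 0]
  if (length(px) == 0L) stop("empty ROI: all pixels are black")
  q <- unname(quantile(px, c(0.25, 0.5, 0.75), type = 7))
  structure(
    list(n_pixels = length(px), min = min(px), q1 = q[1], median = q[2],
         q3 = q[3], max = max(px), mean = mean(px),
         sd = if (length(px) > 1) sd(px) else 0),
    class = "grayscale_stats")
}

#' ROI-mean attenuation index
#'
#' `index = (mean / 256) * hu_max` in arbitrary units. The 256 denominator
#' is the published convention and is kept verbatim even though the 8-bit
#' maximum is 255, so a saturated ROI attains `(255/256) * hu_max`.
#'
#' @param stats a [roi_grayscale_stats()] result.
#' @param config a [modality_config()].
#' @return Numeric index in a.u.
#' @export
ctoam_index <- function(stats, config) {
  stopifnot(inherits(stats, "grayscale_stats"),
            inherits(config, "modality_config"))
  (stats$mean / 256) * config$hu_max
}

#' Specimen-level ROI-mean index
#'
#' Composes the full per-level chain -- level selection, MIP slab, 8-bit
#' windowing, central disk ROI, non-black grayscale statistics, index
#' formula -- and averages the three level indices into the specimen
#' index. The per-level cancellous mask is the intersection of the
#' interior mask over the MIP slab, so the ROI avoids cortex in every
#' slab slice.
#'
#' @param vol a [scalar_volume()].
#' @param extent an [axial_extent()] of the head.
#' @param config a [modality_config()].
#' @param interior_mask logical 3D array marking cancellous voxels.
#' @param margin_px ROI safety margin.
#' @return A list of class `ctoam_result`: `level_indices` (slices),
#'   `level_index_values`, `level_stats`, `specimen_index`.
#' @export
specimen_ctoam <- function(vol, extent, config, interior_mask,
                           margin_px = 2) {
  assert_volume(vol)
  levels <- select_levels(extent)
  m <- config$mip_slab_slices
  vals <- numeric(3)
  stats <- vector("list", 3)
  for (i in 1:3) {
    lv <- levels[i]
    res <- tryCatch({
      img <- make_mip(vol, lv, m)
      img8 <- to_8bit(img, c(config$hu_min, config$hu_max))
      lo <- max(lv - floor((m - 1) / 2), 1L)
      hi <- min(lv + ceiling((m - 1) / 2), n_slices(vol))
      msk <- interior_mask[, , lo]
      if (hi > lo) for (s in (lo + 1L):hi) msk <- msk & interior_mask[, , s]
      roi <- central_roi_disk(msk, margin_px, slice_id = lv)
      st <- roi_grayscale_stats(img8, roi)
      list(index = ctoam_index(st, config), stats = st)
    }, error = function(e)
      stop("level ", lv, ": ", conditionMessage(e), call. = FALSE))
    vals[i] <- res$index
    stats[[i]] <- res$stats
  }
  structure(
    list(level_indices = levels, level_index_values = vals,
         level_stats = stats, specimen_index = mean(vals)),
    class = "ctoam_result")
}
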