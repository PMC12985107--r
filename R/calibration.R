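#' Measure reference inserts
#'
#' One reference point per insert: the mask-mean intensity paired with the
#' insert's known density.
#'
#' @param phantom_vol a [scalar_volume()] of the calibration phantom.
#' @param insert_masks list of logical arrays, one per insert (disjoint,
#'   nonempty).
#' @param known_densities numeric vector of insert densities (mg/cm3).
#' @return A data.frame of class `reference_points` with columns
#'   `mean_intensity`, `known_density`.
#' @export
measure_inserts <- function(phantom_vol, insert_masks, known_densities) {
  assert_volume(phantom_vol)
  if (length(insert_masks) != length(known_densities))
    stop("one known density per insert mask is required")
  total <- array(0L, dim(phantom_vol$values))
  for (m in insert_masks) {
    if (!any(m)) stop("empty insert mask")
    total <- total + m
  }
  if (any(total > 1L)) stop("insert masks must be disjoint")
  means <- vapply(insert_masks,
                  function(m) mean(phantom_vol$values[m]), numeric(1))
  structure(data.frame(mean_intensity = means,
                       known_density = as.numeric(known_densities)),
            class = c("reference_points", "data.frame"))
}

#' Fit the linear intensity-to-density calibration
#'
#' Ordinary least squares of density on intensity:
#' `density = sigma * intensity + beta`. The regression direction follows
#' the conversion use-case (grayscale values are converted to BMD), so
#' density is the response.
#'
#' @param points a [measure_inserts()] data.frame (or any data.frame with
#'   `mean_intensity` and `known_density`), >= 2 rows with >= 2 distinct
#'   intensities.
#' @return A list of class `calibration_model`: `sigma` (slope), `beta`
#'   (intercept), `r2`, `n_points`, `points`.
#' @export
fit_calibration <- function(points) {
  if (nrow(points) < 2L) stop("need at least two reference points")
  x <- points$mean_intensity
  y <- points$known_density
  if (length(unique(x)) < 2L)
    stop("singular fit: all insert intensities are identical")
  fit <- lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(
    list(sigma = unname(coef(fit)[2]), beta = unname(coef(fit)[1]),
         r2 = r2, n_points = nrow(points),
         points = as.data.frame(points)),
    class = "calibration_model")
}

#' Apply a calibration model
#' @param intensity numeric intensities.
#' @param model a [fit_calibration()] model or [identity_calibration()].
#' @return Densities `sigma * intensity + beta` (mg/cm3).
#' @export
apply_calibration <- function(intensity, model) {
  stopifnot(inherits(model, "calibration_model"))
  model$sigma * intensity + model$beta
}

#' Identity calibration (pre-calibrated data pass-through)
#'
#' Used where the acquisition already stores calibrated densities
#' (e.g. factory-calibrated micro-CT reported in mg HA/cm3).
#' @return A `calibration_model` with slope 1 and intercept 0.
#' @export
identity_calibration <- function() {
  structure(list(sigma = 1, beta = 0, r2 = 1, n_points = 0L,
                 points = NULL),
            class = "calibration_model")
}

#' Save / load a calibration model as JSON
#' @param model a `calibration_model`.
#' @param path JSON file path.
#' @return `write_calibration` invisibly returns `path`;
#'   `read_calibration` returns the model.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(
    list(sigma = model$sigma, beta = model$beta, r2 = model$r2,
         n_points = model$n_points, points = model$points),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(sigma = j$sigma, beta = j$beta, r2 = j$r2,
                 n_points = j$n_points,
                 points = if (!is.null(j$points)) as.data.frame(j$points)),
            class = "calibration_model")
}
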