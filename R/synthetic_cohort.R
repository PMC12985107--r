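#' Humeral-head phantom specification
#'
#' Parametric ground truth for one synthetic specimen: a sphere of radius
#' `head_radius_mm` carrying a dense cortical shell of thickness
#' `cortical_thickness_mm`, truncated distally at the surgical-neck landmark
#' (`neck_slice_fraction` of the axial extent, measured from the proximal
#' pole). The trabecular interior carries the specimen's ground-truth mean
#' density, modulated by (i) a deterministic radial densification gradient
#' (denser toward the subchondral periphery, as in real humeral heads),
#' (ii) a deterministic sinusoidal trabecular lattice (a plate/rod
#' stand-in with spacing `lattice_period_mm`, identical in phase across
#' specimens), and (iii) a stochastic trabecular texture
#' (Gaussian-smoothed white noise with correlation length
#' `texture_scale_mm`). All modulations are zero-meaned over the
#' trabecular mask, so the realized interior mean density equals
#' `true_density_mgcm3` exactly.
#'
#' The default geometry (head radius 22 mm, cortex 1.5 mm) is a fabricated
#' but plausible adult humeral head; no specimen dimensions are implied by
#' any real cohort.
#'
#' @param head_radius_mm head radius in mm (> cortical thickness).
#' @param cortical_thickness_mm cortical shell thickness in mm (> 0).
#' @param true_density_mgcm3 ground-truth mean trabecular density.
#' @param cortical_density_mgcm3 shell density (uniform, untextured).
#' @param texture_scale_mm correlation length of the trabecular texture.
#' @param texture_contrast multiplicative texture amplitude in `[0, 1)`.
#' @param radial_gradient fractional density increase from center to
#'   periphery (deterministic, common shape across specimens).
#' @param lattice_amplitude fractional amplitude of the deterministic
#'   trabecular lattice modulation.
#' @param lattice_period_mm spatial period of the lattice (trabecular
#'   spacing surrogate).
#' @param neck_slice_fraction fraction of the sphere's axial extent, from
#'   the proximal pole, at which the head is truncated (surgical neck).
#' @param noise_sd additive Gaussian intensity noise (image units).
#' @param seed integer seed controlling texture and noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(head_radius_mm = 22, cortical_thickness_mm = 1.5,
                         true_density_mgcm3 = 150,
                         cortical_density_mgcm3 = 1100,
                         texture_scale_mm = 1.5, texture_contrast = 0.2,
                         radial_gradient = 0.1,
                         lattice_amplitude = 0.25,
                         lattice_period_mm = 1.6,
                         neck_slice_fraction = 0.85,
                         noise_sd = 0, seed = 1L) {
  if (!(head_radius_mm > cortical_thickness_mm &&
        cortical_thickness_mm > 0))
    stop("need head_radius_mm > cortical_thickness_mm > 0")
  if (texture_contrast < 0 || texture_contrast >= 1)
    stop("texture_contrast must lie in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (texture_scale_mm <= 0) stop("texture_scale_mm must be > 0")
  if (neck_slice_fraction <= 0 || neck_slice_fraction > 1)
    stop("neck_slice_fraction must lie in (0, 1]")
  if (lattice_amplitude < 0 || lattice_amplitude >= 1)
    stop("lattice_amplitude must lie in [0, 1)")
  if (lattice_period_mm <= 0) stop("lattice_period_mm must be > 0")
  if (true_density_mgcm3 <= 0) stop("true_density_mgcm3 must be > 0")
  structure(
    list(head_radius_mm = head_radius_mm,
         cortical_thickness_mm = cortical_thickness_mm,
         true_density_mgcm3 = true_density_mgcm3,
         cortical_density_mgcm3 = cortical_density_mgcm3,
         texture_scale_mm = texture_scale_mm,
         texture_contrast = texture_contrast,
         radial_gradient = radial_gradient,
         lattice_amplitude = lattice_amplitude,
         lattice_period_mm = lattice_period_mm,
         neck_slice_fraction = neck_slice_fraction,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec")
}

#' Rendering model for a synthetic modality
#'
#' Maps local density to image intensity by an affine transform
#' (`intensity = slope * density + intercept`) on an isotropic voxel grid,
#' with an optional Gaussian point-spread surrogate. The clinical-CT
#' defaults emulate a coarse HU-like scale; the micro-CT render is generated
#' directly at 0.2 mm, the working resolution of the downstream analysis.
#'
#' @param modality `"clinical_ct"` or `"micro_ct"`.
#' @param voxel_mm isotropic voxel size in mm.
#' @param intensity_slope,intensity_intercept affine density-to-intensity map.
#' @param blur_sigma_mm Gaussian point-spread sigma in mm (0 = none).
#' @return An object of class `render_model`.
#' @export
render_model <- function(modality = c("clinical_ct", "micro_ct"),
                         voxel_mm = NULL,
                         intensity_slope = NULL, intensity_intercept = NULL,
                         blur_sigma_mm = 0) {
  modality <- match.arg(modality)
  def <- switch(modality,
    clinical_ct = list(voxel_mm = 0.5, slope = 0.32, icpt = 195),
    micro_ct    = list(voxel_mm = 0.2, slope = 1.1,  icpt = 200))
  voxel_mm <- voxel_mm %||% def$voxel_mm
  intensity_slope <- intensity_slope %||% def$slope
  intensity_intercept <- intensity_intercept %||% def$icpt
  if (voxel_mm <= 0) stop("voxel_mm must be > 0")
  if (blur_sigma_mm < 0) stop("blur_sigma_mm must be >= 0")
  structure(
    list(modality = modality, voxel_mm = voxel_mm,
         intensity_slope = intensity_slope,
         intensity_intercept = intensity_intercept,
         blur_sigma_mm = blur_sigma_mm),
    class = "render_model")
}

#' Default paired renders for a bilateral cohort
#' @return Named list with `clinical_ct` and `micro_ct` render models.
#' @export
default_render_pair <- function() {
  pair <- list(clinical_ct = render_model("clinical_ct"),
               micro_ct = render_model("micro_ct"))
  stopifnot(pair$clinical_ct$voxel_mm > pair$micro_ct$voxel_mm)
  pair
}

# Stable 31-bit hash of (seed, key string); keeps sub-seeds reproducible
# independently of generation order.
hash_seed <- function(seed, key) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% m
  as.integer(h)
}

# Evaluate `code` under a temporary RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Smooth texture field sampled at voxel centers: white noise on a coarse
# lattice (spacing = texture_scale_mm), trilinearly interpolated, then
# normalized by the lattice maximum so the modulation amplitude is bounded.
texture_field <- function(spec, xs, ys, zs, seed) {
  ts <- spec$texture_scale_mm
  rngx <- range(xs); rngy <- range(ys); rngz <- range(zs)
  orig <- c(rngx[1], rngy[1], rngz[1]) - ts
  nl <- ceiling(c(diff(rngx), diff(rngy), diff(rngz)) / ts) + 3L
  lat <- with_seed(seed, array(rnorm(prod(nl)), nl))
  qx <- (xs - orig[1]) / ts + 1
  qy <- (ys - orig[2]) / ts + 1
  qz <- (zs - orig[3]) / ts + 1
  f <- cpp_trilinear_grid(lat, dim(lat), qx, qy, qz)
  array(f / max(abs(lat)), c(length(xs), length(ys), length(zs)))
}

gaussian_kernel <- function(sigma_vox) {
  h <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-h:h)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

apply_blur <- function(values, sigma_vox) {
  if (sigma_vox <= 0) return(values)
  k <- gaussian_kernel(sigma_vox)
  d <- dim(values)
  for (ax in 0:2) values <- array(cpp_convolve_axis(values, d, k, ax), d)
  values
}

#' Generate one humeral-head phantom volume
#'
#' Renders a `phantom_spec` under a `render_model` and returns the volume
#' together with exact ground-truth masks. Identical `(spec, render)`
#' inputs reproduce the volume bit for bit. Slice 1 is the proximal pole;
#' the head ends distally at the recorded `neck_slice`.
#'
#' @param spec a [phantom_spec()].
#' @param render a [render_model()].
#' @param margin_mm air margin around the head (grid sizing).
#' @param dim optional fixed grid dimensions; an error is raised if the head
#'   does not fit.
#' @return A list of class `head_phantom` with elements `volume`
#'   (a [scalar_volume()]), `cortical_mask`, `trabecular_mask` (logical
#'   arrays), `true_density`, `neck_slice`, `bone_slices` (first/last slice
#'   containing bone), plus the generating `spec` and `render`.
#' @export
generate_head_phantom <- function(spec, render, margin_mm = 2, dim = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(render, "render_model"))
  R <- spec$head_radius_mm
  Rin <- R - spec$cortical_thickness_mm
  v <- render$voxel_mm
  z_neck <- R - 2 * R * spec$neck_slice_fraction
  half_xy <- R + margin_mm
  z_hi <- R + margin_mm
  z_lo <- z_neck - margin_mm
  nx <- ceiling(2 * half_xy / v)
  nz <- ceiling((z_hi - z_lo) / v)
  if (!is.null(dim)) {
    if (length(dim) != 3L || any(dim < c(nx, nx, nz)))
      stop("head does not fit in the requested grid")
    nx <- dim[1]; nz <- dim[3]
  }
  xs <- -half_xy + (seq_len(nx) - 0.5) * v
  ys <- xs
  zs <- z_hi - (seq_len(nz) - 0.5) * v  # slice 1 = proximal
  r2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  in_head <- array(rep(zs >= z_neck, each = nx * nx), c(nx, nx, nz))
  trab <- r2 <= Rin^2 & in_head
  cort <- r2 <= R^2 & r2 > Rin^2 & in_head
  if (!any(trab)) stop("head does not fit: no trabecular voxels on grid")

  rel <- array(0, c(nx, nx, nz))
  if (spec$radial_gradient != 0) {
    g <- r2 / Rin^2
    rel <- spec$radial_gradient * (g - mean(g[trab]))
  }
  if (spec$lattice_amplitude > 0) {
    p <- 2 * pi / spec$lattice_period_mm
    lat <- (outer(outer(sin(p * xs), sin(p * ys), "+"),
                  sin(p * zs), "+")) / 3
    rel <- rel + spec$lattice_amplitude * (lat - mean(lat[trab]))
  }
  if (spec$texture_contrast > 0) {
    tex <- texture_field(spec, xs, ys, zs,
                         seed = hash_seed(spec$seed, "texture"))
    rel <- rel + spec$texture_contrast * (tex - mean(tex[trab]))
  }
  density <- array(0, c(nx, nx, nz))
  density[trab] <- spec$true_density_mgcm3 * pmax(1 + rel[trab], 0.01)
  density[cort] <- spec$cortical_density_mgcm3

  values <- array(0, c(nx, nx, nz))
  inside <- trab | cort
  values[inside] <- render$intensity_slope * density[inside] +
    render$intensity_intercept
  if (render$blur_sigma_mm > 0)
    values <- apply_blur(values, render$blur_sigma_mm / v)
  if (spec$noise_sd > 0) {
    noise_seed <- hash_seed(spec$seed, paste0("noise:", render$modality))
    values <- values + with_seed(noise_seed,
      array(rnorm(length(values), 0, spec$noise_sd), c(nx, nx, nz)))
  }

  occupied <- which(apply(inside, 3L, any))
  structure(
    list(volume = scalar_volume(values, v, "HU", render$modality),
         cortical_mask = cort, trabecular_mask = trab,
         true_density = spec$true_density_mgcm3,
         neck_slice = max(occupied),
         bone_slices = c(min(occupied), max(occupied)),
         spec = spec, render = render),
    class = "head_phantom")
}

#' Generate a calibration phantom with cylindrical inserts
#'
#' Parallel cylindrical reference inserts of known density, rendered under
#' the same affine density-to-intensity model as the head phantoms. Used to
#' fit the intensity-to-density calibration.
#'
#' @param insert_densities numeric vector (length >= 2) of known densities
#'   in mg/cm3; must contain at least two distinct values.
#' @param render a [render_model()].
#' @param noise_sd additive Gaussian intensity noise.
#' @param seed integer seed for the noise.
#' @param insert_radius_mm,insert_length_mm,gap_mm insert geometry.
#' @return A list of class `calibration_phantom` with `volume`,
#'   `insert_masks` (list of logical arrays) and `insert_densities`.
#' @export
generate_calibration_phantom <- function(insert_densities, render,
                                         noise_sd = 0, seed = 1L,
                                         insert_radius_mm = 4,
                                         insert_length_mm = 12,
                                         gap_mm = 3) {
  stopifnot(inherits(render, "render_model"))
  if (length(insert_densities) < 2L ||
      length(unique(insert_densities)) < 2L)
    stop("need at least two distinct insert densities")
  v <- render$voxel_mm
  k <- length(insert_densities)
  pitch <- 2 * insert_radius_mm + gap_mm
  wx <- k * pitch + gap_mm
  wy <- 2 * insert_radius_mm + 2 * gap_mm
  wz <- insert_length_mm + 2 * gap_mm
  nx <- ceiling(wx / v); ny <- ceiling(wy / v); nz <- ceiling(wz / v)
  xs <- (seq_len(nx) - 0.5) * v
  ys <- (seq_len(ny) - 0.5) * v
  zs <- (seq_len(nz) - 0.5) * v
  zin <- zs >= gap_mm & zs <= gap_mm + insert_length_mm
  values <- array(0, c(nx, ny, nz))
  masks <- vector("list", k)
  cy <- wy / 2
  for (i in seq_len(k)) {
    cx <- gap_mm + (i - 1) * pitch + insert_radius_mm
    d2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
    m <- array(d2 <= insert_radius_mm^2, c(nx, ny, 1))[, , rep(1, nz)] &
      array(rep(zin, each = nx * ny), c(nx, ny, nz))
    masks[[i]] <- m
    values[m] <- render$intensity_slope * insert_densities[i] +
      render$intensity_intercept
  }
  if (noise_sd > 0)
    values <- values + with_seed(as.integer(seed),
      array(rnorm(length(values), 0, noise_sd), c(nx, ny, nz)))
  structure(
    list(volume = scalar_volume(values, v, "HU", render$modality),
         insert_masks = masks,
         insert_densities = as.numeric(insert_densities)),
    class = "calibration_phantom")
}

#' Generate a clustered bilateral cohort manifest
#'
#' Draws specimen ground-truth densities from a donor-clustered model
#' `D_ij = mean + b_i + e_ij`, `b_i ~ N(0, donor_sd^2)`,
#' `e_ij ~ N(0, residual_sd^2)`, and attaches a phantom spec per specimen.
#' Each specimen is rendered at both modalities from the same density field
#' (the texture sub-seed depends on donor and side only, never on
#' modality). Volumes are generated on demand via [render_specimen()].
#'
#' @param n_donors number of donors (>= 2).
#' @param bilateral if `TRUE`, two sides (L, R) per donor.
#' @param donor_sd,residual_sd between-donor and within-donor density SDs.
#' @param mean_density cohort mean trabecular density (mg/cm3).
#' @param render_pair named list of render models (see
#'   [default_render_pair()]).
#' @param seed global integer seed; per-specimen sub-seeds are derived by
#'   stable hashing of (donor, side).
#' @param spec_template a [phantom_spec()] supplying all non-density fields.
#' @param min_density lower bound below which a specimen density is redrawn
#'   (`on_negative = "resample"`) or generation fails.
#' @param on_negative `"resample"` or `"fail"`.
#' @return A list of class `cohort_manifest` with `entries` (data.frame of
#'   donor, side, true density, sub-seed), `specs` (list of phantom specs),
#'   `render_pair` and the generating parameters.
#' @export
generate_cohort <- function(n_donors = 6, bilateral = TRUE,
                            donor_sd = 30, residual_sd = 5,
                            mean_density = 150,
                            render_pair = default_render_pair(),
                            seed = 1L,
                            spec_template = phantom_spec(),
                            min_density = 10,
                            on_negative = c("resample", "fail")) {
  on_negative <- match.arg(on_negative)
  if (n_donors < 2) stop("n_donors must be >= 2")
  sides <- if (bilateral) c("L", "R") else "L"
  donors <- sprintf("D%02d", seq_len(n_donors))
  dens <- with_seed(as.integer(seed), {
    b <- rnorm(n_donors, 0, donor_sd)
    d <- numeric(0)
    for (i in seq_len(n_donors)) for (s in sides) {
      val <- mean_density + b[i] + rnorm(1, 0, residual_sd)
      tries <- 0
      while (val < min_density) {
        if (on_negative == "fail")
          stop("sampled density below bound for donor ", donors[i])
        tries <- tries + 1
        if (tries > 1000) stop("density resampling did not converge")
        val <- mean_density + b[i] + rnorm(1, 0, residual_sd)
      }
      d <- c(d, val)
    }
    d
  })
  entries <- data.frame(
    donor_id = rep(donors, each = length(sides)),
    side = rep(sides, times = n_donors),
    true_density = dens,
    stringsAsFactors = FALSE)
  entries$sub_seed <- mapply(
    function(d, s) hash_seed(seed, paste0(d, ":", s)),
    entries$donor_id, entries$side)
  specs <- lapply(seq_len(nrow(entries)), function(i) {
    sp <- spec_template
    sp$true_density_mgcm3 <- entries$true_density[i]
    sp$seed <- entries$sub_seed[i]
    sp
  })
  structure(
    list(entries = entries, specs = specs, render_pair = render_pair,
         params = list(n_donors = n_donors, bilateral = bilateral,
                       donor_sd = donor_sd, residual_sd = residual_sd,
                       mean_density = mean_density, seed = as.integer(seed))),
    class = "cohort_manifest")
}

#' Render one cohort specimen at a given modality
#' @param manifest a [generate_cohort()] manifest.
#' @param index specimen row in `manifest$entries`.
#' @param modality name of a render model in `manifest$render_pair`.
#' @param ... passed to [generate_head_phantom()].
#' @return A `head_phantom`.
#' @export
render_specimen <- function(manifest, index, modality, ...) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  if (index < 1 || index > nrow(manifest$entries))
    stop("specimen index out of range")
  render <- manifest$render_pair[[modality]]
  if (is.null(render)) stop("unknown modality: ", modality)
  generate_head_phantom(manifest$specs[[index]], render, ...)
}

#' Serialize a cohort manifest to CSV + JSON sidecar
#' @param manifest a `cohort_manifest`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_manifest <- function(manifest, dir) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "cohort_manifest.csv")
  json <- file.path(dir, "cohort_manifest.json")
  write.csv(manifest$entries, csv, row.names = FALSE)
  jsonlite::write_json(
    list(params = manifest$params,
         spec_template = unclass(manifest$specs[[1]]),
         render_pair = lapply(manifest$render_pair, unclass),
         entries = manifest$entries),
    json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv = csv, json = json))
}
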