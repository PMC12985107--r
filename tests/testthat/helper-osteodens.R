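# Shared fixtures: small (8 mm radius, coarse-voxel) phantoms keep unit
# tests fast; full-scale geometry is exercised only in the acceptance file.

small_spec <- function(density = 150, seed = 7, contrast = 0.2,
                       gradient = 0.1, noise = 0, ...) {
  phantom_spec(head_radius_mm = 8, cortical_thickness_mm = 1.2,
               true_density_mgcm3 = density, texture_contrast = contrast,
               radial_gradient = gradient, noise_sd = noise,
               seed = seed, ...)
}

small_render_pair <- function() {
  list(clinical_ct = render_model("clinical_ct", voxel_mm = 0.8),
       micro_ct = render_model("micro_ct", voxel_mm = 0.4))
}

small_clinical <- function() small_render_pair()$clinical_ct

# identity render: intensity == density
identity_render <- function(voxel = 0.8)
  render_model("clinical_ct", voxel_mm = voxel,
               intensity_slope = 1, intensity_intercept = 0)

# brute-force 3D median filter with border replication (oracle)
naive_median3 <- function(a, k) {
  d <- dim(a)
  h <- k %/% 2
  out <- array(0, d)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    xs <- pmin(pmax((x - h):(x + h), 1), d[1])
    ys <- pmin(pmax((y - h):(y + h), 1), d[2])
    zs <- pmin(pmax((z - h):(z + h), 1), d[3])
    out[x, y, z] <- median(a[xs, ys, zs])
  }
  out
}
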