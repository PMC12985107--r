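test_that("threshold segmentation recovers shell and interior on a clean phantom", {
  sp <- small_spec(density = 150, contrast = 0.2)
  for (mod in c("clinical_ct", "micro_ct")) {
    ph <- generate_head_phantom(sp, small_render_pair()[[mod]])
    map <- segment_compartments(ph$volume, modality_config(mod))
    expect_gte(dice_coefficient(map$cortical_mask, ph$cortical_mask), 0.95)
    expect_gte(dice_coefficient(map$trabecular_mask, ph$trabecular_mask),
               0.95)
    expect_false(any(map$cortical_mask & map$trabecular_mask))
  }
})

test_that("segmentation errors are explicit on degenerate inputs", {
  air <- scalar_volume(array(0, c(6, 6, 6)), 1)
  expect_error(segment_compartments(air, modality_config("clinical_ct")),
               "no cortex")
  # a cortex-only volume has no trabecular compartment
  solid <- array(0, c(10, 10, 10)); solid[3:8, 3:8, 3:8] <- 800
  expect_error(
    segment_compartments(scalar_volume(solid, 1),
                         modality_config("clinical_ct")),
    "trabecular")
})

test_that("compartment maps stay disjoint through refinement", {
  ph <- generate_head_phantom(small_spec(noise = 10, seed = 21),
                              small_clinical())
  map <- segment_compartments(median_filter_3d(ph$volume, 3),
                              modality_config("clinical_ct"))
  ref <- refine_map(map)
  expect_false(any(ref$cortical_mask & ref$trabecular_mask))
  expect_equal(ref$provenance, "refined")
})

test_that("refinement is idempotent on an already clean map", {
  ph <- generate_head_phantom(small_spec(contrast = 0), small_clinical())
  map <- segment_compartments(ph$volume, modality_config("clinical_ct"))
  r1 <- refine_map(map)
  r2 <- refine_map(r1)
  expect_equal(sum(xor(r1$cortical_mask, r2$cortical_mask)), 0)
  expect_equal(sum(xor(r1$trabecular_mask, r2$trabecular_mask)), 0)
})

test_that("closing seals a perforated shell and grows the filled envelope", {
  d <- c(40, 40, 5)
  ring <- array(FALSE, d)
  cx <- 20.5
  for (s in 1:5) {
    rr <- sqrt((row(matrix(0, 40, 40)) - cx)^2 +
               (col(matrix(0, 40, 40)) - cx)^2)
    ring[, , s] <- rr <= 15 & rr > 12
  }
  ring[20:21, 34:36, 3] <- FALSE          # perforate one slice
  blob <- array(FALSE, d); blob[15:26, 15:26, 2:4] <- TRUE
  blob <- blob & !ring
  map <- osteodens:::compartment_map(ring, blob, "auto")
  ref <- refine_map(map, closing_radius_px = 2)
  # oracle: slice-wise hole fill of the refined shell covers the old hole
  filled <- EBImage::fillHull(EBImage::Image(ref$cortical_mask * 1, dim = d))
  filled <- array(EBImage::imageData(filled) > 0.5, d)
  unref <- EBImage::fillHull(EBImage::Image(ring * 1, dim = d))
  unref <- array(EBImage::imageData(unref) > 0.5, d)
  expect_gt(sum(filled), sum(unref))
  expect_true(all(filled[, , 3][(row(matrix(0, 40, 40)) - cx)^2 +
                                (col(matrix(0, 40, 40)) - cx)^2 <= 11^2]))
})

test_that("small trabecular speckle is removed by the component filter", {
  d <- c(30, 30, 6)
  ring <- array(FALSE, d)
  for (s in 1:6) {
    rr <- sqrt((row(matrix(0, 30, 30)) - 15.5)^2 +
               (col(matrix(0, 30, 30)) - 15.5)^2)
    ring[, , s] <- rr <= 12 & rr > 9
  }
  blob <- array(FALSE, d); blob[12:19, 12:19, 2:5] <- TRUE
  speck <- array(FALSE, d); speck[2, 2, c(1, 3, 5)] <- TRUE
  map <- osteodens:::compartment_map(ring, blob | speck, "auto")
  ref <- refine_map(map, min_component_voxels = 5)
  expect_false(any(ref$trabecular_mask[2, 2, ]))
  expect_true(any(ref$trabecular_mask[15, 15, ]))
})

test_that("trabecular density maps the mask mean through the calibration", {
  sp <- small_spec(density = 150, contrast = 0, gradient = 0,
                   lattice_amplitude = 0)
  ph <- generate_head_phantom(sp, identity_render())
  map <- osteodens:::compartment_map(ph$cortical_mask, ph$trabecular_mask,
                                     "auto")
  expect_equal(trabecular_density(ph$volume, map), 150)
  cal <- fit_calibration(data.frame(mean_intensity = c(10, 210, 410),
                                    known_density = c(0, 100, 200)))
  v2 <- ph$volume; v2$values[ph$trabecular_mask] <- 410
  expect_equal(trabecular_density(v2, map, cal), 200, tolerance = 1e-10)
})

test_that("trabecular density is independent of cortical intensities", {
  ph <- generate_head_phantom(small_spec(), small_clinical())
  map <- osteodens:::compartment_map(ph$cortical_mask, ph$trabecular_mask,
                                     "auto")
  v2 <- ph$volume
  v2$values[ph$cortical_mask] <- 9999
  expect_equal(trabecular_density(ph$volume, map),
               trabecular_density(v2, map))
})
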