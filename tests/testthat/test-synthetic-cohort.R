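test_that("identity render reproduces the nominal density exactly", {
  sp <- small_spec(density = 150, contrast = 0, gradient = 0, noise = 0,
                   lattice_amplitude = 0)
  ph <- generate_head_phantom(sp, identity_render())
  expect_true(all(ph$volume$values[ph$trabecular_mask] == 150))
  expect_equal(ph$true_density, 150)
})

test_that("phantom generation is deterministic under a fixed seed", {
  sp <- small_spec(contrast = 0.3, noise = 5, seed = 11)
  r <- small_clinical()
  a <- generate_head_phantom(sp, r)
  b <- generate_head_phantom(sp, r)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$trabecular_mask, b$trabecular_mask)
  # a different seed changes the realization
  c <- generate_head_phantom(small_spec(contrast = 0.3, noise = 5,
                                        seed = 12), r)
  expect_false(identical(a$volume$values, c$volume$values))
})

test_that("interior mask mean matches the nominal density under texture and noise", {
  sp <- small_spec(density = 150, contrast = 0.3, gradient = 0, noise = 5,
                   seed = 3)
  ph <- generate_head_phantom(sp, identity_render())
  px <- ph$volume$values[ph$trabecular_mask]     # brute-force mask mean
  n <- length(px)
  expect_gt(n, 1000)
  # texture is zero-meaned over the mask, so only noise moves the mean
  expect_lt(abs(mean(px) - 150), 3 * sd(px) / sqrt(n))
})

test_that("ground-truth masks partition the head and avoid each other", {
  ph <- generate_head_phantom(small_spec(), small_clinical())
  expect_false(any(ph$cortical_mask & ph$trabecular_mask))
  outside <- !(ph$cortical_mask | ph$trabecular_mask)
  expect_true(all(ph$volume$values[outside] == 0))
})

test_that("noiseless interior mean intensity is strictly monotone in density", {
  r <- small_clinical()
  means <- sapply(c(100, 150, 200), function(d) {
    ph <- generate_head_phantom(small_spec(density = d, noise = 0), r)
    mean(ph$volume$values[ph$trabecular_mask])
  })
  expect_true(all(diff(means) > 0))
})

test_that("noiseless interior means at the two modalities are exactly affinely related", {
  pair <- small_render_pair()
  dens <- c(110, 150, 190)
  m <- sapply(dens, function(d) {
    sp <- small_spec(density = d, contrast = 0.3, noise = 0, seed = 5)
    sapply(pair, function(r) {
      ph <- generate_head_phantom(sp, r)
      mean(ph$volume$values[ph$trabecular_mask])
    })
  })
  # each modality mean is slope * density + intercept exactly
  for (i in 1:2) {
    r <- pair[[i]]
    expect_equal(unname(m[i, ]),
                 r$intensity_slope * dens + r$intensity_intercept,
                 tolerance = 1e-12)
  }
})

test_that("phantom sizing fails when a fixed grid is too small", {
  expect_error(
    generate_head_phantom(small_spec(), small_clinical(),
                          dim = c(5, 5, 5)),
    "does not fit")
})

test_that("calibration phantom insert means follow the affine render exactly", {
  r0 <- identity_render()
  ph <- generate_calibration_phantom(c(0, 100, 200), r0)
  pts <- measure_inserts(ph$volume, ph$insert_masks, ph$insert_densities)
  expect_equal(pts$mean_intensity, c(0, 100, 200))
  r2 <- render_model("clinical_ct", voxel_mm = 0.8,
                     intensity_slope = 2, intensity_intercept = 10)
  ph2 <- generate_calibration_phantom(c(50, 150), r2)
  pts2 <- measure_inserts(ph2$volume, ph2$insert_masks,
                          ph2$insert_densities)
  expect_equal(pts2$mean_intensity, c(110, 310))
  expect_error(generate_calibration_phantom(c(100, 100), r0), "distinct")
})

test_that("cohort structure matches a six-donor bilateral design", {
  man <- generate_cohort(n_donors = 6, bilateral = TRUE, seed = 2)
  e <- man$entries
  expect_equal(nrow(e), 12L)
  expect_equal(length(unique(e$donor_id)), 6L)
  expect_true(all(table(e$donor_id) == 2))
  expect_true(all(sort(unique(e$side)) == c("L", "R")))
  expect_true(all(c("true_density", "sub_seed") %in% names(e)))
  # degenerate variance collapses to the mean
  m0 <- generate_cohort(n_donors = 6, donor_sd = 0, residual_sd = 0,
                        mean_density = 150, seed = 2)
  expect_true(all(m0$entries$true_density == 150))
  expect_error(generate_cohort(n_donors = 1), ">= 2")
})

test_that("donor clustering yields the closed-form intraclass correlation", {
  # ICC = donor_sd^2 / (donor_sd^2 + residual_sd^2) = 900/925 ~ 0.973
  iccs <- sapply(1:200, function(s) {
    d <- generate_cohort(n_donors = 6, donor_sd = 30, residual_sd = 5,
                         seed = s)$entries
    fit <- stats::aov(true_density ~ donor_id, data = d)
    ms <- summary(fit)[[1]]$`Mean Sq`
    (ms[1] - ms[2]) / (ms[1] + ms[2])   # 2 specimens per donor
  })
  expect_gt(mean(iccs), 0.9)
})

test_that("density resampling respects the lower bound", {
  man <- generate_cohort(n_donors = 6, donor_sd = 80, residual_sd = 40,
                         mean_density = 60, min_density = 10, seed = 4)
  expect_true(all(man$entries$true_density >= 10))
})

test_that("sub-seeds are stable hashes independent of generation order", {
  a <- generate_cohort(n_donors = 4, seed = 9)
  b <- generate_cohort(n_donors = 6, seed = 9)
  shared <- intersect(paste(a$entries$donor_id, a$entries$side),
                      paste(b$entries$donor_id, b$entries$side))
  expect_equal(
    a$entries$sub_seed[match(shared, paste(a$entries$donor_id, a$entries$side))],
    b$entries$sub_seed[match(shared, paste(b$entries$donor_id, b$entries$side))])
})

test_that("manifest serializes to CSV and JSON", {
  man <- generate_cohort(n_donors = 3, seed = 1)
  dir <- tempfile("manifest")
  paths <- write_manifest(man, dir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(paths[["csv"]])
  expect_equal(back$true_density, man$entries$true_density)
})
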