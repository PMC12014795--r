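small_spec <- function(n_lesions = 2, ...) {
  phantom_spec(prostate_half_axes = c(16, 14, 12), n_lesions = n_lesions,
               lesion_radius_range = c(4, 7), margin_mm = 6, ...)
}

test_that("cell tables hit the H-Score extremes and converge by LLN", {
  top <- generate_cell_table(c(0, 0, 0, 1), 50, seed = 1)
  expect_true(all(top$level == 3L))
  expect_equal(100 * mean(top$level), 300)

  bot <- generate_cell_table(c(1, 0, 0, 0), 10, seed = 1)
  expect_true(all(bot$level == 0L))

  big <- generate_cell_table(rep(0.25, 4), 1e5, seed = 2)
  expect_lt(abs(100 * mean(big$level) - 150), 2)

  expect_error(generate_cell_table(c(0.5, 0.5), 10), "4 non-negative")
  expect_error(generate_cell_table(c(-1, 1, 0.5, 0.5), 10), "non-negative")
  expect_error(generate_cell_table(c(0, 0, 0, 0), 10), "positive sum")
})

test_that("phantom generation is deterministic and honours its truth", {
  sp <- small_spec(noise_sd = 0.1)
  a <- generate_phantom(sp, 99)
  b <- generate_phantom(sp, 99)
  expect_identical(a$pet$values, b$pet$values)
  expect_identical(a$areas$hscore, b$areas$hscore)
  expect_identical(a$cells, b$cells)

  # recorded truth H-Score equals the H-Score computed from the cell table
  hs <- compute_hscore(a$cells)
  expect_identical(a$areas$hscore,
                   hs$hscore[match(a$areas$area_id, hs$area_id)])
  expect_identical(a$truth$areas$hscore, a$areas$hscore)

  # polygons lie inside the prostate cross-section of their slab
  for (i in seq_len(nrow(a$areas))) {
    v <- a$areas$polygon[[i]][[1]] / 1000
    expect_true(all(rowSums(sweep(v, 2, sp$prostate_half_axes[1:2], "/")^2) <= 1))
  }
})

test_that("a lesion-free phantom is background plus noise only", {
  sp <- small_spec(n_lesions = 0, noise_sd = 0, psf_fwhm = 0)
  suppressWarnings(ph <- generate_phantom(sp, 3))
  expect_equal(nrow(ph$areas), 0L)
  expect_equal(nrow(ph$cells), 0L)
  expect_true(all(ph$pet$values == sp$uptake_background))
})

test_that("noiseless blur-free uptake equals slope x H-Score + background", {
  sp <- phantom_spec(n_lesions = 1, lesion_radius_range = c(8, 8),
                     noise_sd = 0, psf_fwhm = 0, lesion_shape = "box",
                     margin_mm = 6, gtv_threshold = 3)
  ph <- generate_phantom(sp, 7)
  ctr <- ph$truth$lesions$center[[1]]
  vox <- histopet:::world_to_voxel(ph$pet, matrix(ctr, 1))
  holds <- vapply(ph$areas$section, function(s) {
    sb <- histopet:::slab_bounds(s, ph$geom$base_z, ph$geom$slab_thickness)
    ctr[3] >= sb[1] && ctr[3] < sb[2]
  }, logical(1))
  h <- ph$areas$hscore[holds][1]
  expect_equal(ph$pet$values[vox], 0.09 * h + sp$uptake_background,
               tolerance = 1e-12)
})

test_that("impossible lesion packing raises a placement error", {
  sp <- phantom_spec(prostate_half_axes = c(9, 9, 9), n_lesions = 6,
                     lesion_radius_range = c(7, 8), margin_mm = 4)
  expect_error(generate_phantom(sp, 1), class = "histopet_placement_error")
})

test_that("PET simulation: identity, uniform invariance, mass conservation", {
  vol <- scalar_volume(array(stats::runif(15^3), c(15, 15, 15)))
  out <- simulate_pet(vol, psf_fwhm = 0, noise_sd = 0)
  expect_identical(out$values, vol$values)

  unif <- scalar_volume(array(3.7, c(15, 15, 15)))
  bl <- simulate_pet(unif, psf_fwhm = 4.8, noise_sd = 0)
  expect_equal(bl$values[8, 8, 8], 3.7, tolerance = 1e-9)

  # interior hot sphere: total activity preserved by the blur within 0.1%
  hot <- scalar_volume(array(0, c(24, 24, 24)))
  ctr <- c(23, 23, 23)
  for (k in 1:24) {
    xy <- expand.grid(i = 1:24, j = 1:24)
    pts <- cbind((xy$i - 1) * 2, (xy$j - 1) * 2, (k - 1) * 2)
    inside <- rowSums(sweep(pts, 2, ctr, "-")^2) <= 64
    hot$values[, , k][matrix(c(xy$i, xy$j), ncol = 2)[inside, ]] <- 5
  }
  blh <- simulate_pet(hot, psf_fwhm = 4.8, noise_sd = 0)
  expect_lt(abs(sum(blh$values) - sum(hot$values)) / sum(hot$values), 0.001)
})

test_that("blurred sphere centre matches the numerical kernel-integral oracle", {
  # continuum-resolution sphere (0.5 mm grid) so discretisation is negligible
  vol <- empty_volume(c(-12, -12, -12), c(12, 12, 12), spacing = c(0.5, 0.5, 0.5))
  ctr <- c(0, 0, 0)
  reg <- rasterise_region(list(center = ctr, radii = 5), vol, sub_factor = 2)
  vw <- histopet:::voxel_weights(reg)
  vol$values[vw$idx] <- vw$w
  bl <- simulate_pet(vol, psf_fwhm = 4.8, noise_sd = 0)
  centre_vox <- histopet:::world_to_voxel(vol, matrix(ctr, 1))
  rc <- bl$values[centre_vox]
  sigma <- 4.8 / (2 * sqrt(2 * log(2)))
  expect_lt(abs(rc - oracle_blurred_sphere_centre(5, sigma)) /
              oracle_blurred_sphere_centre(5, sigma), 0.02)
})

test_that("centre recovery is non-decreasing in sphere radius (PVE)", {
  rc <- sapply(c(3, 5, 8, 11), function(r) {
    vol <- empty_volume(rep(-r - 8, 3), rep(r + 8, 3), spacing = rep(1, 3))
    reg <- rasterise_region(list(center = c(0, 0, 0), radii = r), vol, 2)
    vw <- histopet:::voxel_weights(reg)
    vol$values[vw$idx] <- vw$w
    bl <- simulate_pet(vol, psf_fwhm = 4.8, noise_sd = 0)
    bl$values[histopet:::world_to_voxel(vol, matrix(0, 1, 3))]
  })
  expect_true(all(diff(rc) >= 0))
  expect_lt(rc[1], 0.9)
  expect_gt(rc[4], 0.99)
})

test_that("negative SUV after noise is clipped at zero", {
  vol <- scalar_volume(array(0.01, c(10, 10, 10)))
  out <- simulate_pet(vol, psf_fwhm = 0, noise_sd = 1, seed = 5)
  expect_gte(min(out$values), 0)
})

test_that("misregistration: degenerate range is the identity, truth recorded", {
  ph <- generate_phantom(small_spec(noise_sd = 0), 12)
  id <- apply_misregistration(ph, range_mm = c(0, 0), seed = 4)
  expect_length(id$chain$steps, 0)
  expect_equal(id$truth$misregistration$translation, c(0, 0, 0))

  five <- apply_misregistration(ph, range_mm = c(5, 5), seed = 4)
  expect_equal(sqrt(sum(five$truth$misregistration$translation^2)), 5)
  expect_length(five$chain$steps, 1)
})

test_that("region-list misregistration round-trips through its inverse", {
  vol <- scalar_volume(array(0, c(16, 16, 16)))
  reg <- rasterise_region(list(center = c(14, 14, 14), radii = 5), vol)
  out <- apply_misregistration(list(reg), range_mm = c(4, 9), seed = 8)
  mr <- attr(out, "misregistration")
  back <- histopet:::region_shift(out[[1]], -mr$translation)
  expect_gt(histopet:::dice_regions(reg, back), 0.99)
})

test_that("two-cohort scenario carries labels, determinism and the 2x slope", {
  sp <- phantom_spec(prostate_half_axes = c(16, 14, 12), n_lesions = 1,
                     lesion_radius_range = c(6, 8), margin_mm = 6,
                     noise_sd = 0, psf_fwhm = 0, uptake_background = 0,
                     lesion_shape = "box", gtv_threshold = 0.5)
  ov <- list(I = list(uptake_slope = 0.09, psf_fwhm = 0),
             II = list(uptake_slope = 0.18, psf_fwhm = 0))
  co <- suppressWarnings(make_cohort(c(I = 2, II = 2), base = sp,
                                     overrides = ov, seed = 6))
  expect_equal(vapply(co, `[[`, character(1), "cohort"),
               c("I", "I", "II", "II"))
  co2 <- suppressWarnings(make_cohort(c(I = 2, II = 2), base = sp,
                                      overrides = ov, seed = 6))
  expect_identical(co[[1]]$pet$values, co2[[1]]$pet$values)

  med <- sapply(co, function(ph) {
    masks <- histopet:::transfer_areas(ph$areas, ph$geom, ph$chain, ph$pet)
    reg <- Reduce(histopet:::region_union, masks)
    hbar <- weighted_hscore(ph$areas$hscore, ph$areas$area_um2)$mean
    extract_uptake_stats(reg, ph$pet)$suv_mean / hbar
  })
  r1 <- stats::median(med[1:2]); r2 <- stats::median(med[3:4])
  expect_lt(abs(r2 / r1 - 2), 0.01)

  expect_error(make_cohort(c(I = 0, II = 2)), "at least one")
})
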