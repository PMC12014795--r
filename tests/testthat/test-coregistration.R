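grid_vol <- function(n = 20, sp = 2) {
  scalar_volume(array(0, c(n, n, n)), spacing = rep(sp, 3),
                origin = rep(-n, 3) + sp / 2 + (n %% 2))
}

# 10 x 10 mm square annotation (in micrometres) on section 3
square_um <- cbind(c(0, 10000, 10000, 0), c(0, 0, 10000, 10000))

test_that("an identity chain extrudes the polygon through its slab", {
  vol <- grid_vol()
  geom <- section_geometry(base_z = -8)
  reg <- transfer_contour(square_um, 3, geom, identity_chain(), vol)
  # 10 x 10 x 4 mm prism = 0.4 ml
  expect_lt(abs(region_volume_ml(reg) - 0.4) / 0.4, 0.01)
  occ <- compute_occupancy(reg)
  expect_true(all(occ$weight <= 1))
})

test_that("transfer is equivariant under a pure translation chain", {
  vol <- grid_vol()
  geom <- section_geometry(base_z = -8)
  a <- transfer_contour(square_um, 3, geom, identity_chain(), vol)
  ch <- transform_chain(rigid_transform(translation = c(10, 0, 0)))
  b <- transfer_contour(square_um, 3, geom, ch, vol)
  shifted <- histopet:::region_shift(a, c(10, 0, 0))
  expect_gt(histopet:::dice_regions(shifted, b), 0.999)
  # occupancy volume preserved under the rigid chain within 1%
  expect_lt(abs(region_volume_ml(a) - region_volume_ml(b)) /
              region_volume_ml(a), 0.01)
})

test_that("occupancy volume is preserved under rotation chains", {
  vol <- grid_vol()
  geom <- section_geometry(base_z = -8)
  poly <- withr::with_seed(
    61, random_simple_polygon(10L, radius = 8000, center = c(2000, -1000),
                                   r_min = 0.7))
  a <- transfer_contour(poly, 3, geom, identity_chain(), vol)
  ch <- transform_chain(rigid_transform(translation = c(3, -2, 0),
                                        rotation_deg = 25))
  b <- transfer_contour(poly, 3, geom, ch, vol)
  expect_lt(abs(region_volume_ml(a) - region_volume_ml(b)) /
              region_volume_ml(a), 0.01)
})

test_that("phantom truth polygons round-trip with high Dice", {
  sp <- phantom_spec(n_lesions = 1, lesion_radius_range = c(8, 8),
                     noise_sd = 0, margin_mm = 6)
  suppressWarnings(ph <- generate_phantom(sp, 21)) # low-H lesion: empty GTV
  i <- which.max(ph$areas$area_um2)
  reg <- transfer_contour(ph$areas$polygon[[i]], ph$areas$section[i],
                          ph$geom, ph$chain, ph$pet)
  # truth: the same polygon extruded directly in world coordinates
  rings <- lapply(ph$areas$polygon[[i]], function(r) r / 1000)
  sb <- histopet:::slab_bounds(ph$areas$section[i], ph$geom$base_z, 4)
  pred <- function(p) {
    p[, 3] >= sb[1] & p[, 3] < sb[2] &
      histopet:::points_in_polygon(p[, 1], p[, 2], rings)
  }
  truth <- rasterise_region(pred, ph$pet, 4)
  expect_gte(histopet:::dice_regions(reg, truth), 0.98)
})

test_that("a displacement-field step is applied and inverted numerically", {
  # smooth small deformation over a coarse field grid
  fdim <- c(8, 8, 8)
  field <- array(0, c(fdim, 3))
  xs <- seq(-20, 20, length.out = 8)
  field[, , , 1] <- outer(sin(xs / 25), rep(1, 8)) |>
    array(dim = fdim) * 1.5
  tr <- histopet:::displacement_transform(field, spacing = rep(40 / 7, 3),
                                          origin = c(-20, -20, -20))
  ch <- transform_chain(tr)
  pts <- matrix(stats::runif(30, -10, 10), ncol = 3)
  fwd <- chain_apply(ch, pts)
  back <- chain_apply_inverse(ch, fwd)
  expect_lt(max(abs(back - pts)), 1e-6)
})

test_that("shape interpolation fills the gap between two equal circles", {
  vol <- grid_vol(24)
  geom <- section_geometry(base_z = -16)
  circ <- circle_polygon(c(0, 0), 8) * 1000
  areas <- tibble::tibble(
    patient = "P", section = c(2L, 4L), area_id = c("a2", "a4"),
    polygon = list(list(circ), list(circ)),
    area_um2 = polygon_area(circ), hscore = c(100, 120))
  masks <- histopet:::transfer_areas(areas, geom, identity_chain(), vol, 4)
  tv <- build_tumour_volume(masks, areas)
  # against the full cylinder through sections 2-4
  pred <- function(p) {
    sb2 <- histopet:::slab_bounds(2, -16, 4)
    sb4 <- histopet:::slab_bounds(4, -16, 4)
    p[, 1]^2 + p[, 2]^2 <= 64 & p[, 3] >= sb2[1] & p[, 3] < sb4[2]
  }
  cyl <- rasterise_region(pred, vol, 4)
  expect_gte(histopet:::dice_regions(tv$region, cyl), 0.95)
  expect_equal(tv$hscore$mean, 110)
})

test_that("single-section volumes stay in their slab (no extrapolation)", {
  vol <- grid_vol(24)
  geom <- section_geometry(base_z = -16)
  circ <- circle_polygon(c(0, 0), 6) * 1000
  areas <- tibble::tibble(patient = "P", section = 3L, area_id = "a",
                          polygon = list(list(circ)),
                          area_um2 = polygon_area(circ), hscore = 50)
  masks <- histopet:::transfer_areas(areas, geom, identity_chain(), vol, 4)
  tv <- build_tumour_volume(masks, areas)
  fp <- histopet:::fine_points(tv$region)
  sb <- histopet:::slab_bounds(3, -16, 4)
  expect_true(all(fp$pts[, 3] >= sb[1] & fp$pts[, 3] < sb[2]))
})

test_that("disjoint lesions are chained into separate tumour volumes", {
  vol <- grid_vol(24)
  geom <- section_geometry(base_z = -16)
  c1 <- circle_polygon(c(-12, -12), 5) * 1000
  c2 <- circle_polygon(c(12, 12), 5) * 1000
  areas <- tibble::tibble(
    patient = "P", section = c(2L, 3L, 2L, 3L),
    area_id = c("l1s2", "l1s3", "l2s2", "l2s3"),
    polygon = list(list(c1), list(c1), list(c2), list(c2)),
    area_um2 = polygon_area(c1), hscore = c(60, 70, 200, 210))
  tvs <- build_tumour_volumes(areas, geom, identity_chain(), vol, 4)
  expect_length(tvs, 2L)
  ids <- sort(unlist(lapply(tvs, `[[`, "constituents")))
  expect_equal(ids, sort(areas$area_id))
})

test_that("tumour areas combine within groups, never across", {
  vol <- grid_vol(24)
  geom <- section_geometry(base_z = -16)
  sq <- cbind(c(0, 8000, 8000, 0), c(0, 0, 8000, 8000))
  mk <- function(id, s, h, dx = 0) {
    tibble::tibble(patient = "P", section = s, area_id = id,
                   polygon = list(list(sq + dx)), area_um2 = polygon_area(sq),
                   hscore = h)
  }
  one_per_group <- dplyr::bind_rows(
    mk("a", 2L, 10), mk("b", 3L, 80), mk("c", 4L, 150), mk("d", 5L, 250))
  tas <- build_tumour_areas(one_per_group, hscore_group_scheme(), geom,
                            identity_chain(), vol)
  expect_length(tas, 4L)
  expect_equal(vapply(tas, `[[`, character(1), "group"),
               c("very_low", "low", "medium", "high"))
  expect_true(all(vapply(tas, function(t) t$hscore$sd, numeric(1)) == 0))

  two_low <- dplyr::bind_rows(mk("a", 2L, 80), mk("b", 3L, 120))
  tas2 <- build_tumour_areas(two_low, hscore_group_scheme(), geom,
                             identity_chain(), vol)
  expect_length(tas2, 1L)
  expect_equal(tas2[[1]]$hscore$mean, 100)
  expect_equal(tas2[[1]]$hscore$sd, 20)
  # constituent ids partition the input
  expect_setequal(unlist(lapply(tas2, `[[`, "constituents")), two_low$area_id)
})

test_that("rigid refinement: identity at optimum, recovery, flat objective", {
  sp <- phantom_spec(n_lesions = 1, lesion_radius_range = c(9, 9),
                     level_probs = list(c(0, 0, 0.2, 0.8)),
                     noise_sd = 0.05, margin_mm = 10)
  ph <- generate_phantom(sp, 31)
  masks <- histopet:::transfer_areas(ph$areas, ph$geom, ph$chain, ph$pet)
  reg <- Reduce(histopet:::region_union, masks)

  centred <- refine_rigid(reg, ph$pet, max_shift_mm = 6)
  expect_lte(sqrt(sum(centred$translation^2)), 1)
  expect_false(centred$flat)

  off <- histopet:::region_shift(reg, c(8, 0, 0))
  rec <- refine_rigid(off, ph$pet)
  expect_lt(sqrt(sum((rec$translation - c(-8, 0, 0))^2)), 2)

  unif <- scalar_volume(array(1, dim(ph$pet$values)), ph$pet$spacing,
                        ph$pet$origin)
  flat <- refine_rigid(reg, unif)
  expect_true(flat$flat)
  expect_equal(flat$translation, c(0, 0, 0))
})
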