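#' Specification of a synthetic prostate/PET phantom
#'
#' Defines the study conditions a synthetic patient is generated under: an
#' ellipsoidal prostate cut into 4 mm whole-mount sections, spherical (or
#' voxel-aligned box) PCa lesions with heterogeneous PSMA expression drawn
#' from per-lesion staining-level mixtures, a linear uptake model
#' `SUV = background + slope * H-Score`, Gaussian scanner blur at the device
#' FWHM, 2 mm PET voxels, additive noise, a threshold-derived GTV and rigid
#' misregistrations in the 1-16 mm range.
#'
#' @param prostate_half_axes ellipsoid half-axes in mm.
#' @param n_lesions number of lesions (0 allowed).
#' @param lesion_radius_range min/max lesion radius in mm; a 2-column matrix
#'   gives one radius band per lesion (rows recycled), e.g. to mix
#'   sub-resolution and large lesions in one patient.
#' @param section_thickness slab thickness in mm (whole-mount sectioning).
#' @param level_probs list of probability 4-vectors over staining levels
#'   0..3, recycled over lesions; the defaults give expected H-Scores of
#'   about 40, 100, 160 and 240, one per expression group.
#' @param n_cells_per_area cells sampled per annotated area.
#' @param uptake_slope SUV (g/ml) per H-Score unit.
#' @param uptake_background background SUV in g/ml.
#' @param noise_sd additive Gaussian noise SD in g/ml (clipped at 0).
#' @param psf_fwhm scanner point-spread FWHM in mm.
#' @param voxel_spacing PET voxel spacing in mm.
#' @param misregistration_range translation magnitude range in mm for
#'   [apply_misregistration()].
#' @param gtv_threshold SUV threshold (g/ml) of the surrogate GTV contour.
#' @param lesion_shape `"sphere"`, or `"box"` for the voxel- and slab-aligned
#'   calibration geometry whose rasterisation is exact.
#' @param margin_mm world margin around the prostate covered by the PET grid.
#' @param paint_sub_factor sub-voxel factor used to paint fractional lesion
#'   occupancy into the true uptake volume.
#' @param area_unit unit label attached to polygon areas (the histological
#'   convention is micrometres squared).
#' @return A validated `phantom_spec` list.
#' @export
phantom_spec <- function(prostate_half_axes = c(20, 17, 15),
                         n_lesions = 3,
                         lesion_radius_range = c(4, 12),
                         section_thickness = 4,
                         level_probs = default_level_probs(),
                         n_cells_per_area = 400,
                         uptake_slope = 0.09,
                         uptake_background = 0.5,
                         noise_sd = 0.3,
                         psf_fwhm = 4.8,
                         voxel_spacing = c(2, 2, 2),
                         misregistration_range = c(1, 16),
                         gtv_threshold = 5,
                         lesion_shape = c("sphere", "box"),
                         margin_mm = 8,
                         paint_sub_factor = 4,
                         area_unit = "um2") {
  lesion_shape <- match.arg(lesion_shape)
  if (is.matrix(lesion_radius_range)) {
    storage.mode(lesion_radius_range) <- "double"
  } else {
    lesion_radius_range <- matrix(as.numeric(lesion_radius_range), 1L, 2L)
  }
  spec <- list(
    prostate_half_axes = as.numeric(prostate_half_axes),
    n_lesions = as.integer(n_lesions),
    lesion_radius_range = lesion_radius_range,
    section_thickness = as.numeric(section_thickness),
    level_probs = lapply(level_probs, as.numeric),
    n_cells_per_area = as.integer(n_cells_per_area),
    uptake_slope = as.numeric(uptake_slope),
    uptake_background = as.numeric(uptake_background),
    noise_sd = as.numeric(noise_sd),
    psf_fwhm = as.numeric(psf_fwhm),
    voxel_spacing = rep_len(as.numeric(voxel_spacing), 3L),
    misregistration_range = as.numeric(misregistration_range),
    gtv_threshold = as.numeric(gtv_threshold),
    lesion_shape = lesion_shape,
    margin_mm = as.numeric(margin_mm),
    paint_sub_factor = as.integer(paint_sub_factor),
    area_unit = area_unit
  )
  with(spec, {
    stopifnot(
      length(prostate_half_axes) == 3L, all(prostate_half_axes > 0),
      n_lesions >= 0L,
      ncol(lesion_radius_range) == 2L, all(lesion_radius_range > 0),
      all(lesion_radius_range[, 1] <= lesion_radius_range[, 2]),
      section_thickness > 0,
      n_cells_per_area >= 1L,
      uptake_slope >= 0, uptake_background >= 0, noise_sd >= 0, psf_fwhm >= 0,
      all(voxel_spacing > 0),
      length(misregistration_range) == 2L,
      misregistration_range[1] >= 0,
      misregistration_range[1] <= misregistration_range[2],
      gtv_threshold > 0, margin_mm >= 0, paint_sub_factor >= 1L
    )
    if (misregistration_range[2] > 16) {
      stop("misregistration_range must lie within [0, 16] mm", call. = FALSE)
    }
    if (max(lesion_radius_range[, 2]) >= min(prostate_half_axes)) {
      stop("largest lesion radius must be smaller than the smallest ",
           "prostate half-axis", call. = FALSE)
    }
    for (p in level_probs) {
      if (length(p) != 4L || any(!is.finite(p)) || any(p < 0) || sum(p) <= 0) {
        stop("each level_probs entry must be 4 non-negative weights with ",
             "positive sum", call. = FALSE)
      }
    }
  })
  structure(spec, class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_level_probs <- function() {
  list(
    c(0.70, 0.20, 0.10, 0.00), # E[H] =  40, "very_low"
    c(0.30, 0.40, 0.30, 0.00), # E[H] = 100, "low"
    c(0.15, 0.30, 0.35, 0.20), # E[H] = 160, "medium"
    c(0.00, 0.10, 0.40, 0.50)  # E[H] = 240, "high"
  )
}

#' Sample a cell-level staining table
#'
#' Draws `n_cells` independent staining levels from a categorical
#' distribution over levels 0..3. The empirical H-Score of the table
#' converges to `100 * sum(0:3 * probs)` as `n_cells` grows.
#'
#' @param level_probs non-negative weights over levels 0..3 (normalised
#'   internally; a non-normalisable vector is an error).
#' @param n_cells number of cells (>= 1).
#' @param area_id area identifier attached to every row.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return Tibble `(area_id, cell_id, level)`.
#' @examples
#' generate_cell_table(c(0, 0, 0, 1), 5, seed = 1) # all level 3, H = 300
#' @export
generate_cell_table <- function(level_probs, n_cells, area_id = "area1",
                                seed = NULL) {
  p <- as.numeric(level_probs)
  if (length(p) != 4L || any(!is.finite(p)) || any(p < 0) || sum(p) <= 0) {
    stop("`level_probs` must be 4 non-negative finite weights with a ",
         "positive sum", call. = FALSE)
  }
  n_cells <- as.integer(n_cells)
  stopifnot(n_cells >= 1L)
  draw <- function() sample(0:3, n_cells, replace = TRUE, prob = p / sum(p))
  lv <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble::tibble(area_id = area_id, cell_id = seq_len(n_cells),
                 level = as.integer(lv))
}

#' Simulate PET acquisition of a true uptake volume
#'
#' Applies the scanner point-spread function as an isotropic Gaussian blur in
#' world millimetres (`sigma = fwhm / (2 sqrt(2 ln 2))`, per-axis sigma in
#' voxel units for anisotropic grids) followed by i.i.d. additive Gaussian
#' noise; negative values after noise are clipped at 0. The blur kernel is
#' normalised so total activity away from the grid boundary is conserved.
#' The blur is what produces the partial volume effect: small hot lesions
#' appear larger and less bright.
#'
#' @param true_uptake a [scalar_volume()] of true SUV values.
#' @param psf_fwhm point-spread FWHM in mm (>= 0; 0 means no blur).
#' @param noise_sd additive noise SD in g/ml (>= 0).
#' @param seed optional integer seed for the noise draw.
#' @return A `scalar_volume` of simulated PET SUV.
#' @export
simulate_pet <- function(true_uptake, psf_fwhm, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(true_uptake, "scalar_volume"),
            psf_fwhm >= 0, noise_sd >= 0)
  out <- gaussian_blur(true_uptake, psf_fwhm)
  if (noise_sd > 0) {
    add_noise <- function() {
      out$values <- out$values +
        array(stats::rnorm(length(out$values), sd = noise_sd), dim(out$values))
      out$values[out$values < 0] <- 0
      out
    }
    out <- if (is.null(seed)) add_noise() else withr::with_seed(seed, add_noise())
  }
  out
}

## z-interval of section s: [base_z + (s-1) t, base_z + s t)
slab_bounds <- function(s, base_z, thickness) {
  c(base_z + (s - 1) * thickness, base_z + s * thickness)
}

## sample one lesion geometry inside the prostate, away from existing
## lesions; box lesions are snapped to voxel/slab boundaries before the
## overlap and containment checks so the accepted geometry is the final one
place_lesion <- function(spec, existing, base_z, lesion = 1L,
                         max_attempts = 500L) {
  ha <- spec$prostate_half_axes
  rr <- spec$lesion_radius_range
  band <- rr[((lesion - 1L) %% nrow(rr)) + 1L, ]
  for (a in seq_len(max_attempts)) {
    r <- stats::runif(1, band[1], band[2])
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2)) * stats::runif(1)^(1 / 3)
    ctr <- u * (ha - r)
    if (spec$lesion_shape == "box") {
      geo <- snap_box(ctr, r, spec$voxel_spacing, base_z,
                      spec$section_thickness)
      geo$radius <- r
      corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
      pts <- sweep(corners * rep(geo$half, each = 8), 2, geo$center, "+")
      if (any(rowSums(sweep(pts, 2, ha, "/")^2) > 1)) next
      ok <- TRUE
      for (e in existing) {
        gap <- abs(geo$center - e$center) - (geo$half + e$half)
        if (all(gap < 0)) ok <- FALSE
      }
      if (ok) return(geo)
    } else {
      ok <- TRUE
      for (e in existing) {
        if (sqrt(sum((ctr - e$center)^2)) <= r + e$radius + 1) ok <- FALSE
      }
      if (ok) return(list(center = ctr, radius = r))
    }
  }
  stop(structure(
    class = c("histopet_placement_error", "error", "condition"),
    list(message = sprintf(
      "could not place %d non-overlapping lesions in %d attempts",
      spec$n_lesions, max_attempts), call = NULL)
  ))
}

## snap a box lesion to voxel boundaries in-plane and slab boundaries in z
snap_box <- function(center, radius, spacing, base_z, thickness) {
  hx <- spacing[1] * max(1, round(radius / spacing[1]))
  hy <- spacing[2] * max(1, round(radius / spacing[2]))
  hz <- thickness * max(1, round(radius / thickness))
  cx <- spacing[1] * round(center[1] / spacing[1])
  cy <- spacing[2] * round(center[2] / spacing[2])
  cz <- base_z + thickness * round((center[3] - base_z) / thickness)
  list(center = c(cx, cy, cz), half = c(hx, hy, hz))
}

#' Generate one synthetic patient with full ground truth
#'
#' Builds the complete bundle a real patient would contribute: per-section
#' lesion polygons in section micrometres (the histological annotation
#' export), a cell-level staining table per area, the true uptake volume
#' painted from the linear uptake model with the per-area H-Scores actually
#' realised in the cell tables, the simulated PET (blur + noise), a
#' threshold-surrogate GTV, an identity transform chain, and a truth record.
#' Deterministic given `(spec, seed)`.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @param patient_id identifier attached to all outputs.
#' @return A `phantom` bundle: list with elements `patient_id`, `spec`,
#'   `areas` (tibble with list-column `polygon`), `cells`, `pet`,
#'   `true_uptake`, `gtv`, `chain`, `truth`, `cohort`.
#' @export
generate_phantom <- function(spec, seed, patient_id = "P01") {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(as.integer(seed), {
    ha <- spec$prostate_half_axes
    t <- spec$section_thickness
    base_z <- -t * ceiling(ha[3] / t)
    n_sections <- as.integer(2 * ceiling(ha[3] / t))
    vol <- empty_volume(-(ha + spec$margin_mm), ha + spec$margin_mm,
                        spacing = spec$voxel_spacing)

    ## a large early lesion can make the remaining placements infeasible;
    ## restart the whole constellation rather than fail on one bad draw
    lesions <- NULL
    for (outer in 1:20) {
      lesions <- tryCatch({
        tmp <- list()
        for (l in seq_len(spec$n_lesions)) {
          geo <- place_lesion(spec, tmp, base_z, lesion = l)
          probs <- spec$level_probs[[((l - 1L) %% length(spec$level_probs)) + 1L]]
          tmp[[l]] <- c(geo, list(lesion_id = l, probs = probs))
        }
        tmp
      }, histopet_placement_error = function(e) NULL)
      if (!is.null(lesions)) break
    }
    if (is.null(lesions)) {
      stop(structure(
        class = c("histopet_placement_error", "error", "condition"),
        list(message = sprintf(
          "could not place %d non-overlapping lesions (20 restarts)",
          spec$n_lesions), call = NULL)
      ))
    }

    areas <- list(); cells <- list()
    uptake <- vol
    uptake$values[] <- spec$uptake_background
    for (les in lesions) {
      zr <- if (spec$lesion_shape == "box") {
        les$center[3] + c(-1, 1) * les$half[3]
      } else {
        les$center[3] + c(-1, 1) * les$radius
      }
      for (s in seq_len(n_sections)) {
        sb <- slab_bounds(s, base_z, t)
        zmid <- mean(sb)
        poly <- NULL
        if (spec$lesion_shape == "box") {
          if (zmid > zr[1] && zmid < zr[2]) {
            h <- les$half
            poly <- cbind(
              les$center[1] + c(-h[1], h[1], h[1], -h[1]),
              les$center[2] + c(-h[2], -h[2], h[2], h[2])
            ) * 1000 # mm -> um
          }
        } else {
          dz <- zmid - les$center[3]
          if (abs(dz) < les$radius) {
            rs <- sqrt(les$radius^2 - dz^2)
            if (rs >= 0.8) {
              poly <- circle_polygon(les$center[1:2], rs) * 1000
            }
          }
        }
        if (is.null(poly)) next
        aid <- sprintf("%s_L%02d_S%02d", patient_id, les$lesion_id, s)
        tab <- generate_cell_table(les$probs, spec$n_cells_per_area,
                                   area_id = aid)
        h <- 100 * mean(tab$level)
        areas[[length(areas) + 1L]] <- tibble::tibble(
          patient = patient_id, section = s, area_id = aid,
          lesion_id = les$lesion_id,
          label = sprintf("lesion%02d", les$lesion_id),
          polygon = list(list(poly)), area_um2 = polygon_area(poly),
          hscore = h
        )
        cells[[length(cells) + 1L]] <- tab
        ## paint this lesion-slab into the true uptake volume
        pred <- if (spec$lesion_shape == "box") {
          local({
            ctr <- les$center; hf <- les$half; lo <- sb[1]; hi <- sb[2]
            function(p) {
              abs(p[, 1] - ctr[1]) < hf[1] & abs(p[, 2] - ctr[2]) < hf[2] &
                p[, 3] >= lo & p[, 3] < hi
            }
          })
        } else {
          local({
            ctr <- les$center; rr <- les$radius; lo <- sb[1]; hi <- sb[2]
            function(p) {
              rowSums(sweep(p, 2, ctr, "-")^2) <= rr^2 &
                p[, 3] >= lo & p[, 3] < hi
            }
          })
        }
        bb <- if (spec$lesion_shape == "box") {
          rbind(les$center - les$half, les$center + les$half)
        } else {
          rbind(les$center - les$radius, les$center + les$radius)
        }
        bb[, 3] <- sb
        reg <- rasterise_region(pred, vol, sub_factor = spec$paint_sub_factor,
                                bbox = bb)
        vw <- voxel_weights(reg)
        if (nrow(vw$idx)) {
          uptake$values[vw$idx] <- uptake$values[vw$idx] +
            spec$uptake_slope * h * vw$w
        }
      }
    }

    areas <- if (length(areas)) dplyr::bind_rows(areas) else tibble::tibble(
      patient = character(), section = integer(), area_id = character(),
      lesion_id = integer(), label = character(), polygon = list(),
      area_um2 = numeric(), hscore = numeric()
    )
    cells <- if (length(cells)) dplyr::bind_rows(cells) else tibble::tibble(
      area_id = character(), cell_id = integer(), level = integer()
    )

    pet <- simulate_pet(uptake, spec$psf_fwhm, spec$noise_sd)
    gtv <- contour_gtv(pet, spec$gtv_threshold, min_component_voxels = 2L)

    geom <- section_geometry(slab_thickness = t, base_z = base_z)
    truth <- list(
      lesions = tibble::tibble(
        lesion_id = vapply(lesions, `[[`, integer(1), "lesion_id"),
        center = lapply(lesions, `[[`, "center"),
        radius = vapply(lesions, function(l) as.numeric(l$radius), numeric(1)),
        shape = spec$lesion_shape
      ),
      areas = areas[, c("area_id", "lesion_id", "section", "hscore",
                        "area_um2")],
      uptake_slope = spec$uptake_slope,
      uptake_background = spec$uptake_background,
      gtv_threshold = spec$gtv_threshold,
      base_z = base_z, n_sections = n_sections,
      misregistration = NULL
    )
    structure(
      list(patient_id = patient_id, spec = spec, areas = areas, cells = cells,
           pet = pet, true_uptake = uptake, gtv = gtv,
           chain = identity_chain(), geom = geom, truth = truth,
           cohort = NA_character_),
      class = "phantom"
    )
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "<phantom> patient %s (cohort %s): %d histo-areas on %d sections, PET %s\n",
    x$patient_id, x$cohort, nrow(x$areas), x$truth$n_sections,
    paste(dim(x$pet$values), collapse = "x")
  ))
  invisible(x)
}

#' Inject a known rigid misregistration
#'
#' Emulates the residual co-registration error that the study's final visual
#' position correction (translations of 1-16 mm) had to fix. For a `phantom`,
#' a rigid step with translation magnitude drawn uniformly from `range_mm`
#' (direction uniform on the sphere) and an optional small rotation about the
#' section axis is appended to the transform chain, and the truth transform
#' is recorded for recovery experiments. For a list of `region_mask`s the
#' masks themselves are displaced. `range_mm = c(0, 0)` with zero rotation is
#' exactly the identity.
#'
#' @param x a `phantom` or a list of `region_mask` objects.
#' @param range_mm translation magnitude interval in mm (within \[0, 16\]).
#' @param seed integer seed.
#' @param rotation_max_deg rotation magnitude bound in degrees (<= 5).
#' @param ... unused.
#' @return Displaced object; for phantoms, `truth$misregistration` holds
#'   `translation` and `rotation_deg`; for region lists, an attribute
#'   `"misregistration"` does.
#' @export
apply_misregistration <- function(x, range_mm = c(1, 16), seed = 1,
                                  rotation_max_deg = 0, ...) {
  UseMethod("apply_misregistration")
}

sample_misreg <- function(range_mm, rotation_max_deg) {
  stopifnot(length(range_mm) == 2L, range_mm[1] >= 0,
            range_mm[1] <= range_mm[2], range_mm[2] <= 16,
            rotation_max_deg >= 0, rotation_max_deg <= 5)
  mag <- stats::runif(1, range_mm[1], range_mm[2])
  if (mag == 0 && rotation_max_deg == 0) {
    return(list(translation = c(0, 0, 0), rotation_deg = 0))
  }
  u <- stats::rnorm(3)
  u <- u / sqrt(sum(u^2))
  th <- if (rotation_max_deg > 0) {
    stats::runif(1, -rotation_max_deg, rotation_max_deg)
  } else 0
  list(translation = mag * u, rotation_deg = th)
}

#' @export
apply_misregistration.phantom <- function(x, range_mm = x$spec$misregistration_range,
                                          seed = 1, rotation_max_deg = 0, ...) {
  mr <- withr::with_seed(as.integer(seed),
                         sample_misreg(range_mm, rotation_max_deg))
  if (any(mr$translation != 0) || mr$rotation_deg != 0) {
    x$chain <- chain_append(
      x$chain,
      rigid_transform(mr$translation, mr$rotation_deg, center = c(0, 0, 0))
    )
  }
  x$truth$misregistration <- mr
  x
}

#' @export
apply_misregistration.list <- function(x, range_mm = c(1, 16), seed = 1,
                                       rotation_max_deg = 0, ...) {
  stopifnot(length(x) > 0, all(vapply(x, inherits, logical(1), "region_mask")))
  if (rotation_max_deg != 0) {
    stop("rotation of rasterised region lists is not supported; ",
         "misregister the phantom chain instead", call. = FALSE)
  }
  mr <- withr::with_seed(as.integer(seed), sample_misreg(range_mm, 0))
  out <- lapply(x, region_shift, t_mm = mr$translation)
  attr(out, "misregistration") <- mr
  out
}

#' Generate a two-cohort synthetic study
#'
#' Builds the cohort structure of a two-tracer study: `n_patients["I"]`
#' patients imaged with the first tracer and `n_patients["II"]` with the
#' second, each cohort with its own uptake slope, scanner FWHM and GTV
#' threshold. The default cohort II slope (0.19 g/ml per H-Score unit) is
#' about twice the cohort I slope (0.09), emulating the roughly doubled
#' median uptake observed with the second tracer.
#'
#' @param n_patients named vector `c(I = , II = )`, both >= 1.
#' @param base a [phantom_spec()] shared by both cohorts.
#' @param overrides named list of per-cohort spec overrides.
#' @param misregister logical: inject a random misregistration per patient?
#' @param rotation_max_deg rotation bound passed to
#'   [apply_misregistration()].
#' @param seed integer master seed; patient seeds are derived from it.
#' @return List of `phantom` bundles with `cohort` labels `"I"` / `"II"`.
#' @export
make_cohort <- function(n_patients = c(I = 2, II = 2),
                        base = phantom_spec(),
                        overrides = list(
                          I = list(uptake_slope = 0.09, psf_fwhm = 4.8,
                                   gtv_threshold = 5),
                          II = list(uptake_slope = 0.19, psf_fwhm = 4.2,
                                    gtv_threshold = 10)
                        ),
                        misregister = FALSE, rotation_max_deg = 0,
                        seed = 1) {
  if (is.null(names(n_patients))) names(n_patients) <- c("I", "II")
  if (any(n_patients < 1)) {
    stop("each cohort needs at least one patient", call. = FALSE)
  }
  labels <- rep(names(n_patients), times = n_patients)
  n <- length(labels)
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max %/% 2, 2L * n))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    co <- labels[i]
    spec_i <- base
    for (nm in names(overrides[[co]])) spec_i[[nm]] <- overrides[[co]][[nm]]
    spec_i <- do.call(phantom_spec, unclass(spec_i)[names(formals(phantom_spec))])
    ph <- generate_phantom(spec_i, seeds[i],
                           patient_id = sprintf("P%02d", i))
    ph$cohort <- co
    if (misregister) {
      ph <- apply_misregistration(ph, range_mm = spec_i$misregistration_range,
                                  seed = seeds[n + i],
                                  rotation_max_deg = rotation_max_deg)
    }
    out[[i]] <- ph
  }
  out
}
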