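#' Sub-voxel uptake statistics of a region
#'
#' Computes SUVmean, SUVmax and in-vivo volume of a fractional-occupancy
#' region directly on the PET grid, without interpolating or resampling SUV
#' values: `suv_mean` is the occupancy-weighted mean of the voxel SUVs,
#' `suv_max` the maximum SUV over voxels whose occupancy passes
#' `max_occupancy_floor` (with the default floor of 0, any overlap counts —
#' voxels with strictly positive weight), and `volume_ml` the sum of
#' fractional weights times the voxel volume. `volume_voxel_ml` additionally
#' reports the volume by whole-voxel inclusion.
#'
#' @param weights per-voxel occupancy: a tibble from [compute_occupancy()]
#'   (columns `i, j, k, weight`), or a `region_mask`.
#' @param pet the PET [scalar_volume()] (SUV in g/ml).
#' @param max_occupancy_floor minimum occupancy for SUVmax eligibility; 0
#'   means any positive overlap.
#' @return One-row tibble `(suv_mean, suv_max, volume_ml, volume_voxel_ml,
#'   n_voxels)`.
#' @examples
#' pet <- scalar_volume(array(5, c(3, 3, 3)))
#' w <- tibble::tibble(i = 2, j = 2, k = 2, weight = 1)
#' extract_uptake_stats(w, pet) # mean 5, max 5, volume 0.008 ml
#' @export
extract_uptake_stats <- function(weights, pet, max_occupancy_floor = 0) {
  stopifnot(inherits(pet, "scalar_volume"))
  if (inherits(weights, "region_mask")) weights <- compute_occupancy(weights)
  stopifnot(all(c("i", "j", "k", "weight") %in% names(weights)))
  if (nrow(weights) == 0L || sum(weights$weight) <= 0) {
    stop("region has no occupancy on the PET grid", call. = FALSE)
  }
  suv <- pet$values[cbind(weights$i, weights$j, weights$k)]
  w <- weights$weight
  elig <- if (max_occupancy_floor <= 0) w > 0 else w >= max_occupancy_floor
  if (!any(elig)) {
    stop("no voxel reaches max_occupancy_floor = ", max_occupancy_floor,
         "; reduce the floor", call. = FALSE)
  }
  vox_ml <- prod(pet$spacing) / 1000
  tibble::tibble(
    suv_mean = sum(w * suv) / sum(w),
    suv_max = max(suv[elig]),
    volume_ml = sum(w) * vox_ml,
    volume_voxel_ml = sum(w > 0) * vox_ml,
    n_voxels = sum(w > 0)
  )
}

#' Threshold-surrogate gross tumour volume
#'
#' Replaces manual windowed PET contouring with a fixed SUV threshold:
#' voxels at or above `threshold` form the GTV, after removing connected
#' components (26-connectivity) smaller than `min_component_voxels`. An
#' empty GTV is a valid outcome and returns an empty mask with a warning.
#'
#' @param pet the PET [scalar_volume()].
#' @param threshold SUV threshold in g/ml (> 0).
#' @param min_component_voxels smallest component kept.
#' @return A binary `scalar_volume` (unit `"1"`) on the PET grid.
#' @export
contour_gtv <- function(pet, threshold, min_component_voxels = 1L) {
  stopifnot(inherits(pet, "scalar_volume"), threshold > 0,
            min_component_voxels >= 1L)
  m <- pet$values >= threshold
  if (any(m) && min_component_voxels > 1L) {
    lab <- label_components_26(m)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_component_voxels)
    m <- array(lab %in% keep, dim(m))
  }
  if (!any(m)) warning("GTV is empty at threshold ", threshold)
  scalar_volume(array(as.numeric(m), dim(m)), spacing = pet$spacing,
                origin = pet$origin, unit = "1")
}

#' GTV agreement of a co-registered tumour region
#'
#' The proportion of a tumour area's extent that lies inside the PET GTV:
#' like a Sorensen-Dice coefficient but normalised by the region alone,
#' `sum(w_v [v in GTV]) / sum(w_v)` over the fractional occupancy weights.
#' Always in \[0, 1\]; an empty GTV gives 0.
#'
#' @param weights per-voxel occupancy (tibble from [compute_occupancy()] or a
#'   `region_mask`).
#' @param gtv binary GTV mask as a `scalar_volume` on the same grid.
#' @return Single numeric agreement fraction.
#' @export
gtv_agreement <- function(weights, gtv) {
  stopifnot(inherits(gtv, "scalar_volume"))
  if (inherits(weights, "region_mask")) weights <- compute_occupancy(weights)
  if (nrow(weights) == 0L || sum(weights$weight) <= 0) {
    stop("region has no occupancy on the PET grid", call. = FALSE)
  }
  inside <- gtv$values[cbind(weights$i, weights$j, weights$k)] > 0
  sum(weights$weight * inside) / sum(weights$weight)
}
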