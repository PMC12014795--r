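## RegionMask: a 3D region represented at sub-voxel resolution -------------
##
## A region lives on the "fine grid" of a parent volume: each parent voxel is
## split into sub_factor^3 fine cells. `fine` holds occupancy values in [0, 1]
## on a bounding box of that grid; `f_off` is the (0-based) global fine index
## offset of fine[1, 1, 1]. Keeping regions at sub-voxel resolution is what
## lets uptake statistics be extracted without resampling the PET grid, so
## small tumour regions are not lost to interpolation.

region_mask <- function(fine, f_off, sub_factor, vol_dim, spacing, origin) {
  stopifnot(length(dim(fine)) == 3L)
  structure(
    list(fine = fine, f_off = as.integer(f_off),
         sub_factor = as.integer(sub_factor),
         vol_dim = as.integer(vol_dim),
         spacing = as.numeric(spacing), origin = as.numeric(origin)),
    class = "region_mask"
  )
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf(
    "<region_mask> sub_factor %d, fine bbox %s, occupancy volume %.3f ml\n",
    x$sub_factor, paste(dim(x$fine), collapse = " x "),
    region_volume_ml(x)
  ))
  invisible(x)
}

fine_spacing <- function(region) region$spacing / region$sub_factor

## world coordinates of fine-cell centres for global fine indices f (1-based)
fine_coord <- function(region, f, axis) {
  fs <- region$spacing[axis] / region$sub_factor
  region$origin[axis] - region$spacing[axis] / 2 + (f - 0.5) * fs
}

## world coords (n x 3) and weights of all occupied fine cells
fine_points <- function(region, min_w = 0) {
  idx <- which(region$fine > min_w)
  if (length(idx) == 0L) {
    return(list(pts = matrix(0, 0, 3), w = numeric(0)))
  }
  ai <- arrayInd(idx, dim(region$fine))
  pts <- vapply(1:3, function(ax) {
    fine_coord(region, region$f_off[ax] + ai[, ax], ax)
  }, numeric(nrow(ai)))
  list(pts = matrix(pts, ncol = 3L), w = region$fine[idx])
}

#' Total region volume in millilitres
#'
#' Sum of fractional fine-cell occupancy times the fine-cell volume.
#'
#' @param region a `region_mask`.
#' @return volume in ml.
#' @export
region_volume_ml <- function(region) {
  sum(region$fine) * prod(fine_spacing(region)) / 1000
}

#' Rasterise a world-space region onto the fine grid of a volume
#'
#' Evaluates `fun` (a predicate of world coordinates, or an ellipsoid
#' specification `list(center =, radii =)`) at the centres of the fine cells
#' inside `bbox` (clipped to the volume extent) and returns the resulting
#' sub-voxel occupancy mask.
#'
#' @param fun either `function(pts)` returning a logical/numeric occupancy for
#'   an n x 3 matrix of world points, or a list with `center` and `radii`
#'   describing an axis-aligned ellipsoid in mm.
#' @param vol parent [scalar_volume()] defining grid, spacing and origin.
#' @param sub_factor fine cells per voxel edge (>= 1).
#' @param bbox optional 2 x 3 matrix (rows lo, hi) of the world bounding box;
#'   defaults to the full volume.
#' @return A `region_mask`; empty regions are allowed (a warning is given when
#'   the requested box lies fully outside the grid).
#' @export
rasterise_region <- function(fun, vol, sub_factor = 4L, bbox = NULL) {
  sub_factor <- as.integer(sub_factor)
  stopifnot(sub_factor >= 1L)
  if (is.list(fun) && !is.function(fun)) {
    ell <- fun
    stopifnot(length(ell$center) == 3L, length(ell$radii) %in% c(1L, 3L))
    radii <- rep_len(ell$radii, 3L)
    ctr <- ell$center
    if (is.null(bbox)) bbox <- rbind(ctr - radii, ctr + radii)
    fun <- function(pts) {
      rowSums(sweep(sweep(pts, 2, ctr, "-"), 2, radii, "/")^2) <= 1
    }
  }
  ext <- grid_extent(vol)
  if (is.null(bbox)) bbox <- ext
  lo <- pmax(bbox[1, ], ext[1, ])
  hi <- pmin(bbox[2, ], ext[2, ])
  d <- dim(vol$values)
  fs <- vol$spacing / sub_factor
  empty <- region_mask(array(0, c(1, 1, 1)), c(0L, 0L, 0L), sub_factor,
                       d, vol$spacing, vol$origin)
  if (any(hi <= lo)) {
    warning("region lies outside the volume grid; returning empty mask")
    return(empty)
  }
  ## global fine index range covering [lo, hi]
  base <- vol$origin - vol$spacing / 2
  f0 <- pmax(1L, as.integer(floor((lo - base) / fs)) + 1L)
  f1 <- pmin(d * sub_factor, as.integer(ceiling((hi - base) / fs)))
  nf <- f1 - f0 + 1L
  xs <- base[1] + (seq.int(f0[1], f1[1]) - 0.5) * fs[1]
  ys <- base[2] + (seq.int(f0[2], f1[2]) - 0.5) * fs[2]
  zs <- base[3] + (seq.int(f0[3], f1[3]) - 0.5) * fs[3]
  fine <- array(0, nf)
  layer <- cbind(rep(xs, times = nf[2]), rep(ys, each = nf[1]), 0)
  for (k in seq_len(nf[3])) {
    layer[, 3] <- zs[k]
    fine[, , k] <- as.numeric(fun(layer))
  }
  region_mask(fine, f0 - 1L, sub_factor, d, vol$spacing, vol$origin)
}

## aggregate one array axis (first) in blocks of `sub`, given global offset;
## pads with zeros so blocks align with parent voxel boundaries
agg_axis1 <- function(a, sub, off) {
  d <- dim(a)
  pad_l <- off %% sub
  pad_r <- (sub - (off + d[1]) %% sub) %% sub
  if (pad_l > 0 || pad_r > 0) {
    b <- array(0, c(pad_l + d[1] + pad_r, d[2], d[3]))
    b[pad_l + seq_len(d[1]), , ] <- a
    a <- b
    d <- dim(a)
  }
  dim(a) <- c(sub, d[1] / sub, d[2] * d[3])
  out <- colSums(a)
  dim(out) <- c(d[1] / sub, d[2], d[3])
  out
}

## per-voxel occupancy: returns list(idx = n x 3 voxel indices, w = weights,
## v_off = voxel offset of the aggregated bbox)
voxel_weights <- function(region) {
  a <- region$fine
  sub <- region$sub_factor
  off <- region$f_off
  v_off <- integer(3)
  for (ax in 1:3) {
    a <- aperm(a, c(ax, setdiff(1:3, ax)))
    a <- agg_axis1(a, sub, off[ax])
    a <- aperm(a, order(c(ax, setdiff(1:3, ax))))
    v_off[ax] <- off[ax] %/% sub
  }
  a <- a / sub^3
  idx <- which(a > 0)
  ai <- arrayInd(idx, dim(a))
  keep <- rep(TRUE, nrow(ai))
  vidx <- sweep(ai, 2, v_off, "+")
  for (ax in 1:3) keep <- keep & vidx[, ax] >= 1L & vidx[, ax] <= region$vol_dim[ax]
  list(idx = vidx[keep, , drop = FALSE], w = a[idx][keep],
       dim = region$vol_dim)
}

#' Fractional per-voxel occupancy of a region
#'
#' Aggregates a sub-voxel region to the parent PET grid: the weight of a voxel
#' is the fraction of its `sub_factor`^3 fine cells covered by the region.
#' The sum of weights times the voxel volume converges to the true region
#' volume as `sub_factor` grows.
#'
#' @param region a `region_mask`, or a geometry accepted by
#'   [rasterise_region()] (predicate function or ellipsoid list), in which
#'   case `volume` must be supplied.
#' @param volume parent [scalar_volume()] (required when `region` is a
#'   geometry).
#' @param sub_factor fine cells per voxel edge used for rasterisation.
#' @return A tibble with voxel indices `i, j, k` and `weight` in (0, 1].
#'   For analytic ellipsoid geometries the eligible support is computed
#'   exactly (a separable clamp test of the voxel box against the
#'   ellipsoid), so voxels the region grazes by less than one fine cell are
#'   still included — with half a fine cell's occupancy — and the support
#'   does not depend on `sub_factor`.
#' @examples
#' vol <- scalar_volume(array(1, c(6, 6, 6)))
#' occ <- compute_occupancy(list(center = c(5, 5, 5), radii = 3), vol)
#' sum(occ$weight) * 8 / 1000 # ml, close to 4/3 pi 3^3 / 1000
#' @export
compute_occupancy <- function(region, volume = NULL, sub_factor = 4L) {
  ellipsoid <- NULL
  if (!inherits(region, "region_mask")) {
    if (is.null(volume)) {
      stop("`volume` is required when `region` is a geometry", call. = FALSE)
    }
    if (is.list(region) && !is.function(region)) ellipsoid <- region
    region <- rasterise_region(region, volume, sub_factor = sub_factor)
  }
  vw <- voxel_weights(region)
  out <- tibble::tibble(i = vw$idx[, 1], j = vw$idx[, 2], k = vw$idx[, 3],
                        weight = vw$w)
  if (!is.null(ellipsoid)) {
    extra <- grazed_voxels(ellipsoid, volume, out)
    if (nrow(extra)) {
      extra$weight <- 0.5 / region$sub_factor^3
      out <- dplyr::bind_rows(out, extra)
    }
  }
  out
}

## voxels whose box exactly intersects an axis-aligned ellipsoid but carry no
## sampled occupancy; the box/ellipsoid test clamps the centre to the box
## per axis, which minimises the separable convex ellipsoid form exactly
grazed_voxels <- function(ell, vol, occ) {
  ctr <- ell$center
  radii <- rep_len(ell$radii, 3L)
  d <- dim(vol$values)
  lo_i <- pmax(1L, world_to_voxel(vol, matrix(ctr - radii, 1)))
  hi_i <- pmin(d, world_to_voxel(vol, matrix(ctr + radii, 1)))
  if (any(hi_i < lo_i)) return(occ[0, ])
  g <- expand.grid(i = lo_i[1]:hi_i[1], j = lo_i[2]:hi_i[2],
                   k = lo_i[3]:hi_i[3])
  s <- 0
  for (ax in 1:3) {
    cen <- vol$origin[ax] + (g[[ax]] - 1) * vol$spacing[ax]
    nearest <- pmin(pmax(ctr[ax], cen - vol$spacing[ax] / 2),
                    cen + vol$spacing[ax] / 2)
    s <- s + ((nearest - ctr[ax]) / radii[ax])^2
  }
  hit <- s <= 1
  key <- paste(g$i, g$j, g$k)
  have <- paste(occ$i, occ$j, occ$k)
  sel <- hit & !(key %in% have)
  tibble::tibble(i = g$i[sel], j = g$j[sel], k = g$k[sel],
                 weight = 0)
}

## shift a region by a world translation (rounded to whole fine cells)
region_shift <- function(region, t_mm) {
  fs <- fine_spacing(region)
  region$f_off <- region$f_off + as.integer(round(t_mm / fs))
  region
}

#' Union of two regions on the same parent grid
#'
#' Combines two sub-voxel regions by taking the per-fine-cell occupancy
#' maximum; both must share the parent volume grid and sub-resolution.
#'
#' @param a,b `region_mask` objects.
#' @return A `region_mask` covering both.
#' @export
region_union <- function(a, b) {
  stopifnot(a$sub_factor == b$sub_factor, all(a$vol_dim == b$vol_dim))
  lo <- pmin(a$f_off, b$f_off)
  hi <- pmax(a$f_off + dim(a$fine), b$f_off + dim(b$fine))
  fine <- array(0, hi - lo)
  ia <- a$f_off - lo
  sel_a <- lapply(1:3, function(ax) ia[ax] + seq_len(dim(a$fine)[ax]))
  fine[sel_a[[1]], sel_a[[2]], sel_a[[3]]] <- a$fine
  ib <- b$f_off - lo
  sel_b <- lapply(1:3, function(ax) ib[ax] + seq_len(dim(b$fine)[ax]))
  fine[sel_b[[1]], sel_b[[2]], sel_b[[3]]] <-
    pmax(fine[sel_b[[1]], sel_b[[2]], sel_b[[3]]], b$fine)
  region_mask(fine, lo, a$sub_factor, a$vol_dim, a$spacing, a$origin)
}

## Dice coefficient between two regions (fractional occupancy)
dice_regions <- function(a, b) {
  lo <- pmin(a$f_off, b$f_off)
  hi <- pmax(a$f_off + dim(a$fine), b$f_off + dim(b$fine))
  fa <- array(0, hi - lo); fb <- array(0, hi - lo)
  ia <- a$f_off - lo
  fa[ia[1] + seq_len(dim(a$fine)[1]), ia[2] + seq_len(dim(a$fine)[2]),
     ia[3] + seq_len(dim(a$fine)[3])] <- a$fine
  ib <- b$f_off - lo
  fb[ib[1] + seq_len(dim(b$fine)[1]), ib[2] + seq_len(dim(b$fine)[2]),
     ib[3] + seq_len(dim(b$fine)[3])] <- b$fine
  2 * sum(pmin(fa, fb)) / (sum(fa) + sum(fb))
}

## region occupancy as a scalar_volume on the parent grid (for NIfTI export)
region_as_volume <- function(region) {
  vw <- voxel_weights(region)
  a <- array(0, vw$dim)
  a[vw$idx] <- vw$w
  scalar_volume(a, spacing = region$spacing, origin = region$origin, unit = "1")
}

## inverse of region_as_volume: a weights volume as a sub_factor-1 region
region_from_weights_volume <- function(vol) {
  region_mask(vol$values, c(0L, 0L, 0L), 1L, dim(vol$values),
              vol$spacing, vol$origin)
}
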