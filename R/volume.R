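#' Axis-aligned 3D scalar volume
#'
#' Light container for a 3D image on a regular axis-aligned grid in world
#' millimetres. PET volumes carry standardised uptake values (SUV) in g/ml;
#' masks carry 0/1 or fractional occupancy. `origin` is the world coordinate
#' of the centre of voxel `[1, 1, 1]`; the centre of voxel `[i, j, k]` is
#' `origin + (c(i, j, k) - 1) * spacing`. The axis convention (x, y, z with z
#' running from prostate base toward apex) is used consistently for all
#' volumes, masks and transforms in the package.
#'
#' @param values numeric 3D array.
#' @param spacing voxel edge lengths in mm (length 3, strictly positive).
#' @param origin world coordinate (mm) of the centre of the first voxel.
#' @param unit value unit label; `"g/ml"` for PET SUV, `"1"` for masks.
#' @return A `scalar_volume` object.
#' @examples
#' vol <- scalar_volume(array(0, c(4, 4, 4)), spacing = c(2, 2, 2))
#' dim(vol$values)
#' @export
scalar_volume <- function(values, spacing = c(2, 2, 2), origin = c(0, 0, 0),
                          unit = "g/ml") {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive numbers (mm)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("volume values must be finite", call. = FALSE)
  }
  structure(
    list(values = values, spacing = spacing, origin = origin, unit = unit),
    class = "scalar_volume"
  )
}

#' @export
print.scalar_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<scalar_volume> %d x %d x %d voxels, spacing %s mm, origin %s mm, unit %s\n",
    d[1], d[2], d[3],
    paste(format(x$spacing), collapse = " x "),
    paste(format(x$origin), collapse = ", "),
    x$unit
  ))
  cat(sprintf("  value range [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.scalar_volume <- function(x) dim(x$values)

## world coordinates of voxel centres along one axis
axis_coords <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$values)[axis]) - 1) * vol$spacing[axis]
}

## world extent of the grid (outer voxel faces), 2 x 3 matrix (lo, hi)
grid_extent <- function(vol) {
  d <- dim(vol$values)
  lo <- vol$origin - vol$spacing / 2
  hi <- vol$origin + (d - 0.5) * vol$spacing
  rbind(lo = lo, hi = hi)
}

## voxel index (possibly outside 1..dim) containing world point(s);
## pts is an n x 3 matrix, returns n x 3 integer matrix
world_to_voxel <- function(vol, pts) {
  idx <- sweep(pts, 2, vol$origin, "-")
  idx <- sweep(idx, 2, vol$spacing, "/")
  matrix(as.integer(floor(idx + 0.5)) + 1L, ncol = 3L)
}

#' Create an empty volume covering a world extent
#'
#' Builds a zero-filled [scalar_volume()] whose voxel grid covers at least
#' `[lo, hi]` in each axis at the requested spacing, with voxel faces at
#' integer multiples of the spacing (so phantom geometry can be aligned to
#' voxel boundaries when needed).
#'
#' @param lo,hi world corners in mm (length-3).
#' @param spacing voxel spacing in mm.
#' @param unit value unit label.
#' @return A `scalar_volume` of zeros.
#' @export
empty_volume <- function(lo, hi, spacing = c(2, 2, 2), unit = "g/ml") {
  spacing <- rep_len(as.numeric(spacing), 3L)
  i0 <- floor(lo / spacing)
  i1 <- ceiling(hi / spacing)
  d <- pmax(as.integer(i1 - i0), 1L)
  scalar_volume(array(0, d), spacing = spacing,
                origin = (i0 + 0.5) * spacing, unit = unit)
}

## separable Gaussian convolution along the first array axis, sigma in voxels;
## zero padding outside the grid, kernel normalised to unit sum so interior
## activity is conserved
blur_axis1 <- function(a, sigma_vox) {
  if (sigma_vox <= 0) return(a)
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  k <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  k <- k / sum(k)
  d <- dim(a)
  n <- d[1]
  off <- outer(seq_len(n), seq_len(n), "-") # i - j in [-(n-1), n-1]
  m <- matrix(0, n, n)
  sel <- abs(off) <= r
  m[sel] <- k[off[sel] + r + 1L]
  dim(a) <- c(n, prod(d[-1]))
  a <- m %*% a
  dim(a) <- d
  a
}

## isotropic world-space Gaussian blur: per-axis sigma in voxel units
gaussian_blur <- function(vol, fwhm_mm) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(vol)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  a <- vol$values
  for (ax in 1:3) {
    a <- aperm(a, c(ax, setdiff(1:3, ax)))
    a <- blur_axis1(a, sigma_mm / vol$spacing[ax])
    a <- aperm(a, order(c(ax, setdiff(1:3, ax))))
  }
  out <- vol
  out$values <- a
  out
}

## 26-connected component labels on a logical 3D array (union-find over the
## sparse foreground); returns integer array, 0 = background
label_components_26 <- function(mask) {
  d <- dim(mask)
  fg <- which(mask)
  lab <- array(0L, d)
  if (length(fg) == 0L) return(lab)
  ord <- fg # already sorted ascending
  pos <- arrayInd(ord, d)
  parent <- seq_along(ord)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # forward half of the 26-neighbourhood (13 offsets)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[(offs[, 3] > 0) |
                 (offs[, 3] == 0 & (offs[, 2] > 0 | (offs[, 2] == 0 & offs[, 1] > 0))), ,
               drop = FALSE]
  lin <- function(p) (p[, 3] - 1) * d[1] * d[2] + (p[, 2] - 1) * d[1] + p[, 1]
  idx_of <- integer(prod(d))
  idx_of[ord] <- seq_along(ord)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(pos, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
      nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nl <- lin(nb[ok, , drop = FALSE])
    j <- idx_of[nl]
    hit <- which(j > 0L)
    ii <- which(ok)[hit]
    jj <- j[hit]
    for (q in seq_along(ii)) {
      a <- find(ii[q]); b <- find(jj[q])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_along(ord), find, integer(1))
  lab[ord] <- match(roots, unique(roots))
  lab
}
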