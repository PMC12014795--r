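## Polygon utilities ---------------------------------------------------------
##
## A polygon is a list of rings under the even-odd fill rule; ring 1 is the
## outer boundary, further rings are holes. A ring is an n x 2 numeric matrix
## of vertices (not closed: first vertex is not repeated). A bare matrix is
## accepted as a single-ring polygon. Annotation coordinates are in section
## micrometres.

as_polygon <- function(polygon) {
  if (is.matrix(polygon)) polygon <- list(polygon)
  if (!is.list(polygon) || length(polygon) == 0L) {
    stop("polygon must be a ring matrix or a non-empty list of rings",
         call. = FALSE)
  }
  lapply(polygon, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2L || nrow(r) < 3L) {
      stop("each polygon ring needs >= 3 vertices with 2 coordinates",
           call. = FALSE)
    }
    # drop a closing vertex repeated from the first
    if (nrow(r) > 3L && all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    storage.mode(r) <- "double"
    unname(r)
  })
}

shoelace <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(seq_len(nrow(ring))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

## do two segments (p1,p2) and (p3,p4) properly intersect?
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

validate_ring_simple <- function(ring) {
  n <- nrow(ring)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (a in seq_len(n - 1L)) {
    for (b in seq((a + 1L), n)) {
      # skip adjacent segments (shared vertex)
      if (b == a + 1L || (a == 1L && b == n)) next
      if (segments_cross(ring[idx[a, 1], ], ring[idx[a, 2], ],
                         ring[idx[b, 1], ], ring[idx[b, 2], ])) {
        stop("self-intersecting polygon ring", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Polygon surface area
#'
#' Shoelace area of a simple polygon, holes subtracted (even-odd rule with
#' ring 1 as the outer boundary). Used for the histological surface area of
#' annotated PCa areas, in the unit of the vertex coordinates squared
#' (micrometres squared for section annotations).
#'
#' @param polygon a ring matrix (n x 2) or list of ring matrices.
#' @return Single non-negative numeric area.
#' @examples
#' polygon_area(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' @export
polygon_area <- function(polygon) {
  rings <- as_polygon(polygon)
  for (r in rings) validate_ring_simple(r)
  outer_a <- abs(shoelace(rings[[1]]))
  holes <- if (length(rings) > 1L) {
    sum(vapply(rings[-1], function(r) abs(shoelace(r)), numeric(1)))
  } else 0
  a <- outer_a - holes
  if (a <= 0) stop("degenerate polygon: non-positive area", call. = FALSE)
  a
}

## vectorised even-odd point-in-polygon over all rings
points_in_polygon <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (ring in rings) {
    x <- ring[, 1]; y <- ring[, 2]
    n <- length(x)
    jx <- x[c(n, seq_len(n - 1L))]
    jy <- y[c(n, seq_len(n - 1L))]
    for (k in seq_len(n)) {
      xi <- x[k]; yi <- y[k]; xj <- jx[k]; yj <- jy[k]
      if (yi == yj) next
      cross <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, cross)
    }
  }
  inside
}

## regular n-gon approximation of a circle, optionally radially perturbed
circle_polygon <- function(center, radius, n = 64L, wobble = 0, rng = NULL) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- rep(radius, n)
  if (wobble > 0) r <- r * (1 + wobble * sin(3 * th + stats::runif(1, 0, 2 * pi)))
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

## Affine transforms and chains ----------------------------------------------

#' Affine and rigid 3D transforms
#'
#' `affine_transform()` wraps a 4 x 4 homogeneous matrix mapping world mm to
#' world mm. `rigid_transform()` builds rotation (degrees about the z axis,
#' around `center`) followed by translation. Transforms are composed into a
#' [transform_chain()] and applied in declared order.
#'
#' @param matrix 4 x 4 homogeneous affine matrix.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(matrix) {
  matrix <- as.matrix(matrix)
  stopifnot(all(dim(matrix) == c(4L, 4L)))
  if (abs(det(matrix[1:3, 1:3])) < 1e-12) {
    stop("affine transform is not invertible", call. = FALSE)
  }
  structure(list(type = "affine", matrix = unname(matrix)),
            class = "affine_transform")
}

#' @rdname affine_transform
#' @param translation length-3 translation in mm.
#' @param rotation_deg rotation about the z (section) axis in degrees.
#' @param center rotation centre in world mm.
#' @export
rigid_transform <- function(translation = c(0, 0, 0), rotation_deg = 0,
                            center = c(0, 0, 0)) {
  th <- rotation_deg * pi / 180
  r <- diag(3)
  r[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  m <- diag(4)
  m[1:3, 1:3] <- r
  m[1:3, 4] <- translation + center - r %*% center
  affine_transform(m)
}

## dense displacement step: x' = x + D(x), D trilinear-interpolated
displacement_transform <- function(field, spacing, origin) {
  stopifnot(length(dim(field)) == 4L, dim(field)[4] == 3L)
  structure(list(type = "displacement", field = field,
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "displacement_transform")
}

#' Ordered chain of co-registration transforms
#'
#' Collects the transform steps that carry a histological section frame into
#' the PET world frame: section to ex-vivo CT (rigid per section), ex-vivo to
#' in-vivo CT (affine, optionally followed by a dense displacement field) and
#' in-vivo CT to PET (rigid). Steps are applied in the declared order. Every
#' step must be invertible (displacement fields numerically, by fixed-point
#' iteration).
#'
#' @param ... transform steps (`affine_transform` / `displacement_transform`).
#' @return A `transform_chain`.
#' @examples
#' ch <- transform_chain(rigid_transform(translation = c(5, 0, 0)))
#' chain_apply(ch, matrix(0, 1, 3))
#' @export
transform_chain <- function(...) {
  steps <- list(...)
  if (length(steps) == 1L && is.list(steps[[1]]) &&
      !inherits(steps[[1]], c("affine_transform", "displacement_transform"))) {
    steps <- steps[[1]]
  }
  ok <- vapply(steps, inherits, logical(1),
               what = c("affine_transform", "displacement_transform"))
  if (length(steps) && !all(ok)) {
    stop("chain steps must be affine or displacement transforms", call. = FALSE)
  }
  structure(list(steps = steps), class = "transform_chain")
}

#' @rdname transform_chain
#' @export
identity_chain <- function() transform_chain()

interp_field <- function(tr, pts) {
  d <- dim(tr$field)[1:3]
  g <- sweep(sweep(pts, 2, tr$origin, "-"), 2, tr$spacing, "/") + 1
  g <- pmin(pmax(g, 1), matrix(rep(d, each = nrow(pts)), ncol = 3))
  i0 <- pmin(floor(g), matrix(rep(d - 1L, each = nrow(pts)), ncol = 3))
  f <- g - i0
  out <- matrix(0, nrow(pts), 3)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
      (if (dy) f[, 2] else 1 - f[, 2]) *
      (if (dz) f[, 3] else 1 - f[, 3])
    ii <- cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)
    for (c3 in 1:3) {
      out[, c3] <- out[, c3] + w * tr$field[cbind(ii, c3)]
    }
  }
  out
}

step_apply <- function(tr, pts, inverse = FALSE) {
  if (tr$type == "affine") {
    m <- if (inverse) solve(tr$matrix) else tr$matrix
    sweep(pts %*% t(m[1:3, 1:3]), 2, m[1:3, 4], "+")
  } else {
    if (!inverse) {
      pts + interp_field(tr, pts)
    } else {
      x <- pts
      for (it in 1:20) x <- pts - interp_field(tr, x)
      x
    }
  }
}

#' @rdname transform_chain
#' @param chain a `transform_chain`.
#' @param pts n x 3 matrix of world points (mm).
#' @export
chain_apply <- function(chain, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  for (s in chain$steps) pts <- step_apply(s, pts)
  pts
}

#' @rdname transform_chain
#' @export
chain_apply_inverse <- function(chain, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  for (s in rev(chain$steps)) pts <- step_apply(s, pts, inverse = TRUE)
  pts
}

## append a step to a chain (used to inject misregistration)
chain_append <- function(chain, step) {
  transform_chain(c(chain$steps, list(step)))
}
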