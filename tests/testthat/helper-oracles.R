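# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# supersampled rasterisation estimate of a polygon's area (even-odd rule
# re-implemented from scratch over a point grid)
oracle_polygon_area <- function(rings, n_grid = 400L) {
  allv <- do.call(rbind, rings)
  xr <- range(allv[, 1]); yr <- range(allv[, 2])
  xs <- seq(xr[1], xr[2], length.out = n_grid)
  ys <- seq(yr[1], yr[2], length.out = n_grid)
  px <- rep(xs, times = n_grid); py <- rep(ys, each = n_grid)
  crossings <- integer(length(px))
  for (ring in rings) {
    m <- nrow(ring)
    for (k in seq_len(m)) {
      p1 <- ring[k, ]; p2 <- ring[if (k == m) 1L else k + 1L, ]
      if (p1[2] == p2[2]) next
      hit <- ((p1[2] > py) != (p2[2] > py)) &
        (px < p1[1] + (p2[1] - p1[1]) * (py - p1[2]) / (p2[2] - p1[2]))
      crossings <- crossings + hit
    }
  }
  cell <- diff(xr) * diff(yr) / n_grid^2
  sum(crossings %% 2L == 1L) * cell
}

# centre value of a unit-intensity sphere of radius R blurred with an
# isotropic Gaussian of SD sigma: radial numerical integration of the kernel
oracle_blurred_sphere_centre <- function(radius, sigma) {
  f <- function(r) r^2 / sigma^3 * sqrt(2 / pi) * exp(-r^2 / (2 * sigma^2))
  stats::integrate(f, 0, radius, rel.tol = 1e-10)$value
}

# Spearman's rho from first principles: average ranks by sorting, then the
# Pearson product-moment formula written out longhand
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    n <- length(v)
    r <- numeric(n)
    for (i in seq_len(n)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# textbook Dunn z statistics, coded independently (explicit rank sums and
# tie correction)
oracle_dunn_z <- function(groups) {
  vals <- unlist(groups)
  n <- length(vals)
  r <- rank(vals)
  idx <- rep(seq_along(groups), lengths(groups))
  rs <- tapply(r, idx, sum)
  ni <- lengths(groups)
  tie <- 0
  for (v in unique(vals)) {
    t <- sum(vals == v)
    tie <- tie + (t^3 - t)
  }
  A <- n * (n + 1) / 12 - tie / (12 * (n - 1))
  out <- c()
  for (a in seq_along(groups)) {
    for (b in seq_along(groups)) {
      if (b <= a) next
      z <- (rs[[a]] / ni[a] - rs[[b]] / ni[b]) /
        sqrt(A * (1 / ni[a] + 1 / ni[b]))
      out <- c(out, z)
    }
  }
  out
}

# tie-corrected Kruskal-Wallis H from the rank-sum formula
oracle_kw_h <- function(groups) {
  vals <- unlist(groups)
  n <- length(vals)
  r <- rank(vals)
  idx <- rep(seq_along(groups), lengths(groups))
  rs <- tapply(r, idx, sum)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / lengths(groups)) - 3 * (n + 1)
  tie <- 0
  for (v in unique(vals)) {
    t <- sum(vals == v)
    tie <- tie + (t^3 - t)
  }
  h / (1 - tie / (n^3 - n))
}

# a random star-shaped simple polygon (never self-intersecting)
random_simple_polygon <- function(n = 12L, radius = 1, center = c(0, 0),
                                  r_min = 0.4) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, r_min, 1) * radius
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# small uniform test volume with reproducible noise values
random_volume <- function(dim = c(16, 16, 16), spacing = c(2, 2, 2),
                          origin = c(0, 0, 0)) {
  scalar_volume(array(stats::runif(prod(dim), 1, 10), dim),
                spacing = spacing, origin = origin)
}
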