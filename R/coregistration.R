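#' Slab geometry of whole-mount sectioning
#'
#' The resected prostate is cut perpendicular to the urethra into slabs of
#' `slab_thickness` mm, numbered from the prostate base; section `s` occupies
#' the half-open world interval `[base_z + (s-1) t, base_z + s t)` along the
#' section normal (the z axis). In-plane annotation coordinates are
#' micrometres, converted with `scale_um_per_mm`.
#'
#' @param slab_thickness section thickness in mm (default 4, the cutting
#'   interval of the localizer grid).
#' @param base_z world z of the basal face of section 1, in mm.
#' @param scale_um_per_mm in-plane scale of annotation coordinates.
#' @return A `section_geometry` object.
#' @export
section_geometry <- function(slab_thickness = 4, base_z = 0,
                             scale_um_per_mm = 1000) {
  stopifnot(slab_thickness > 0, scale_um_per_mm > 0)
  structure(list(slab_thickness = slab_thickness, base_z = base_z,
                 scale_um_per_mm = scale_um_per_mm),
            class = "section_geometry")
}

#' Transfer a 2D section annotation into the 3D PET frame
#'
#' Extrudes a histo-area polygon through its 4 mm slab, maps it through the
#' co-registration transform chain into the PET world frame, and rasterises
#' it to fractional occupancy on the sub-voxel grid of the PET volume. Parts
#' mapped outside the PET grid are clipped with a warning; a region that is
#' entirely outside is an error.
#'
#' @param polygon annotation polygon in section micrometres (matrix or list
#'   of rings, even-odd rule).
#' @param section section index (1 = prostate base).
#' @param geom a [section_geometry()].
#' @param chain a [transform_chain()] carrying section frame to PET frame.
#' @param vol the PET [scalar_volume()] whose grid defines the rasterisation.
#' @param sub_factor sub-voxel resolution factor (default 4, i.e. masks at
#'   1/4 of the PET spacing).
#' @return A `region_mask`.
#' @export
transfer_contour <- function(polygon, section, geom, chain, vol,
                             sub_factor = 4L) {
  stopifnot(inherits(geom, "section_geometry"),
            inherits(chain, "transform_chain"),
            inherits(vol, "scalar_volume"), section >= 1)
  rings_mm <- lapply(as_polygon(polygon), function(r) r / geom$scale_um_per_mm)
  sb <- slab_bounds(section, geom$base_z, geom$slab_thickness)
  ## world bbox from forward-transformed extruded vertices
  verts <- do.call(rbind, rings_mm)
  ext <- rbind(cbind(verts, sb[1]), cbind(verts, sb[2]))
  fwd <- chain_apply(chain, ext)
  pad <- max(vol$spacing)
  bbox <- rbind(apply(fwd, 2, min) - pad, apply(fwd, 2, max) + pad)
  pred <- function(pts) {
    p <- chain_apply_inverse(chain, pts)
    p[, 3] >= sb[1] & p[, 3] < sb[2] &
      points_in_polygon(p[, 1], p[, 2], rings_mm)
  }
  reg <- rasterise_region(pred, vol, sub_factor = sub_factor, bbox = bbox)
  if (sum(reg$fine) == 0) {
    stop("transferred contour is empty after clipping to the PET grid",
         call. = FALSE)
  }
  reg
}

## transfer every area of a patient; returns named list of region_masks
transfer_areas <- function(areas, geom, chain, vol, sub_factor = 4L) {
  masks <- lapply(seq_len(nrow(areas)), function(i) {
    transfer_contour(areas$polygon[[i]], areas$section[i], geom, chain, vol,
                     sub_factor = sub_factor)
  })
  names(masks) <- areas$area_id
  masks
}

## 2D footprint (max over z) of a region's fine array, with xy offset
footprint <- function(region) {
  list(m = apply(region$fine, c(1, 2), max), off = region$f_off[1:2])
}

## do two footprints overlap in-plane?
footprints_overlap <- function(a, b) {
  lo <- pmax(a$off, b$off)
  hi <- pmin(a$off + dim(a$m), b$off + dim(b$m))
  if (any(hi <= lo)) return(FALSE)
  sa <- a$m[(lo[1] - a$off[1] + 1):(hi[1] - a$off[1]),
            (lo[2] - a$off[2] + 1):(hi[2] - a$off[2]), drop = FALSE]
  sb <- b$m[(lo[1] - b$off[1] + 1):(hi[1] - b$off[1]),
            (lo[2] - b$off[2] + 1):(hi[2] - b$off[2]), drop = FALSE]
  any(sa > 0 & sb > 0)
}

#' Chain histo-areas into longitudinal lesions
#'
#' Which histo-areas belong to one longitudinal lesion is decided by
#' adjacency: areas on consecutive sections whose transferred masks overlap
#' in-plane are chained into the same lesion (transitively). Areas on the
#' same section never merge.
#'
#' @param areas tibble of histo-areas (needs `area_id`, `section`).
#' @param masks named list of transferred `region_mask`s, one per area.
#' @return Integer lesion assignment, parallel to rows of `areas`.
#' @export
chain_lesions <- function(areas, masks) {
  n <- nrow(areas)
  if (n == 0L) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  fps <- lapply(areas$area_id, function(id) footprint(masks[[id]]))
  for (a in seq_len(n - 1L)) {
    for (b in seq((a + 1L), n)) {
      if (abs(areas$section[a] - areas$section[b]) != 1L) next
      if (footprints_overlap(fps[[a]], fps[[b]])) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

## signed distance (mm) of a 2D binary mask, positive inside
signed_distance_2d <- function(m, px_mm) {
  storage.mode(m) <- "double"
  d_in <- EBImage::distmap(m)
  d_out <- EBImage::distmap(1 - m)
  (d_in - d_out) * px_mm
}

#' Interpolate per-section masks into a longitudinal tumour volume
#'
#' Pathway 1: the per-section masks of one lesion are interpolated along the
#' section axis by shape-based (signed-distance) blending, filling the slabs
#' between consecutive occupied sections. No extrapolation beyond the first
#' and last occupied slab is performed. The H-Score of the volume is the
#' area-weighted mean of its constituent histo-areas, with the area-weighted
#' SD alongside.
#'
#' @param masks list of transferred `region_mask`s of the lesion's areas.
#' @param areas tibble of the same areas (needs `area_id`, `section`,
#'   `hscore`, `area_um2`, and a single `patient`).
#' @return A `tumour_volume`: list with `region`, `constituents`, `hscore`
#'   (one-row tibble from [weighted_hscore()]).
#' @export
build_tumour_volume <- function(masks, areas) {
  stopifnot(length(masks) >= 1L, nrow(areas) == length(masks))
  if (length(unique(areas$patient)) > 1L) {
    stop("constituent areas must come from a single patient", call. = FALSE)
  }
  reg <- Reduce(region_union, masks)
  fine <- reg$fine
  nz <- dim(fine)[3]
  occ_layer <- which(vapply(seq_len(nz), function(k) any(fine[, , k] > 0),
                            logical(1)))
  if (length(occ_layer) >= 2L) {
    px <- fine_spacing(reg)[1]
    sdf_cache <- list()
    get_sdf <- function(k) {
      key <- as.character(k)
      if (is.null(sdf_cache[[key]])) {
        sdf_cache[[key]] <<- signed_distance_2d(fine[, , k] > 0.5, px)
      }
      sdf_cache[[key]]
    }
    gaps <- setdiff(seq(min(occ_layer), max(occ_layer)), occ_layer)
    for (k in gaps) {
      k0 <- max(occ_layer[occ_layer < k])
      k1 <- min(occ_layer[occ_layer > k])
      alpha <- (k - k0) / (k1 - k0)
      sd_blend <- (1 - alpha) * get_sdf(k0) + alpha * get_sdf(k1)
      fine[, , k] <- as.numeric(sd_blend > 0)
    }
  }
  reg$fine <- fine
  structure(
    list(region = reg, constituents = areas$area_id,
         hscore = weighted_hscore(areas$hscore, areas$area_um2)),
    class = "tumour_volume"
  )
}

#' Build all tumour volumes of a patient (pathway 1)
#'
#' Transfers every histo-area, chains areas into lesions by consecutive-
#' section overlap, and interpolates each lesion into a [build_tumour_volume()]
#' result. Disjoint lesions are never bridged.
#'
#' @inheritParams build_tumour_areas
#' @return List of `tumour_volume` objects.
#' @export
build_tumour_volumes <- function(areas, geom, chain, vol, sub_factor = 4L,
                                 masks = NULL) {
  if (nrow(areas) == 0L) return(list())
  if (is.null(masks)) masks <- transfer_areas(areas, geom, chain, vol, sub_factor)
  lesion <- chain_lesions(areas, masks)
  lapply(unique(lesion), function(l) {
    sel <- lesion == l
    build_tumour_volume(masks[areas$area_id[sel]], areas[sel, ])
  })
}

#' Combine histo-areas of one H-Score group into a tumour area (pathway 2)
#'
#' All histo-areas of a patient falling in the same H-Score group are
#' combined into a single 3D tumour area confined to the constituent slabs
#' (no interpolation along the section axis). Each tumour area carries the
#' area-weighted mean and SD of its constituents' H-Scores; the SD measures
#' the expression resolution lost by combining.
#'
#' @param areas tibble of a single patient's histo-areas (`patient`,
#'   `section`, `area_id`, `polygon`, `area_um2`, `hscore`).
#' @param scheme an [hscore_group_scheme()].
#' @param geom a [section_geometry()].
#' @param chain a [transform_chain()].
#' @param vol the PET [scalar_volume()].
#' @param sub_factor sub-voxel resolution factor.
#' @param masks optional pre-computed list of transferred masks per area id.
#' @return List of `tumour_area` objects (`group`, `constituents`, `region`,
#'   `hscore`), at most one per group.
#' @export
build_tumour_areas <- function(areas, scheme = hscore_group_scheme(),
                               geom = section_geometry(), chain = identity_chain(),
                               vol = NULL, sub_factor = 4L, masks = NULL) {
  if (nrow(areas) == 0L) return(list())
  if (length(unique(areas$patient)) > 1L) {
    stop("areas must come from a single patient", call. = FALSE)
  }
  if (is.null(masks)) masks <- transfer_areas(areas, geom, chain, vol, sub_factor)
  grp <- assign_group(areas$hscore, scheme)
  out <- list()
  for (g in levels(grp)) {
    sel <- which(grp == g)
    if (length(sel) == 0L) next
    reg <- Reduce(region_union, masks[areas$area_id[sel]])
    out[[length(out) + 1L]] <- structure(
      list(group = g, constituents = areas$area_id[sel], region = reg,
           hscore = weighted_hscore(areas$hscore[sel], areas$area_um2[sel])),
      class = "tumour_area"
    )
  }
  out
}

#' Automated rigid position refinement against the PET signal
#'
#' Surrogate for the study's final visual position correction: searches small
#' rigid displacements of a co-registered region (translations up to
#' `max_shift_mm`, optionally a rotation about the section axis) for the one
#' maximising the occupancy-weighted SUVmean of the region, on a
#' coarse-to-fine grid (`coarse_step_mm`, then `fine_step_mm` around the
#' coarse optimum). Deterministic; ties are broken toward the smallest
#' displacement magnitude, then lexicographically by axis. A flat objective
#' (e.g. uniform PET) returns the identity with `flat = TRUE`.
#'
#' @param region a `region_mask`.
#' @param pet the PET [scalar_volume()].
#' @param max_shift_mm translation search bound (<= 16 mm, the range of the
#'   manual correction this replaces).
#' @param coarse_step_mm,fine_step_mm grid steps of the two search stages.
#' @param rot_max_deg rotation search bound in degrees (<= 5; 0 disables
#'   rotation search).
#' @param rot_step_deg rotation grid step.
#' @return List with `translation` (mm), `rotation_deg`, `region` (displaced
#'   copy), `objective` (best weighted SUVmean), `trace` (tibble of evaluated
#'   candidates) and `flat`.
#' @export
refine_rigid <- function(region, pet, max_shift_mm = 16, coarse_step_mm = 2,
                         fine_step_mm = 0.5, rot_max_deg = 0,
                         rot_step_deg = 2.5) {
  stopifnot(inherits(region, "region_mask"), inherits(pet, "scalar_volume"),
            max_shift_mm >= 0, max_shift_mm <= 16,
            rot_max_deg >= 0, rot_max_deg <= 5)
  a <- pet$values
  d <- dim(a)
  vw <- voxel_weights(region)
  if (nrow(vw$idx) == 0L) stop("empty region", call. = FALSE)
  wsum <- sum(vw$w)

  ## zero-padded PET array: shifted lookups need no bounds checks, and
  ## regions pushed off the grid score 0 there (penalising the move)
  npad <- as.integer(ceiling(max_shift_mm / min(pet$spacing))) + 2L
  dp <- d + 2L * npad
  ap <- array(0, dp)
  ap[npad + seq_len(d[1]), npad + seq_len(d[2]), npad + seq_len(d[3])] <- a
  lin_pad <- function(idx) {
    (idx[, 3] + npad - 1L) * (dp[1] * dp[2]) + (idx[, 2] + npad - 1L) * dp[1] +
      idx[, 1] + npad
  }
  ## weighted SUVmean for many integer-voxel shifts of one sparse weight set
  obj_shifts <- function(idx, w, shifts) {
    lin0 <- lin_pad(idx)
    soff <- shifts[, 3] * (dp[1] * dp[2]) + shifts[, 2] * dp[1] + shifts[, 1]
    n <- length(lin0)
    out <- numeric(length(soff))
    chunk <- max(1L, floor(4e6 / n))
    for (st in seq(1L, length(soff), by = chunk)) {
      en <- min(st + chunk - 1L, length(soff))
      im <- outer(lin0, soff[st:en], "+")
      out[st:en] <- as.vector(crossprod(w, matrix(ap[im], nrow = n)))
    }
    out / wsum
  }
  fp <- fine_points(region)
  obj_points <- function(pts) {
    vi <- world_to_voxel(pet, pts)
    ok <- vi[, 1] >= 1L & vi[, 1] <= d[1] & vi[, 2] >= 1L & vi[, 2] <= d[2] &
      vi[, 3] >= 1L & vi[, 3] <= d[3]
    if (!any(ok)) return(0)
    lin <- (vi[ok, 3] - 1L) * (d[1] * d[2]) + (vi[ok, 2] - 1L) * d[1] + vi[ok, 1]
    sum(fp$w[ok] * a[lin]) / sum(fp$w)
  }
  centroid <- colSums(fp$pts * fp$w) / sum(fp$w)
  rot_pts <- function(th) {
    if (th == 0) return(fp$pts)
    r <- matrix(c(cos(th * pi / 180), sin(th * pi / 180),
                  -sin(th * pi / 180), cos(th * pi / 180)), 2, 2)
    p <- fp$pts
    p[, 1:2] <- sweep(sweep(p[, 1:2, drop = FALSE], 2, centroid[1:2], "-") %*%
                        t(r), 2, centroid[1:2], "+")
    p
  }

  pick_best <- function(cand, score) {
    best <- max(score)
    if (diff(range(score)) < 1e-12) return(NULL) # flat
    ok <- which(score >= best - 1e-12)
    mag <- rowSums(cand[ok, 1:3, drop = FALSE]^2) + cand[ok, 4]^2 * 1e-6
    ord <- order(mag, cand[ok, 1], cand[ok, 2], cand[ok, 3], cand[ok, 4])
    cand[ok[ord[1]], ]
  }

  thetas <- if (rot_max_deg > 0) {
    seq(-rot_max_deg, rot_max_deg, by = rot_step_deg)
  } else 0
  ## coarse stage: integer-voxel shifts (cross-correlation on the PET grid)
  nst <- floor(max_shift_mm / pet$spacing)
  sv <- expand.grid(si = -nst[1]:nst[1], sj = -nst[2]:nst[2],
                    sk = -nst[3]:nst[3])
  keep <- sqrt((sv$si * pet$spacing[1])^2 + (sv$sj * pet$spacing[2])^2 +
                 (sv$sk * pet$spacing[3])^2) <= max_shift_mm + 1e-9
  sv <- as.matrix(sv[keep, , drop = FALSE])
  cand <- NULL; score <- NULL
  for (th in thetas) {
    sc <- if (th == 0) {
      obj_shifts(vw$idx, vw$w, sv)
    } else {
      pts_th <- rot_pts(th)
      apply(sv, 1, function(s) obj_points(sweep(pts_th, 2, s * pet$spacing, "+")))
    }
    cand <- rbind(cand, cbind(sweep(sv, 2, pet$spacing, "*"), th))
    score <- c(score, sc)
  }
  trace <- tibble::tibble(stage = "coarse", tx = cand[, 1], ty = cand[, 2],
                          tz = cand[, 3], rot = cand[, 4], objective = score)
  ## flatness is judged near the identity, where boundary clipping cannot
  ## depress the objective of an interior region (zero-signal PET contract)
  near <- rowSums(cand[, 1:3, drop = FALSE]^2) <= (2 * coarse_step_mm)^2 + 1e-9
  flat_near <- diff(range(score[near])) <
    1e-9 * max(1, max(abs(score[near])))
  best <- if (flat_near) NULL else pick_best(cand, score)
  if (is.null(best)) {
    return(list(translation = c(0, 0, 0), rotation_deg = 0, region = region,
                objective = score[1], trace = trace, flat = TRUE))
  }
  ## fine stage: sub-voxel translations around the coarse optimum. Each total
  ## shift is decomposed into an integer-voxel part plus a sub-voxel phase;
  ## per phase the region is re-aggregated to voxel weights once, and the
  ## integer parts reuse the padded-array gather.
  offs <- seq(-coarse_step_mm, coarse_step_mm, by = fine_step_mm)
  fg <- as.matrix(expand.grid(dx = offs, dy = offs, dz = offs))
  if (best[4] != 0) {
    pts0 <- rot_pts(best[4])
    sc2 <- apply(fg, 1, function(dt) {
      obj_points(sweep(pts0, 2, best[1:3] + dt, "+"))
    })
  } else {
    tot <- sweep(fg, 2, best[1:3], "+")
    q <- floor(sweep(tot, 2, pet$spacing, "/") + 1e-9)
    ph <- tot - sweep(q, 2, pet$spacing, "*")
    key <- apply(round(ph, 6), 1, paste, collapse = ",")
    sc2 <- numeric(nrow(fg))
    for (kk in unique(key)) {
      rows <- which(key == kk)
      vwp <- voxel_weights(region_shift(region, ph[rows[1], ]))
      sc2[rows] <- obj_shifts(vwp$idx, vwp$w,
                              matrix(as.integer(q[rows, ]), ncol = 3))
    }
  }
  cand2 <- cbind(sweep(fg, 2, best[1:3], "+"), best[4])
  trace <- dplyr::bind_rows(trace, tibble::tibble(
    stage = "fine", tx = cand2[, 1], ty = cand2[, 2], tz = cand2[, 3],
    rot = cand2[, 4], objective = sc2
  ))
  best2 <- pick_best(cand2, sc2)
  if (is.null(best2)) best2 <- best
  out_region <- region_shift(region, best2[1:3])
  list(translation = unname(best2[1:3]), rotation_deg = unname(best2[4]),
       region = out_region, objective = max(sc2),
       trace = trace, flat = FALSE)
}
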