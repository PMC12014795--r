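#' Read and write histo-area annotations (GeoJSON)
#'
#' Annotations travel as a GeoJSON FeatureCollection in the digital-pathology
#' export dialect: one `Polygon` feature per histo-area, coordinates in
#' section micrometres, with per-feature properties `patient`, `section`,
#' `area_id` and a label carried either as a plain `label` property or as the
#' nested `classification: {name}` used by QuPath exports. A missing
#' `section` property, or a ring with fewer than 3 vertices, is an error
#' naming the offending feature.
#'
#' @param path file path.
#' @return `read_annotations()`: tibble `(patient, section, area_id, label,
#'   polygon, area_um2)` with `polygon` a list of ring lists.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  js <- jsonlite::read_json(path)
  if (!identical(js$type, "FeatureCollection")) {
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  }
  unit <- js$properties$area_unit %||% "um2"
  rows <- lapply(seq_along(js$features), function(i) {
    f <- js$features[[i]]
    pr <- f$properties %||% list()
    fid <- pr$area_id %||% sprintf("feature %d", i)
    if (is.null(pr$section)) {
      stop("feature ", fid, ": missing `section` property", call. = FALSE)
    }
    if (!identical(f$geometry$type, "Polygon")) {
      stop("feature ", fid, ": only Polygon geometries are supported",
           call. = FALSE)
    }
    rings <- lapply(f$geometry$coordinates, function(rg) {
      m <- do.call(rbind, lapply(rg, function(xy) as.numeric(unlist(xy))))
      # closed GeoJSON ring: drop repeated last vertex
      if (nrow(m) >= 2L && all(m[1, ] == m[nrow(m), ])) {
        m <- m[-nrow(m), , drop = FALSE]
      }
      if (nrow(m) < 3L) {
        stop("feature ", fid, ": ring with fewer than 3 vertices",
             call. = FALSE)
      }
      m
    })
    label <- pr$classification$name %||% pr$label %||% NA_character_
    tibble::tibble(
      patient = pr$patient %||% NA_character_,
      section = as.integer(pr$section),
      area_id = pr$area_id %||% sprintf("area%03d", i),
      label = label, polygon = list(rings),
      area_um2 = polygon_area(rings)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "area_unit") <- unit
  out
}

#' @rdname read_annotations
#' @param areas tibble of histo-areas with a `polygon` list-column.
#' @param area_unit unit label recorded in the collection metadata.
#' @export
write_annotations <- function(areas, path, area_unit = "um2") {
  feats <- lapply(seq_len(nrow(areas)), function(i) {
    rings <- as_polygon(areas$polygon[[i]])
    coords <- lapply(rings, function(r) {
      r <- rbind(r, r[1, ]) # close the ring
      lapply(seq_len(nrow(r)), function(q) as.list(unname(r[q, ])))
    })
    list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = coords),
      properties = list(
        patient = areas$patient[i], section = areas$section[i],
        area_id = areas$area_id[i],
        classification = list(name = areas$label[i])
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection",
         properties = list(area_unit = area_unit),
         features = feats),
    path, auto_unbox = TRUE, digits = NA, pretty = FALSE
  )
  invisible(path)
}

#' Read and write cell-level staining tables (CSV)
#'
#' One row per detected cell: `area_id`, `cell_id` and the staining `level`
#' in 0..3 assigned by the (AI-assisted) cell classifier.
#'
#' @param path CSV path.
#' @return Validated tibble `(area_id, cell_id, level)`.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- readr::read_csv(path, col_types = readr::cols(
    area_id = readr::col_character(), cell_id = readr::col_integer(),
    level = readr::col_integer()))
  validate_cell_table(tab)
}

#' @rdname read_cell_table
#' @param cells cell table to write.
#' @export
write_cell_table <- function(cells, path) {
  validate_cell_table(cells)
  readr::write_csv(cells[, c("area_id", "cell_id", "level")], path)
  invisible(path)
}

#' Read and write scalar volumes (NIfTI)
#'
#' Volumes are written as NIfTI-1 with the grid geometry in the sform (a
#' diagonal world matrix: this package keeps one axis convention for all
#' volumes and transforms) and the value unit in a JSON sidecar next to the
#' image (`<file>.json`), since NIfTI has no SUV-unit field. Reading a file
#' without any orientation information (qform and sform both absent) is a
#' hard error — axes are never guessed. Spacing, origin and values
#' round-trip exactly (within float32 header precision for the geometry).
#'
#' @param path NIfTI path (`.nii` or `.nii.gz`).
#' @param expected_unit if given, a mismatching sidecar unit raises a
#'   warning.
#' @return A [scalar_volume()].
#' @export
read_volume <- function(path, expected_unit = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  if (identical(attr(xf, "code"), 0L)) {
    stop("volume has no orientation information (qform/sform code 0); ",
         "refusing to guess axes: ", path, call. = FALSE)
  }
  spacing <- abs(diag(xf[1:3, 1:3]))
  origin <- xf[1:3, 4]
  unit <- "unknown"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    unit <- meta$unit %||% "unknown"
  }
  if (!is.null(expected_unit) && !identical(unit, expected_unit)) {
    warning("sidecar unit '", unit, "' does not match expected '",
            expected_unit, "' for ", path)
  }
  a <- array(as.numeric(img), dim(img)[1:3])
  scalar_volume(a, spacing = spacing, origin = origin, unit = unit)
}

#' @rdname read_volume
#' @param vol a [scalar_volume()] to write.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "scalar_volume"))
  img <- RNifti::asNifti(vol$values, datatype = "double",
                         pixdim = vol$spacing)
  m <- diag(4)
  diag(m)[1:3] <- vol$spacing
  m[1:3, 4] <- vol$origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(unit = vol$unit), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

## transform chain <-> JSON manifest (affine steps inline, 4 x 4 row-major)
write_chain <- function(chain, path, misregistration = NULL) {
  steps <- lapply(chain$steps, function(s) {
    if (s$type != "affine") {
      stop("only affine steps can be serialised to the chain manifest",
           call. = FALSE)
    }
    list(type = "affine", matrix = as.vector(t(s$matrix)))
  })
  jsonlite::write_json(list(steps = steps, misregistration = misregistration),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_chain <- function(path) {
  js <- jsonlite::read_json(path)
  steps <- lapply(js$steps, function(s) {
    affine_transform(matrix(as.numeric(unlist(s$matrix)), 4, 4, byrow = TRUE))
  })
  transform_chain(steps)
}

## ---- run configuration -----------------------------------------------------

config_schema <- function() {
  list(
    seed = NULL, out_dir = NULL, verbosity = NULL,
    cohort = c("n_I", "n_II", "misregister", "rotation_max_deg"),
    phantom = names(formals(phantom_spec)),
    analysis = setdiff(names(formals(study_config)), "scheme"),
    groups = NULL
  )
}

#' Read and validate a run configuration (YAML)
#'
#' Validates the document against the published schema before any stage
#' runs: recognised top-level blocks are `seed`, `out_dir`, `verbosity`,
#' `cohort` (sizes and misregistration switches), `phantom` (any
#' [phantom_spec()] field), `analysis` (any [study_config()] field except the
#' scheme) and `groups` (named H-Score upper limits). Unknown keys anywhere
#' are rejected.
#'
#' @param path YAML file.
#' @return Validated nested list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  schema <- config_schema()
  bad <- setdiff(names(cfg), names(schema))
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (blk in names(schema)) {
    allowed <- schema[[blk]]
    if (is.null(allowed) || is.null(cfg[[blk]])) next
    bad <- setdiff(names(cfg[[blk]]), allowed)
    if (length(bad)) {
      stop("unknown key(s) in `", blk, "`: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}
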