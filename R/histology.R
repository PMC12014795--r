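#' H-Score of immunohistochemical staining
#'
#' The H-Score summarises per-cell PSMA staining intensity over a
#' pathologist-defined PCa area. Every cell carries a staining level between
#' 0 (no expression) and 3 (strong expression); the score is the sum of each
#' level times the percentage of cells at that level,
#' \eqn{H = \sum_{i=0}^{3} i \cdot 100\, n_i / n}, and therefore lies in
#' \[0, 300\]. Exact cell fractions are used (no rounding of percentages).
#'
#' @param cells a cell table: data frame with columns `area_id` and `level`
#'   (integer staining level in 0..3); an optional `cell_id` column is
#'   ignored.
#' @param area_id if supplied, return the scalar H-Score for that single
#'   area; otherwise a tibble with one row per area.
#' @return A tibble `(area_id, n_cells, hscore)`, or a single numeric when
#'   `area_id` is given.
#' @examples
#' cells <- tibble::tibble(area_id = "a", level = c(0, 0, 2, 2))
#' compute_hscore(cells, "a") # 100
#' @export
compute_hscore <- function(cells, area_id = NULL) {
  stopifnot(is.data.frame(cells))
  if (!all(c("area_id", "level") %in% names(cells))) {
    stop("cell table needs columns `area_id` and `level`", call. = FALSE)
  }
  lv <- cells$level
  if (any(!is.finite(lv)) || any(lv != floor(lv)) || any(lv < 0 | lv > 3)) {
    stop("staining `level` must be an integer in 0..3", call. = FALSE)
  }
  if (!is.null(area_id)) {
    sel <- cells$area_id == area_id
    if (!any(sel)) stop("unknown area_id: ", area_id, call. = FALSE)
    return(100 * mean(lv[sel]))
  }
  cells |>
    dplyr::group_by(.data$area_id) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     hscore = 100 * mean(.data$level),
                     .groups = "drop")
}

#' H-Score grouping scheme
#'
#' Ordered, contiguous, non-overlapping integer intervals partitioning
#' \[0, 300\] into expression groups. The default limits split the score
#' range into "very_low" (0-75), "low" (76-132), "medium" (133-180) and
#' "high" (181-300); the printed limits are integers, so non-integer scores
#' are assigned by extending each interval to its half-open real hull
#' \[lo, hi + 1) except the last, which is closed at 300.
#'
#' @param breaks named integer vector of upper limits per group, in order.
#' @return An object of class `hscore_scheme`.
#' @export
hscore_group_scheme <- function(breaks = c(very_low = 75, low = 132,
                                           medium = 180, high = 300)) {
  if (is.null(names(breaks)) || any(names(breaks) == "") ||
      anyDuplicated(names(breaks))) {
    stop("group breaks must have unique names", call. = FALSE)
  }
  if (is.unsorted(breaks, strictly = TRUE) || utils::tail(breaks, 1) != 300) {
    stop("group upper limits must be strictly increasing and end at 300",
         call. = FALSE)
  }
  lo <- c(0, utils::head(breaks, -1) + 1)
  structure(
    tibble::tibble(group = names(breaks), lo = lo, hi = as.numeric(breaks)),
    class = c("hscore_scheme", "tbl_df", "tbl", "data.frame")
  )
}

#' Assign H-Scores to expression groups
#'
#' @param hscore numeric vector of H-Scores in \[0, 300\].
#' @param scheme an [hscore_group_scheme()].
#' @return Factor of group labels with the scheme's level order.
#' @examples
#' assign_group(c(75, 76, 300))
#' @export
assign_group <- function(hscore, scheme = hscore_group_scheme()) {
  if (any(!is.finite(hscore)) || any(hscore < 0 | hscore > 300)) {
    stop("H-Scores must lie in [0, 300]", call. = FALSE)
  }
  n <- nrow(scheme)
  # half-open real hulls [lo, hi + 1), last interval closed at 300
  cuts <- c(scheme$lo[1], scheme$hi[-n] + 1, 300)
  idx <- findInterval(hscore, cuts, rightmost.closed = TRUE)
  factor(scheme$group[idx], levels = scheme$group)
}

#' Area-weighted H-Score of a combined tumour region
#'
#' When histo-areas are combined into a tumour area or interpolated into a
#' tumour volume, the region's H-Score is the area-weighted mean of its
#' constituents, and the area-weighted standard deviation measures the loss
#' of expression resolution caused by combining them. The population
#' (biased) form \eqn{\sqrt{\sum w_i (h_i - \bar h)^2 / \sum w_i}} is used;
#' a single constituent always gives sd 0.
#'
#' @param hscore numeric H-Scores of the constituent areas.
#' @param weight strictly positive weights (histological areas, conventionally
#'   in micrometres squared).
#' @return One-row tibble `(mean, sd, total_weight)`.
#' @examples
#' weighted_hscore(c(100, 200), c(100, 300)) # mean 175
#' @export
weighted_hscore <- function(hscore, weight = rep(1, length(hscore))) {
  if (length(hscore) == 0L) {
    stop("weighted H-Score of an empty area list is undefined", call. = FALSE)
  }
  if (length(weight) != length(hscore) || any(!is.finite(weight)) ||
      any(weight <= 0)) {
    stop("weights must be strictly positive and match `hscore`", call. = FALSE)
  }
  m <- sum(weight * hscore) / sum(weight)
  s <- sqrt(sum(weight * (hscore - m)^2) / sum(weight))
  tibble::tibble(mean = m, sd = s, total_weight = sum(weight))
}

## validate a cell table read from disk / generator
validate_cell_table <- function(cells) {
  stopifnot(is.data.frame(cells))
  need <- c("area_id", "cell_id", "level")
  if (!all(need %in% names(cells))) {
    stop("cell table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lv <- cells$level
  if (any(!is.finite(lv)) || any(lv != floor(lv)) || any(lv < 0 | lv > 3)) {
    stop("staining `level` must be an integer in 0..3", call. = FALSE)
  }
  invisible(cells)
}
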