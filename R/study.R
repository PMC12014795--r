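#' Analysis configuration for a co-registration study
#'
#' Collects the knobs of the end-to-end analysis: the H-Score grouping
#' scheme, the sub-voxel resolution, whether the automated rigid position
#' refinement runs before uptake extraction, the size-filter thresholds of
#' the subset analyses (histological area, in-vivo volume > 1 ml, patient
#' GTV > 5 ml), the CI method for Spearman correlations and the master seed
#' behind every stochastic step (bootstrap resampling).
#'
#' @param scheme an [hscore_group_scheme()].
#' @param sub_factor sub-voxel resolution for mask rasterisation.
#' @param refine run [refine_rigid()] on every unit before extraction?
#' @param refine_max_shift_mm translation bound of the refinement.
#' @param area_threshold histological-area cut for the large-area subset, in
#'   the unit the annotations carry (micrometres squared by convention).
#' @param volume_threshold_ml in-vivo volume cut for tumour volumes.
#' @param gtv_threshold_ml patient-level GTV size cut.
#' @param ci_method,n_boot CI settings passed to [spearman_cor()].
#' @param dunn_adjust multiple-testing adjustment for [dunn_posthoc()].
#' @param max_occupancy_floor SUVmax eligibility floor, see
#'   [extract_uptake_stats()].
#' @param seed master seed.
#' @return A `study_config` list.
#' @export
study_config <- function(scheme = hscore_group_scheme(),
                         sub_factor = 4L,
                         refine = FALSE,
                         refine_max_shift_mm = 16,
                         area_threshold = 400,
                         volume_threshold_ml = 1,
                         gtv_threshold_ml = 5,
                         ci_method = "bootstrap",
                         n_boot = 10000L,
                         dunn_adjust = "none",
                         max_occupancy_floor = 0,
                         seed = 1L) {
  structure(list(
    scheme = scheme, sub_factor = as.integer(sub_factor),
    refine = isTRUE(refine), refine_max_shift_mm = refine_max_shift_mm,
    area_threshold = area_threshold,
    volume_threshold_ml = volume_threshold_ml,
    gtv_threshold_ml = gtv_threshold_ml,
    ci_method = ci_method, n_boot = as.integer(n_boot),
    dunn_adjust = dunn_adjust,
    max_occupancy_floor = max_occupancy_floor,
    seed = as.integer(seed)
  ), class = "study_config")
}

unit_schema <- function() {
  tibble::tibble(
    patient = character(), cohort = character(), unit_kind = character(),
    unit_id = character(), group = character(), hscore_mean = numeric(),
    hscore_sd = numeric(), hist_area = numeric(), suv_mean = numeric(),
    suv_max = numeric(), volume_ml = numeric(), gtv_agreement = numeric(),
    patient_gtv_ml = numeric(), n_constituents = integer(),
    constituents = list()
  )
}

cor_schema <- function() {
  tibble::tibble(unit_kind = character(), subset = character(),
                 metric = character(), rho = numeric(), p_value = numeric(),
                 ci_low = numeric(), ci_high = numeric(), n = integer())
}

safe_spearman <- function(x, y, config) {
  tryCatch({
    fit <- spearman_cor(x, y, ci_method = config$ci_method,
                        n_boot = config$n_boot, seed = config$seed)
    tidy(fit)[, c("rho", "p_value", "ci_low", "ci_high", "n")]
  }, error = function(e) {
    tibble::tibble(rho = NA_real_, p_value = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, n = length(x))
  })
}

extract_unit <- function(unit, bundle, config) {
  region <- unit$region
  refined <- NULL
  if (config$refine) {
    refined <- refine_rigid(region, bundle$pet,
                            max_shift_mm = config$refine_max_shift_mm)
    region <- refined$region
  }
  occ <- compute_occupancy(region)
  us <- extract_uptake_stats(occ, bundle$pet,
                             max_occupancy_floor = config$max_occupancy_floor)
  agr <- gtv_agreement(occ, bundle$gtv)
  list(stats = us, agreement = agr, refined = refined)
}

#' Run the full two-pathway study on a cohort
#'
#' Executes both analysis pathways end to end on a list of patient bundles
#' (synthetic phantoms or equivalently structured real data): transfers each
#' patient's histo-areas into the PET frame, builds interpolated tumour
#' volumes (pathway 1) and per-group combined tumour areas (pathway 2),
#' optionally refines each unit's position against the PET, extracts
#' SUVmean/SUVmax/in-vivo volume and GTV agreement, and computes the
#' statistical surface: Spearman correlations of H-Score to uptake for the
#' standard subsets (all units, per tracer cohort, large histological areas,
#' patients with GTV above the size cut, volumes above 1 ml), Kruskal-Wallis
#' with Dunn post-hoc comparisons across H-Score groups and between cohorts,
#' and through-origin regressions of uptake on H-Score. Patients missing an
#' input layer are skipped with a logged reason. Fully deterministic given
#' the bundles and the config seed.
#'
#' @param cohort list of `phantom`-structured bundles (elements `areas`,
#'   `cells`, `pet`, `gtv`, `chain`, `geom`, `patient_id`, `cohort`).
#' @param config a [study_config()].
#' @return A `study_result`: list of tibbles `units`, `correlations`,
#'   `group_comparisons`, `dunn`, `regressions`, `cohort_comparison`, plus
#'   `log` and `config`. `tidy()` returns the correlation table, `glance()`
#'   a one-row summary.
#' @export
run_study <- function(cohort, config = study_config()) {
  units <- unit_schema()
  log <- character(0)
  for (bundle in cohort) {
    miss <- setdiff(c("areas", "pet", "gtv", "chain", "geom"),
                    names(bundle)[!vapply(bundle, is.null, logical(1))])
    if (length(miss)) {
      msg <- sprintf("skipping patient %s: missing %s",
                     bundle$patient_id %||% "?", paste(miss, collapse = ", "))
      message(msg)
      log <- c(log, msg)
      next
    }
    if (nrow(bundle$areas) == 0L) {
      msg <- sprintf("skipping patient %s: no annotated areas", bundle$patient_id)
      message(msg)
      log <- c(log, msg)
      next
    }
    gtv_ml <- sum(bundle$gtv$values > 0) * prod(bundle$gtv$spacing) / 1000
    masks <- transfer_areas(bundle$areas, bundle$geom, bundle$chain,
                            bundle$pet, config$sub_factor)
    tvols <- build_tumour_volumes(bundle$areas, bundle$geom, bundle$chain,
                                  bundle$pet, config$sub_factor, masks = masks)
    tareas <- build_tumour_areas(bundle$areas, config$scheme, bundle$geom,
                                 bundle$chain, bundle$pet, config$sub_factor,
                                 masks = masks)
    row_of <- function(unit, kind, id, group = NA_character_) {
      ex <- extract_unit(unit, bundle, config)
      aid <- unit$constituents
      ha <- sum(bundle$areas$area_um2[bundle$areas$area_id %in% aid])
      tibble::tibble(
        patient = bundle$patient_id, cohort = as.character(bundle$cohort),
        unit_kind = kind, unit_id = id, group = group,
        hscore_mean = unit$hscore$mean, hscore_sd = unit$hscore$sd,
        hist_area = ha, suv_mean = ex$stats$suv_mean,
        suv_max = ex$stats$suv_max, volume_ml = ex$stats$volume_ml,
        gtv_agreement = if (kind == "tumour_area") ex$agreement else NA_real_,
        patient_gtv_ml = gtv_ml, n_constituents = length(aid),
        constituents = list(aid)
      )
    }
    for (i in seq_along(tvols)) {
      units <- dplyr::bind_rows(units, row_of(
        tvols[[i]], "tumour_volume",
        sprintf("%s_TV%02d", bundle$patient_id, i)))
    }
    for (ta in tareas) {
      units <- dplyr::bind_rows(units, row_of(
        ta, "tumour_area",
        sprintf("%s_TA_%s", bundle$patient_id, ta$group), group = ta$group))
    }
  }

  correlations <- cor_schema()
  add_cor <- function(df, kind, subset, metric) {
    if (nrow(df) >= 3L) {
      res <- safe_spearman(df$hscore_mean, df[[metric]], config)
      correlations <<- dplyr::bind_rows(correlations, dplyr::bind_cols(
        tibble::tibble(unit_kind = kind, subset = subset, metric = metric), res))
    }
  }
  tv <- units[units$unit_kind == "tumour_volume", ]
  ta <- units[units$unit_kind == "tumour_area", ]
  for (m in c("suv_mean", "suv_max")) {
    add_cor(tv, "tumour_volume", "all", m)
    add_cor(tv[tv$volume_ml > config$volume_threshold_ml, ], "tumour_volume",
            "volume_gt_threshold", m)
    add_cor(ta, "tumour_area", "all", m)
    add_cor(ta[ta$cohort == "I", ], "tumour_area", "cohort_I", m)
    add_cor(ta[ta$cohort == "II", ], "tumour_area", "cohort_II", m)
    add_cor(ta[ta$hist_area > config$area_threshold, ], "tumour_area",
            "area_gt_threshold", m)
    add_cor(ta[ta$patient_gtv_ml > config$gtv_threshold_ml, ], "tumour_area",
            "gtv_gt_threshold", m)
  }
  add_cor(ta, "tumour_area", "all", "gtv_agreement")

  group_comparisons <- tibble::tibble(
    comparison = character(), metric = character(), statistic = numeric(),
    df = numeric(), p_value = numeric())
  dunn <- tibble::tibble(comparison = character(), metric = character(),
                         group_a = character(), group_b = character(),
                         z = numeric(), p_raw = numeric(),
                         p_adjusted = numeric())
  for (m in c("suv_mean", "suv_max", "gtv_agreement")) {
    ok <- ta[is.finite(ta[[m]]), ]
    if (nrow(ok) && length(unique(ok$group)) >= 2L) {
      kw <- kruskal_wallis(split(ok[[m]], ok$group))
      group_comparisons <- dplyr::bind_rows(group_comparisons, dplyr::bind_cols(
        tibble::tibble(comparison = "hscore_group", metric = m),
        kw[, c("statistic", "df", "p_value")]))
      dn <- dunn_posthoc(split(ok[[m]], ok$group), adjust = config$dunn_adjust)
      if (nrow(dn)) {
        dunn <- dplyr::bind_rows(dunn, dplyr::bind_cols(
          tibble::tibble(comparison = "hscore_group", metric = m,
                         .rows = nrow(dn)), dn))
      }
    }
    if (nrow(ok) && length(unique(ok$cohort)) >= 2L) {
      kw <- kruskal_wallis(split(ok[[m]], ok$cohort))
      group_comparisons <- dplyr::bind_rows(group_comparisons, dplyr::bind_cols(
        tibble::tibble(comparison = "cohort", metric = m),
        kw[, c("statistic", "df", "p_value")]))
    }
  }

  regressions <- tibble::tibble(
    unit_kind = character(), subset = character(), metric = character(),
    slope = numeric(), slope_se = numeric(), r_squared = numeric(),
    p_value = numeric(), n = integer())
  add_reg <- function(df, subset, metric) {
    if (nrow(df) >= 2L && any(df$hscore_mean != 0)) {
      fit <- regress_through_origin(df$hscore_mean, df[[metric]])
      regressions <<- dplyr::bind_rows(regressions, tibble::tibble(
        unit_kind = "tumour_area", subset = subset, metric = metric,
        slope = fit$slope, slope_se = fit$slope_se,
        r_squared = fit$r_squared, p_value = fit$p_value, n = fit$n))
    }
  }
  for (m in c("suv_mean", "suv_max")) {
    add_reg(ta, "all", m)
    add_reg(ta[ta$hist_area > config$area_threshold, ], "area_gt_threshold", m)
  }

  cohort_comparison <- tibble::tibble(metric = character(), z = numeric(),
                                      p_value = numeric())
  for (m in c("suv_mean", "suv_max")) {
    r1 <- correlations[correlations$subset == "cohort_I" &
                         correlations$metric == m, ]
    r2 <- correlations[correlations$subset == "cohort_II" &
                         correlations$metric == m, ]
    if (nrow(r1) == 1L && nrow(r2) == 1L && is.finite(r1$rho) &&
        is.finite(r2$rho) && abs(r1$rho) < 1 && abs(r2$rho) < 1 &&
        r1$n >= 4 && r2$n >= 4) {
      cc <- compare_correlations(r1$rho, r1$n, r2$rho, r2$n)
      cohort_comparison <- dplyr::bind_rows(cohort_comparison, dplyr::bind_cols(
        tibble::tibble(metric = m), cc))
    }
  }

  structure(list(units = units, correlations = correlations,
                 group_comparisons = group_comparisons, dunn = dunn,
                 regressions = regressions,
                 cohort_comparison = cohort_comparison,
                 log = log, config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf(
    "<study_result> %d units (%d tumour volumes, %d tumour areas), %d correlations\n",
    nrow(x$units), sum(x$units$unit_kind == "tumour_volume"),
    sum(x$units$unit_kind == "tumour_area"), nrow(x$correlations)))
  if (length(x$log)) cat(" ", length(x$log), "patient(s) skipped\n")
  invisible(x)
}

#' @method tidy study_result
#' @export
tidy.study_result <- function(x, ...) x$correlations

#' @method glance study_result
#' @export
glance.study_result <- function(x, ...) {
  ta <- x$units[x$units$unit_kind == "tumour_area", ]
  tibble::tibble(
    n_patients = length(unique(x$units$patient)),
    n_tumour_volumes = sum(x$units$unit_kind == "tumour_volume"),
    n_tumour_areas = nrow(ta),
    mean_hscore = mean(ta$hscore_mean),
    mean_hscore_sd = mean(ta$hscore_sd),
    median_suv_mean = stats::median(ta$suv_mean),
    median_gtv_agreement = stats::median(ta$gtv_agreement),
    n_skipped = length(x$log)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
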