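test_that("Spearman rho hits the monotone extremes", {
  x <- 1:10
  expect_equal(spearman_cor(x, x^3, ci_method = "none")$rho, 1)
  expect_equal(spearman_cor(x, -sqrt(x), ci_method = "none")$rho, -1)
})

test_that("Spearman with ties matches the brute-force rank oracle exactly", {
  withr::with_seed(81, {
    for (i in 1:20) {
      n <- sample(5:15, 1)
      x <- sample(1:5, n, replace = TRUE)
      y <- sample(1:4, n, replace = TRUE)
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      fit <- spearman_cor(x, y, ci_method = "none")
      expect_equal(fit$rho, oracle_spearman(x, y), tolerance = 1e-12)
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
      expect_equal(fit$rho, unname(ct$estimate), tolerance = 1e-12)
    }
  })
})

test_that("Spearman p matches the t approximation used by cor.test", {
  withr::with_seed(82, {
    x <- stats::rnorm(30); y <- x + stats::rnorm(30)
    fit <- spearman_cor(x, y, ci_method = "none")
    ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
    expect_equal(fit$p_value, ct$p.value, tolerance = 1e-10)
  })
})

test_that("Spearman is invariant under strictly monotone transforms", {
  withr::with_seed(83, {
    x <- stats::rnorm(40); y <- stats::rnorm(40)
    r0 <- spearman_cor(x, y, ci_method = "none")$rho
    expect_equal(spearman_cor(exp(x), y, ci_method = "none")$rho, r0)
    expect_equal(spearman_cor(x, y^3 + 5 * y, ci_method = "none")$rho, r0)
  })
})

test_that("constant input is a classed degenerate error", {
  expect_error(spearman_cor(rep(1, 5), 1:5), class = "histopet_degenerate")
})

test_that("bootstrap CIs are seeded and bracket the estimate", {
  withr::with_seed(84, {
    x <- stats::rnorm(40); y <- 0.5 * x + stats::rnorm(40)
  })
  a <- spearman_cor(x, y, n_boot = 500, seed = 9)
  b <- spearman_cor(x, y, n_boot = 500, seed = 9)
  expect_identical(c(a$ci_low, a$ci_high), c(b$ci_low, b$ci_high))
  expect_lte(a$ci_low, a$rho)
  expect_gte(a$ci_high, a$rho)
})

test_that("Kruskal-Wallis: identical groups, separated groups, tie correction", {
  same <- kruskal_wallis(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-10)

  sep <- list(a = c(1, 2, 3), b = c(101, 102, 103), c = c(201, 202, 203))
  h <- kruskal_wallis(sep)$statistic
  expect_equal(h, oracle_kw_h(sep), tolerance = 1e-12)
  # no rank overlap: H at its maximum for n = 9, k = 3
  hmax <- 12 / (9 * 10) * (sum(1:3)^2 + sum(4:6)^2 + sum(7:9)^2) / 3 - 3 * 10
  expect_equal(h, hmax, tolerance = 1e-12)

  tied <- list(a = c(1, 1, 2), b = c(2, 3, 3), c = c(1, 3, 4))
  expect_equal(kruskal_wallis(tied)$statistic, oracle_kw_h(tied),
               tolerance = 1e-12)

  df <- tibble::tibble(v = unlist(sep), g = rep(letters[1:3], each = 3))
  expect_equal(kruskal_wallis(df, v, g)$statistic, h)
  expect_error(kruskal_wallis(list(a = 1:3)), "2 groups")
})

test_that("Dunn z agrees with an independent textbook implementation", {
  groups <- list(a = c(2.1, 3.5, 3.5, 4), b = c(5, 6.2, 6.2),
                 c = c(1, 2.1, 7, 8, 9))
  dn <- dunn_posthoc(groups)
  expect_equal(dn$z, unname(oracle_dunn_z(groups)), tolerance = 1e-10)
  expect_equal(dn$p_raw, dn$p_adjusted) # default: no adjustment
  holm <- dunn_posthoc(groups, adjust = "holm")
  expect_equal(holm$p_adjusted, stats::p.adjust(dn$p_raw, "holm"))
})

test_that("Dunn table shape and degenerate cases", {
  four <- split(stats::rnorm(40), rep(1:4, 10))
  expect_equal(nrow(dunn_posthoc(four)), 6L)
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_true(all(dunn_posthoc(same)$p_raw > 0.99))
  expect_equal(nrow(dunn_posthoc(list(a = 1:3))), 0L)
})

test_that("through-origin regression matches closed forms and lm", {
  x <- c(50, 100, 200)
  exact <- regress_through_origin(x, 0.09 * x)
  expect_equal(exact$slope, 0.09)
  expect_equal(exact$r_squared, 1)

  single <- regress_through_origin(100, 9)
  expect_equal(single$slope, 0.09)

  withr::with_seed(91, {
    xx <- stats::runif(25, 10, 300)
    yy <- 0.09 * xx + stats::rnorm(25, sd = 0.5)
  })
  fit <- regress_through_origin(xx, yy)
  lmfit <- summary(stats::lm(yy ~ 0 + xx))
  expect_equal(fit$slope, unname(coef(lmfit)[1, 1]), tolerance = 1e-12)
  expect_equal(fit$slope_se, unname(coef(lmfit)[1, 2]), tolerance = 1e-12)
  expect_equal(fit$p_value, unname(coef(lmfit)[1, 4]), tolerance = 1e-12)
  # parameter recovery at this noise level
  expect_lt(abs(fit$slope - 0.09), 2 * fit$slope_se)

  expect_error(regress_through_origin(c(0, 0), c(1, 2)),
               class = "histopet_degenerate")
  td <- tidy(fit)
  expect_equal(td$estimate, fit$slope)
  expect_equal(glance(fit)$r_squared_convention, "uncentered")
})

test_that("correlation comparison follows the Fisher z closed form", {
  expect_equal(compare_correlations(0.37, 50, 0.37, 40)$p_value, 1)
  expect_lt(compare_correlations(0.9, 500, 0, 500)$p_value, 1e-10)

  z_oracle <- (atanh(0.6) - atanh(0.2)) / sqrt(1 / (30 - 3) + 1 / (45 - 3))
  cc <- compare_correlations(0.6, 30, 0.2, 45)
  expect_equal(cc$z, z_oracle, tolerance = 1e-12)
  expect_equal(cc$p_value, 2 * stats::pnorm(-abs(z_oracle)), tolerance = 1e-12)

  expect_error(compare_correlations(1, 10, 0.5, 10),
               class = "histopet_degenerate")
})

test_that("an empty cohort yields an empty, schema-valid study result", {
  res <- run_study(list())
  expect_s3_class(res, "study_result")
  expect_equal(nrow(res$units), 0L)
  expect_named(res$correlations,
               c("unit_kind", "subset", "metric", "rho", "p_value",
                 "ci_low", "ci_high", "n"))
  expect_equal(nrow(res$correlations), 0L)
})

test_that("patients with missing layers are skipped with a logged reason", {
  sp <- phantom_spec(prostate_half_axes = c(16, 14, 12), n_lesions = 1,
                     lesion_radius_range = c(5, 7), margin_mm = 6,
                     noise_sd = 0)
  suppressWarnings(ph <- generate_phantom(sp, 55))
  broken <- ph
  broken$pet <- NULL
  expect_message(res <- run_study(list(broken), study_config(n_boot = 100)),
                 "skipping")
  expect_length(res$log, 1L)
  expect_equal(nrow(res$units), 0L)
})

test_that("a noiseless linear phantom cohort gives perfect rank correlation", {
  sp <- phantom_spec(n_lesions = 2, lesion_radius_range = c(4, 6),
                     margin_mm = 6, noise_sd = 0, psf_fwhm = 0,
                     uptake_background = 0, lesion_shape = "box",
                     gtv_threshold = 1)
  cohort <- lapply(1:4, function(i) {
    ph <- suppressWarnings(generate_phantom(sp, 700 + i,
                                            patient_id = sprintf("P%02d", i)))
    ph$cohort <- if (i <= 2) "I" else "II"
    ph
  })
  res <- run_study(cohort, study_config(n_boot = 100))
  ta <- res$correlations[res$correlations$unit_kind == "tumour_area" &
                           res$correlations$subset == "all" &
                           res$correlations$metric == "suv_mean", ]
  expect_equal(ta$rho, 1)
  reg <- res$regressions[res$regressions$subset == "all" &
                           res$regressions$metric == "suv_mean", ]
  expect_lt(abs(reg$slope - 0.09) / 0.09, 1e-6)
})
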