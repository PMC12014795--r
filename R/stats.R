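#' Spearman rank correlation with confidence interval
#'
#' Spearman's rho with average-rank tie handling, a p-value from the
#' standard large-sample t approximation
#' (`t = rho sqrt((n-2)/(1-rho^2))`, n-2 df), and a confidence interval from
#' either a seeded percentile bootstrap (default, 10,000 resamples) or the
#' Fisher z transform. Constant input is a degenerate case and raises a
#' classed error (`histopet_degenerate`).
#'
#' @param x,y numeric vectors of equal length >= 3 (ties allowed).
#' @param ci_method `"bootstrap"`, `"fisher"` or `"none"`.
#' @param n_boot bootstrap resamples.
#' @param conf_level confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return An object of class `spearman_cor`; `tidy()` gives a one-row
#'   tibble `(rho, p_value, ci_low, ci_high, n, ci_method)`.
#' @examples
#' fit <- spearman_cor(1:10, (1:10)^2, ci_method = "fisher")
#' generics::tidy(fit)
#' @export
spearman_cor <- function(x, y, ci_method = c("bootstrap", "fisher", "none"),
                         n_boot = 10000L, conf_level = 0.95, seed = 1L) {
  ci_method <- match.arg(ci_method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || length(y) != n) {
    stop("need equal-length x and y with n >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop(structure(class = c("histopet_degenerate", "error", "condition"),
                   list(message = "Spearman rho is undefined for constant input",
                        call = NULL)))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- spearman_p(rho, n)
  alpha <- 1 - conf_level
  ci <- c(NA_real_, NA_real_)
  if (ci_method == "bootstrap") {
    if (n >= 4L) {
      rb <- withr::with_seed(as.integer(seed), boot_spearman(x, y, n_boot))
      ci <- stats::quantile(rb, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                            names = FALSE)
    }
  } else if (ci_method == "fisher") {
    if (n >= 4L && abs(rho) < 1) {
      z <- atanh(rho)
      ## Fieller-style SE for Spearman's rho on the z scale
      se <- sqrt(1.06 / (n - 3))
      ci <- tanh(z + c(-1, 1) * stats::qnorm(1 - alpha / 2) * se)
    }
  }
  structure(
    list(rho = rho, p_value = p, ci_low = ci[1], ci_high = ci[2], n = n,
         ci_method = ci_method, conf_level = conf_level),
    class = "spearman_cor"
  )
}

spearman_p <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

## vectorised bootstrap of Spearman's rho (percentile resampling of pairs)
boot_spearman <- function(x, y, n_boot) {
  n <- length(x)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
  rx <- apply(matrix(x[idx], n, n_boot), 2, rank)
  ry <- apply(matrix(y[idx], n, n_boot), 2, rank)
  mx <- colMeans(rx); my <- colMeans(ry)
  sxy <- colSums(rx * ry) / n - mx * my
  sx <- colSums(rx^2) / n - mx^2
  sy <- colSums(ry^2) / n - my^2
  out <- sxy / sqrt(sx * sy)
  out[sx <= 0 | sy <= 0] <- NA_real_
  out
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (n = %d), p = %.3g, %g%% CI [%.3f, %.3f] (%s)\n",
              x$rho, x$n, x$p_value, 100 * x$conf_level, x$ci_low, x$ci_high,
              x$ci_method))
  invisible(x)
}

#' @method tidy spearman_cor
#' @export
tidy.spearman_cor <- function(x, ...) {
  tibble::tibble(rho = x$rho, p_value = x$p_value, ci_low = x$ci_low,
                 ci_high = x$ci_high, n = x$n, ci_method = x$ci_method)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-square p-value on k-1 degrees of
#' freedom (delegated to [stats::kruskal.test()]). Accepts a data frame with
#' value/group columns or a list of numeric vectors.
#'
#' @param data data frame, or list of numeric group vectors.
#' @param value,group column names (tidy-eval) when `data` is a data frame.
#' @return One-row tibble `(statistic, df, p_value, n_groups, n)`.
#' @examples
#' kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
kruskal_wallis <- function(data, value = NULL, group = NULL) {
  groups <- split_groups(data, {{ value }}, {{ group }})
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) == 0L)) stop("empty group", call. = FALSE)
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1L) {
    kw <- list(statistic = c(`Kruskal-Wallis chi-squared` = 0),
               parameter = length(groups) - 1L, p.value = 1)
  } else {
    kw <- stats::kruskal.test(groups)
  }
  tibble::tibble(statistic = unname(kw$statistic),
                 df = unname(kw$parameter), p_value = kw$p.value,
                 n_groups = length(groups), n = length(vals))
}

split_groups <- function(data, value, group) {
  if (is.list(data) && !is.data.frame(data)) {
    out <- lapply(data, as.numeric)
    if (is.null(names(out)) || any(names(out) == "")) {
      names(out) <- paste0("g", seq_along(out))
    }
    return(out)
  }
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  if (is.null(v) || is.null(g)) {
    stop("supply `value` and `group` columns for data-frame input",
         call. = FALSE)
  }
  split(as.numeric(v), g)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise z statistics after a Kruskal-Wallis test, using the pooled
#' tie-corrected rank variance:
#' `z = (Rbar_a - Rbar_b) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_a + 1/n_b))`
#' with `T = sum(t^3 - t)` over tie groups. The default applies no
#' multiple-testing adjustment (the analysis convention here); Holm or
#' Bonferroni are selectable.
#'
#' @inheritParams kruskal_wallis
#' @param adjust `"none"`, `"holm"` or `"bonferroni"`.
#' @return Tibble with one row per unordered pair: `(group_a, group_b, z,
#'   p_raw, p_adjusted)`; empty for a single group.
#' @export
dunn_posthoc <- function(data, value = NULL, group = NULL,
                         adjust = c("none", "holm", "bonferroni")) {
  adjust <- match.arg(adjust)
  groups <- split_groups(data, {{ value }}, {{ group }})
  k <- length(groups)
  empty <- tibble::tibble(group_a = character(), group_b = character(),
                          z = numeric(), p_raw = numeric(),
                          p_adjusted = numeric())
  if (k < 2L) return(empty)
  vals <- unlist(groups, use.names = FALSE)
  n_tot <- length(vals)
  r <- rank(vals)
  gl <- rep(names(groups), lengths(groups))
  rbar <- tapply(r, gl, mean)
  nn <- lengths(groups)
  ties <- table(vals)
  tie_term <- sum(ties^3 - ties)
  v0 <- n_tot * (n_tot + 1) / 12 - tie_term / (12 * (n_tot - 1))
  pairs <- utils::combn(names(groups), 2)
  z <- vapply(seq_len(ncol(pairs)), function(q) {
    a <- pairs[1, q]; b <- pairs[2, q]
    (rbar[[a]] - rbar[[b]]) / sqrt(v0 * (1 / nn[[a]] + 1 / nn[[b]]))
  }, numeric(1))
  p_raw <- 2 * stats::pnorm(-abs(z))
  tibble::tibble(group_a = pairs[1, ], group_b = pairs[2, ], z = z,
                 p_raw = p_raw,
                 p_adjusted = stats::p.adjust(p_raw, method = adjust))
}

#' Linear regression through the origin
#'
#' Fits `y = slope * x` with a fixed zero intercept (the convention for
#' uptake-vs-H-Score calibration plots): `slope = sum(xy) / sum(x^2)`, the
#' standard error from the residual variance on n-1 degrees of freedom, and
#' the uncentered coefficient of determination
#' `R^2 = 1 - sum((y - yhat)^2) / sum(y^2)` (the centred form is ill-defined
#' without an intercept; the convention is recorded in the output).
#'
#' @param x,y numeric vectors (n >= 1; `x` must not be all zero). A data
#'   frame first argument with tidy-eval `x`/`y` columns is also accepted.
#' @return Object of class `origin_fit`; `tidy()` gives
#'   `(slope, slope_se, p_value)`, `glance()` gives
#'   `(r_squared, r_squared_convention, n, df)`.
#' @examples
#' fit <- regress_through_origin(c(50, 100, 200), 0.09 * c(50, 100, 200))
#' generics::tidy(fit)
#' @export
regress_through_origin <- function(x, y = NULL) {
  if (is.data.frame(x)) {
    stop("pass numeric vectors: regress_through_origin(x, y)", call. = FALSE)
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 1L || length(y) != n) stop("need matching x and y", call. = FALSE)
  if (all(x == 0)) {
    stop(structure(class = c("histopet_degenerate", "error", "condition"),
                   list(message = "slope through the origin is undefined when all x are 0",
                        call = NULL)))
  }
  sxx <- sum(x^2)
  slope <- sum(x * y) / sxx
  res <- y - slope * x
  df <- n - 1L
  se <- if (df > 0) sqrt(sum(res^2) / df / sxx) else NA_real_
  r2 <- if (sum(y^2) > 0) 1 - sum(res^2) / sum(y^2) else NA_real_
  p <- if (df > 0 && is.finite(se) && se > 0) {
    2 * stats::pt(-abs(slope / se), df = df)
  } else NA_real_
  structure(list(slope = slope, slope_se = se, r_squared = r2,
                 p_value = p, n = n, df = df,
                 data = tibble::tibble(x = x, y = y)),
            class = "origin_fit")
}

#' @export
print.origin_fit <- function(x, ...) {
  cat(sprintf(
    "Through-origin fit: slope = %.4g +/- %.2g, uncentered R^2 = %.3f, p = %.3g (n = %d)\n",
    x$slope, x$slope_se, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' @method tidy origin_fit
#' @export
tidy.origin_fit <- function(x, ...) {
  tibble::tibble(term = "slope", estimate = x$slope, std_error = x$slope_se,
                 p_value = x$p_value)
}

#' @method glance origin_fit
#' @export
glance.origin_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared,
                 r_squared_convention = "uncentered",
                 n = x$n, df = x$df)
}

#' Compare two independent correlation coefficients
#'
#' Two-sided test of equality of correlations from independent samples via
#' the Fisher z transform:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`.
#'
#' @param r1,r2 correlation coefficients with `|r| < 1`.
#' @param n1,n2 sample sizes (>= 4).
#' @return One-row tibble `(z, p_value)`.
#' @examples
#' compare_correlations(0.37, 43, 0.37, 33) # p = 1
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop(structure(class = c("histopet_degenerate", "error", "condition"),
                   list(message = "|r| = 1 gives an infinite Fisher z; comparison undefined",
                        call = NULL)))
  }
  stopifnot(n1 >= 4, n2 >= 4)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble::tibble(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}
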