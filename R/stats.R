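#' Linear regression of a metric on PEEP
#'
#' Ordinary least squares `y = m * x + k` of an airspace metric on the
#' applied end-expiratory pressure, with the slope t-test, R^2 and
#' residual bookkeeping. Observations are conventionally one per animal
#' per pressure step.
#'
#' @param x PEEP values (cmH2O); must be non-constant, n >= 3.
#' @param y Metric values (same length). Pairs with missing `y` are
#'   dropped.
#' @return An object of class `peep_fit` wrapping the `lm` fit, with
#'   `m`, `k`, `r_squared`, `p`, `n`, `rss`, `dof` and the 95% slope
#'   confidence interval.
#' @export
fit_peep_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("need at least 3 observations", call. = FALSE)
  if (var(x) == 0) stop("`x` must not be constant", call. = FALSE)
  fit <- lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- stats::confint(fit, "x", level = 0.95)
  r2 <- sm$r.squared
  pval <- unname(co["x", "Pr(>|t|)"])
  if (var(y) == 0) {  # flat response: no variance to explain
    r2 <- 0
    pval <- 1
    ci[] <- 0
  }
  structure(list(
    m = unname(co["x", "Estimate"]),
    k = unname(co["(Intercept)", "Estimate"]),
    r_squared = r2,
    p = pval,
    n = length(x),
    rss = sum(fit$residuals^2),
    dof = fit$df.residual,
    ci_low = unname(ci[1, 1]),
    ci_high = unname(ci[1, 2]),
    fit = fit), class = "peep_fit")
}

#' @export
print.peep_fit <- function(x, ...) {
  cat(sprintf(
    "<peep_fit> m=%.4g k=%.4g R2=%.3f p=%.3g (n=%d)\n",
    x$m, x$k, x$r_squared, x$p, x$n))
  invisible(x)
}

#' @export
tidy.peep_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$k, x$m),
                 conf.low = c(NA_real_, x$ci_low),
                 conf.high = c(NA_real_, x$ci_high),
                 p.value = c(NA_real_, x$p))
}

#' @export
glance.peep_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, p.value = x$p, nobs = x$n,
                 df.residual = x$dof, rss = x$rss)
}

#' Compare two regressions by the extra-sum-of-squares F-test
#'
#' Tests whether the pressure response differs between two datasets (e.g.
#' two ROIs). The primary `"coincidence"` variant tests a single common
#' line against separate lines (2 numerator dof: slope and intercept);
#' the `"slopes"` variant tests equal slopes allowing different
#' intercepts (1 numerator dof).
#'
#' @param data_a,data_b Data frames with columns `x` and `y`.
#' @param variant `"coincidence"` (default) or `"slopes"`.
#' @return An object of class `ftest_result` with `f`, `df1`, `df2`, `p`.
#' @export
compare_regressions <- function(data_a, data_b,
                                variant = c("coincidence", "slopes")) {
  variant <- match.arg(variant)
  stopifnot(all(c("x", "y") %in% names(data_a)),
            all(c("x", "y") %in% names(data_b)))
  a <- data_a[is.finite(data_a$x) & is.finite(data_a$y), c("x", "y")]
  b <- data_b[is.finite(data_b$x) & is.finite(data_b$y), c("x", "y")]
  if (nrow(a) < 3L || nrow(b) < 3L || var(a$x) == 0 || var(b$x) == 0)
    stop("degenerate fits: each dataset needs >= 3 points and ",
         "non-constant x", call. = FALSE)
  dat <- rbind(cbind(a, g = "a"), cbind(b, g = "b"))
  dat$g <- factor(dat$g)
  full <- lm(y ~ x * g, data = dat)
  reduced <- if (variant == "coincidence") lm(y ~ x, data = dat)
             else lm(y ~ x + g, data = dat)
  rss_full <- sum(full$residuals^2)
  rss_red <- sum(reduced$residuals^2)
  df1 <- reduced$df.residual - full$df.residual
  df2 <- full$df.residual
  if (rss_full <= .Machine$double.eps * rss_red && rss_red > 0) {
    f <- Inf; p <- 0
  } else if (rss_full == 0 && rss_red == 0) {
    f <- 0; p <- 1
  } else {
    f <- ((rss_red - rss_full) / df1) / (rss_full / df2)
    f <- max(f, 0)
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }
  structure(list(f = f, df1 = df1, df2 = df2, p = p, variant = variant),
            class = "ftest_result")
}

#' @export
print.ftest_result <- function(x, ...) {
  cat(sprintf("<ftest_result> %s: F(%d, %d)=%.4g, p=%.3g\n",
              x$variant, x$df1, x$df2, x$f, x$p))
  invisible(x)
}

#' @export
tidy.ftest_result <- function(x, ...) {
  tibble::tibble(statistic = x$f, df1 = x$df1, df2 = x$df2,
                 p.value = x$p, variant = x$variant)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test. Zero differences are dropped. For
#' n <= 15 effective pairs the p-value is exact, computed by enumerating
#' all 2^n sign assignments of the (possibly tied) ranks; beyond that a
#' normal approximation with tie correction is used. The exact branch is
#' therefore valid in the presence of ties, where the classical
#' signed-rank distribution is not.
#'
#' @param a,b Paired metric vectors of equal length.
#' @param exact_max Largest n for the exact enumeration (default 15).
#' @return An object of class `wilcoxon_result` with `w` (sum of ranks of
#'   positive differences), `n_eff`, `exact` flag and two-sided `p`.
#' @export
wilcoxon_paired <- function(a, b, exact_max = 15L) {
  stopifnot(length(a) == length(b), length(a) >= 1L)
  d <- a - b
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop("all differences are zero: no information", call. = FALSE)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    # enumerate all sign assignments; two-sided p by doubling the smaller
    # tail, capped at 1
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- as.vector(signs %*% r)
    p_le <- mean(ws <= w + 1e-9)
    p_ge <- mean(ws >= w - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    exact <- FALSE
  }
  structure(list(w = w, n_eff = n, exact = exact, p = p),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("<wilcoxon_result> W=%.3g, n=%d, p=%.4g (%s)\n",
              x$w, x$n_eff, x$p,
              if (x$exact) "exact" else "approximate"))
  invisible(x)
}

#' @export
tidy.wilcoxon_result <- function(x, ...) {
  tibble::tibble(statistic = x$w, n = x$n_eff, p.value = x$p,
                 exact = x$exact)
}

#' Multiplicity-corrected per-test alpha
#'
#' Bonferroni by default: the family-wise 0.05 level divided by the
#' number of comparisons. [holm_reject()] offers the sequential Holm
#' alternative for a set of observed p-values.
#'
#' @param n_comparisons Number of comparisons in the family (>= 1).
#' @param alpha Family-wise error rate (default 0.05).
#' @return The per-test significance level.
#' @export
adjust_alpha <- function(n_comparisons, alpha = 0.05) {
  if (n_comparisons < 1) stop("n_comparisons must be >= 1", call. = FALSE)
  alpha / n_comparisons
}

#' Holm sequential rejection
#'
#' @param p Vector of p-values.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Logical vector: which hypotheses are rejected.
#' @export
holm_reject <- function(p, alpha = 0.05) {
  stats::p.adjust(p, method = "holm") <= alpha
}

#' Summary report of a metrics table
#'
#' Produces the standard report for a tidy per-ROI metrics table: per-ROI
#' mean and SD of ASden/ASext at each nominal pressure step, per-ROI
#' regressions of each metric on PEEP, the pairwise extra-sum-of-squares
#' F-test matrix between the regional regressions, and pairwise paired
#' Wilcoxon tests between ROIs at each pressure with the
#' Bonferroni-corrected alpha. Missing ROI/pressure cells are reported as
#' NA, never dropped silently; ordering is deterministic.
#'
#' @param metrics Tidy metrics tibble from [roi_metrics()] (rows: animal x
#'   pressure x ROI).
#' @param regressor `"measured"` (default, when available) or
#'   `"nominal"`: which PEEP enters the regressions.
#' @param alpha Family-wise error rate (default 0.05).
#' @return An object of class `airspace_report`: a list of tibbles
#'   `summary`, `regressions`, `f_tests`, `wilcoxon`, plus `alpha` and
#'   the corrected `alpha_per_test`.
#' @export
summarize_run <- function(metrics, regressor = c("measured", "nominal"),
                          alpha = 0.05) {
  regressor <- match.arg(regressor)
  metric_cols <- c("asext", "asden")
  if (nrow(metrics) == 0L) {
    chr <- character(); num <- numeric(); int <- integer()
    return(structure(list(
      summary = tibble::tibble(metric = chr, roi = chr,
                               pressure_nominal = num, mean = num,
                               sd = num, n = int),
      regressions = tibble::tibble(metric = chr, roi = chr, m = num,
                                   k = num, r_squared = num, p = num,
                                   n = int, ci_low = num, ci_high = num),
      f_tests = tibble::tibble(metric = chr, roi_a = chr, roi_b = chr,
                               f = num, df1 = int, df2 = int, p = num),
      wilcoxon = tibble::tibble(metric = chr, pressure_nominal = num,
                                roi_a = chr, roi_b = chr, w = num,
                                n_eff = int, p = num,
                                significant = logical()),
      alpha = alpha, alpha_per_test = alpha, regressor = regressor),
      class = "airspace_report"))
  }
  if (regressor == "measured" &&
      all(is.na(metrics$pressure_measured))) regressor <- "nominal"
  metrics$x <- if (regressor == "measured") metrics$pressure_measured
               else metrics$pressure_nominal
  metrics$roi <- factor(as.character(metrics$roi), levels = ROI_LEVELS)
  long <- metrics |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols), names_to = "metric",
                        values_to = "value") |>
    dplyr::mutate(metric = factor(.data$metric, levels = metric_cols))
  summary_tbl <- long |>
    dplyr::group_by(metric = .data$metric, roi = .data$roi,
                    pressure_nominal = .data$pressure_nominal) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = sd(.data$value),
                     n = sum(is.finite(.data$value)),
                     .groups = "drop") |>
    tidyr::complete(metric, roi, pressure_nominal) |>
    dplyr::arrange(.data$metric, .data$roi,
                   dplyr::desc(.data$pressure_nominal))
  fit_one <- function(df) {
    ok <- is.finite(df$x) & is.finite(df$value)
    if (sum(ok) < 3L || var(df$x[ok]) == 0)
      return(tibble::tibble(m = NA_real_, k = NA_real_,
                            r_squared = NA_real_, p = NA_real_,
                            n = sum(ok), ci_low = NA_real_,
                            ci_high = NA_real_))
    f <- fit_peep_regression(df$x[ok], df$value[ok])
    tibble::tibble(m = f$m, k = f$k, r_squared = f$r_squared, p = f$p,
                   n = f$n, ci_low = f$ci_low, ci_high = f$ci_high)
  }
  regressions <- long |>
    dplyr::group_by(metric = .data$metric, roi = .data$roi) |>
    dplyr::group_modify(~fit_one(.x)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$metric, .data$roi)
  regional <- setdiff(levels(metrics$roi), "ALL")
  pairs <- utils::combn(regional, 2, simplify = FALSE)
  ftest_rows <- list()
  for (mc in metric_cols) for (pr in pairs) {
    da <- long[long$metric == mc & long$roi == pr[1], c("x", "value")]
    db <- long[long$metric == mc & long$roi == pr[2], c("x", "value")]
    names(da) <- names(db) <- c("x", "y")
    res <- tryCatch(compare_regressions(da, db), error = function(e) NULL)
    ftest_rows[[length(ftest_rows) + 1L]] <- tibble::tibble(
      metric = mc, roi_a = pr[1], roi_b = pr[2],
      f = if (is.null(res)) NA_real_ else res$f,
      df1 = if (is.null(res)) NA_integer_ else res$df1,
      df2 = if (is.null(res)) NA_integer_ else res$df2,
      p = if (is.null(res)) NA_real_ else res$p)
  }
  f_tests <- dplyr::bind_rows(ftest_rows)
  alpha_per_test <- adjust_alpha(length(pairs), alpha)
  wil_rows <- list()
  press <- sort(unique(metrics$pressure_nominal), decreasing = TRUE)
  for (mc in metric_cols) for (pn in press) for (pr in pairs) {
    da <- long[long$metric == mc & long$roi == pr[1] &
                 long$pressure_nominal == pn, c("animal", "value")]
    db <- long[long$metric == mc & long$roi == pr[2] &
                 long$pressure_nominal == pn, c("animal", "value")]
    merged <- dplyr::inner_join(da, db, by = "animal",
                                suffix = c("_a", "_b"))
    res <- tryCatch(
      wilcoxon_paired(merged$value_a, merged$value_b),
      error = function(e) NULL)
    wil_rows[[length(wil_rows) + 1L]] <- tibble::tibble(
      metric = mc, pressure_nominal = pn, roi_a = pr[1], roi_b = pr[2],
      w = if (is.null(res)) NA_real_ else res$w,
      n_eff = if (is.null(res)) NA_integer_ else res$n_eff,
      p = if (is.null(res)) NA_real_ else res$p,
      significant = if (is.null(res)) NA else res$p < alpha_per_test)
  }
  structure(list(summary = summary_tbl, regressions = regressions,
                 f_tests = f_tests, wilcoxon = dplyr::bind_rows(wil_rows),
                 alpha = alpha, alpha_per_test = alpha_per_test,
                 regressor = regressor),
            class = "airspace_report")
}

#' @export
print.airspace_report <- function(x, ...) {
  cat("<airspace_report> regressor:", x$regressor,
      " alpha per test:", format(x$alpha_per_test), "\n")
  if (nrow(x$regressions)) {
    cat("regressions:\n")
    print(x$regressions)
  } else cat("(empty report)\n")
  invisible(x)
}
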