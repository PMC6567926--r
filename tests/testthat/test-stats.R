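test_that("OLS recovers exact lines and matches the closed form", {
  x <- c(0, 3, 6, 9, 12)
  f <- suppressWarnings(fit_peep_regression(x, 2 * x + 5))
  expect_equal(f$m, 2)
  expect_equal(f$k, 5)
  expect_equal(f$r_squared, 1)
  # closed-form Sxy/Sxx identity on random data
  set.seed(31)
  for (k in 1:25) {
    xx <- rnorm(sample(5:30, 1))
    yy <- 1.5 * xx + rnorm(length(xx))
    fit <- fit_peep_regression(xx, yy)
    sxy <- sum((xx - mean(xx)) * (yy - mean(yy)))
    sxx <- sum((xx - mean(xx))^2)
    expect_equal(fit$m, sxy / sxx, tolerance = 1e-10)
    expect_equal(fit$k, mean(yy) - fit$m * mean(xx), tolerance = 1e-10)
  }
  # flat response
  f0 <- suppressWarnings(fit_peep_regression(x, rep(4, 5)))
  expect_equal(f0$m, 0)
  expect_equal(f0$r_squared, 0)
  expect_error(fit_peep_regression(rep(1, 5), 1:5), "constant")
  expect_error(fit_peep_regression(1:2, 1:2), "at least 3")
})

test_that("a reference mean ASden profile gives the pre-computed slope", {
  # frozen from the hand Sxy/Sxx formula: Sxy = 118.5, Sxx = 90
  x <- c(12, 9, 6, 3, 0)
  y <- c(233.5, 230.6, 229.1, 224.7, 216.7)
  f <- fit_peep_regression(x, y)
  expect_equal(f$m, 1.3166666667, tolerance = 1e-9)
  expect_equal(f$k, 219.02, tolerance = 1e-9)
  expect_equal(f$r_squared, 118.5^2 / (90 * 170.968), tolerance = 1e-9)
  # fitting group means is NOT the same as the disaggregated fit that
  # yielded the reported disaggregated coefficient 1.47
  expect_gt(abs(f$m - 1.47), 0.1)
})

test_that("pooled OLS equals the fit to group means in balanced designs", {
  set.seed(17)
  for (k in 1:10) {
    x_levels <- c(12, 9, 6, 3, 0)
    n_per <- 7
    x <- rep(x_levels, each = n_per)
    y <- 220 + 1.4 * x + rnorm(length(x), 0, 8)
    pooled <- fit_peep_regression(x, y)
    means <- tapply(y, x, mean)
    bym <- fit_peep_regression(as.numeric(names(means)),
                               as.numeric(means))
    expect_equal(pooled$m, bym$m, tolerance = 1e-10)
    expect_equal(pooled$k, bym$k, tolerance = 1e-10)
  }
})

test_that("tidy and glance expose the fit in broom shape", {
  f <- fit_peep_regression(c(0, 3, 6, 9, 12), c(1, 2, 2.5, 4, 5))
  td <- tidy(f)
  expect_equal(td$term, c("intercept", "slope"))
  expect_equal(td$estimate[2], f$m)
  gl <- glance(f)
  expect_equal(gl$r.squared, f$r_squared)
  expect_equal(gl$nobs, 5L)
})

test_that("F-test separates different regressions and accepts identical ones", {
  x <- 1:20
  a <- data.frame(x = x, y = 1 * x + 3)
  b <- data.frame(x = x, y = 2 * x + 3)
  res <- compare_regressions(a, b)
  expect_lt(res$p, 1e-6)
  # identical datasets: no extra variance explained
  set.seed(41)
  aa <- data.frame(x = x, y = x + rnorm(20))
  same <- compare_regressions(aa, aa)
  expect_gte(same$p, 0.999)
  expect_lt(same$f, 1e-6)
  # equal slopes, different intercepts: slopes-only variant sees nothing
  cc <- data.frame(x = x, y = x + 5 + rnorm(20, 0, 0.3))
  slopes <- compare_regressions(aa, cc, variant = "slopes")
  expect_gte(slopes$p, 0.05)
  coinc <- compare_regressions(aa, cc, variant = "coincidence")
  expect_lt(coinc$p, 0.01)
  expect_equal(slopes$df1, 1L)
  expect_equal(coinc$df1, 2L)
  expect_error(compare_regressions(a[1:2, ], b), "degenerate")
})

test_that("identical groups give p >= 0.999 across many random fixtures", {
  set.seed(53)
  for (k in 1:100) {
    n <- sample(5:15, 1)
    d <- data.frame(x = rnorm(n), y = rnorm(n))
    expect_gte(compare_regressions(d, d)$p, 0.999)
  }
})

test_that("exact Wilcoxon enumeration reproduces the small-sample law", {
  # n = 7 pairs, all differences positive: p = 2 / 2^7
  res <- wilcoxon_paired(c(11, 14, 16, 20, 25, 31, 38), 1:7)
  expect_true(res$exact)
  expect_equal(res$n_eff, 7L)
  expect_equal(res$p, 2 / 128)
  expect_equal(res$w, 28)
  # equal except one pair: a single rank carries no information
  a <- c(1, 2, 3, 4); b <- c(1, 2, 3, 7)
  r1 <- wilcoxon_paired(a, b)
  expect_equal(r1$n_eff, 1L)
  expect_equal(r1$p, 1)
  # antisymmetric differences: W is half the total rank sum, p = 1
  r2 <- wilcoxon_paired(c(5, 1), c(1, 5))
  expect_equal(r2$w, 1.5)
  expect_equal(r2$p, 1)
  expect_error(wilcoxon_paired(1:4, 1:4), "zero")
})

test_that("exact branch agrees with the base signed-rank test when tie-free", {
  set.seed(61)
  for (k in 1:20) {
    n <- sample(4:10, 1)
    a <- rnorm(n); b <- rnorm(n)
    mine <- wilcoxon_paired(a, b)
    base <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(mine$p, base$p.value, tolerance = 1e-12)
  }
})

test_that("large samples fall back to the tie-corrected normal approximation", {
  set.seed(71)
  a <- rnorm(25, 0.4); b <- rnorm(25)
  mine <- wilcoxon_paired(a, b)
  expect_false(mine$exact)
  base <- wilcox.test(a, b, paired = TRUE, exact = FALSE,
                      correct = FALSE)
  expect_equal(mine$p, base$p.value, tolerance = 1e-10)
})

test_that("multiplicity corrections follow Bonferroni and Holm", {
  expect_equal(adjust_alpha(1), 0.05)
  expect_equal(adjust_alpha(3), 0.05 / 3)
  expect_error(adjust_alpha(0), ">= 1")
  # Holm sequence on {0.001, 0.02, 0.04}: 0.001 < 0.05/3, 0.02 < 0.05/2,
  # 0.04 < 0.05/1 -> all three rejected
  expect_equal(holm_reject(c(0.001, 0.02, 0.04)), rep(TRUE, 3))
  # 0.03 > 0.05/2 stops the Holm sequence after the first rejection
  expect_equal(holm_reject(c(0.001, 0.03, 0.06)), c(TRUE, FALSE, FALSE))
})

test_that("summarize_run produces the full deterministic report", {
  set.seed(91)
  grid <- expand.grid(animal = sprintf("a%d", 1:5),
                      pressure_nominal = c(12, 9, 6, 3, 0),
                      roi = c("ALL", "subpleural", "mantellar", "core"),
                      stringsAsFactors = FALSE)
  grid$pressure_measured <- grid$pressure_nominal + rnorm(nrow(grid), 0.5,
                                                          0.2)
  grid$asden <- 200 + 1.5 * grid$pressure_nominal + rnorm(nrow(grid), 0, 4)
  grid$asext <- 17 + rnorm(nrow(grid), 0, 0.5)
  rep <- summarize_run(tibble::tibble(grid), regressor = "nominal")
  expect_s3_class(rep, "airspace_report")
  expect_equal(nrow(rep$regressions), 8)  # 2 metrics x 4 ROIs
  expect_equal(nrow(rep$f_tests), 6)     # 2 metrics x 3 ROI pairs
  expect_equal(nrow(rep$wilcoxon), 30)   # 2 x 5 pressures x 3 pairs
  expect_equal(rep$alpha_per_test, 0.05 / 3)
  asden_all <- rep$regressions[rep$regressions$metric == "asden" &
                                 rep$regressions$roi == "ALL", ]
  expect_lt(abs(asden_all$m - 1.5), 0.5)
  # deterministic: same input, identical report
  rep2 <- summarize_run(tibble::tibble(grid), regressor = "nominal")
  expect_identical(rep$regressions, rep2$regressions)
  # missing cells are reported as NA rather than dropped
  part <- grid[!(grid$roi == "core" & grid$pressure_nominal == 0), ]
  rep3 <- summarize_run(tibble::tibble(part), regressor = "nominal")
  core0 <- rep3$summary[rep3$summary$roi == "core" &
                          rep3$summary$pressure_nominal == 0, ]
  expect_equal(nrow(core0), 2)
  expect_true(all(is.na(core0$mean)))
})

test_that("an empty metrics table gives an empty report with headers", {
  rep <- summarize_run(tibble::tibble(
    animal = character(), pressure_nominal = numeric(),
    pressure_measured = numeric(), roi = character(),
    asden = numeric(), asext = numeric()))
  expect_equal(nrow(rep$regressions), 0)
  expect_true(all(c("metric", "roi", "m", "k", "r_squared", "p") %in%
                    names(rep$regressions)))
  expect_true(all(c("metric", "roi_a", "roi_b", "p") %in%
                    names(rep$f_tests)))
})
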