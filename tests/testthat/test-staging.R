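# Curve families, model selection, standard curves, inverse prediction, and
# the cohort statistics.

test_that("exact data are recovered exactly by their family", {
  x <- 1:10
  lin <- fit_family(x, 2 * x + 1, "linear")
  expect_equal(unname(coef(lin)), c(1, 2), tolerance = 1e-12)
  expect_gt(lin$r_squared, 1 - 1e-12)

  quad <- fit_family(x, x^2, "quadratic")
  expect_equal(unname(coef(quad)), c(0, 0, 1), tolerance = 1e-9)
  expect_gt(quad$r_squared, 1 - 1e-12)
  expect_lt(fit_family(x, x^2, "linear")$r_squared, 1)

  pw <- fit_family(x, 3 * x^1.7, "power")
  expect_equal(unname(coef(pw)), c(3, 1.7), tolerance = 1e-9)
  ex <- fit_family(x, 2 * exp(0.3 * x), "exponential")
  expect_equal(unname(coef(ex)), c(2, 0.3), tolerance = 1e-9)
  lg <- fit_family(x, 1 + 4 * log(x), "logarithmic")
  expect_equal(unname(coef(lg)), c(1, 4), tolerance = 1e-9)
  sq <- fit_family(x, -2 + 5 * sqrt(x), "sqrt")
  expect_equal(unname(coef(sq)), c(-2, 5), tolerance = 1e-9)
})

test_that("family domain constraints are enforced as skippable conditions", {
  expect_error(fit_family(c(-1, 1:9), 1:10, "logarithmic"),
               class = "rrna_domain_error")
  expect_error(fit_family(1:10, c(-1, 1:9), "power"),
               class = "rrna_domain_error")
  expect_error(fit_family(c(-1, 1:9), 1:10, "sqrt"),
               class = "rrna_domain_error")
  expect_error(fit_family(1:3, 1:3, "cubic"), "at least")
})

test_that("coefficients match an independent normal-equations solve", {
  co <- gen_cohort(recovery_params("quadratic", sd = 0.3), 100, seed = 55)
  fit <- fit_family(co$gsi, co$ln_pct5S, "quadratic")
  X <- cbind(1, co$gsi, co$gsi^2)
  beta <- solve(t(X) %*% X, t(X) %*% co$ln_pct5S)
  expect_equal(unname(coef(fit)), as.numeric(beta), tolerance = 1e-8)
  # and the estimates sit within 3 SE of the generating model
  truth <- c(1, 0.5, -0.02)
  expect_true(all(abs(fit$coef_table[, "estimate"] - truth) <
                    3 * fit$coef_table[, "se"]))
})

test_that("R-squared respects polynomial nesting on arbitrary data", {
  for (seed in 1:5) {
    co <- gen_cohort(cohort_preset("bluegill_like"), 60, seed = seed)
    f <- co[co$sex == "F", ]
    r2 <- vapply(c("linear", "quadratic", "cubic"),
                 function(fam) fit_family(f$gsi, f$ln_pct5S, fam)$r_squared,
                 numeric(1))
    expect_gte(r2[["quadratic"]], r2[["linear"]] - 1e-12)
    expect_gte(r2[["cubic"]], r2[["quadratic"]] - 1e-12)
  }
})

test_that("selection prefers significant fits and earns extra terms", {
  x <- seq(1, 10, length.out = 40)
  y <- with_seed(7, 1 + 0.5 * x - 0.15 * x^2 + rnorm(40, 0, 0.3))
  fits <- lapply(c("linear", "quadratic", "cubic"),
                 function(fam) fit_family(x, y, fam))
  best <- select_best(fits)
  expect_s3_class(best, "rrna_fit")
  expect_identical(best$family, "quadratic")

  # a clearly better quadratic beats a worse linear when both significant
  expect_gt(fits[[2]]$r_squared, fits[[1]]$r_squared)

  # pure noise: no family significant
  y0 <- with_seed(8, rnorm(40))
  f0 <- lapply(c("linear", "quadratic"), function(fam) fit_family(x, y0, fam))
  expect_s3_class(select_best(f0), "rrna_no_fit")
  expect_error(select_best(list()), "no candidate")
})

test_that("the selector recovers the generating family across seeds", {
  pick <- function(preset, index, seeds) {
    vapply(seeds, function(s) {
      co <- gen_cohort(cohort_preset(preset), 100, seed = s)
      build_standard_curve(co[co$sex == "F", ], index, "gsi")$fit$family
    }, character(1))
  }
  lin <- pick("yellow_perch_like", "ln_pct5S", 1:10)
  expect_gte(sum(lin == "linear"), 6)
  quad <- pick("yellow_perch_like", "ln_ratio", 1:10)
  expect_gte(sum(quad == "quadratic"), 6)
})

test_that("standard curves validate their inputs", {
  co <- gen_cohort(cohort_preset("bluegill_like"), 60, seed = 3)
  f <- co[co$sex == "F", ]
  expect_error(build_standard_curve(f[1:5, ], "ln_pct5S", "gsi"), "at least")
  f2 <- f
  f2$gsi <- 5
  expect_error(build_standard_curve(f2, "ln_pct5S", "gsi"), "constant")
  expect_error(build_standard_curve(f, "nope", "gsi"), "contain")
})

test_that("noiseless standard curves reproduce the generator and invert", {
  co <- gen_cohort(recovery_params("linear", sd = 0), 50, seed = 4)
  cv <- build_standard_curve(co, "ln_pct5S", "gsi")
  expect_identical(cv$fit$family, "linear")
  expect_equal(unname(coef(cv$fit)), c(2, 0.3), tolerance = 1e-8)
  expect_gt(cv$fit$r_squared, 1 - 1e-9)

  # inverse consistency across the response range
  for (g in seq(cv$gsi_min, cv$gsi_max, length.out = 9)) {
    p <- predict_maturity(cv, curve_forward(cv, g))
    expect_equal(p$response, g, tolerance = 1e-6)
    expect_false(p$extrapolated)
  }
  # score endpoints and monotonicity
  expect_equal(maturity_score(cv, cv$gsi_min), 0)
  expect_equal(maturity_score(cv, cv$gsi_max), 10)
  sc <- maturity_score(cv, seq(cv$gsi_min, cv$gsi_max, length.out = 20))
  expect_true(all(diff(sc) > 0))
  # clipping outside the anchors
  expect_equal(maturity_score(cv, cv$gsi_max + 5), 10)
  expect_equal(maturity_score(cv, cv$gsi_min - 5), 0)
})

test_that("a non-monotone quadratic returns both admissible branches", {
  x <- seq(0, 10, length.out = 60)
  y <- 2 + 3 * x - 0.3 * x^2   # vertex at x = 5
  rec <- data.frame(gsi = x, idx = y)
  cv <- build_standard_curve(rec, "idx", "gsi")
  expect_identical(cv$fit$family, "quadratic")
  p <- predict_maturity(cv, 8)  # crossed twice inside [0, 10]
  expect_equal(p$n_branches, 2L)
  # brute-force grid oracle for the two crossings of y = 8
  g <- seq(0, 10, length.out = 200001)
  d <- abs(2 + 3 * g - 0.3 * g^2 - 8)
  lo <- g[g < 5][which.min(d[g < 5])]
  hi <- g[g >= 5][which.min(d[g >= 5])]
  expect_equal(sort(p$response), sort(c(lo, hi)), tolerance = 1e-4)
})

test_that("prediction flags extrapolation and impossible inversions", {
  co <- gen_cohort(recovery_params("linear", sd = 0), 50, seed = 4)
  cv <- build_standard_curve(co, "ln_pct5S", "gsi")
  p <- predict_maturity(cv, max(co$ln_pct5S) + 1)
  expect_true(p$extrapolated)
  # sqrt family: index below the intercept has no preimage
  rec <- data.frame(gsi = seq(1, 16, length.out = 30))
  rec$idx <- 1 + 2 * sqrt(rec$gsi)
  cvs <- build_standard_curve(rec, "idx", "gsi")
  if (cvs$fit$family == "sqrt") {
    p2 <- predict_maturity(cvs, 0.5)
    expect_true(p2$extrapolated)
  }
})

test_that("prediction intervals are finite and contain the point estimate", {
  co <- gen_cohort(recovery_params("linear", sd = 0.3), 80, seed = 14)
  cv <- build_standard_curve(co, "ln_pct5S", "gsi")
  p <- predict_maturity(cv, curve_forward(cv, 5))
  expect_true(all(is.finite(p$interval)))
  expect_lt(p$interval[1, "lower"], p$response[1])
  expect_gt(p$interval[1, "upper"], p$response[1])
})

test_that("standard curves round-trip through JSON", {
  co <- gen_cohort(cohort_preset("bluegill_like"), 80, seed = 6)
  cv <- build_standard_curve(co[co$sex == "F", ], "ln_pct5S", "gsi")
  path <- withr::local_tempfile(fileext = ".json")
  write_standard_curve(cv, path)
  back <- read_standard_curve(path)
  expect_equal(back$fit$coefficients, cv$fit$coefficients, tolerance = 1e-12)
  expect_equal(predict_maturity(back, 2.5)$response,
               predict_maturity(cv, 2.5)$response, tolerance = 1e-9)
})

test_that("pearson_r matches the textbook formula and handles sign", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.4, 6.1, 0.8, 7.3, 2.9, 5.0)
  y <- c(2.0, 3.1, 2.4, 6.0, 4.1, 5.2, 1.1, 8.0, 3.5, 4.6)
  out <- pearson_r(x, y)
  n <- length(x)
  r_hand <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  t_hand <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
  p_hand <- 2 * pt(-abs(t_hand), n - 2)
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  expect_equal(out$p, p_hand, tolerance = 1e-12)

  expect_equal(pearson_r(1:10, 1:10)$r, 1)
  expect_equal(pearson_r(1:10, -(1:10))$r, -1)
  expect_error(pearson_r(1:10, rep(1, 10)), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("the t-test matches the pooled-variance hand formula", {
  x <- c(5.1, 4.8, 6.0, 5.5, 4.9, 5.7, 5.2, 6.1, 5.0, 5.4)
  y <- x + 0.8   # shifted copy: equal variances by construction
  out <- two_sample_ttest(x, y)
  expect_true(out$var_equal)
  n <- length(x)
  sp2 <- ((n - 1) * var(x) + (n - 1) * var(y)) / (2 * n - 2)
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / n))
  p_hand <- 2 * pt(-abs(t_hand), 2 * n - 2)
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  expect_equal(out$p, p_hand, tolerance = 1e-12)
  expect_equal(out$df, 2 * n - 2)

  same <- two_sample_ttest(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(two_sample_ttest(1, 1:5), "at least 2")
})

test_that("a five-sd shift is detected with p < 0.001 at n = 20", {
  x <- with_seed(19, rnorm(20, 0, 1))
  y <- with_seed(20, rnorm(20, 5, 1))   # true difference of 5 sd
  out <- two_sample_ttest(x, y)
  expect_lt(out$p, 0.001)
  expect_identical(out$stars, "***")
})
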