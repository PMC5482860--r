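# Shared fixtures: small deterministic traces and cohorts built in code.

# single Gaussian peak on a uniform grid, optionally offset; analytic area
# amp * sigma * sqrt(2*pi)
gaussian_trace <- function(amp = 40, apex = 70, sigma = 0.3, offset = 0,
                           from = 38, to = 124, dt = 0.02, id = "g1") {
  t <- seq(from, to, by = dt)
  new_trace(t, offset + amp * exp(-0.5 * ((t - apex) / sigma)^2),
            meta = list(id = id))
}

# hand-coded trapezoid sum, the independent integration oracle
trapz_oracle <- function(t, y) {
  n <- length(t)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

# random composition with all five fractions comfortably detectable
random_composition <- function(seed, min_frac = 0.02) {
  with_seed(seed, {
    w <- stats::rgamma(5, shape = 2) + 0.2
    f <- w / sum(w)
    f <- (1 - 5 * min_frac) * f + min_frac
    composition_truth(f[1], f[2], f[3], f[4], f[5])
  })
}

# all-female cohort parameters with a stated linear or quadratic model for
# ln_pct5S, used by the regression-recovery tests
recovery_params <- function(family = c("linear", "quadratic"), sd = 0.4) {
  family <- match.arg(family)
  coef <- if (family == "linear") c(2, 0.3) else c(1, 0.5, -0.02)
  flat <- list(family = "flat", coef = 0, sd = 0.1)
  cohort_params(
    species = "recovery", oogenesis = "synchronous",
    female = list(ln_pct5S = list(family = family, coef = coef, sd = sd),
                  ln_ratio = flat, pct18S = list(family = "flat", coef = 10,
                                                 sd = 0.5)),
    male = list(ln_pct5S = flat, ln_ratio = flat,
                pct18S = list(family = "flat", coef = 10, sd = 0.5)),
    gsi_range_f = c(1, 10), sex_ratio = 1
  )
}
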