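# Standard curves for maturity staging: fit the calibration regression of an
# rRNA index on maturity (GSI or PGO volume percent) across the family menu,
# select the best model, and invert it to predict maturity from a measured
# index, reported both as the response value and as a normalized 10-point
# score anchored to the cohort's observed GSI range.

#' Build a species-specific standard curve
#'
#' Fits every family in `families` as the calibration regression
#' `index = f(maturity)` -- the direction in which the relationship was
#' established (index on the y axis, GSI or PGO volume percent on the x
#' axis) -- and selects the best-fitting significant model. Prediction of
#' maturity from a measured index is the inverse of this fit
#' ([predict_maturity()]). The curve also stores the observed index range
#' (valid range for inversion) and the observed response min/max, which are
#' the anchors of the 10-point score.
#'
#' @param records Data frame of fish records, one row per fish, carrying the
#'   predictor and response columns (e.g. from [gen_cohort()]). Should be one
#'   species and one sex.
#' @param predictor Name of the index column used later for prediction:
#'   `"ln_pct5S"`, `"ln_ratio"` or `"pct18S"` (any numeric column works).
#' @param response Name of the maturity column: `"gsi"` or
#'   `"pgoo_volume_percent"`.
#' @param families Families to compare, see [curve_families()]. Families
#'   whose domain constraints are violated by the data are skipped with a
#'   recorded reason.
#' @param alpha Significance level for the model F-test.
#' @param min_n Minimum number of complete records (default 8).
#' @return An object of class `"rrna_standard_curve"` with components `fit`
#'   (the selected `rrna_fit`), `predictor`, `response`, `predictor_range`,
#'   `gsi_min`, `gsi_max`, `n`, `skipped`.
#' @export
build_standard_curve <- function(records, predictor, response,
                                 families = curve_families(), alpha = 0.05,
                                 min_n = 8) {
  stopifnot(is.data.frame(records))
  if (!predictor %in% names(records) || !response %in% names(records)) {
    stop("`records` must contain the predictor and response columns",
         call. = FALSE)
  }
  x <- as.numeric(records[[response]])   # maturity axis of the fit
  y <- as.numeric(records[[predictor]])  # index axis of the fit
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < min_n) {
    stop(sprintf("need at least %d complete records, got %d", min_n,
                 length(x)), call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("constant response; no curve can be built", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant predictor; no curve can be built", call. = FALSE)

  fits <- list()
  skipped <- character()
  for (fam in families) {
    fits[[fam]] <- tryCatch(fit_family(x, y, fam), rrna_domain_error = function(e) {
      skipped[[fam]] <<- conditionMessage(e)
      NULL
    })
  }
  best <- select_best(fits, alpha = alpha)
  if (inherits(best, "rrna_no_fit")) {
    stop("no regression family reached significance; no standard curve built",
         call. = FALSE)
  }
  structure(list(
    fit = best,
    predictor = predictor,
    response = response,
    predictor_range = range(y),
    gsi_min = min(x),
    gsi_max = max(x),
    n = length(x),
    skipped = skipped
  ), class = "rrna_standard_curve")
}

#' @export
print.rrna_standard_curve <- function(x, ...) {
  cat(sprintf("<rrna_standard_curve> %s ~ f(%s), n = %d\n",
              x$predictor, x$response, x$n))
  print(x$fit)
  cat(sprintf("  valid %s range: [%.4g, %.4g]; score anchors: [%.4g, %.4g]\n",
              x$predictor, x$predictor_range[1], x$predictor_range[2],
              x$gsi_min, x$gsi_max))
  invisible(x)
}

#' Forward evaluation of a standard curve
#'
#' The fitted index value at a given maturity (the calibration direction).
#'
#' @param curve An `rrna_standard_curve`.
#' @param g Maturity values (GSI or PGO volume percent).
#' @return Fitted index values.
#' @export
curve_forward <- function(curve, g) {
  stopifnot(inherits(curve, "rrna_standard_curve"))
  unname(forward_eval(curve$fit, g))
}

#' Normalized 10-point maturity score
#'
#' Linear rescaling of the response onto `[0, 10]` over the cohort's observed
#' range, clipped at the ends: `score = 10 (g - gsi_min)/(gsi_max - gsi_min)`.
#'
#' @param curve An `rrna_standard_curve`.
#' @param g Response values.
#' @return Scores in `[0, 10]`.
#' @export
maturity_score <- function(curve, g) {
  stopifnot(inherits(curve, "rrna_standard_curve"))
  s <- 10 * (g - curve$gsi_min) / (curve$gsi_max - curve$gsi_min)
  pmin(10, pmax(0, s))
}

# analytic inverses for the monotone families; returns numeric(0) when no
# real solution exists in the family's domain
invert_analytic <- function(fit, v) {
  b <- fit$coefficients
  switch(fit$family,
    linear      = if (b[2] != 0) (v - b[1]) / b[2] else numeric(0),
    logarithmic = if (b[2] != 0) exp((v - b[1]) / b[2]) else numeric(0),
    exponential = if (b[2] != 0 && v / b[1] > 0) log(v / b[1]) / b[2] else numeric(0),
    power       = if (b[2] != 0 && v / b[1] > 0) (v / b[1])^(1 / b[2]) else numeric(0),
    sqrt        = if (b[2] != 0 && (v - b[1]) / b[2] >= 0)
                    ((v - b[1]) / b[2])^2 else numeric(0),
    NULL)
}

# numeric inversion on [lo, hi]: locate sign changes of f(g) - v on a grid,
# refine each bracket by uniroot
invert_numeric <- function(fit, v, lo, hi, n_grid = 1024L) {
  g <- seq(lo, hi, length.out = n_grid)
  d <- forward_eval(fit, g) - v
  roots <- numeric(0)
  exact <- which(d == 0)
  roots <- c(roots, g[exact])
  sgn <- sign(d)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in flips) {
    r <- stats::uniroot(function(z) forward_eval(fit, z) - v,
                        lower = g[i], upper = g[i + 1], tol = 1e-10)
    roots <- c(roots, r$root)
  }
  sort(unique(roots))
}

#' Predict maturity (and its 10-point score) from a measured index
#'
#' Inverts the standard curve at the measured index value: analytically for
#' the monotone families (linear, logarithmic, power, exponential,
#' sqrt-linear), by bisection over the curve's response range for the
#' quadratic and cubic families. A non-monotone curve can admit more than
#' one maturity value for the same index; all admissible branches are
#' returned with `n_branches > 1` so the caller can disambiguate (e.g. by
#' sampling month). A prediction interval is propagated to the response
#' scale by the delta method from `s`, the standard error of the estimate.
#'
#' @param curve An `rrna_standard_curve`.
#' @param index_value A single measured index value (finite).
#' @param level Coverage of the prediction interval (default 0.95).
#' @return A list of class `"rrna_prediction"`: `response` (vector, one per
#'   branch), `score` (10-point score per branch), `interval` (matrix with
#'   columns `lower`, `upper`), `extrapolated` (TRUE when the index lies
#'   outside the curve's observed range or the solution leaves the response
#'   range), `n_branches`.
#' @export
predict_maturity <- function(curve, index_value, level = 0.95) {
  stopifnot(inherits(curve, "rrna_standard_curve"))
  stopifnot_scalar_number(index_value, "index_value")
  fit <- curve$fit
  lo <- curve$gsi_min
  hi <- curve$gsi_max

  g <- invert_analytic(fit, index_value)
  if (is.null(g)) {
    g <- invert_numeric(fit, index_value, lo, hi)
  }
  g <- as.numeric(g)
  outside_x <- index_value < curve$predictor_range[1] ||
    index_value > curve$predictor_range[2]
  if (!length(g)) {
    return(structure(list(response = NA_real_, score = NA_real_,
                          interval = cbind(lower = NA_real_, upper = NA_real_),
                          extrapolated = TRUE, n_branches = 0L),
                     class = "rrna_prediction"))
  }
  outside_g <- g < lo | g > hi

  dfdg <- forward_deriv(fit, g)
  tq <- stats::qt((1 + level) / 2, df = max(fit$df_residual, 1))
  half <- if (fit$transformed_y) {
    # s lives on the log-index scale; d log f / dg = f'/f
    fv <- forward_eval(fit, g)
    tq * fit$s * abs(fv / dfdg)
  } else {
    tq * fit$s / abs(dfdg)
  }
  structure(list(
    response = g,
    score = maturity_score(curve, g),
    interval = cbind(lower = g - half, upper = g + half),
    extrapolated = outside_x || any(outside_g),
    n_branches = length(g)
  ), class = "rrna_prediction")
}

#' @export
print.rrna_prediction <- function(x, ...) {
  cat(sprintf("<rrna_prediction> %d branch(es)%s\n", x$n_branches,
              if (isTRUE(x$extrapolated)) " [extrapolated]" else ""))
  for (i in seq_len(x$n_branches)) {
    cat(sprintf("  response = %.4g (score %.2f), %s\n", x$response[i],
                x$score[i],
                sprintf("PI [%.4g, %.4g]", x$interval[i, 1], x$interval[i, 2])))
  }
  invisible(x)
}

#' Serialize / restore a standard curve as JSON
#'
#' Stores the selected family, natural-scale coefficients, fit statistics,
#' valid index range and score anchors so a curve built once can be reused
#' for prediction and sex calling without refitting.
#'
#' @param curve An `rrna_standard_curve`.
#' @param path JSON file path.
#' @export
write_standard_curve <- function(curve, path) {
  stopifnot(inherits(curve, "rrna_standard_curve"))
  obj <- list(
    predictor = curve$predictor, response = curve$response,
    family = curve$fit$family,
    coefficients = as.list(curve$fit$coefficients),
    r_squared = curve$fit$r_squared, p_value = curve$fit$p_value,
    s = curve$fit$s, n = curve$fit$n, df_residual = curve$fit$df_residual,
    transformed_y = curve$fit$transformed_y,
    predictor_range = curve$predictor_range,
    gsi_min = curve$gsi_min, gsi_max = curve$gsi_max
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_standard_curve
#' @export
read_standard_curve <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- structure(list(
    family = obj$family,
    coefficients = unlist(obj$coefficients),
    r_squared = obj$r_squared, p_value = obj$p_value, s = obj$s,
    n = obj$n, df_residual = obj$df_residual,
    transformed_y = isTRUE(obj$transformed_y)
  ), class = "rrna_fit")
  structure(list(
    fit = fit, predictor = obj$predictor, response = obj$response,
    predictor_range = as.numeric(obj$predictor_range),
    gsi_min = obj$gsi_min, gsi_max = obj$gsi_max, n = obj$n,
    skipped = character()
  ), class = "rrna_standard_curve")
}
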