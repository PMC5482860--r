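# Electropherogram handling: the trace container, ladder-based time-to-size
# calibration, baseline correction, valley-to-valley peak detection and
# integration with time-corrected areas, and marker removal.

#' Construct an electropherogram trace
#'
#' @param time Migration times in seconds, strictly increasing.
#' @param fluorescence Fluorescence in arbitrary units, finite, same length.
#' @param meta Named list of sample metadata: `id`, `species`, `tissue`,
#'   `month`, `rin` (all optional).
#' @return An object of class `"rrna_trace"`: a list with `time`,
#'   `fluorescence`, `meta`.
#' @export
new_trace <- function(time, fluorescence, meta = list()) {
  time <- as.numeric(time)
  fluorescence <- as.numeric(fluorescence)
  if (length(time) != length(fluorescence)) {
    stop("time and fluorescence must have the same length", call. = FALSE)
  }
  if (length(time) >= 2 && any(diff(time) <= 0)) {
    bad <- which(diff(time) <= 0)[1] + 1L
    stop(sprintf("time must be strictly increasing (violation at point %d)",
                 bad), call. = FALSE)
  }
  if (any(!is.finite(fluorescence))) {
    stop("fluorescence values must be finite", call. = FALSE)
  }
  structure(list(time = time, fluorescence = fluorescence, meta = meta),
            class = "rrna_trace")
}

#' @export
print.rrna_trace <- function(x, ...) {
  cat(sprintf("<rrna_trace> %d points, %.2f-%.2f s, id=%s\n",
              length(x$time), min(x$time), max(x$time),
              x$meta$id %||% "?"))
  invisible(x)
}

#' Read / write electropherogram traces
#'
#' The on-disk format is plain text: header lines starting with `#` carrying
#' `key=value` metadata, one column-name line, then two delimited numeric
#' columns `time_s` and `fluorescence_au`. Round-tripping preserves values to
#' full double precision.
#'
#' @param path File path.
#' @return `read_trace()` returns an `rrna_trace`; `write_trace()` returns
#'   `path` invisibly.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in lines[hdr]) {
    kv <- sub("^#\\s*", "", h)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- trimws(substr(kv, 1, eq - 1))
      val <- trimws(substr(kv, eq + 1, nchar(kv)))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) stop("malformed trace file: no data rows", call. = FALSE)
  dat <- utils::read.delim(text = body, header = TRUE, sep = "\t")
  if (ncol(dat) < 2) {
    stop("malformed trace file: expected two tab-separated columns",
         call. = FALSE)
  }
  tm <- as.numeric(dat[[1]])
  if (any(!is.finite(tm))) stop("malformed trace file: non-numeric time", call. = FALSE)
  if (length(tm) >= 2 && any(diff(tm) <= 0)) {
    bad <- which(diff(tm) <= 0)[1] + 1L
    stop(sprintf("non-increasing time at data line %d of %s", bad, path),
         call. = FALSE)
  }
  new_trace(tm, as.numeric(dat[[2]]), meta = meta)
}

#' @rdname read_trace
#' @param trace An `rrna_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "rrna_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(trace$meta)) {
    writeLines(sprintf("# %s=%s", key, format(trace$meta[[key]], digits = 17)),
               con)
  }
  writeLines("time_s\tfluorescence_au", con)
  writeLines(paste(format(trace$time, digits = 17, trim = TRUE),
                   format(trace$fluorescence, digits = 17, trim = TRUE),
                   sep = "\t"), con)
  invisible(path)
}

peak_columns <- c("sample_id", "label", "apparent_size_nt", "start_s",
                  "apex_s", "end_s", "raw_area", "tc_area", "below_detection")

empty_peaks <- function() {
  out <- data.frame(sample_id = character(), label = character(),
                    apparent_size_nt = numeric(), start_s = numeric(),
                    apex_s = numeric(), end_s = numeric(),
                    raw_area = numeric(), tc_area = numeric(),
                    below_detection = logical(), stringsAsFactors = FALSE)
  class(out) <- c("rrna_peaks", "data.frame")
  out
}

#' Read / write peak tables
#'
#' Tab-separated tables with columns `sample_id`, `label`,
#' `apparent_size_nt`, `start_s`, `apex_s`, `end_s`, `raw_area`, `tc_area`,
#' `below_detection`. Values round-trip at full precision.
#'
#' @param peaks A peak data frame (class `rrna_peaks`).
#' @param path File path.
#' @export
write_peaks <- function(peaks, path) {
  stopifnot(is.data.frame(peaks))
  out <- as.data.frame(peaks)[, peak_columns]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(z) format(z, digits = 17, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  dat <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(peak_columns, names(dat))
  if (length(missing)) {
    stop(sprintf("peak table missing columns: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  dat$below_detection <- as.logical(dat$below_detection)
  class(dat) <- c("rrna_peaks", "data.frame")
  dat
}

#' Calibrate migration time to apparent fragment size from a ladder
#'
#' Fits a monotone piecewise-cubic interpolant of log(size) against migration
#' time through the ladder anchors (sizing is close to log-linear in time in
#' capillary electrophoresis). The mapping is exact at every anchor and
#' strictly increasing over the anchored range; queries outside the range are
#' extrapolated with a flag.
#'
#' @param ladder_peaks Data frame with columns `time_s` and `size_nt`
#'   (>= 3 rows, distinct times, sizes strictly increasing with time).
#' @return An object of class `"rrna_calibration"`.
#' @export
#' @examples
#' cal <- calibrate(data.frame(time_s = c(40, 60, 90),
#'                             size_nt = c(25, 150, 1000)))
#' size_at(cal, 60)  # exactly 150
calibrate <- function(ladder_peaks) {
  stopifnot(is.data.frame(ladder_peaks),
            all(c("time_s", "size_nt") %in% names(ladder_peaks)))
  t <- as.numeric(ladder_peaks$time_s)
  s <- as.numeric(ladder_peaks$size_nt)
  if (length(t) < 3) stop("calibration needs >= 3 ladder anchors", call. = FALSE)
  if (anyDuplicated(t)) stop("ladder anchor times must be distinct", call. = FALSE)
  o <- order(t)
  t <- t[o]; s <- s[o]
  if (any(diff(s) <= 0) || any(s <= 0)) {
    stop("ladder sizes must be positive and strictly increasing with time",
         call. = FALSE)
  }
  f <- stats::splinefun(t, log(s), method = "hyman")
  structure(list(fun = f, time_range = range(t), anchors =
                   data.frame(time_s = t, size_nt = s)),
            class = "rrna_calibration")
}

#' Apparent size at a migration time
#'
#' @param calibration An [calibrate()] object.
#' @param time_s Migration times (seconds).
#' @return Numeric sizes in nt, with a logical attribute `"extrapolated"`
#'   marking queries outside the anchored time range.
#' @export
size_at <- function(calibration, time_s) {
  stopifnot(inherits(calibration, "rrna_calibration"))
  out <- exp(calibration$fun(time_s))
  attr(out, "extrapolated") <- time_s < calibration$time_range[1] |
    time_s > calibration$time_range[2]
  out
}

#' Baseline-correct a trace
#'
#' Estimates a slowly varying baseline from the off-peak portion of the
#' signal and subtracts it. Points are flagged as peak points when they
#' exceed the signal median by more than three robust noise standard
#' deviations (noise estimated from first differences); the baseline is the
#' remaining points, linearly interpolated across the peak gaps and smoothed
#' by a rolling mean of width `window`. Unlike a lower-envelope (rolling
#' minimum) estimator this is unbiased under pure mean-zero noise, so
#' integrated peak areas carry no systematic offset. Every step commutes
#' with adding a constant (offset invariance) and is positively homogeneous
#' (areas scale linearly with fluorescence).
#'
#' @param trace An `rrna_trace`.
#' @param window Baseline smoothing window in seconds; should exceed the
#'   widest peak but be shorter than the trace span. Default 5 s.
#' @return The corrected `rrna_trace`.
#' @export
baseline_correct <- function(trace, window = 5) {
  stopifnot(inherits(trace, "rrna_trace"))
  stopifnot_scalar_number(window, "window", positive = TRUE)
  t <- trace$time
  y <- trace$fluorescence
  span <- diff(range(t))
  if (window >= span) {
    stop("baseline window must be shorter than the trace span", call. = FALSE)
  }
  dt <- stats::median(diff(t))
  k <- max(3L, as.integer(round(window / dt)))
  # robust noise scale from first differences (diff of iid noise has sd
  # sqrt(2) times the noise sd); exactly 0 for noiseless traces
  sigma <- stats::median(abs(diff(y))) / (sqrt(2) * 0.6745)
  peakish <- y > stats::median(y) + 3 * sigma
  # widen the exclusion zone so sub-threshold peak flanks do not leak into
  # the baseline estimate (guard of 1 s on each side)
  kg <- 2L * max(1L, as.integer(round(1 / dt))) + 1L
  peakish <- as.logical(zoo::rollapply(zoo::zoo(as.numeric(peakish)),
                                       width = kg, FUN = max,
                                       align = "center", partial = TRUE))
  mask <- !peakish
  if (!any(mask)) mask[which.min(y)] <- TRUE
  # anchor the baseline on a pre-smoothed copy of the off-peak signal so a
  # single noisy sample at a gap edge cannot tilt the interpolated baseline
  ysm <- moving_average(y, max(3L, k %/% 5L))
  zb <- stats::approx(t[mask], ysm[mask], xout = t, rule = 2)$y
  base <- moving_average(zb, k)
  new_trace(t, y - base, meta = trace$meta)
}

# local maxima / minima of a numeric vector (strict on the left, non-strict
# on the right so plateaus yield their first point)
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer())
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

# Sub-grid apex refinement: vertex of the parabola through the three points
# around the discrete maximum, on the log scale when all three ordinates are
# positive (exact for a Gaussian peak), on the raw scale otherwise.
refine_apex <- function(t, y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) return(t[i])
  y3 <- y[(i - 1):(i + 1)]
  v <- if (all(y3 > 0)) log(y3) else y3
  denom <- v[1] - 2 * v[2] + v[3]
  if (!is.finite(denom) || denom >= 0) return(t[i])
  delta <- 0.5 * (v[1] - v[3]) / denom
  if (!is.finite(delta) || abs(delta) > 1) return(t[i])
  t[i] + delta * (t[i + 1] - t[i])
}

# topographic prominence of peak apexes within the trace
peak_prominence <- function(y, apexes) {
  vapply(seq_along(apexes), function(j) {
    i <- apexes[j]
    h <- y[i]
    left <- y[seq_len(i - 1)]
    higher_l <- which(left > h)
    lmin <- if (length(higher_l)) min(y[(max(higher_l) + 1):(i - 1)]) else min(left, h)
    right <- y[(i + 1):length(y)]
    higher_r <- which(right > h)
    rmin <- if (length(higher_r)) min(y[(i + 1):(i + min(higher_r) - 1)]) else min(right, h)
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Detect and integrate peaks in a baseline-corrected trace
#'
#' Finds peak apexes as local maxima of a lightly smoothed signal with
#' topographic prominence above `min_prominence`, places boundaries
#' valley-to-valley (at the minimum of the smoothed signal between adjacent
#' retained apexes, and at the signal minimum flanking the first/last apex),
#' and integrates the raw corrected signal over each region by the
#' trapezoidal rule. The time-corrected area is the raw area divided by the
#' apex migration time, which makes areas comparable across elution
#' positions. Peaks with time-corrected area below `detection_limit` are
#' flagged `below_detection`. The earliest-eluting peak with apparent size
#' below 30 nt is labeled `"marker"` (lower-marker convention); all other
#' peaks are `"unassigned"`.
#'
#' @param trace A baseline-corrected `rrna_trace` (>= 50 points).
#' @param calibration An [calibrate()] object mapping time to size.
#' @param min_prominence Minimum apex prominence in fluorescence units.
#' @param detection_limit Time-corrected-area detection limit (default 0.2).
#' @param smooth_window Smoothing window (seconds) used only for apex and
#'   valley location, never for integration.
#' @return An `rrna_peaks` data frame sorted by apex time. If no peak
#'   exceeds `min_prominence`, an empty table is returned with a warning.
#' @export
detect_and_integrate <- function(trace, calibration, min_prominence = 5,
                                 detection_limit = detection_limit_default(),
                                 smooth_window = 0.2) {
  stopifnot(inherits(trace, "rrna_trace"),
            inherits(calibration, "rrna_calibration"))
  if (length(trace$time) < 50) {
    stop("trace too short for peak detection (< 50 points)", call. = FALSE)
  }
  stopifnot_scalar_number(detection_limit, "detection_limit", positive = TRUE)
  t <- trace$time
  y <- trace$fluorescence
  dt <- stats::median(diff(t))
  ys <- moving_average(y, max(1L, as.integer(round(smooth_window / dt))))

  apexes <- local_maxima(ys)
  if (length(apexes)) {
    prom <- peak_prominence(ys, apexes)
    apexes <- apexes[prom >= min_prominence]
  }
  if (!length(apexes)) {
    warning("no peaks found above the prominence threshold")
    return(empty_peaks())
  }
  apexes <- sort(apexes)
  n <- length(apexes)
  starts <- integer(n)
  ends <- integer(n)
  # boundaries: minimum of the smoothed signal between adjacent apexes
  bounds <- integer(n + 1)
  bounds[1] <- which.min(ys[1:apexes[1]])
  if (n > 1) {
    for (j in 1:(n - 1)) {
      seg <- apexes[j]:apexes[j + 1]
      bounds[j + 1] <- seg[which.min(ys[seg])]
    }
  }
  bounds[n + 1] <- (apexes[n]:length(ys))[which.min(ys[apexes[n]:length(ys)])]

  raw_area <- numeric(n)
  for (j in seq_len(n)) {
    s <- bounds[j]; e <- bounds[j + 1]
    raw_area[j] <- pracma::trapz(t[s:e], y[s:e])
    starts[j] <- s; ends[j] <- e
  }
  # apexes located on the smoothed signal, refined to sub-grid precision on
  # the raw signal (the smoothed one is only used to decide where peaks are)
  apex_t <- vapply(apexes, function(i) refine_apex(t, y, i), numeric(1))
  tc_area <- raw_area / apex_t
  sizes <- size_at(calibration, apex_t)

  label <- rep("unassigned", n)
  small <- which(as.numeric(sizes) < 30)
  if (length(small)) label[small[1]] <- "marker"

  out <- data.frame(
    sample_id = trace$meta$id %||% "sample",
    label = label,
    apparent_size_nt = as.numeric(sizes),
    start_s = t[starts],
    apex_s = apex_t,
    end_s = t[ends],
    raw_area = raw_area,
    tc_area = tc_area,
    below_detection = tc_area < detection_limit,
    stringsAsFactors = FALSE
  )
  class(out) <- c("rrna_peaks", "data.frame")
  out
}

#' Remove the marker peak from a peak table
#'
#' The lower marker is an internal standard and is excluded from every
#' quantity downstream (totals, percents, ratios). The input table is not
#' modified.
#'
#' @param peaks An `rrna_peaks` data frame.
#' @return The table without marker-labeled rows.
#' @export
remove_marker <- function(peaks) {
  stopifnot(is.data.frame(peaks))
  out <- peaks[peaks$label != "marker", , drop = FALSE]
  rownames(out) <- NULL
  out
}
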