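# Oocyte morphometry: oblate-ellipsoid volumes, classification of
# primary-growth oocytes (PGO) by the species-specific critical long-axis
# size, and aggregation to the volume percent of PGO per fish.

#' Oocyte volume from its axes
#'
#' Oocytes are treated as oblate ellipsoids:
#' \deqn{V = \pi a b^2 / 8}
#' with `a` the long and `b` the short axis. No stereological correction for
#' section truncation is applied.
#'
#' @param a Long axis (um), `a >= b > 0`. Vectorized.
#' @param b Short axis (um).
#' @return Volumes in cubic micrometers.
#' @export
#' @examples
#' oocyte_volume(2, 2)       # pi
#' oocyte_volume(184, 92)    # ~ 611,000 um^3
oocyte_volume <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(b <= 0)) {
    stop("axes must be finite and positive", call. = FALSE)
  }
  if (any(b > a)) {
    stop("short axis must not exceed long axis (b <= a)", call. = FALSE)
  }
  pi * a * b^2 / 8
}

#' Classify an oocyte as primary-growth by its long axis
#'
#' Primary-growth oocytes are those whose long axis is strictly below the
#' species-specific critical size (184 um for yellow perch, 174 um for
#' bluegill). The boundary itself is counted as non-PGO.
#'
#' @param long_axis_um Long axes (um). Vectorized.
#' @param critical_size_um Critical size (> 0).
#' @return Logical vector, `TRUE` for primary-growth oocytes.
#' @export
classify_pgo <- function(long_axis_um, critical_size_um) {
  stopifnot_scalar_number(critical_size_um, "critical_size_um", positive = TRUE)
  long_axis_um < critical_size_um
}

#' Volume percent of primary-growth oocytes per fish
#'
#' Only oocytes with a visible nucleolus enter the sums (the measurement rule
#' under which the axes were collected). The statistic is
#' \deqn{100 \cdot \sum_{PGO} V_i \,/\, \sum_{all} V_i}
#' with volumes from [oocyte_volume()], pooling oocytes across cuttings. The
#' measurement protocol asks for at least 4 cuttings over at least 2 slices
#' per fish; `protocol_ok` records whether the table satisfies it, and a
#' warning (not an error) is raised when `require_protocol` is set and it
#' does not.
#'
#' @param oocytes Data frame with columns `long_axis_um`, `short_axis_um`,
#'   `nucleolus` (0/1 or logical), and optionally `fish_id`, `slice_id`,
#'   `cutting_id`.
#' @param critical_size_um Critical long-axis size (um).
#' @param require_protocol Warn when the cuttings/slices rule is not met.
#' @return A list of class `"rrna_morphometry"` with `fish_id`, `n_oocytes`,
#'   `n_cuttings`, `n_slices`, `total_volume_um3`, `pgo_volume_um3`,
#'   `pgoo_volume_percent`, `protocol_ok`.
#' @export
pgoo_volume_percent <- function(oocytes, critical_size_um,
                                require_protocol = TRUE) {
  stopifnot(is.data.frame(oocytes))
  need <- c("long_axis_um", "short_axis_um", "nucleolus")
  missing <- setdiff(need, names(oocytes))
  if (length(missing)) {
    stop(sprintf("oocyte table missing columns: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  eligible <- oocytes[as.logical(oocytes$nucleolus), , drop = FALSE]
  if (!nrow(eligible)) {
    stop("no oocytes with a visible nucleolus; nothing to measure",
         call. = FALSE)
  }
  vol <- oocyte_volume(eligible$long_axis_um, eligible$short_axis_um)
  pgo <- classify_pgo(eligible$long_axis_um, critical_size_um)

  n_cuttings <- if ("cutting_id" %in% names(eligible)) {
    nrow(unique(eligible[, intersect(c("slice_id", "cutting_id"),
                                     names(eligible)), drop = FALSE]))
  } else NA_integer_
  n_slices <- if ("slice_id" %in% names(eligible)) {
    length(unique(eligible$slice_id))
  } else NA_integer_
  protocol_ok <- isTRUE(n_cuttings >= 4) && isTRUE(n_slices >= 2)
  if (require_protocol && !protocol_ok) {
    warning("measurement protocol not met (< 4 cuttings or < 2 slices); ",
            "result returned anyway")
  }

  out <- list(
    fish_id = if ("fish_id" %in% names(eligible)) eligible$fish_id[1] else NA,
    n_oocytes = nrow(eligible),
    n_cuttings = n_cuttings,
    n_slices = n_slices,
    total_volume_um3 = sum(vol),
    pgo_volume_um3 = sum(vol[pgo]),
    pgoo_volume_percent = 100 * sum(vol[pgo]) / sum(vol),
    protocol_ok = protocol_ok
  )
  structure(out, class = "rrna_morphometry")
}

#' @export
print.rrna_morphometry <- function(x, ...) {
  cat(sprintf(
    "<rrna_morphometry> fish=%s  n=%d oocytes (%s cuttings / %s slices)\n",
    x$fish_id, x$n_oocytes, x$n_cuttings, x$n_slices))
  cat(sprintf("  PGO volume percent: %.2f%%  (protocol_ok=%s)\n",
              x$pgoo_volume_percent, x$protocol_ok))
  invisible(x)
}

#' Read / write oocyte morphometry tables
#'
#' Tab-separated tables with columns `fish_id`, `slice_id`, `cutting_id`,
#' `long_axis_um`, `short_axis_um`, `nucleolus` (0/1).
#'
#' @param oocytes Oocyte data frame.
#' @param path File path.
#' @export
write_oocytes <- function(oocytes, path) {
  utils::write.table(oocytes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_oocytes
#' @export
read_oocytes <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
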