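# Assignment of peaks to RNA species and computation of the three rRNA
# indexes: percent 5S rRNA of total RNA, percent 18S rRNA of total RNA, and
# the 5S/18S ratio (with its natural log, the form the regressions use).

#' Assign peaks to RNA species by apparent-size windows
#'
#' Small RNAs are labeled by fixed apparent-size windows (tRNA 99--110 nt,
#' 5S 131--144 nt, 5.8S 164--168 nt). The large ribosomal RNAs drift in
#' apparent size between chips, so among peaks above 1000 nt the two with
#' the largest time-corrected areas are taken as the major large-subunit
#' peaks and labeled 18S then 28S in increasing size order. Everything else
#' becomes `"other"`. Marker rows, if still present, are left untouched.
#'
#' @param peaks An `rrna_peaks` data frame carrying `apparent_size_nt`.
#' @param windows Size windows, see [size_windows()].
#' @return The peak table with the `label` column filled in.
#' @export
#' @examples
#' pk <- data.frame(sample_id = "s", label = "unassigned",
#'                  apparent_size_nt = 137, start_s = 1, apex_s = 2,
#'                  end_s = 3, raw_area = 10, tc_area = 5,
#'                  below_detection = FALSE)
#' assign_species(pk)$label  # "5S"
assign_species <- function(peaks, windows = size_windows()) {
  stopifnot(is.data.frame(peaks))
  if (!nrow(peaks)) return(peaks)
  sz <- peaks$apparent_size_nt
  lab <- peaks$label
  open <- lab != "marker"

  in_win <- function(w) open & !is.na(sz) & sz >= w[1] & sz <= w[2]
  lab[in_win(windows$tRNA)] <- "tRNA"
  lab[in_win(windows$`rRNA5S`)] <- "5S"
  lab[in_win(windows$`rRNA5.8S`)] <- "5.8S"

  big <- which(open & !is.na(sz) & sz > windows$large_min)
  if (length(big)) {
    major <- big[order(peaks$tc_area[big], decreasing = TRUE)]
    major <- major[seq_len(min(2L, length(major)))]
    major <- major[order(sz[major])]
    lab[major[1]] <- "18S"
    if (length(major) > 1) lab[major[2]] <- "28S"
  }
  lab[open & !(lab %in% c("tRNA", "5S", "5.8S", "18S", "28S"))] <- "other"
  peaks$label <- lab
  peaks
}

profile_columns <- c("sample_id", "area_tRNA", "area_5S", "area_5.8S",
                     "area_18S", "area_28S", "area_other", "total",
                     "pct5S", "pct18S", "ratio5S18S", "ln_pct5S", "ln_ratio",
                     "flag_5S_bd", "flag_18S_bd")

#' Compute the per-sample rRNA profile from labeled peaks
#'
#' Sums time-corrected areas per species (multiple peaks inside one window
#' are pooled), applies the below-detection substitution, and computes the
#' three indexes:
#' \deqn{pct5S = 100 \cdot a_{5S}/total, \quad
#'       pct18S = 100 \cdot a_{18S}/total, \quad
#'       ratio = a_{5S}/a_{18S}.}
#' When the 5S or 18S area falls below the detection limit it is replaced by
#' `substitution` (half the limit by default) and flagged, so ratios and log
#' transforms stay defined instead of collapsing to zero. Natural-log
#' transforms are populated only for positive inputs.
#'
#' The total is either the sum of all non-marker peak areas
#' (`total_mode = "peak_sum"`, the default: exactly testable against ground
#' truth) or a caller-supplied whole-region integral
#' (`total_mode = "region_integral"`, pass `region_total`).
#'
#' @param peaks A labeled `rrna_peaks` table for one sample (marker rows are
#'   dropped if present).
#' @param total_mode `"peak_sum"` or `"region_integral"`.
#' @param detection_limit Time-corrected-area detection limit.
#' @param substitution Value substituted for a below-detection 5S/18S area.
#' @param region_total Total time-corrected area of the whole RNA region,
#'   required for `total_mode = "region_integral"`.
#' @return A one-row data frame of class `"rrna_profile"` with the area,
#'   total, index and flag columns.
#' @export
compute_profile <- function(peaks, total_mode = c("peak_sum", "region_integral"),
                            detection_limit = detection_limit_default(),
                            substitution = detection_limit / 2,
                            region_total = NULL) {
  total_mode <- match.arg(total_mode)
  stopifnot(is.data.frame(peaks))
  peaks <- remove_marker(peaks)
  sample_id <- if (nrow(peaks)) peaks$sample_id[1] else "sample"

  area_of <- function(lab) sum(peaks$tc_area[peaks$label == lab])
  areas <- c(tRNA = area_of("tRNA"), `5S` = area_of("5S"),
             `5.8S` = area_of("5.8S"), `18S` = area_of("18S"),
             `28S` = area_of("28S"),
             other = sum(peaks$tc_area[!(peaks$label %in%
                         c("tRNA", "5S", "5.8S", "18S", "28S"))]))

  flag5 <- areas[["5S"]] < detection_limit
  flag18 <- areas[["18S"]] < detection_limit
  if (flag5) areas[["5S"]] <- substitution
  if (flag18) areas[["18S"]] <- substitution

  total <- if (total_mode == "peak_sum") {
    sum(areas)
  } else {
    if (is.null(region_total)) {
      stop("total_mode = 'region_integral' requires `region_total`",
           call. = FALSE)
    }
    region_total
  }
  if (!is.finite(total) || total <= 0) {
    stop("total RNA area is not positive; cannot form indexes", call. = FALSE)
  }

  pct5S <- 100 * areas[["5S"]] / total
  pct18S <- 100 * areas[["18S"]] / total
  ratio <- areas[["5S"]] / areas[["18S"]]

  out <- data.frame(
    sample_id = sample_id,
    area_tRNA = areas[["tRNA"]], area_5S = areas[["5S"]],
    `area_5.8S` = areas[["5.8S"]], area_18S = areas[["18S"]],
    area_28S = areas[["28S"]], area_other = areas[["other"]],
    total = total,
    pct5S = pct5S, pct18S = pct18S, ratio5S18S = ratio,
    ln_pct5S = if (pct5S > 0) log(pct5S) else NA_real_,
    ln_ratio = if (is.finite(ratio) && ratio > 0) log(ratio) else NA_real_,
    flag_5S_bd = flag5, flag_18S_bd = flag18,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  names(out) <- profile_columns
  class(out) <- c("rrna_profile", "data.frame")
  out
}

#' Profile every sample in a multi-sample peak table
#'
#' @param peaks An `rrna_peaks` table possibly covering several `sample_id`s.
#' @param ... Passed to [compute_profile()].
#' @return A data frame with one profile row per sample.
#' @export
compute_profiles <- function(peaks, ...) {
  stopifnot(is.data.frame(peaks))
  ids <- unique(peaks$sample_id)
  rows <- lapply(ids, function(id) {
    compute_profile(peaks[peaks$sample_id == id, , drop = FALSE], ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full trace-to-profile convenience wrapper
#'
#' Baseline-corrects a trace, detects and integrates peaks, assigns species
#' and computes the rRNA profile in one call.
#'
#' @inheritParams detect_and_integrate
#' @inheritParams compute_profile
#' @param baseline_window Baseline window in seconds, see
#'   [baseline_correct()].
#' @return A one-row `rrna_profile` data frame.
#' @export
profile_trace <- function(trace, calibration, baseline_window = 5,
                          min_prominence = 5,
                          detection_limit = detection_limit_default(),
                          total_mode = "peak_sum") {
  bc <- baseline_correct(trace, window = baseline_window)
  pk <- detect_and_integrate(bc, calibration, min_prominence = min_prominence,
                             detection_limit = detection_limit)
  pk <- assign_species(remove_marker(pk))
  compute_profile(pk, total_mode = total_mode,
                  detection_limit = detection_limit)
}
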