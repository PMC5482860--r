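# Sex classification by rRNA-index thresholds. The empirical claim behind
# the method is that, within an applicability regime (a GSI ceiling and/or a
# window of sampling months), female and male index distributions are
# disjoint; the natural formalization is a midpoint-of-gap threshold with
# the gap width as the margin, rather than a probabilistic classifier.

#' Applicability of records under a regime
#'
#' @param records Data frame with `gsi` and/or `month` columns.
#' @param applicability A list with `max_gsi` (GSI ceiling, `Inf` for none)
#'   and `months` (allowed sampling months, `NULL` for all), e.g. from
#'   [species_preset()]. `NULL` means always applicable.
#' @return Logical vector.
#' @export
is_applicable <- function(records, applicability) {
  n <- nrow(records)
  if (is.null(applicability)) return(rep(TRUE, n))
  ok <- rep(TRUE, n)
  max_gsi <- applicability$max_gsi %||% Inf
  if (is.finite(max_gsi) && "gsi" %in% names(records)) {
    ok <- ok & records$gsi < max_gsi
  }
  months <- applicability$months
  if (!is.null(months) && "month" %in% names(records)) {
    ok <- ok & records$month %in% months
  }
  ok
}

#' Learn a sex threshold from records with known sex
#'
#' After restricting to the applicability regime, compares the index ranges
#' of the two sexes. If they are disjoint, the threshold is the midpoint of
#' the gap and the margin is the gap width (the "unambiguous separation"
#' case). If they overlap, the best-separating threshold is found by an
#' exhaustive scan over candidate cutpoints, the margin is 0, and the
#' records inside the overlap zone are listed as diagnostics.
#'
#' @param records Data frame with a `sex` column (`"F"`/`"M"`), the index
#'   column, and (for filtering) `gsi`/`month`.
#' @param index Name of the index column (`"pct5S"`, `"ln_ratio"`,
#'   `"pct18S"`, ...).
#' @param applicability Regime list (see [is_applicable()]); `NULL` for none.
#' @return An object of class `"rrna_sex_threshold"`: `index`, `threshold`,
#'   `orientation` (`"female-above"`/`"female-below"`), `margin`,
#'   `applicability`, `n_female`, `n_male`, `ambiguous_ids`.
#' @export
learn_threshold <- function(records, index, applicability = NULL) {
  stopifnot(is.data.frame(records), "sex" %in% names(records))
  if (!index %in% names(records)) {
    stop(sprintf("no column '%s' in records", index), call. = FALSE)
  }
  keep <- is_applicable(records, applicability) &
    is.finite(records[[index]]) & records$sex %in% c("F", "M")
  rec <- records[keep, , drop = FALSE]
  vf <- rec[[index]][rec$sex == "F"]
  vm <- rec[[index]][rec$sex == "M"]
  if (length(vf) < 2 || length(vm) < 2) {
    stop("need at least 2 records per sex inside the applicability regime",
         call. = FALSE)
  }

  fr <- range(vf); mr <- range(vm)
  if (mr[2] < fr[1]) {
    threshold <- (mr[2] + fr[1]) / 2
    margin <- fr[1] - mr[2]
    orientation <- "female-above"
    ambiguous <- character()
  } else if (fr[2] < mr[1]) {
    threshold <- (fr[2] + mr[1]) / 2
    margin <- mr[1] - fr[2]
    orientation <- "female-below"
    ambiguous <- character()
  } else {
    # overlap: exhaustive scan over midpoints between consecutive sorted
    # values, both orientations, maximizing training accuracy
    v <- sort(unique(c(vf, vm)))
    cand <- if (length(v) > 1) (v[-1] + v[-length(v)]) / 2 else v
    acc <- function(thr, female_above) {
      calls_f <- if (female_above) vf > thr else vf < thr
      calls_m <- if (female_above) vm < thr else vm > thr
      (sum(calls_f) + sum(calls_m)) / (length(vf) + length(vm))
    }
    acc_up <- vapply(cand, acc, numeric(1), female_above = TRUE)
    acc_dn <- vapply(cand, acc, numeric(1), female_above = FALSE)
    if (max(acc_up) >= max(acc_dn)) {
      threshold <- cand[which.max(acc_up)]
      orientation <- "female-above"
    } else {
      threshold <- cand[which.max(acc_dn)]
      orientation <- "female-below"
    }
    margin <- 0
    zone <- c(max(fr[1], mr[1]), min(fr[2], mr[2]))
    in_zone <- rec[[index]] >= zone[1] & rec[[index]] <= zone[2]
    ambiguous <- if ("fish_id" %in% names(rec)) {
      rec$fish_id[in_zone]
    } else {
      rownames(rec)[in_zone]
    }
  }

  structure(list(index = index, threshold = threshold,
                 orientation = orientation, margin = margin,
                 applicability = applicability,
                 n_female = length(vf), n_male = length(vm),
                 ambiguous_ids = ambiguous),
            class = "rrna_sex_threshold")
}

#' @export
print.rrna_sex_threshold <- function(x, ...) {
  cat(sprintf("<rrna_sex_threshold> %s %s %.4g (margin %.4g; F n=%d, M n=%d)\n",
              x$index, if (x$orientation == "female-above") ">" else "<",
              x$threshold, x$margin, x$n_female, x$n_male))
  if (length(x$ambiguous_ids)) {
    cat("  overlapping records:", paste(x$ambiguous_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify sex from index values
#'
#' Calls each record by the threshold orientation; a value exactly at the
#' threshold is called `"ambiguous"` with confidence 0. Confidence is the
#' distance to the threshold in units of the margin, capped at 1 (0 whenever
#' the margin is 0). Records outside the applicability regime are still
#' called but flagged `applicable = FALSE`.
#'
#' @param records Data frame with the index column and, for the
#'   applicability flag, `gsi`/`month` columns.
#' @param threshold An [learn_threshold()] object.
#' @return A data frame `fish_id`, `call` (`"F"`/`"M"`/`"ambiguous"`),
#'   `confidence`, `applicable`.
#' @export
classify_sex <- function(records, threshold) {
  stopifnot(inherits(threshold, "rrna_sex_threshold"),
            is.data.frame(records))
  v <- records[[threshold$index]]
  if (is.null(v)) {
    stop(sprintf("records lack the index column '%s'", threshold$index),
         call. = FALSE)
  }
  fa <- threshold$orientation == "female-above"
  call <- ifelse(v == threshold$threshold, "ambiguous",
                 ifelse((v > threshold$threshold) == fa, "F", "M"))
  call[!is.finite(v)] <- NA_character_
  conf <- if (threshold$margin > 0) {
    pmin(1, abs(v - threshold$threshold) / threshold$margin)
  } else {
    rep(0, length(v))
  }
  conf[call == "ambiguous"] <- 0
  data.frame(
    fish_id = if ("fish_id" %in% names(records)) records$fish_id
              else as.character(seq_along(v)),
    call = call,
    confidence = conf,
    applicable = is_applicable(records, threshold$applicability),
    stringsAsFactors = FALSE
  )
}

#' Evaluate a sex threshold against records with known sex
#'
#' Tabulates calls against true sex. Accuracy is computed over applicable,
#' unambiguous records only; when there are none, accuracy is `NA` and
#' `message` says so.
#'
#' @param records Data frame with true `sex` plus the columns
#'   [classify_sex()] needs.
#' @param threshold An `rrna_sex_threshold`.
#' @return A list with `confusion` (table of truth vs call), `accuracy`,
#'   `n_evaluated`, `n_ambiguous`, `n_not_applicable`, `message`.
#' @export
evaluate_sexcall <- function(records, threshold) {
  stopifnot("sex" %in% names(records))
  pred <- classify_sex(records, threshold)
  usable <- pred$applicable & !is.na(pred$call) & pred$call != "ambiguous"
  confusion <- table(truth = records$sex[usable], call = pred$call[usable])
  accuracy <- if (any(usable)) {
    mean(records$sex[usable] == pred$call[usable])
  } else {
    NA_real_
  }
  list(
    confusion = confusion,
    accuracy = accuracy,
    n_evaluated = sum(usable),
    n_ambiguous = sum(pred$call == "ambiguous", na.rm = TRUE),
    n_not_applicable = sum(!pred$applicable),
    message = if (!any(usable)) {
      "no applicable, unambiguous records; accuracy undefined"
    } else {
      NULL
    }
  )
}

#' Serialize / restore a sex threshold as JSON
#'
#' @param threshold An `rrna_sex_threshold`.
#' @param path JSON file path.
#' @export
write_sex_threshold <- function(threshold, path) {
  stopifnot(inherits(threshold, "rrna_sex_threshold"))
  obj <- unclass(threshold)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_sex_threshold
#' @export
read_sex_threshold <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$applicability)) {
    if (!is.null(obj$applicability$max_gsi) &&
        is.character(obj$applicability$max_gsi)) {
      obj$applicability$max_gsi <- as.numeric(obj$applicability$max_gsi)
    }
  }
  obj$ambiguous_ids <- as.character(obj$ambiguous_ids %||% character())
  structure(obj, class = "rrna_sex_threshold")
}
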