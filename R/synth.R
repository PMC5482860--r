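# Synthetic-data generators: electropherogram traces with known peak
# composition, fish cohorts with known index-vs-GSI models, and oocyte
# morphometry tables with a known volume fraction of primary-growth oocytes.
# Every generator takes one explicit seed and leaves global RNG state alone.

# The synthetic instrument's time-to-size map. Apparent size is log-linear in
# migration time, as in capillary electrophoresis sizing: 25 nt elutes at
# 40 s, 6000 nt at 120 s.
.SYNTH_T0 <- 40
.SYNTH_T1 <- 120
.SYNTH_S0 <- 25
.SYNTH_S1 <- 6000

synth_size_to_time <- function(size_nt) {
  .SYNTH_T0 + (.SYNTH_T1 - .SYNTH_T0) *
    log(size_nt / .SYNTH_S0) / log(.SYNTH_S1 / .SYNTH_S0)
}

#' Synthetic sizing ladder
#'
#' Anchor pairs (migration time, known fragment size) for the synthetic
#' instrument, suitable for [calibrate()]. The ladder spans 25--6000 nt so
#' every RNA species produced by [gen_trace()] lies inside the anchored
#' range.
#'
#' @return A data frame with columns `time_s` and `size_nt`.
#' @export
synthetic_ladder <- function() {
  sizes <- c(25, 50, 100, 150, 300, 500, 1000, 2000, 4000, 6000)
  data.frame(time_s = synth_size_to_time(sizes), size_nt = sizes)
}

#' Ground-truth RNA composition
#'
#' Fractions of total RNA signal carried by each species on the chip. The 5S
#' fraction spans essentially the whole unit interval across ovary
#' development (up to 98.77% of total RNA in ovaries dominated by
#' primary-growth oocytes), which is what makes it usable as a maturity and
#' sex marker.
#'
#' @param tRNA,rRNA5S,rRNA5.8S,rRNA18S,rRNA28S Fractions in `[0,1]`; must sum
#'   to 1 within `1e-9`.
#' @return A named numeric vector of class `"rrna_composition"`.
#' @export
#' @examples
#' composition_truth(rRNA5S = 0.9877, tRNA = 0.004, `rRNA5.8S` = 0.003,
#'                   rRNA18S = 0.0023, rRNA28S = 0.003)
composition_truth <- function(tRNA = 0.2, rRNA5S = 0.2, `rRNA5.8S` = 0.2,
                              rRNA18S = 0.2, rRNA28S = 0.2) {
  x <- c(tRNA = tRNA, rRNA5S = rRNA5S, `rRNA5.8S` = `rRNA5.8S`,
         rRNA18S = rRNA18S, rRNA28S = rRNA28S)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("composition fractions must be finite and in [0, 1]", call. = FALSE)
  }
  if (abs(sum(x) - 1) > 1e-9) {
    stop(sprintf("composition fractions must sum to 1 (got %.12f)", sum(x)),
         call. = FALSE)
  }
  structure(x, class = "rrna_composition")
}

#' Generate a synthetic electropherogram with known peak composition
#'
#' Simulates a fluorescence-vs-migration-time trace containing a lower marker
#' peak plus one Gaussian peak per RNA species, with time-corrected areas
#' exactly proportional to the ground-truth composition fractions, and
#' additive Gaussian baseline noise. Apparent-size centers of the small RNAs
#' are drawn inside their assignment windows (tRNA 99--110 nt, 5S 131--144,
#' 5.8S 164--168); 18S and 28S sit at nominal 1900 and 4000 nt.
#'
#' @param truth An [composition_truth()] object.
#' @param peak_shape_params List with `sigma_s`, the Gaussian peak standard
#'   deviation in seconds (default 0.25).
#' @param noise_sd Standard deviation of additive baseline noise in
#'   fluorescence units; must be >= 0. Default 0.5.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param total_area Total time-corrected signal area shared among the RNA
#'   species (default 300 area units, comfortably above the 0.2 detection
#'   limit for all but trace fractions).
#' @param marker_tc_area Time-corrected area of the lower marker peak.
#' @param dt Sampling interval of the trace in seconds.
#' @param meta Named list of sample metadata (`id`, `species`, `tissue`,
#'   `month`, `rin`).
#' @return A list of class `"rrna_sim"` with components `trace` (an
#'   `rrna_trace`), `truth` (data frame `label`, `apparent_size_nt`,
#'   `apex_s`, `tc_area`, `raw_area`) and `ladder` (see
#'   [synthetic_ladder()]).
#' @export
gen_trace <- function(truth, peak_shape_params = list(sigma_s = 0.25),
                      noise_sd = 0.5, seed = 1L, total_area = 300,
                      marker_tc_area = 5, dt = 0.02,
                      meta = list(id = "sim")) {
  if (!inherits(truth, "rrna_composition")) {
    truth <- do.call(composition_truth, as.list(truth))
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  sigma <- peak_shape_params$sigma_s %||% 0.25
  stopifnot_scalar_number(sigma, "sigma_s", positive = TRUE)

  with_seed(seed, {
    win <- size_windows()
    sizes <- c(
      tRNA       = stats::runif(1, win$tRNA[1], win$tRNA[2]),
      rRNA5S     = stats::runif(1, win$`rRNA5S`[1], win$`rRNA5S`[2]),
      `rRNA5.8S` = stats::runif(1, win$`rRNA5.8S`[1], win$`rRNA5.8S`[2]),
      rRNA18S    = 1900,
      rRNA28S    = 4000
    )
    labels <- c("marker", names(sizes))
    all_sizes <- c(marker = .SYNTH_S0, sizes)
    tc <- c(marker = marker_tc_area, total_area * as.numeric(truth))
    apex <- synth_size_to_time(all_sizes)
    raw <- tc * apex

    tgrid <- seq(38, 124, by = dt)
    y <- numeric(length(tgrid))
    for (i in seq_along(labels)) {
      if (raw[i] <= 0) next
      amp <- raw[i] / (sigma * sqrt(2 * pi))
      y <- y + amp * exp(-0.5 * ((tgrid - apex[i]) / sigma)^2)
    }
    if (noise_sd > 0) y <- y + stats::rnorm(length(tgrid), 0, noise_sd)

    keep <- tc > 0
    truth_tab <- data.frame(
      label = labels[keep],
      apparent_size_nt = as.numeric(all_sizes[keep]),
      apex_s = as.numeric(apex[keep]),
      tc_area = as.numeric(tc[keep]),
      raw_area = as.numeric(raw[keep]),
      stringsAsFactors = FALSE
    )

    trace <- new_trace(tgrid, y, meta = meta)
    structure(list(trace = trace, truth = truth_tab,
                   ladder = synthetic_ladder()),
              class = "rrna_sim")
  })
}

# ---- cohorts ----------------------------------------------------------------

model_spec <- function(family, coef, sd = 0) {
  family <- match.arg(family, c("linear", "quadratic", "flat"))
  if (!is.numeric(sd) || sd < 0) stop("model noise sd must be >= 0", call. = FALSE)
  need <- switch(family, linear = 2L, quadratic = 3L, flat = 1L)
  if (length(coef) != need) {
    stop(sprintf("family '%s' needs %d coefficients", family, need),
         call. = FALSE)
  }
  list(family = family, coef = as.numeric(coef), sd = sd)
}

# Gaussian noise truncated at +/- 3.5 sd (by rejection). Index noise is
# bounded so that the sex-specific index distributions have disjoint
# supports, which is the separation regime threshold-based sex calling rests
# on; an unbounded tail would cross any finite gap eventually.
rnorm_trunc <- function(n, sd, limit = 3.5) {
  if (sd == 0 || n == 0) return(numeric(n))
  x <- stats::rnorm(n, 0, sd)
  bad <- which(abs(x) > limit * sd)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), 0, sd)
    bad <- bad[abs(x[bad]) > limit * sd]
  }
  x
}

eval_model <- function(m, gsi) {
  switch(m$family,
         flat      = rep(m$coef[1], length(gsi)),
         linear    = m$coef[1] + m$coef[2] * gsi,
         quadratic = m$coef[1] + m$coef[2] * gsi + m$coef[3] * gsi^2)
}

#' Cohort generating model
#'
#' Describes how each rRNA index depends on GSI in each sex, for use by
#' [gen_cohort()]. Female indexes follow a stated regression family (on the
#' transformed scale the field analyses: `Ln(5S%)`, `Ln(5S/18S)`, raw
#' `18S%`) plus Gaussian noise; males follow their own (typically flat)
#' models at somatic-like levels.
#'
#' @param species Label carried into the cohort table.
#' @param oogenesis `"synchronous"` or `"asynchronous"`.
#' @param female,male Named lists with elements `ln_pct5S`, `ln_ratio`,
#'   `pct18S`, each a list `(family, coef, sd)` with family one of
#'   `"linear"`, `"quadratic"`, `"flat"`.
#' @param gsi_range_f,gsi_range_m Positive, increasing GSI ranges sampled
#'   uniformly for females and males.
#' @param sex_ratio Probability that a fish is female.
#' @param spawning_month Month (1--12) of spawning, used to place sampling
#'   months along the maturity cycle for synchronous species.
#' @return A list of class `"rrna_cohort_params"`.
#' @export
cohort_params <- function(species, oogenesis, female, male,
                          gsi_range_f, gsi_range_m = c(0.1, 3),
                          sex_ratio = 0.5, spawning_month = 3L) {
  stopifnot(length(gsi_range_f) == 2, length(gsi_range_m) == 2)
  if (any(gsi_range_f <= 0) || diff(gsi_range_f) <= 0 ||
      any(gsi_range_m <= 0) || diff(gsi_range_m) <= 0) {
    stop("GSI ranges must be positive and increasing", call. = FALSE)
  }
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must be in [0,1]", call. = FALSE)
  idx <- c("ln_pct5S", "ln_ratio", "pct18S")
  if (!all(idx %in% names(female)) || !all(idx %in% names(male))) {
    stop("female and male must provide models for ln_pct5S, ln_ratio, pct18S",
         call. = FALSE)
  }
  female <- lapply(female[idx], function(m) do.call(model_spec, m))
  male <- lapply(male[idx], function(m) do.call(model_spec, m))
  structure(list(species = species,
                 oogenesis = match.arg(oogenesis,
                                       c("synchronous", "asynchronous")),
                 female = female, male = male,
                 gsi_range_f = as.numeric(gsi_range_f),
                 gsi_range_m = as.numeric(gsi_range_m),
                 sex_ratio = sex_ratio,
                 spawning_month = as.integer(spawning_month)),
            class = "rrna_cohort_params")
}

#' Preset cohort models
#'
#' Ready-made [cohort_params()] for the two reference species profiles. The
#' female models reproduce the reported regression structure: in the
#' synchronous preset `Ln(5S%)` is linear in GSI while `Ln(5S/18S)` and
#' `18S%` are quadratic; in the asynchronous preset all three are linear.
#' Coefficients are chosen so the index extremes match the reported
#' compositional extremes (5S up to ~98.8% / 18S down to ~0.1% in the
#' synchronous species; ~68.6% / ~5.9% in the asynchronous one) and male
#' levels sit at somatic-like values (5S a few percent of total RNA).
#'
#' @param species `"yellow_perch_like"` or `"bluegill_like"`.
#' @return An `rrna_cohort_params` object.
#' @export
cohort_preset <- function(species = c("yellow_perch_like", "bluegill_like")) {
  species <- match.arg(species)
  male <- list(
    ln_pct5S = list(family = "flat", coef = log(1.7), sd = 0.15),
    ln_ratio = list(family = "flat", coef = log(1.7 / 32), sd = 0.2),
    pct18S   = list(family = "flat", coef = 32, sd = 2.5)
  )
  if (species == "yellow_perch_like") {
    cohort_params(
      species = species, oogenesis = "synchronous",
      female = list(
        ln_pct5S = list(family = "linear", coef = c(4.55, -0.154), sd = 0.15),
        ln_ratio = list(family = "quadratic", coef = c(7.0, -0.55, 0.006),
                        sd = 0.25),
        pct18S   = list(family = "quadratic", coef = c(0.1, 0.50, 0.033),
                        sd = 1.2)
      ),
      male = male,
      gsi_range_f = c(0.3, 25), gsi_range_m = c(0.1, 3),
      sex_ratio = 0.5, spawning_month = 3L
    )
  } else {
    cohort_params(
      species = species, oogenesis = "asynchronous",
      # asynchronous ovaries keep primary-growth oocytes at every stage, so
      # the female 5S indexes decline only gently with GSI (the reported
      # regressions for this mode are correspondingly weaker) and stay
      # clearly above male/somatic levels throughout the cycle
      female = list(
        ln_pct5S = list(family = "linear", coef = c(4.23, -0.16), sd = 0.15),
        ln_ratio = list(family = "linear", coef = c(2.46, -0.38), sd = 0.2),
        pct18S   = list(family = "linear", coef = c(5.9, 3.0), sd = 1.5)
      ),
      male = male,
      gsi_range_f = c(0.5, 8), gsi_range_m = c(0.1, 3),
      sex_ratio = 0.5, spawning_month = 6L
    )
  }
}

# Sampling month placed along the maturity cycle for synchronous species
# (GSI grows from post-spawn recovery toward the spawning month); uniform
# across the year for asynchronous species and for males.
month_for_gsi <- function(gsi, range, spawning_month, synchronous) {
  if (!synchronous) {
    return(sample(1:12, length(gsi), replace = TRUE))
  }
  f <- (gsi - range[1]) / diff(range)
  months <- (spawning_month + 1 + floor(f * 10.999)) %% 12
  as.integer(months + 1L)
}

#' Generate a synthetic fish cohort with known index-vs-GSI structure
#'
#' Each fish receives a sex (Bernoulli with the preset sex ratio), a GSI
#' drawn uniformly inside the sex's range, body and gonad weights consistent
#' with that GSI, a sampling month, and the three rRNA indexes generated from
#' the sex-specific models plus Gaussian noise on the transformed scale,
#' truncated at 3.5 standard deviations so that the sex-specific index
#' distributions have bounded, disjoint supports (the separation regime the
#' threshold sex caller formalizes). Derived columns `pct5S`, `ratio5S18S`
#' are exponentials of their generated logs.
#'
#' @param params An [cohort_params()] / [cohort_preset()] object.
#' @param n Number of fish (>= 2).
#' @param seed Integer seed.
#' @return A data frame with columns `fish_id`, `species`, `sex`,
#'   `body_weight_g`, `gonad_weight_g`, `gsi`, `month`, `ln_pct5S`, `pct5S`,
#'   `ln_ratio`, `ratio5S18S`, `pct18S`, `tissue`.
#' @export
gen_cohort <- function(params, n, seed = 1L) {
  if (!inherits(params, "rrna_cohort_params")) {
    stop("`params` must be created by cohort_params() or cohort_preset()",
         call. = FALSE)
  }
  if (!is.numeric(n) || n < 2) stop("`n` must be >= 2", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed, {
    female <- stats::runif(n) < params$sex_ratio
    gsi <- ifelse(female,
                  stats::runif(n, params$gsi_range_f[1], params$gsi_range_f[2]),
                  stats::runif(n, params$gsi_range_m[1], params$gsi_range_m[2]))
    body <- stats::rlnorm(n, meanlog = log(150), sdlog = 0.25)
    gonad <- gsi / 100 * body

    gen_index <- function(name) {
      out <- numeric(n)
      mf <- params$female[[name]]
      mm <- params$male[[name]]
      out[female] <- eval_model(mf, gsi[female]) +
        rnorm_trunc(sum(female), mf$sd)
      out[!female] <- eval_model(mm, gsi[!female]) +
        rnorm_trunc(sum(!female), mm$sd)
      out
    }
    ln_pct5S <- gen_index("ln_pct5S")
    ln_ratio <- gen_index("ln_ratio")
    pct18S <- pmax(gen_index("pct18S"), 0.01)

    month <- integer(n)
    sync <- params$oogenesis == "synchronous"
    month[female] <- month_for_gsi(gsi[female], params$gsi_range_f,
                                   params$spawning_month, sync)
    month[!female] <- sample(1:12, sum(!female), replace = TRUE)

    data.frame(
      fish_id = sprintf("fish_%03d", seq_len(n)),
      species = params$species,
      sex = ifelse(female, "F", "M"),
      body_weight_g = body,
      gonad_weight_g = gonad,
      gsi = gsi,
      month = month,
      ln_pct5S = ln_pct5S,
      pct5S = exp(ln_pct5S),
      ln_ratio = ln_ratio,
      ratio5S18S = exp(ln_ratio),
      pct18S = pct18S,
      tissue = "gonad",
      stringsAsFactors = FALSE
    )
  })
}

# ---- oocytes ----------------------------------------------------------------

#' Generate a synthetic oocyte morphometry table
#'
#' Draws oocyte long axes from a two-component size distribution straddling
#' the species' critical size (primary-growth oocytes at 0.40--0.95 of the
#' critical long axis, later stages at 1.10--1.80), with short axes a random
#' 0.6--0.9 fraction of the long axis. The split between components is chosen
#' deterministically (monotone search over the drawn volumes) so the achieved
#' primary-growth volume percent lands within about two percentage points of
#' the target. Oocytes are spread over 4 cuttings on 2 slices so the table
#' satisfies the measurement protocol.
#'
#' @param target_pgoo_percent Target volume percent of primary-growth oocytes
#'   in `[0, 100]`.
#' @param n_oocytes Number of oocytes (>= 1; >= 2 for interior targets).
#' @param critical_size_um Critical long-axis size in micrometers (> 0).
#' @param seed Integer seed.
#' @param fish_id Identifier written into the table.
#' @return A data frame with columns `fish_id`, `slice_id`, `cutting_id`,
#'   `long_axis_um`, `short_axis_um`, `nucleolus` (0/1), with attributes
#'   `target` and `achieved` (volume percents).
#' @export
gen_oocytes <- function(target_pgoo_percent, n_oocytes, critical_size_um,
                        seed = 1L, fish_id = "sim") {
  stopifnot_scalar_number(critical_size_um, "critical_size_um", positive = TRUE)
  if (!is.numeric(target_pgoo_percent) || target_pgoo_percent < 0 ||
      target_pgoo_percent > 100) {
    stop("`target_pgoo_percent` must be in [0, 100]", call. = FALSE)
  }
  if (!is.numeric(n_oocytes) || n_oocytes < 1) {
    stop("`n_oocytes` must be >= 1", call. = FALSE)
  }
  n <- as.integer(n_oocytes)
  interior <- target_pgoo_percent > 0 && target_pgoo_percent < 100
  if (interior && n < 2) {
    stop("an interior target needs at least 2 oocytes (one per component)",
         call. = FALSE)
  }
  with_seed(seed, {
    u <- stats::runif(n)
    r <- stats::runif(n, 0.6, 0.9)
    a_pgo <- critical_size_um * (0.40 + u * (0.95 - 0.40))
    a_adv <- critical_size_um * (1.10 + u * (1.80 - 1.10))
    v_pgo <- pi * a_pgo^3 * r^2 / 8
    v_adv <- pi * a_adv^3 * r^2 / 8

    target <- target_pgoo_percent / 100
    if (target_pgoo_percent == 100) {
      k <- n
    } else if (target_pgoo_percent == 0) {
      k <- 0L
    } else {
      # achieved fraction is monotone increasing in k (each flip swaps a
      # large advanced volume for a small PGO volume); pick the k whose
      # achieved fraction is closest to the target
      cp <- cumsum(v_pgo)
      ca <- rev(cumsum(rev(v_adv)))          # sum of v_adv[(k+1):n]
      frac <- c(0, cp / (cp + c(ca[-1], 0)))  # frac[k+1] = achieved with k PGO
      k <- which.min(abs(frac - target)) - 1L
      k <- max(1L, min(n - 1L, k))
    }
    is_pgo <- seq_len(n) <= k
    a <- ifelse(is_pgo, a_pgo, a_adv)
    b <- r * a
    achieved <- 100 * sum(v_pgo[is_pgo]) /
      (sum(v_pgo[is_pgo]) + sum(v_adv[!is_pgo]))

    ord <- sample.int(n)
    cutting <- rep_len(1:4, n)
    out <- data.frame(
      fish_id = fish_id,
      slice_id = ifelse(cutting <= 2, 1L, 2L),
      cutting_id = cutting,
      long_axis_um = a[ord],
      short_axis_um = b[ord],
      nucleolus = 1L,
      stringsAsFactors = FALSE
    )
    attr(out, "target") <- target_pgoo_percent
    attr(out, "achieved") <- achieved
    out
  })
}
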