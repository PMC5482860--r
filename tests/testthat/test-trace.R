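# Trace handling: file round trips, ladder calibration, baseline correction,
# peak detection/integration, marker removal, and scale equivariance.

test_that("trace files round-trip at full precision", {
  tr <- gaussian_trace(id = "rt1")
  tr$meta$species <- "yellow_perch_like"
  tr$meta$rin <- 9.3
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_identical(back$time, tr$time)
  expect_identical(back$fluorescence, tr$fluorescence)
  expect_equal(back$meta$rin, 9.3)
  expect_equal(back$meta$species, "yellow_perch_like")
})

test_that("a minimal three-row trace file parses to a length-3 trace", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# id=tiny", "time_s\tfluorescence_au",
               "1\t0.5", "2\t0.7", "3\t0.6"), path)
  tr <- read_trace(path)
  expect_length(tr$time, 3)
  expect_equal(tr$fluorescence, c(0.5, 0.7, 0.6))
})

test_that("non-increasing time is rejected with the offending line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time_s\tfluorescence_au", "1\t0", "3\t0", "2\t0"), path)
  expect_error(read_trace(path), "non-increasing time at data line 3")
  expect_error(read_trace(file.path(tempdir(), "does-not-exist.tsv")),
               "no such file")
})

test_that("peak tables round-trip exactly", {
  sim <- gen_trace(composition_truth(), noise_sd = 0, seed = 4)
  pk <- detect_and_integrate(baseline_correct(sim$trace),
                             calibrate(sim$ladder))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peaks(pk, path)
  back <- read_peaks(path)
  expect_equal(back$raw_area, pk$raw_area, tolerance = 1e-15)
  expect_equal(back$tc_area, pk$tc_area, tolerance = 1e-15)
  expect_identical(back$label, pk$label)
  expect_identical(back$below_detection, pk$below_detection)
})

test_that("calibration is exact at anchors and monotone between them", {
  lad <- data.frame(time_s = c(40, 60, 90), size_nt = c(25, 150, 1000))
  cal <- calibrate(lad)
  expect_equal(as.numeric(size_at(cal, 60)), 150, tolerance = 1e-12)
  expect_equal(as.numeric(size_at(cal, c(40, 90))), c(25, 1000),
               tolerance = 1e-12)
  mid <- as.numeric(size_at(cal, 75))
  expect_gt(mid, 150)
  expect_lt(mid, 1000)
  # strictly increasing over a fine grid of the anchored range
  g <- as.numeric(size_at(cal, seq(40, 90, length.out = 200)))
  expect_true(all(diff(g) > 0))
  # extrapolation flagged
  expect_true(attr(size_at(cal, 30), "extrapolated"))
  expect_false(attr(size_at(cal, 60), "extrapolated"))
})

test_that("calibration rejects degenerate ladders", {
  expect_error(calibrate(data.frame(time_s = c(40, 60), size_nt = c(25, 150))),
               ">= 3")
  expect_error(calibrate(data.frame(time_s = c(40, 60, 90),
                                    size_nt = c(25, 1000, 150))),
               "strictly increasing")
  expect_error(calibrate(data.frame(time_s = c(40, 40, 90),
                                    size_nt = c(25, 150, 1000))),
               "distinct")
})

test_that("apex sizes of synthetic peaks are recovered through calibration", {
  for (seed in c(1, 8)) {
    sim <- gen_trace(composition_truth(0.2, 0.2, 0.2, 0.2, 0.2),
                     noise_sd = 0, seed = seed)
    pk <- detect_and_integrate(baseline_correct(sim$trace),
                               calibrate(sim$ladder))
    expect_equal(sort(pk$apparent_size_nt), sort(sim$truth$apparent_size_nt),
                 tolerance = 2 / 100)  # within 2 nt at 100 nt scale
  }
})

test_that("baseline correction zeroes flat signal and ignores offsets", {
  flat <- new_trace(seq(0, 100, 0.5), rep(100, 201))
  expect_equal(max(abs(baseline_correct(flat)$fluorescence)), 0)

  g0 <- baseline_correct(gaussian_trace(offset = 0))
  g50 <- baseline_correct(gaussian_trace(offset = 50))
  a0 <- trapz_oracle(g0$time, g0$fluorescence)
  a50 <- trapz_oracle(g50$time, g50$fluorescence)
  analytic <- 40 * 0.3 * sqrt(2 * pi)
  expect_equal(a0, analytic, tolerance = 0.01)
  expect_equal(a50, analytic, tolerance = 0.01)
  expect_lt(max(abs(g0$fluorescence - g50$fluorescence)), 1e-9)
})

test_that("pure mean-zero noise stays mean-zero after correction", {
  tr <- with_seed(31, new_trace(seq(0, 100, 0.02), rnorm(5001)))
  bc <- baseline_correct(tr)
  expect_lt(abs(mean(bc$fluorescence)), 3 / sqrt(5001))
})

test_that("baseline window validation", {
  tr <- gaussian_trace()
  expect_error(baseline_correct(tr, window = 0), "> 0")
  expect_error(baseline_correct(tr, window = 1000), "shorter than the trace")
})

test_that("a noiseless Gaussian integrates to its area with tc = area/apex", {
  lad <- synthetic_ladder()
  cal <- calibrate(lad)
  amp <- 30; apex <- 70; sigma <- 0.3
  tr <- gaussian_trace(amp = amp, apex = apex, sigma = sigma)
  pk <- detect_and_integrate(tr, cal)
  expect_equal(nrow(pk), 1)
  analytic <- amp * sigma * sqrt(2 * pi)
  expect_equal(pk$raw_area, analytic, tolerance = 1e-6)
  expect_identical(pk$tc_area, pk$raw_area / pk$apex_s)
  expect_equal(pk$apex_s, apex, tolerance = 1e-6)
})

test_that("time correction halves the tc area of a twice-as-late peak", {
  cal <- calibrate(synthetic_ladder())
  t <- seq(38, 124, 0.02)
  y <- 30 * exp(-0.5 * ((t - 50) / 0.3)^2) +
       30 * exp(-0.5 * ((t - 100) / 0.3)^2)
  pk <- detect_and_integrate(new_trace(t, y), cal)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$tc_area[2] / pk$tc_area[1], 50 / 100, tolerance = 1e-3)
})

test_that("tiny peaks are flagged below the detection limit", {
  cal <- calibrate(synthetic_ladder())
  apex <- 70
  tc_target <- 0.1   # below the 0.2 limit
  amp <- tc_target * apex / (0.3 * sqrt(2 * pi))
  pk <- detect_and_integrate(gaussian_trace(amp = amp, apex = apex),
                             cal, min_prominence = amp / 2)
  expect_equal(nrow(pk), 1)
  expect_true(pk$below_detection)
  expect_equal(pk$tc_area, 0.1, tolerance = 1e-3)
})

test_that("an empty trace yields an empty peak table with a warning", {
  cal <- calibrate(synthetic_ladder())
  tr <- new_trace(seq(38, 124, 0.1), rep(0, length(seq(38, 124, 0.1))))
  expect_warning(pk <- detect_and_integrate(tr, cal), "no peaks")
  expect_equal(nrow(pk), 0)
})

test_that("marker removal drops exactly the marker rows and is idempotent", {
  sim <- gen_trace(composition_truth(), noise_sd = 0, seed = 6)
  pk <- detect_and_integrate(baseline_correct(sim$trace),
                             calibrate(sim$ladder))
  expect_true("marker" %in% pk$label)
  nom <- remove_marker(pk)
  expect_false("marker" %in% nom$label)
  expect_equal(nrow(nom), nrow(pk) - 1)
  expect_identical(remove_marker(nom), nom)
  expect_identical(nrow(remove_marker(empty_peaks <- nom[0, ])), 0L)
  # original untouched
  expect_true("marker" %in% pk$label)
})

test_that("areas are equivariant and indexes invariant under rescaling", {
  sim <- gen_trace(composition_truth(0.1, 0.4, 0.1, 0.3, 0.1),
                   noise_sd = 0, seed = 12)
  cal <- calibrate(sim$ladder)
  tr2 <- new_trace(sim$trace$time, 3.7 * sim$trace$fluorescence,
                   meta = sim$trace$meta)
  pk1 <- detect_and_integrate(baseline_correct(sim$trace), cal,
                              min_prominence = 1)
  pk2 <- detect_and_integrate(baseline_correct(tr2), cal,
                              min_prominence = 3.7)
  expect_equal(pk2$raw_area, 3.7 * pk1$raw_area, tolerance = 1e-9)
  p1 <- compute_profile(assign_species(remove_marker(pk1)))
  p2 <- compute_profile(assign_species(remove_marker(pk2)))
  expect_equal(p2$pct5S, p1$pct5S, tolerance = 1e-9)
  expect_equal(p2$pct18S, p1$pct18S, tolerance = 1e-9)
  expect_equal(p2$ratio5S18S, p1$ratio5S18S, tolerance = 1e-9)
})
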