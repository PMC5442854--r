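# Preprocessing stages: binning, background, lock mass, averaging,
# alignment, peak picking, features, normalisation, log.

test_that("binning follows the half-open edge convention", {
  cfg <- preprocess_config()
  s <- spectrum(c(699.495, 699.503), c(10, 5))
  b <- bin_spectrum(s, cfg)
  expect_equal(b$values[9950], 10) # bin index 9949, 1-based 9950
  expect_equal(b$values[9951], 5)
  expect_equal(sum(b$values), 15)

  s <- spectrum(c(600.00, 1000.00), c(7, 9))
  b <- bin_spectrum(s, cfg)
  expect_equal(b$values[1], 7)     # exactly at mz_lo -> bin 0
  expect_equal(sum(b$values), 7)   # exactly at mz_hi -> discarded
})

test_that("binning conserves in-range intensity for arbitrary spectra", {
  cfg <- preprocess_config()
  set.seed(3)
  for (i in 1:5) {
    s <- spectrum(sort(runif(200, 590, 1010)), rexp(200))
    b <- bin_spectrum(s, cfg)
    in_range <- s$mz >= 600 & s$mz < 1000
    expect_equal(sum(b$values), sum(s$intensity[in_range]),
                 tolerance = 1e-12)
  }
})

test_that("background subtraction removes a constant baseline", {
  b <- binned_spectrum(c(5, 5, 5, 105), 600, 0.01)
  out <- subtract_background(b)
  expect_equal(out$values, c(0, 0, 0, 100))

  z <- binned_spectrum(rep(0, 10), 600, 0.01)
  expect_warning(out <- subtract_background(z), "all-zero")
  expect_equal(out$values, rep(0, 10))

  # generator baseline is recovered: apex height drops by ~baseline_level
  cfg <- tiny_config(noise_cv = 0, calibration_drift_sd = 0,
                     baseline_level = 20, isotope_satellites = FALSE)
  set.seed(1)
  s <- generate_spectrum("normal", "cut", 1, cfg)
  b <- bin_spectrum(s, preprocess_config())
  sub <- subtract_background(b)
  apex <- which.max(b$values)
  expect_equal(b$values[apex] - sub$values[apex], 20, tolerance = 0.1)

  # rolling-minimum alternative also flattens a constant baseline
  sub2 <- subtract_background(b, "rolling_min")
  flat <- bin_centres(b) > 950 & bin_centres(b) < 960
  expect_lt(max(sub2$values[flat]), 1)
})

test_that("lock-mass correction recovers known drifts", {
  cfg <- preprocess_config()
  base <- gaussian_spectrum(699.497, 100)
  for (drift in c(-0.05, 0.03, 0.12)) {
    shifted <- spectrum(base$mz + drift, base$intensity)
    lc <- lock_mass_correct(bin_spectrum(shifted, cfg), cfg)
    # apex position is quantised to the bin grid, so recovery is within
    # half a bin of the true drift
    expect_lte(abs(lc$shift + drift), cfg$bin_width / 2 + 1e-9)
    # post-condition: corrected apex within half a bin of the lock mass
    apex_mz <- bin_centres(lc$spectrum)[which.max(lc$spectrum$values)]
    expect_lte(abs(apex_mz - 699.497), cfg$bin_width / 2)
  }

  # already-calibrated spectrum: |shift| <= bin_width/2
  lc <- lock_mass_correct(bin_spectrum(base, cfg), cfg)
  expect_lte(abs(lc$shift), cfg$bin_width / 2)

  # empty window: flagged, unchanged, NA shift
  far <- gaussian_spectrum(800, 100)
  lc <- lock_mass_correct(bin_spectrum(far, cfg), cfg)
  expect_true(is.na(lc$shift))
  expect_true("lockmass_failed" %in% lc$spectrum$flags)
})

test_that("burn averaging is the element-wise mean", {
  a <- binned_spectrum(c(0, 2), 600, 0.01)
  b <- binned_spectrum(c(0, 4), 600, 0.01)
  expect_equal(average_burns(list(a, b))$values, c(0, 3))
  expect_equal(average_burns(list(a))$values, a$values)
  expect_equal(average_burns(list(b, b, b))$values, b$values)
  expect_error(average_burns(list(a, binned_spectrum(1:3, 600, 0.01))),
               "mismatched")
})

test_that("alignment recovers known integer-bin lags", {
  cfg <- preprocess_config()
  set.seed(4)
  s <- generate_spectrum("normal", "cut", 1,
                         tiny_config(noise_cv = 0,
                                     calibration_drift_sd = 0))
  b <- bin_spectrum(s, cfg)
  shifted <- binned_spectrum(c(rep(0, 3), b$values[1:(b$n_bins - 3)]),
                             600, 0.01)
  aligned <- align_profiles(list(b, b, shifted), max_shift = 0.1)
  lags <- attr(aligned, "lags")
  expect_equal(lags[1:2], c(0L, 0L))
  expect_lte(abs(lags[3] + 3L), 1L)

  # already aligned -> all lags 0; intensities conserved up to edge loss
  aligned2 <- align_profiles(list(b, b, b), max_shift = 0.1)
  expect_identical(attr(aligned2, "lags"), c(0L, 0L, 0L))
  edge_mass <- sum(b$values[c(1:10, (b$n_bins - 9):b$n_bins)])
  for (x in aligned)
    expect_lte(abs(sum(x$values) - sum(b$values)), edge_mass + 1e-9)

  # fewer than two spectra: identity
  one <- align_profiles(list(b))
  expect_identical(one[[1]]$values, b$values)
})

test_that("peak picking finds isolated Gaussians and panel peaks", {
  cfg <- preprocess_config()
  b <- bin_spectrum(gaussian_spectrum(700.005, 100), cfg)
  p <- pick_peaks(b, cfg)
  expect_length(p, 1)
  expect_lte(abs(p - 700.005), cfg$bin_width)

  s2 <- gaussian_spectrum(700, 100)
  s2$intensity <- s2$intensity +
    100 * exp(-0.5 * ((s2$mz - 705) / 0.03)^2)
  p2 <- pick_peaks(bin_spectrum(s2, cfg), cfg)
  expect_length(p2, 2)

  # noiseless synthetic panel: every library peak is recovered
  cfgs <- tiny_config(noise_cv = 0, calibration_drift_sd = 0,
                      baseline_level = 0)
  set.seed(1)
  s <- generate_spectrum("normal", "cut", 1, cfgs)
  peaks <- pick_peaks(subtract_background(bin_spectrum(s, cfg)), cfg)
  lib <- build_peak_library()
  for (mz in lib$mz)
    expect_true(min(abs(peaks - mz)) <= cfg$bin_width + 1e-9)

  expect_error(pick_peaks(binned_spectrum(rep(0, 100), 600, 0.01), cfg),
               "no signal|no peaks")
})

test_that("feature extraction is local and merges overlapping windows", {
  cfg <- preprocess_config()
  b <- bin_spectrum(gaussian_spectrum(700.005, 100, width = 0.01), cfg)
  fm <- extract_features(list(b), 700.005, half_window = 0.05)
  expect_equal(fm$values[1, 1], sum(b$values), tolerance = 1e-4)

  # zero window
  fm0 <- extract_features(list(b), 900, half_window = 0.05)
  expect_identical(unname(fm0$values[1, 1]), 0)

  # locality: adding intensity outside all windows changes nothing
  b2 <- b
  b2$values[100] <- b2$values[100] + 1e6
  fm2 <- extract_features(list(b2), 700.005, half_window = 0.05)
  expect_equal(fm2$values, fm$values, ignore_attr = TRUE)

  expect_warning(
    fm3 <- extract_features(list(b), c(700.00, 700.06),
                            half_window = 0.05),
    "merged")
  expect_identical(ncol(fm3$values), 1L)
})

test_that("median fold change normalisation has its fixed point at 1", {
  fm <- feature_matrix(rbind(c(2, 4, 6), c(1, 2, 3)), c(700, 710, 720))
  out <- normalize_mfc(fm)
  # proportional samples collapse to the same profile
  expect_equal(out$values[1, ], out$values[2, ], tolerance = 1e-12)

  # single sample: unchanged (it is its own reference)
  one <- normalize_mfc(feature_matrix(matrix(c(5, 7, 9), 1),
                                      c(700, 710, 720)))
  expect_equal(unname(one$values[1, ]), c(5, 7, 9))

  # scale invariance: multiplying a sample by 10 changes nothing.
  # Exact against a frozen reference (the prediction-time situation) ...
  set.seed(8)
  x <- matrix(rexp(60), 6)
  mzs <- seq(700, 745, by = 5)
  ref <- apply(x, 2, stats::median)
  f1 <- normalize_mfc(feature_matrix(x, mzs), reference = ref)
  x2 <- x
  x2[3, ] <- x2[3, ] * 10
  f2 <- normalize_mfc(feature_matrix(x2, mzs), reference = ref)
  expect_equal(f2$values[3, ], f1$values[3, ], tolerance = 1e-12)
  # ... and with the default self-derived reference when the scaled
  # sample does not change the column medians (scaling the largest row)
  xo <- t(vapply(1:6, function(i) i * rexp(10, 1 / 10) + i, numeric(10)))
  xo <- apply(xo, 2, sort)
  mz2 <- seq(700, 790, by = 10)
  g1 <- normalize_mfc(feature_matrix(xo, mz2))
  xo2 <- xo
  xo2[6, ] <- xo2[6, ] * 10
  g2 <- normalize_mfc(feature_matrix(xo2, mz2))
  expect_equal(g2$values[6, ], g1$values[6, ], tolerance = 1e-12)

  # invariant: every sample's median fold change vs reference is 1
  ref <- attr(f1, "reference")
  for (i in 1:6) {
    valid <- f1$values[i, ] > 0 & ref > 0
    expect_equal(stats::median(f1$values[i, valid] / ref[valid]), 1,
                 tolerance = 1e-9)
  }

  expect_error(normalize_mfc(feature_matrix(rbind(c(1, 1), c(0, 0)),
                                            c(700, 710))),
               "no nonzero")
})

test_that("log transform handles zeros by policy and is monotone", {
  fm <- feature_matrix(rbind(c(0, 2, 8), c(4, 1, 16)), c(700, 710, 720))
  out <- log_transform(fm)
  offset <- attr(out, "offset")
  expect_equal(offset, 1) # smallest positive value
  expect_equal(out$values[1, 1], log(1))
  expect_true(all(diff(order(out$values[2, ])) ==
                    diff(order(fm$values[2, ]))))

  pos <- feature_matrix(rbind(c(1, 2), c(3, 4)), c(700, 710))
  plain <- log_transform(pos, offset_policy = "none")
  expect_equal(plain$values, log(pos$values), ignore_attr = TRUE)
  expect_error(log_transform(fm, offset_policy = "none"), "zeros")
  neg <- feature_matrix(rbind(c(-1, 2)), c(700, 710))
  expect_error(log_transform(neg), "negative")
})

test_that("the pipeline is deterministic and applies exclusion rules", {
  gen <- generate_dataset(tiny_config(n_patients = 4))
  pp1 <- preprocess_pipeline(gen$dataset)
  pp2 <- preprocess_pipeline(gen$dataset)
  expect_identical(pp1$features$values, pp2$features$values)
  expect_identical(pp1$pipeline$feature_mz, pp2$pipeline$feature_mz)
  expect_identical(pp1$features$stage_log,
                   c("extract", "normalize_mfc", "log"))

  # an all-zero burn is excluded while the sample survives
  ds <- gen$dataset
  grid <- ds$samples[[1]]$burns[[1]]$mz
  ds$samples[[1]]$burns[[1]] <- spectrum(grid, rep(0, length(grid)))
  pp3 <- preprocess_pipeline(ds)
  expect_length(pp3$qc$excluded_burns, 1)
  expect_match(pp3$qc$excluded_burns, "zero signal")
  expect_true(ds$samples[[1]]$sample_id %in% rownames(pp3$features$values))
  expect_identical(
    pp3$meta$n_burns_used[pp3$meta$sample_id ==
                            ds$samples[[1]]$sample_id],
    length(ds$samples[[1]]$burns) - 1L)
})

test_that("noiseless end-to-end features reflect generator amplitudes", {
  cfg <- tiny_config(n_patients = 4, burns_per_sample = 1, noise_cv = 0,
                     calibration_drift_sd = 0, patient_effect_sd = 0,
                     baseline_level = 0, isotope_satellites = FALSE,
                     effect_factor = 2, mode_policy = "cut_only",
                     tumour_fraction = 0.5, seed = 33)
  gen <- generate_dataset(cfg)
  pp <- preprocess_pipeline(gen$dataset)
  lib <- build_peak_library()
  raw <- pp$raw_features
  cls <- pp$meta$tissue_class
  # each library peak maps to a feature; tumour/normal ratio of raw
  # features equals the generator's effect structure (effect^2 between
  # classes for both ranges, opposite directions)
  for (i in seq_len(nrow(lib))) {
    j <- which.min(abs(raw$feature_mz - lib$mz[i]))
    expect_lt(abs(raw$feature_mz[j] - lib$mz[i]), 0.02)
    ratio <- mean(raw$values[cls == "tumour", j]) /
      mean(raw$values[cls == "normal", j])
    expected <- if (lib$range[i] == "phospholipid") 2 else 0.5
    expect_equal(ratio, expected, tolerance = 0.05)
  }
})
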