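# Spectral preprocessing: binning, background subtraction, lock-mass
# recalibration, burn averaging, profile alignment, peak picking, feature
# extraction, median-fold-change normalisation and log transformation.
# Everything here is deterministic.

#' Construct a binned spectrum
#'
#' Bin k covers `[mz_lo + k*w, mz_lo + (k+1)*w)` (left-closed, right-open,
#' anchored at `mz_lo`).
#'
#' @param values Numeric vector of per-bin summed intensities.
#' @param mz_lo Lower edge of bin 0 (Da).
#' @param bin_width Bin width (Da).
#' @param flags Character vector of QC flags.
#' @return Object of class `binned_spectrum`.
#' @export
binned_spectrum <- function(values, mz_lo, bin_width, flags = character()) {
  stopifnot(is.numeric(values), bin_width > 0)
  structure(list(values = as.numeric(values), mz_lo = mz_lo,
                 bin_width = bin_width, n_bins = length(values),
                 flags = flags),
            class = "binned_spectrum")
}

#' Bin centres of a binned spectrum
#' @param binned A [binned_spectrum()].
#' @return Numeric vector of bin-centre m/z values.
#' @export
bin_centres <- function(binned) {
  binned$mz_lo + (seq_len(binned$n_bins) - 0.5) * binned$bin_width
}

#' @export
print.binned_spectrum <- function(x, ...) {
  cat(sprintf("<binned_spectrum> %d bins of %g Da from %g m/z%s\n",
              x$n_bins, x$bin_width, x$mz_lo,
              if (length(x$flags))
                paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

.same_binning <- function(a, b) {
  a$n_bins == b$n_bins && isTRUE(all.equal(a$mz_lo, b$mz_lo)) &&
    isTRUE(all.equal(a$bin_width, b$bin_width))
}

#' Bin a profile spectrum onto a fixed m/z grid
#'
#' Point intensities are summed into left-closed, right-open bins; points
#' outside `[mz_lo, mz_hi)` are discarded. Binning conserves in-range total
#' intensity exactly. Points within 1e-6 of a bin width below a boundary
#' are snapped up to it, so grid-aligned input lands in the intended bin
#' despite floating-point representation.
#'
#' @param spec A [spectrum()].
#' @param config A [preprocess_config()].
#' @return A [binned_spectrum()] with
#'   `n_bins = round((mz_hi - mz_lo)/bin_width)`.
#' @export
bin_spectrum <- function(spec, config = preprocess_config()) {
  stopifnot(inherits(spec, "reims_spectrum"),
            inherits(config, "preprocess_config"))
  n <- round((config$mz_hi - config$mz_lo) / config$bin_width)
  idx <- floor((spec$mz - config$mz_lo) / config$bin_width + 1e-6)
  keep <- idx >= 0 & idx < n
  values <- numeric(n)
  if (any(keep)) {
    s <- rowsum(spec$intensity[keep], group = idx[keep])
    values[as.integer(rownames(s)) + 1L] <- s[, 1]
  }
  binned_spectrum(values, config$mz_lo, config$bin_width)
}

#' Subtract an estimated background from a binned spectrum
#'
#' `"constant_percentile"` subtracts the 25th percentile of the nonzero
#' bins; `"rolling_min"` subtracts a moving-minimum baseline (window
#' `window` Da, block-minimum approximation). Output values are clipped at
#' zero. An all-zero spectrum is returned unchanged with a warning.
#'
#' @param binned A [binned_spectrum()].
#' @param method Background estimator.
#' @param percentile Percentile used by `"constant_percentile"`.
#' @param window Window (Da) for `"rolling_min"`.
#' @return A [binned_spectrum()].
#' @export
subtract_background <- function(binned,
                                method = c("constant_percentile",
                                           "rolling_min"),
                                percentile = 0.25, window = 1) {
  method <- match.arg(method)
  v <- binned$values
  if (all(v == 0)) {
    warning("all-zero spectrum: background subtraction skipped")
    return(binned)
  }
  if (method == "constant_percentile") {
    base <- stats::quantile(v[v > 0], percentile, names = FALSE)
    out <- pmax(0, v - base)
  } else {
    wb <- max(1L, round(window / binned$bin_width))
    block <- (seq_along(v) - 1L) %/% wb
    bmin <- tapply(v, block, min)
    nb <- length(bmin)
    base_block <- pmin(bmin,
                       c(bmin[1], bmin[-nb]),
                       c(bmin[-1], bmin[nb]))
    out <- pmax(0, v - base_block[block + 1L])
  }
  binned_spectrum(out, binned$mz_lo, binned$bin_width, binned$flags)
}

#' Lock-mass recalibration of a binned spectrum
#'
#' Finds the most intense bin within `lockmass_tol` of the lock mass
#' (deprotonated PA(36:2), 699.497 m/z by default), computes the rigid
#' shift `lockmass_mz - apex_mz`, and re-bins the spectrum along the
#' shifted axis by linear interpolation. After correction the apex lies
#' within half a bin of the lock mass. If the window holds no signal the
#' spectrum is returned unchanged, flagged `"lockmass_failed"`, with shift
#' `NA` (such spectra are rejected by the pipeline, mirroring the published
#' spectral-quality exclusion rules).
#'
#' @param binned A [binned_spectrum()].
#' @param config A [preprocess_config()].
#' @return List with elements `spectrum` (corrected [binned_spectrum()])
#'   and `shift` (Da, `NA` on failure).
#' @export
lock_mass_correct <- function(binned, config = preprocess_config()) {
  centres <- bin_centres(binned)
  win <- which(abs(centres - config$lockmass_mz) <= config$lockmass_tol)
  if (!length(win) || all(binned$values[win] == 0)) {
    out <- binned
    out$flags <- union(out$flags, "lockmass_failed")
    return(list(spectrum = out, shift = NA_real_))
  }
  apex <- win[which.max(binned$values[win])]
  shift <- config$lockmass_mz - centres[apex]
  if (abs(shift) < 1e-12)
    return(list(spectrum = binned, shift = 0))
  # corrected value at centre c comes from the uncorrected axis at c - shift
  new_values <- stats::approx(centres, binned$values, xout = centres - shift,
                              yleft = 0, yright = 0)$y
  list(spectrum = binned_spectrum(new_values, binned$mz_lo,
                                  binned$bin_width, binned$flags),
       shift = shift)
}

#' Average burn spectra into one spectrum per sample
#'
#' @param burns List of [binned_spectrum()] with identical binning.
#' @return Element-wise arithmetic mean as a [binned_spectrum()].
#' @export
average_burns <- function(burns) {
  if (!length(burns)) stop("at least one burn required")
  stopifnot(all(vapply(burns, inherits, logical(1), "binned_spectrum")))
  for (b in burns[-1])
    if (!.same_binning(burns[[1]], b))
      stop("burns have mismatched binning")
  vals <- rowMeans(vapply(burns, `[[`, numeric(burns[[1]]$n_bins),
                          "values"))
  binned_spectrum(vals, burns[[1]]$mz_lo, burns[[1]]$bin_width)
}

# Shift a value vector by an integer number of bins, zero-padding the ends.
.shift_bins <- function(v, lag) {
  n <- length(v)
  if (lag == 0) return(v)
  out <- numeric(n)
  if (lag > 0) out[(lag + 1):n] <- v[1:(n - lag)]
  else out[1:(n + lag)] <- v[(1 - lag):n]
  out
}

# Best integer-bin lag (|lag| <= max_lag) maximizing cross-correlation of v
# against ref. Ties break toward the smallest |lag| (0 preferred).
.best_lag <- function(v, ref, max_lag) {
  lags <- 0:max_lag
  lags <- c(0, as.vector(rbind(lags[-1], -lags[-1]))) # 0, 1, -1, 2, -2, ...
  best <- 0L
  best_cc <- -Inf
  for (lag in lags) {
    cc <- sum(ref * .shift_bins(v, lag))
    # strict improvement required, so ties keep the smaller |lag|
    if (cc > best_cc + 1e-12 * max(1, abs(cc))) {
      best_cc <- cc
      best <- lag
    }
  }
  as.integer(best)
}

#' Rigid profile-mode alignment of a set of binned spectra
#'
#' The reference is the element-wise median spectrum; each spectrum is
#' shifted by the integer-bin lag (up to `max_shift`) maximizing its
#' cross-correlation with the reference. Removes residual m/z jitter left
#' after lock-mass correction. With fewer than 2 spectra this is the
#' identity.
#'
#' @param samples List of [binned_spectrum()] with identical binning.
#' @param max_shift Maximum shift (Da).
#' @return List of aligned [binned_spectrum()]; attributes `lags` (integer
#'   bins applied per spectrum) and `reference` (the median reference
#'   values).
#' @export
align_profiles <- function(samples, max_shift = 0.1) {
  stopifnot(all(vapply(samples, inherits, logical(1), "binned_spectrum")))
  if (length(samples) < 2) {
    attr(samples, "lags") <- rep(0L, length(samples))
    attr(samples, "reference") <-
      if (length(samples)) samples[[1]]$values else numeric()
    return(samples)
  }
  for (b in samples[-1])
    if (!.same_binning(samples[[1]], b))
      stop("samples have mismatched binning")
  mat <- vapply(samples, `[[`, numeric(samples[[1]]$n_bins), "values")
  ref <- apply(mat, 1, stats::median)
  max_lag <- floor(max_shift / samples[[1]]$bin_width)
  lags <- vapply(seq_along(samples), function(i)
    .best_lag(mat[, i], ref, max_lag), integer(1))
  out <- lapply(seq_along(samples), function(i) {
    binned_spectrum(.shift_bins(mat[, i], lags[i]), samples[[i]]$mz_lo,
                    samples[[i]]$bin_width, samples[[i]]$flags)
  })
  attr(out, "lags") <- lags
  attr(out, "reference") <- ref
  out
}

#' Align one binned spectrum to a stored reference
#'
#' Used to bring held-out or newly acquired spectra onto the m/z frame of a
#' trained model without ever feeding them back into the reference.
#'
#' @param binned A [binned_spectrum()].
#' @param reference Numeric reference values (same binning).
#' @param max_shift Maximum shift (Da).
#' @return Aligned [binned_spectrum()] with attribute `lag`.
#' @export
align_to_reference <- function(binned, reference, max_shift = 0.1) {
  stopifnot(length(reference) == binned$n_bins)
  lag <- .best_lag(binned$values, reference,
                   floor(max_shift / binned$bin_width))
  out <- binned_spectrum(.shift_bins(binned$values, lag), binned$mz_lo,
                         binned$bin_width, binned$flags)
  attr(out, "lag") <- lag
  out
}

#' Pick peaks from a mean profile spectrum
#'
#' Local maxima whose prominence (apex height above the higher of the
#' minima found within `prominence_window` Da on either side) is at least
#' `peak_min_snr` times the robust noise level (median absolute deviation
#' of the bins, about zero). Apex m/z is refined to sub-bin accuracy by
#' three-point parabolic interpolation on the log intensities (falling
#' back to the bin centre when a neighbour is zero); the refinement stays
#' within half a bin of the apex bin centre. Sub-bin accuracy is what lets
#' the isotope-exclusion rule separate a 13C satellite (+1.00335 Da) from
#' a genuine lipid one double-bond equivalent away (+1.0124 Da relative to
#' the neighbour's satellite). Output is sorted ascending.
#'
#' @param mean_profile A [binned_spectrum()], normally the mean of the
#'   aligned training profiles.
#' @param config A [preprocess_config()].
#' @param prominence_window Half-width (Da) searched for flanking minima.
#' @return Numeric vector of peak m/z values.
#' @export
pick_peaks <- function(mean_profile, config = preprocess_config(),
                       prominence_window = 0.5) {
  v <- mean_profile$values
  n <- length(v)
  if (n < 3) stop("profile too short for peak picking")
  nz <- v[v > 0]
  if (!length(nz))
    stop("no signal in profile; no peaks found")
  # robust noise over ALL bins, measured about zero: on a dense noisy
  # profile this tracks the noise scale; on a sparse background-subtracted
  # spectrum (mostly exact zeros) it collapses to ~0, where every genuine
  # local maximum should be kept. An estimate over nonzero bins only would
  # be dominated by peak flanks and reject real peaks.
  noise <- stats::mad(v, center = 0)
  thr <- max(config$peak_min_snr * noise, 1e-12)
  i <- 2:(n - 1)
  cand <- i[v[i] > v[i - 1] & v[i] >= v[i + 1] & v[i] >= thr]
  if (!length(cand))
    stop("no peaks found; consider lowering peak_min_snr (current ",
         config$peak_min_snr, ")")
  wb <- max(1L, round(prominence_window / mean_profile$bin_width))
  prom <- vapply(cand, function(k) {
    left <- v[max(1, k - wb):(k - 1)]
    right <- v[(k + 1):min(n, k + wb)]
    v[k] - max(min(left), min(right))
  }, numeric(1))
  keep <- cand[prom >= thr]
  if (!length(keep))
    stop("no peaks exceed the prominence threshold; consider lowering ",
         "peak_min_snr (current ", config$peak_min_snr, ")")
  centres <- bin_centres(mean_profile)
  w <- mean_profile$bin_width
  apex <- vapply(keep, function(k) {
    y <- v[(k - 1):(k + 1)]
    if (any(y <= 0)) return(centres[k])
    ly <- log(y)
    denom <- ly[1] - 2 * ly[2] + ly[3]
    if (denom >= -1e-12) return(centres[k])
    delta <- 0.5 * (ly[1] - ly[3]) / denom
    centres[k] + max(-0.5, min(0.5, delta)) * w
  }, numeric(1))
  sort(apex)
}

#' Extract a sample-by-peak feature matrix from binned profiles
#'
#' Each feature is the sum of bin intensities within `half_window` Da of a
#' peak apex. Peaks whose windows overlap are merged into a single feature
#' at their mean apex m/z, with a warning.
#'
#' @param samples List of [binned_spectrum()] (aligned, identical binning).
#' @param peaks Numeric vector of peak apex m/z values.
#' @param half_window Half-width (Da) of each feature window.
#' @param sample_ids Optional row names.
#' @return A `feature_matrix` object: list with `values` (samples x
#'   features matrix), `feature_mz`, `stage_log`.
#' @export
extract_features <- function(samples, peaks, half_window = 0.05,
                             sample_ids = NULL) {
  stopifnot(length(peaks) > 0, half_window > 0)
  peaks <- sort(peaks)
  # merge overlapping windows
  if (length(peaks) > 1) {
    grp <- cumsum(c(1, diff(peaks) >= 2 * half_window))
    if (max(grp) < length(peaks)) {
      warning(length(peaks) - max(grp),
              " overlapping peak window(s) merged")
      peaks <- as.numeric(tapply(peaks, grp, mean))
    }
  }
  centres <- bin_centres(samples[[1]])
  win_idx <- lapply(peaks, function(p)
    which(centres >= p - half_window & centres <= p + half_window))
  values <- t(vapply(samples, function(s)
    vapply(win_idx, function(ix) sum(s$values[ix]), numeric(1)),
    numeric(length(peaks))))
  if (length(peaks) == 1L) values <- matrix(values, ncol = 1L)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(values)))
  feature_matrix(values, peaks, stage_log = "extract",
                 sample_ids = sample_ids)
}

#' Construct a feature matrix
#'
#' @param values Numeric matrix, samples in rows, peak features in columns.
#' @param feature_mz Strictly increasing peak m/z values, one per column.
#' @param stage_log Character vector of transforms applied so far.
#' @param sample_ids Row identifiers.
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, feature_mz, stage_log = character(),
                           sample_ids = rownames(values)) {
  values <- as.matrix(values)
  if (ncol(values) != length(feature_mz))
    stop("feature_mz length must match the number of columns")
  if (is.unsorted(feature_mz, strictly = TRUE))
    stop("feature_mz must be strictly increasing")
  if (anyNA(values)) stop("feature matrix must not contain missing values")
  if (is.null(sample_ids))
    sample_ids <- paste0("sample", seq_len(nrow(values)))
  dimnames(values) <- list(sample_ids, sprintf("%.4f", feature_mz))
  structure(list(values = values, feature_mz = feature_mz,
                 stage_log = stage_log),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features [%s]\n",
              nrow(x$values), ncol(x$values),
              paste(x$stage_log, collapse = " -> ")))
  invisible(x)
}

#' Median-fold-change normalisation
#'
#' Each sample is divided by the median of its per-feature fold changes
#' against a reference profile (the column-wise median across samples by
#' default). Features that are zero in the sample or the reference are
#' ignored in the median. After normalisation every sample's median fold
#' change versus the reference is exactly 1. Makes downstream
#' classification invariant to global intensity scaling.
#'
#' @param fm A [feature_matrix()] of non-negative values.
#' @param reference Optional frozen reference profile (e.g. from a trained
#'   model); defaults to the column-wise median of `fm`.
#' @return A [feature_matrix()] with attributes `reference` and `scales`.
#' @export
normalize_mfc <- function(fm, reference = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- fm$values
  if (any(x < 0)) stop("median-fold-change normalisation needs ",
                       "non-negative features")
  if (is.null(reference)) reference <- apply(x, 2, stats::median)
  stopifnot(length(reference) == ncol(x))
  scales <- vapply(seq_len(nrow(x)), function(i) {
    valid <- x[i, ] > 0 & reference > 0
    if (!any(valid))
      stop("sample ", rownames(x)[i],
           " shares no nonzero features with the reference")
    stats::median(x[i, valid] / reference[valid])
  }, numeric(1))
  out <- feature_matrix(x / scales, fm$feature_mz,
                        c(fm$stage_log, "normalize_mfc"), rownames(x))
  attr(out, "reference") <- reference
  attr(out, "scales") <- scales
  out
}

#' Log-transform a feature matrix
#'
#' Natural log of (value + offset). With the default `"min_positive"`
#' policy the offset is the smallest positive value in the matrix (or a
#' frozen offset passed in); with `"none"` a plain log is taken and any
#' zero raises an error.
#'
#' @param fm A [feature_matrix()], already normalised.
#' @param offset_policy `"min_positive"` or `"none"`.
#' @param offset Optional frozen offset (overrides the policy).
#' @return A [feature_matrix()] with attribute `offset`.
#' @export
log_transform <- function(fm, offset_policy = c("min_positive", "none"),
                          offset = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  offset_policy <- match.arg(offset_policy)
  x <- fm$values
  if (any(x < 0))
    stop("negative values: normalisation must precede log transformation")
  if (is.null(offset)) {
    offset <- if (offset_policy == "none") 0 else {
      pos <- x[x > 0]
      if (!length(pos)) stop("all-zero matrix cannot be log transformed")
      min(pos)
    }
  }
  if (offset == 0 && any(x == 0))
    stop("zeros present with offset policy \"none\"")
  out <- feature_matrix(log(x + offset), fm$feature_mz,
                        c(fm$stage_log, "log"), rownames(x))
  attr(out, "offset") <- offset
  out
}

# --------------------------------------------------------------------------
# Pipeline

#' Aggregate a binned spectrum to a coarser grain
#'
#' Sums each consecutive block of `factor` bins into one bin; exact
#' (conserves total intensity).
#'
#' @param binned A [binned_spectrum()] whose bin count is a multiple of
#'   `factor`.
#' @param factor Positive integer aggregation factor.
#' @return A [binned_spectrum()] with `factor`-fold wider bins.
#' @export
aggregate_bins <- function(binned, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1L) return(binned)
  if (binned$n_bins %% factor != 0L)
    stop("bin count ", binned$n_bins, " is not a multiple of ", factor)
  vals <- colSums(matrix(binned$values, nrow = factor))
  binned_spectrum(vals, binned$mz_lo, binned$bin_width * factor,
                  binned$flags)
}

# One burn -> background-subtracted, lock-mass-corrected profile at the
# configured grain. The lock-mass shift must be estimated at a resolution
# finer than the calibration drift, so for coarse grains (e.g. the 0.1 Da
# recognition bin) the burn is binned, background-subtracted and corrected
# at an internal ~0.01 Da grain and then aggregated exactly to the
# configured bin width; a half-bin shift quantisation at 0.1 Da would
# otherwise dwarf the drift it is meant to remove.
.burn_profile <- function(spec, config) {
  m <- max(1L, as.integer(round(config$bin_width / 0.01)))
  fine_cfg <- config
  fine_cfg$bin_width <- config$bin_width / m
  b <- bin_spectrum(spec, fine_cfg)
  if (sum(b$values) == 0) {
    b$flags <- union(b$flags, "zero_signal")
    return(list(profile = aggregate_bins(b, m), shift = NA_real_))
  }
  b <- subtract_background(b, config$background_method)
  lc <- lock_mass_correct(b, fine_cfg)
  if (is.na(lc$shift)) {
    out <- lc$spectrum
    return(list(profile = aggregate_bins(out, m), shift = NA_real_))
  }
  list(profile = aggregate_bins(lc$spectrum, m), shift = lc$shift)
}

# Per-sample profile construction (fold-independent): bin each burn,
# subtract background, lock-mass correct, average retained burns.
# Burns with zero total signal or a failed lock-mass correction are
# excluded; a sample survives if at least one burn does.
.sample_profiles <- function(dataset, config) {
  stopifnot(inherits(dataset, "reims_dataset"),
            inherits(config, "preprocess_config"))
  profiles <- list()
  meta <- list()
  shifts <- list()
  excluded_burns <- character()
  excluded_samples <- character()
  for (s in dataset$samples) {
    kept <- list()
    for (k in seq_along(s$burns)) {
      bid <- if (nzchar(s$burns[[k]]$burn_id)) s$burns[[k]]$burn_id
             else sprintf("%s_b%d", s$sample_id, k)
      bp <- .burn_profile(s$burns[[k]], config)
      if (is.na(bp$shift)) {
        reason <- if ("zero_signal" %in% bp$profile$flags) "zero signal"
                  else "uncorrectable lock mass"
        excluded_burns <- c(excluded_burns,
                            paste0(bid, " (", reason, ")"))
        next
      }
      shifts[[bid]] <- bp$shift
      kept[[length(kept) + 1L]] <- bp$profile
    }
    if (!length(kept)) {
      excluded_samples <- c(excluded_samples, s$sample_id)
      next
    }
    profiles[[s$sample_id]] <- average_burns(kept)
    meta[[s$sample_id]] <- data.frame(
      sample_id = s$sample_id, patient_id = s$patient_id,
      histology = s$histology, tissue_class = s$tissue_class,
      n_burns_used = length(kept), stringsAsFactors = FALSE)
  }
  list(profiles = profiles,
       meta = if (length(meta)) do.call(rbind, unname(meta)) else NULL,
       qc = list(lockmass_shifts = unlist(shifts),
                 excluded_burns = excluded_burns,
                 excluded_samples = excluded_samples))
}

# Fit the fold-dependent feature stages on a set of profiles: alignment
# reference, peak list, normalisation reference, log offset.
.fit_feature_stages <- function(profiles, config) {
  aligned <- align_profiles(profiles, config$align_max_shift)
  ref <- attr(aligned, "reference")
  mean_profile <- binned_spectrum(
    rowMeans(vapply(aligned, `[[`,
                    numeric(aligned[[1]]$n_bins), "values")),
    aligned[[1]]$mz_lo, aligned[[1]]$bin_width)
  peaks <- pick_peaks(mean_profile, config)
  raw <- extract_features(aligned, peaks, config$feature_half_window,
                          sample_ids = names(profiles))
  norm <- normalize_mfc(raw)
  logged <- log_transform(norm, config$log_offset_policy)
  pipeline <- structure(list(
    config = config,
    align_reference = ref,
    feature_mz = raw$feature_mz,
    norm_reference = attr(norm, "reference"),
    log_offset = attr(logged, "offset")), class = "reims_pipeline")
  list(features = logged, raw_features = raw, pipeline = pipeline,
       align_lags = attr(aligned, "lags"))
}

# Apply frozen feature stages to new profiles. `align` uses the stored
# reference (offline classification); streaming recognition sets it FALSE.
.apply_feature_stages <- function(profiles, pipeline, align = TRUE) {
  cfg <- pipeline$config
  if (align && length(pipeline$align_reference))
    profiles <- lapply(profiles, align_to_reference,
                       reference = pipeline$align_reference,
                       max_shift = cfg$align_max_shift)
  raw <- extract_features(profiles, pipeline$feature_mz,
                          cfg$feature_half_window,
                          sample_ids = names(profiles))
  norm <- normalize_mfc(raw, reference = pipeline$norm_reference)
  log_transform(norm, cfg$log_offset_policy, offset = pipeline$log_offset)
}

#' Run the full preprocessing pipeline on a dataset
#'
#' Applies bin -> background subtraction -> lock-mass correction -> burn
#' averaging -> profile alignment -> peak picking -> feature extraction ->
#' median-fold-change normalisation -> log, recording per-stage QC
#' (lock-mass shifts, excluded burns and samples). Samples whose histology
#' is B3/B4 are carried through with `tissue_class = "excluded"`; callers
#' building two-class models should drop them via the returned metadata.
#'
#' @param dataset A [reims_dataset()] with at least 2 samples.
#' @param config A [preprocess_config()].
#' @return List with `features` (log-scale [feature_matrix()]),
#'   `raw_features` (linear scale, post-extraction — the input for
#'   univariate screening), `meta` (per-sample data.frame), `pipeline`
#'   (frozen references for applying the identical transform to new
#'   spectra) and `qc`.
#' @export
preprocess_pipeline <- function(dataset, config = preprocess_config()) {
  sp <- .sample_profiles(dataset, config)
  if (length(sp$profiles) < 2)
    stop("fewer than 2 samples survived preprocessing")
  fit <- .fit_feature_stages(sp$profiles, config)
  qc <- sp$qc
  qc$align_lags <- fit$align_lags
  qc$n_features <- length(fit$pipeline$feature_mz)
  list(features = fit$features, raw_features = fit$raw_features,
       meta = sp$meta, pipeline = fit$pipeline, qc = qc)
}

#' Preprocess a single burn into a profile on a pipeline's grid
#'
#' Bin, background-subtract and lock-mass correct one spectrum with the
#' pipeline's configuration.
#'
#' @param spec A [spectrum()].
#' @param config A [preprocess_config()].
#' @return A [binned_spectrum()]; flagged `"lockmass_failed"` when the lock
#'   mass cannot be found. For coarse grains the lock-mass shift is
#'   estimated at an internal ~0.01 Da grain before exact aggregation to
#'   the configured bin width (see [preprocess_pipeline()]).
#' @export
preprocess_burn <- function(spec, config = preprocess_config()) {
  bp <- .burn_profile(spec, config)
  out <- bp$profile
  if (is.na(bp$shift) && !"zero_signal" %in% out$flags)
    out$flags <- union(out$flags, "lockmass_failed")
  out
}
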