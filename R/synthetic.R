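# Synthetic REIMS dataset generator. Emulates the documented spectral
# phenotypes of electrosurgical breast-tissue aerosol: normal tissue rich in
# triglycerides (850-1000 m/z), tumour rich in phospholipids (600-850 m/z),
# coag mode boosting triglyceride signal relative to cut, plus calibration
# drift, isotope satellites, patient-level random intensity effects and
# multiplicative noise. Every downstream stage is testable against the
# generator's ground truth.

# Internal seed fixing the per-species base amplitudes (drawn once,
# log-uniform; independent of the user's dataset seed).
.AMPLITUDE_SEED <- 4242L

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. With seed = NULL the current RNG stream is used.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Configuration for the synthetic dataset generator
#'
#' Defaults encode the stated world: triglyceride-dominant normal tissue,
#' phospholipid-dominant tumour, a coag-mode triglyceride boost, per-spectrum
#' calibration drift, a single 13C isotope satellite per peak, log-normal
#' per-patient intensity effects and per-peak multiplicative noise.
#'
#' @param n_patients Number of patients.
#' @param samples_per_patient Samples (tissue specimens) per patient.
#' @param burns_per_sample Electrosurgical burns (spectra) per sample.
#' @param tumour_fraction Probability that a patient contributes tumour
#'   tissue, in `[0, 1]`.
#' @param mode_policy `"mixed"` (per-sample coin flip), `"cut_only"` or
#'   `"coag_only"`.
#' @param effect_factor Tissue effect size, >= 1: tumour spectra multiply
#'   phospholipid amplitudes and divide triglyceride amplitudes by this
#'   factor. 1 = no class difference.
#' @param coag_tg_boost Coag-mode effect, >= 1: coag spectra multiply
#'   triglyceride amplitudes and divide phospholipid amplitudes by this
#'   factor.
#' @param calibration_drift_sd SD (Da) of the per-spectrum rigid m/z
#'   calibration offset.
#' @param noise_cv Coefficient of variation of the per-peak multiplicative
#'   log-normal noise.
#' @param baseline_level Additive flat baseline (intensity units).
#' @param patient_effect_sd SD (log scale) of the per-patient global
#'   intensity factor.
#' @param isotope_satellites Add a +1.00335 Da satellite at
#'   `isotope_fraction` of each parent amplitude.
#' @param isotope_fraction Satellite amplitude as a fraction of the parent.
#' @param peak_width Gaussian peak SD (Da).
#' @param grid_step Profile grid spacing (Da).
#' @param seed Integer seed for [generate_dataset()]; `NULL` uses the
#'   current RNG stream.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 20, samples_per_patient = 2,
                             burns_per_sample = 3, tumour_fraction = 0.4,
                             mode_policy = c("mixed", "cut_only",
                                             "coag_only"),
                             effect_factor = 2, coag_tg_boost = 2,
                             calibration_drift_sd = 0.01, noise_cv = 0.2,
                             baseline_level = 2, patient_effect_sd = 0.3,
                             isotope_satellites = TRUE,
                             isotope_fraction = 0.6, peak_width = 0.03,
                             seed = NULL) {
  mode_policy <- match.arg(mode_policy)
  stopifnot(n_patients >= 1, samples_per_patient >= 1,
            burns_per_sample >= 1)
  if (tumour_fraction < 0 || tumour_fraction > 1)
    stop("tumour_fraction must lie in [0, 1]")
  if (effect_factor < 1) stop("effect_factor must be >= 1")
  if (coag_tg_boost < 1) stop("coag_tg_boost must be >= 1")
  if (calibration_drift_sd < 0 || noise_cv < 0 || baseline_level < 0 ||
      patient_effect_sd < 0)
    stop("drift, noise, baseline and patient-effect parameters must be >= 0")
  if (peak_width <= 0 || peak_width > 0.1)
    stop("peak_width must be in (0, 0.1] Da")
  if (isotope_fraction < 0 || isotope_fraction >= 1)
    stop("isotope_fraction must lie in [0, 1)")
  structure(list(
    n_patients = as.integer(n_patients),
    samples_per_patient = as.integer(samples_per_patient),
    burns_per_sample = as.integer(burns_per_sample),
    tumour_fraction = tumour_fraction, mode_policy = mode_policy,
    effect_factor = effect_factor, coag_tg_boost = coag_tg_boost,
    calibration_drift_sd = calibration_drift_sd, noise_cv = noise_cv,
    baseline_level = baseline_level, patient_effect_sd = patient_effect_sd,
    isotope_satellites = isotope_satellites,
    isotope_fraction = isotope_fraction, peak_width = peak_width,
    grid_step = 0.01, seed = seed), class = "synthetic_config")
}

#' Build the synthetic peak library from a lipid panel
#'
#' Computes each panel entry's theoretical m/z via [ion_mz()] and assigns a
#' base amplitude drawn once per species from a log-uniform range (fixed by
#' an internal seed, so the library is identical across calls and
#' independent of the dataset seed). Triglyceride-range amplitudes are drawn
#' from a higher range (200-2000) than phospholipid-range amplitudes
#' (50-500), encoding the triglyceride dominance of normal breast tissue.
#'
#' @param lipid_panel A data.frame with columns `lipid_class`, `carbons`,
#'   `double_bonds`, `linkage`, `ion` (see [default_lipid_panel()]), or a
#'   list of [lipid_species()] (ion defaults to `"[M-H]-"`).
#' @return data.frame with columns `species`, `ion`, `mz`,
#'   `base_amplitude`, `range` (`"phospholipid"` for m/z < 850,
#'   `"triglyceride"` for >= 850). Species whose theoretical m/z falls
#'   outside `[600, 1000)` are dropped with a warning.
#' @export
build_peak_library <- function(lipid_panel = default_lipid_panel()) {
  if (inherits(lipid_panel, "lipid_species"))
    lipid_panel <- list(lipid_panel)
  if (is.list(lipid_panel) && !is.data.frame(lipid_panel)) {
    if (!length(lipid_panel)) stop("empty lipid panel")
    lipid_panel <- do.call(rbind, lapply(lipid_panel, function(sp) {
      stopifnot(inherits(sp, "lipid_species"))
      data.frame(lipid_class = sp$lipid_class, carbons = sp$carbons,
                 double_bonds = sp$double_bonds, linkage = sp$linkage,
                 ion = "[M-H]-", stringsAsFactors = FALSE)
    }))
  }
  if (!is.data.frame(lipid_panel) || nrow(lipid_panel) == 0L)
    stop("empty lipid panel")
  species <- lapply(seq_len(nrow(lipid_panel)), function(i)
    lipid_species(lipid_panel$lipid_class[i], lipid_panel$carbons[i],
                  lipid_panel$double_bonds[i], lipid_panel$linkage[i]))
  mz <- vapply(seq_along(species), function(i)
    ion_mz(species[[i]], lipid_panel$ion[i]), numeric(1))
  keep <- mz >= 600 & mz < 1000
  if (any(!keep))
    warning(sum(!keep), " species outside [600, 1000) m/z dropped from ",
            "the peak library")
  if (!any(keep)) stop("no panel species falls inside [600, 1000) m/z")
  rng <- ifelse(mz < 850, "phospholipid", "triglyceride")
  amp <- with_seed(.AMPLITUDE_SEED, {
    lo <- ifelse(rng == "triglyceride", 200, 50)
    hi <- ifelse(rng == "triglyceride", 2000, 500)
    exp(stats::runif(length(mz), log(lo), log(hi)))
  })
  out <- data.frame(
    species = vapply(species, format, character(1)),
    ion = lipid_panel$ion, mz = mz, base_amplitude = amp, range = rng,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$mz), , drop = FALSE]
}

#' Generate one synthetic profile-mode spectrum
#'
#' The spectrum is a sum of Gaussian peaks at the library m/z positions,
#' rigidly shifted by one per-spectrum calibration offset drawn from
#' `Normal(0, calibration_drift_sd)`, on a regular grid covering
#' `[600, 1000)`. Tissue class scales phospholipid amplitudes by
#' `effect_factor` (tumour) and triglyceride amplitudes by its inverse;
#' coag mode scales triglycerides by `coag_tg_boost` and phospholipids by
#' its inverse. Per-peak multiplicative log-normal noise (CV `noise_cv`,
#' unit mean), an additive flat baseline, and optional +1.00335 Da isotope
#' satellites complete the model. The lock-mass peak (deprotonated
#' PA(36:2), 699.497 m/z) is always present.
#'
#' Randomness is consumed in a class-independent order (offset first, then
#' one noise draw per library peak), so with `effect_factor = 1` and
#' `coag_tg_boost = 1` identical RNG states yield identical tumour and
#' normal spectra.
#'
#' @param tissue_class `"normal"` or `"tumour"`.
#' @param mode `"cut"` or `"coag"`.
#' @param patient_effect Multiplicative global intensity factor (1 = none).
#' @param config A [synthetic_config()].
#' @param library Peak library from [build_peak_library()].
#' @param burn_id Identifier for the burn.
#' @return A [spectrum()].
#' @export
generate_spectrum <- function(tissue_class = c("normal", "tumour"),
                              mode = c("cut", "coag"), patient_effect = 1,
                              config = synthetic_config(),
                              library = build_peak_library(),
                              burn_id = "") {
  tissue_class <- match.arg(tissue_class)
  mode <- match.arg(mode)
  stopifnot(inherits(config, "synthetic_config"), patient_effect > 0)
  lib <- library
  if (!any(abs(lib$mz - 699.497) < 0.01)) {
    lib <- rbind(lib, data.frame(species = "PA(36:2)", ion = "[M-H]-",
                                 mz = ion_mz(lipid_species("PA", 36, 2)),
                                 base_amplitude = 300,
                                 range = "phospholipid",
                                 stringsAsFactors = FALSE))
  }
  offset <- stats::rnorm(1, 0, config$calibration_drift_sd)
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  noise <- exp(stats::rnorm(nrow(lib), -sdlog^2 / 2, sdlog))

  amp <- lib$base_amplitude
  is_tg <- lib$range == "triglyceride"
  if (tissue_class == "tumour") {
    amp <- ifelse(is_tg, amp / config$effect_factor,
                  amp * config$effect_factor)
  }
  if (mode == "coag") {
    amp <- ifelse(is_tg, amp * config$coag_tg_boost,
                  amp / config$coag_tg_boost)
  }
  amp <- amp * noise * patient_effect

  # profile points sit at bin centres of the standard grid, so downstream
  # binning at the same grain is alias-free
  step <- config$grid_step
  grid <- seq(600 + step / 2, 1000 - step / 2, by = step)
  values <- rep(config$baseline_level, length(grid))
  centres <- lib$mz + offset
  sats <- config$isotope_satellites
  w <- config$peak_width
  add_peak <- function(values, centre, height) {
    # evaluate only within +/-5 SD of the centre
    i0 <- max(1L, ceiling((centre - 5 * w - 600 - step / 2) / step) + 1L)
    i1 <- min(length(grid), floor((centre + 5 * w - 600 - step / 2) /
                                    step) + 1L)
    if (i0 > i1) return(values)
    idx <- i0:i1
    values[idx] <- values[idx] +
      height * exp(-0.5 * ((grid[idx] - centre) / w)^2)
    values
  }
  for (k in seq_len(nrow(lib))) {
    values <- add_peak(values, centres[k], amp[k])
    if (sats)
      values <- add_peak(values, centres[k] + .ISOTOPE_DELTA,
                         amp[k] * config$isotope_fraction)
  }
  spectrum(grid, values, mode = mode, burn_id = burn_id)
}

#' Generate a labelled synthetic dataset with ground truth
#'
#' Patients receive a log-normal global intensity effect and a tissue class
#' (tumour with probability `tumour_fraction`); each patient contributes
#' `samples_per_patient` samples of `burns_per_sample` burns. Identical
#' seeds give identical datasets.
#'
#' @param config A [synthetic_config()].
#' @param library Peak library from [build_peak_library()].
#' @return A list with elements `dataset` (a [reims_dataset()]) and
#'   `ground_truth`: `differential_mz` (data.frame `mz`, `direction` with
#'   `up_in_tumour` phospholipids in `[600, 850)` and `down_in_tumour`
#'   triglycerides in `[850, 1000)`) and `true_labels` (named character
#'   vector, sample_id -> tissue class).
#' @export
generate_dataset <- function(config = synthetic_config(),
                             library = build_peak_library()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_patients < 2 && !(config$tumour_fraction %in% c(0, 1)))
    stop("cannot place both tissue classes with a single patient; ",
         "use n_patients >= 2 or tumour_fraction in {0, 1}")
  with_seed(config$seed, {
    patient_ids <- sprintf("P%03d", seq_len(config$n_patients))
    patient_class <- ifelse(
      stats::runif(config$n_patients) < config$tumour_fraction,
      "tumour", "normal")
    patient_effect <- exp(stats::rnorm(config$n_patients, 0,
                                       config$patient_effect_sd))
    samples <- list()
    labels <- character()
    for (p in seq_len(config$n_patients)) {
      for (s in seq_len(config$samples_per_patient)) {
        sid <- sprintf("%s_S%02d", patient_ids[p], s)
        cls <- patient_class[p]
        histology <- if (cls == "tumour") {
          sample(c("B5b", "B5a"), 1, prob = c(0.85, 0.15))
        } else {
          sample(c("B1", "B2"), 1, prob = c(0.7, 0.3))
        }
        mode <- switch(config$mode_policy,
                       cut_only = "cut", coag_only = "coag",
                       mixed = sample(c("cut", "coag"), 1))
        burns <- lapply(seq_len(config$burns_per_sample), function(b)
          generate_spectrum(cls, mode, patient_effect[p], config, library,
                            burn_id = sprintf("%s_b%d", sid, b)))
        samples[[length(samples) + 1L]] <-
          sample_record(sid, patient_ids[p], burns, histology)
        labels[sid] <- cls
      }
    }
    gt_lib <- library
    truth <- data.frame(
      mz = gt_lib$mz,
      direction = ifelse(gt_lib$range == "phospholipid", "up_in_tumour",
                         "down_in_tumour"),
      stringsAsFactors = FALSE)
    list(dataset = reims_dataset(samples,
                                 provenance = "synthetic REIMS dataset"),
         ground_truth = list(differential_mz = truth, true_labels = labels))
  })
}
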