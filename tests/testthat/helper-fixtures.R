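# Shared fixtures: small synthetic worlds and hand-built spectra.

# Small, fast synthetic configuration for unit tests (not the acceptance
# scale). Noise and nuisance effects kept at their defaults.
tiny_config <- function(...) {
  args <- list(n_patients = 6, samples_per_patient = 1,
               burns_per_sample = 2, tumour_fraction = 0.5,
               effect_factor = 4, seed = 421)
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_config, args)
}

# A lone Gaussian peak as a profile spectrum on the standard centre-aligned
# grid.
gaussian_spectrum <- function(centre = 700, height = 100, width = 0.03,
                              baseline = 0, step = 0.01, mode = "cut") {
  grid <- seq(600 + step / 2, 1000 - step / 2, by = step)
  spectrum(grid, baseline + height * exp(-0.5 * ((grid - centre) / width)^2),
           mode = mode)
}

# Write a burn manifest + TSV spectra for a list of sample descriptors:
# list(list(sample_id=, patient_id=, histology=, mode=, spectra=list(...)))
write_test_manifest <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in samples) {
    for (k in seq_along(s$spectra)) {
      f <- sprintf("%s_b%d.tsv", s$sample_id, k)
      write_spectrum(s$spectra[[k]], file.path(dir, f), "tsv")
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s$sample_id, patient_id = s$patient_id,
        histology = s$histology, mode = s$mode, spectrum_path = f,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE,
                   quote = FALSE)
  manifest
}

# Independent enumeration oracle for the two-sided exact Mann-Whitney p:
# walks every group assignment directly (no shared code with the package).
mw_enum_oracle <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  lo <- min(u_obs, n1 * length(b) - u_obs)
  min(1, 2 * mean(u_all <= lo))
}

# Definitional double-loop Benjamini-Yekutieli oracle.
by_oracle <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (k in seq_len(m)) {
    best <- Inf
    for (j in k:m) best <- min(best, min(1, m * cm * ps[j] / j))
    q[k] <- best
  }
  out <- numeric(m)
  out[o] <- q
  out
}
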