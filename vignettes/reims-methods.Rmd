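---
title: "REIMS tissue classification: models, synthetic world, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{REIMS tissue classification: models, synthetic world, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reims)
```

## The problem

Rapid evaporative ionisation mass spectrometry (REIMS) analyses the aerosol
produced by an electrosurgical blade in real time. In negative-ion mode the
600–1000 m/z window of a breast-tissue burn is dominated by structural
lipids, and the balance between two regions carries the diagnostic signal:
glycerophospholipids (600–850 m/z) are enriched in tumour, triglycerides
(850–1000 m/z) in normal tissue. The electrosurgical mode adds a nuisance
effect of the same character — coagulation boosts triglyceride signal
relative to cutting — so a usable model must separate tissue class while
absorbing mode.

`reims` implements the full ex-vivo pipeline: burn spectra are binned,
background-subtracted, lock-mass corrected, averaged per sample, aligned,
peak-picked and turned into a normalised feature matrix; a PCA–LDA model
with Mahalanobis recognition is trained and validated leave-one-patient-out;
a univariate screen ranks individual peaks; and a lipid-mass module
annotates them.

## Classification model and assumptions

The feature matrix (samples × peaks, median-fold-change normalised and
log-transformed) is mean-centred and projected onto the smallest set of
principal components reaching `variance_retained` (default 0.95) cumulative
variance, capped at `n − g` components for `g` classes. The cap is the
standard guard against a singular LDA within-class scatter when peaks
outnumber samples. LDA then maximises between- over within-class scatter in
score space; with two classes this is a single axis, computed in closed
form as `W⁻¹(μ_tumour − μ_normal)` on the pooled within-class covariance. A
relative ridge (`1e-6 · trace/dim`) is added only if the scatter is
ill-conditioned, with a warning.

Recognition assigns a spectrum to the class with the smaller Mahalanobis
squared distance in discriminant space, using the pooled within-class
covariance of the training discriminant scores. "Greater than 2 SD" is
interpreted as `√d² > 2` for the closest class — spectra beyond the gate
are reported as outliers rather than forced into a class, and the
confusion-matrix metrics exclude them (they are counted in a third
column). At exact equidistance the first class in sorted label order is
returned and the result is flagged as a tie; this keeps every decision
deterministic.

The Mahalanobis gate alone lives in discriminant space, so a spectrum
unlike anything in training — pure chemical noise, an uncalibrated scan —
can project, by accident, between the class centroids and be "classified"
confidently. Recognition therefore also gates on the PCA reconstruction
residual (the chemometric Q statistic, as in SIMCA-style class models): a
spectrum whose residual exceeds five times the largest training residual
is an outlier regardless of its discriminant score. On the synthetic world
the margin is wide — training residuals sit below 1, fresh genuine burns
near 2, pure-noise scans above 16 — so the factor of five rejects noise
without touching real spectra.

The sample-level rule mirrors surgical asymmetry: a sample is called
tumour if *any* non-outlier burn is tumour, normal only if *all*
non-outlier burns are normal, indeterminate when every burn is an outlier.
False reassurance on a tumour sample is the costlier error, which is why
the rule is not majority vote.

Cross-validation is leave-one-patient-out. Each fold refits every
data-dependent stage — alignment reference, peak list, normalisation
reference, log offset, PCA and LDA — on the training patients only; the
held-out patient's profiles are aligned *to* the frozen training reference
and normalised against it, never the other way round. The per-spectrum
stages (binning, background subtraction, lock-mass correction, burn
averaging) involve no cross-sample information and are computed once. The
alternative reading — picking peaks once globally — was rejected as a
leakage channel.

Streaming recognition classifies each scan independently against the
frozen model (per-scan lock-mass correction, normalisation against the
stored training reference, no cross-scan alignment), since a live scan has
no cohort. Models intended for streaming are trained at the 0.1 Da
recognition grain. An optional 3-scan majority vote smooths segment
reporting and is off by default.

## The synthetic world

Real REIMS spectra are not redistributable, so the package carries a
generator whose defaults *are* the stated world of the tests. Each spectrum
is a sum of Gaussian peaks (SD 0.03 Da — a round value consistent with a
quadrupole time-of-flight's ~20k resolving power at m/z 700) at the
theoretical m/z of a 24-species marker panel: 18 phospholipid ions and 6
triglyceride chloride adducts, one representative species per published
differential peak. Base amplitudes are drawn once per species from
log-uniform ranges — 200–2000 for triglycerides, 50–500 for phospholipids,
fixed by an internal seed — so normal tissue is triglyceride-dominant by
construction. Tissue class multiplies phospholipid amplitudes by
`effect_factor` and divides triglyceride amplitudes by it (tumour);
coagulation mode does the reverse with `coag_tg_boost`. On top of this:
one rigid calibration offset per spectrum (`Normal(0, 0.01)` Da), per-peak
log-normal noise with unit mean (`noise_cv = 0.2`), a flat baseline (2
intensity units), a single ¹³C satellite per peak at +1.00335 Da and 0.6×
the parent amplitude, and a log-normal per-patient global intensity factor
(SD 0.3 on the log scale) that makes leave-one-patient-out measurably
different from leave-one-sample-out. Defaults: 20 patients × 2 samples × 3
burns, tumour fraction 0.4 per patient, mixed modes. Randomness is consumed
in a class-independent order, so the null world (`effect_factor = 1`,
`coag_tg_boost = 1`) generates tumour and normal spectra that are
bit-identical under the same RNG state — the basis of the null-calibration
test.

What the generator does **not** emulate: chemical noise and unassigned
background peaks, m/z-dependent resolution, detector saturation, full
isotope envelopes (one satellite only), intensity drift across acquisition
days, or within-patient histological heterogeneity. A green test therefore
establishes that the pipeline recovers the structure it claims to recover
under realistic noise, drift and patient correlation — not that the
published accuracies on real tissue are reproduced. The acceptance suite
makes the same distinction: published numbers are checked only where they
are arithmetic consequences of printed tables or analytic lipid masses;
classifier performance is checked as parameter recovery on the synthetic
world at its stated scales (40 patients at effect 4 for the 95/95 check;
null calibration at effect 1; 100 replicates of a 10+10-sample world for
the 18-up/6-down marker recovery).

## Numerical choices

* **Bin convention.** Bin `k` covers `[mz_lo + k·w, mz_lo + (k+1)·w)` —
  left-closed, right-open, anchored at 600. Points within 1e-6 of a bin
  width below a boundary are snapped up so grid-aligned input is binned as
  intended despite floating point. Binning conserves in-range intensity
  exactly.
* **Lock-mass correction grain.** The rigid shift is estimated from the
  apex bin nearest 699.497 m/z and applied by linear interpolation. At the
  0.1 Da recognition grain a direct estimate would be quantised to ±0.05 Da
  — five times the drift it corrects — so for coarse bins the spectrum is
  binned, background-subtracted and corrected at an internal 0.01 Da grain
  and then aggregated exactly (block sums) to the configured width. A
  spectrum with no signal in the ±0.25 Da lock-mass window is flagged and
  excluded (the pipeline's rendering of the published spectral-quality
  exclusion rules), or reported as an uncalibrated outlier in streaming
  mode.
* **Synthetic grid alignment.** Profile points sit at bin centres
  (600.005, 600.015, …). With points on bin edges the apex estimate
  carries a systematic half-bin bias that would break half-bin lock-mass
  recovery.
* **Background subtraction** (vendor-internal in the original workflow,
  unspecified): default is subtraction of the 25th percentile of nonzero
  bins — deterministic and parameter-light — with a rolling-minimum
  alternative behind the config. Applied post-binning.
* **Alignment.** Reference is the element-wise median spectrum; each
  spectrum shifts by the integer-bin lag (|lag| ≤ 0.1 Da) maximising
  cross-correlation, ties broken toward zero lag. This captures the intent
  of profile-mode alignment (residual jitter removal) with a verifiable
  contract rather than reproducing any particular published algorithm.
* **Peak picking** (also unspecified upstream): local maxima whose
  prominence exceeds `peak_min_snr` (default 5) times a robust noise
  level, prominence measured against the higher of the flanking minima
  within ±0.5 Da. The noise level is the MAD of *all* bins about zero: on
  a dense noisy profile this tracks the noise scale, while on a sparse
  background-subtracted spectrum (mostly exact zeros) it collapses to
  zero, where every genuine local maximum should be kept — an estimate
  over nonzero bins only is dominated by peak flanks and rejects real
  peaks several times weaker than the strongest (measured: 7 of 24 panel
  peaks lost on noiseless data). The apex is refined to sub-bin accuracy
  by three-point
  parabolic interpolation on log intensities. Sub-bin positions matter:
  with bin-centre positions the spacing between a ¹³C satellite
  (+1.00335 Da) and a genuine lipid one double-bond equivalent above a
  neighbour's satellite (+1.0124 Da) quantises to the same 1.01, and the
  isotope filter then discards true markers (measured: marker recall drops
  from ~0.99 to ~0.87).
* **Isotope exclusion tolerance.** Default 0.005 Da on the 1.00335 Da
  spacing. 0.01 Da would flag genuine markers, because
  1.0124 − 1.00335 = 0.009 — e.g. PE(36:1) sits exactly there relative to
  PE(36:2)'s satellite among the published peaks.
* **Median-fold-change normalisation** ignores features that are zero in
  the sample or the reference; after scaling, each sample's median fold
  change against the reference is exactly 1 (asserted to 1e-9). It also
  makes classification invariant to global intensity scaling, which the
  suite checks end-to-end on raw spectra.
* **Log offset.** The matrix is log-transformed as `log(x + offset)` with
  the offset defaulting to the smallest positive value in the training
  matrix (frozen into the model); a plain-log policy is available for
  strictly positive data. The source workflow is silent on zeros.
* **Mann–Whitney p values** are exact (full enumeration) for combined
  group sizes up to 16 without ties, otherwise normal approximation with
  tie and continuity correction. The "Benjamini-Hochburg-Yekutieli"
  correction is read as Benjamini–Yekutieli (2001), valid under arbitrary
  dependence (`c(m) = Σ 1/i`); plain Benjamini–Hochberg sits behind a
  flag. Fold changes use group means of TIC-normalised intensities
  (matching mean-intensity plotting conventions); medians are available.
* **Ion mass conventions.** Anion masses include the electron
  (0.000549 Da) by default; deprotonation removes a proton (1.007276 Da).
  `[M−CH₃−H]⁻` is implemented as demethylation (loss of CH₃⁺,
  15.0235 Da): that delta reproduces the published phosphatidylcholine
  peaks, whereas a CH₄-plus-proton reading misses them by ~1 Da. One
  published peak (717.51) is not reproduced by either of its own printed
  identifications under any convention (best 0.047 Da away; the
  phosphatidylcholine reading lands a full Dalton off, suggesting a typo
  for 718.54), though the annotation grid does offer PG ether candidates
  at 717.508; the representative marker panel keeps the printed
  identification at its theoretical mass and documents the mismatch
  rather than forcing it.
* **Percentages** are reported to one decimal place in printed output;
  stored values are unrounded.

## Known limitations

The generator's amplitude model is stipulated, not fitted — no per-class
intensity distributions are published. Streaming recognition assumes the
acquisition grain of one spectrum per scan and does not model scan-to-scan
carry-over. The annotation grid covers PA/PE/PC/PS/PG/TG with C 32–46
(longer for TG), N 0–7 and two ether linkages; sphingolipids, lyso-species
and oxidised lipids are out of scope, as are MS/MS fragment evidence,
>2-class models beyond relabelling, and probabilistic calibration of the
discriminant scores.
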