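# Univariate lipid-marker screen: total-intensity normalisation,
# Mann-Whitney U per peak, Benjamini-Yekutieli FDR control, log2 fold
# changes, isotope-satellite exclusion.

#' Total-intensity (TIC) normalisation
#'
#' Divides each sample by its feature sum so rows sum to 1. Applied to the
#' linear-scale feature matrix before univariate testing.
#'
#' @param fm A [feature_matrix()] with non-negative values.
#' @return A [feature_matrix()].
#' @export
tic_normalize <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- fm$values
  if (any(x < 0)) stop("TIC normalisation needs non-negative features")
  sums <- rowSums(x)
  zero <- sums == 0
  if (any(zero))
    stop("zero-sum sample(s): ",
         paste(rownames(x)[zero], collapse = ", "))
  feature_matrix(x / sums, fm$feature_mz,
                 c(fm$stage_log, "tic_normalize"), rownames(x))
}

#' Mann-Whitney U test
#'
#' Computes the U statistic for group `a` by midrank-tied rank sums. The
#' two-sided p value is exact — full enumeration of the permutation null —
#' when `length(a) + length(b) <= 16` and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used. When every value is identical across both groups, p = 1.
#'
#' @param a,b Numeric vectors, each non-empty.
#' @param exact_limit Largest combined size for which the exact null is
#'   enumerated.
#' @return List with `u` (U for group `a`), `p`, `method`.
#' @export
mann_whitney <- function(a, b, exact_limit = 16) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  n1 <- length(a)
  n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (length(unique(pooled)) == 1L)
    return(list(u = u, p = 1, method = "degenerate"))
  if (!ties && n1 + n2 <= exact_limit) {
    # exact: distribution of U over all C(n1+n2, n1) group assignments
    combos <- utils::combn(n1 + n2, n1)
    u_null <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    u_lo <- min(u, n1 * n2 - u)
    p <- min(1, 2 * sum(u_null <= u_lo) / length(u_null))
    return(list(u = u, p = p, method = "exact"))
  }
  n <- n1 + n2
  mu <- n1 * n2 / 2
  tie_counts <- table(pooled)
  sigma2 <- n1 * n2 / 12 *
    ((n + 1) - sum(tie_counts^3 - tie_counts) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(u = u, p = 1, method = "degenerate"))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  list(u = u, p = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal_approx")
}

#' Benjamini-Yekutieli false discovery rate adjustment
#'
#' The correction valid under arbitrary dependence: with m tests and
#' harmonic factor `c(m) = sum(1/i, i = 1..m)`, the adjusted value for the
#' k-th ordered p is `min over j >= k of min(1, m * c(m) * p(j) / j)`.
#' Input order is preserved. The plain Benjamini-Hochberg step-up
#' (`c(m) = 1`) is available behind `dependence = "independent"`.
#'
#' @param pvalues Numeric vector of p values in (0, 1].
#' @param dependence `"arbitrary"` (Benjamini-Yekutieli, default) or
#'   `"independent"` (Benjamini-Hochberg).
#' @return q values, same order and length as the input.
#' @export
by_fdr <- function(pvalues, dependence = c("arbitrary", "independent")) {
  dependence <- match.arg(dependence)
  m <- length(pvalues)
  if (m == 0L) return(numeric())
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p values must lie in (0, 1]")
  cm <- if (dependence == "arbitrary") sum(1 / seq_len(m)) else 1
  o <- order(pvalues)
  ranked <- pvalues[o]
  q <- pmin(1, m * cm * ranked / seq_len(m))
  q <- rev(cummin(rev(q))) # min over j >= k
  out <- numeric(m)
  out[o] <- q
  out
}

#' Log2 fold change between groups
#'
#' `log2(mean(a) / mean(b))` with `a` the tumour group, so positive values
#' mean higher in tumour. A pseudo-count (half the smallest positive value
#' across both groups) is used when a group mean is zero; if both means
#' are zero the result is `NA` and flagged.
#'
#' @param a Tumour-group values (TIC-normalised).
#' @param b Normal-group values.
#' @param use `"mean"` (default; matches mean-intensity plots) or
#'   `"median"`.
#' @return Numeric log2 fold change (NA when undefined).
#' @export
log2_fold_change <- function(a, b, use = c("mean", "median")) {
  use <- match.arg(use)
  f <- if (use == "mean") mean else stats::median
  ma <- f(a)
  mb <- f(b)
  if (ma == 0 || mb == 0) {
    pos <- c(a, b)
    pos <- pos[pos > 0]
    if (!length(pos)) return(NA_real_)
    pc <- min(pos) / 2
    ma <- ma + pc
    mb <- mb + pc
  }
  log2(ma / mb)
}

#' Flag isotope-satellite peaks
#'
#' A peak is flagged as an isotope satellite when a more intense peak sits
#' one 13C spacing (1.00335 Da, within `tol`) below it. Flagged peaks are
#' retained but excluded from significance reporting. The default
#' tolerance (0.005 Da) is tight enough to separate a satellite from a
#' genuine lipid one double-bond equivalent above the neighbouring
#' species' satellite (spacing 1.0124 Da); it requires the sub-bin peak
#' m/z that [pick_peaks()] provides.
#'
#' @param peaks data.frame with columns `mz` (sorted ascending) and
#'   `intensity` (group-mean intensity).
#' @param tol Tolerance (Da) on the isotope spacing.
#' @return The input with a logical `isotope` column appended.
#' @export
exclude_isotopes <- function(peaks, tol = 0.005) {
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in%
                                        names(peaks)))
  if (is.unsorted(peaks$mz)) stop("peaks must be sorted by m/z")
  n <- nrow(peaks)
  iso <- logical(n)
  for (i in seq_len(n)) {
    delta <- peaks$mz[i] - peaks$mz
    parents <- which(abs(delta - .ISOTOPE_DELTA) <= tol &
                       peaks$intensity > peaks$intensity[i])
    iso[i] <- length(parents) > 0
  }
  peaks$isotope <- iso
  peaks
}

#' Differential peak analysis between tumour and normal samples
#'
#' The published univariate screen: TIC normalisation, per-peak
#' Mann-Whitney U, Benjamini-Yekutieli FDR adjustment, log2 fold changes
#' (positive = higher in tumour), isotope-satellite exclusion. A peak is
#' significant when `q < alpha` and it is not an isotope satellite.
#'
#' @param fm Linear-scale [feature_matrix()] (post-extraction,
#'   pre-normalisation — `raw_features` from [preprocess_pipeline()]).
#' @param labels Character vector of tissue classes (`"normal"` /
#'   `"tumour"`), one per sample.
#' @param alpha FDR significance threshold, default 0.05.
#' @param isotope_tol Tolerance (Da) for the isotope spacing.
#' @param dependence FDR flavour, see [by_fdr()].
#' @return data.frame, one row per feature: `mz`, `u_statistic`, `p`, `q`,
#'   `log2_fold_change`, `mean_tumour`, `mean_normal`, `isotope_excluded`,
#'   `significant`.
#' @export
differential_analysis <- function(fm, labels, alpha = 0.05,
                                  isotope_tol = 0.005,
                                  dependence = "arbitrary") {
  stopifnot(inherits(fm, "feature_matrix"))
  labels <- as.character(labels)
  if (length(labels) != nrow(fm$values))
    stop("one label per sample required")
  if (!all(c("normal", "tumour") %in% labels))
    stop("both tumour and normal groups must be present")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  norm <- tic_normalize(fm)
  x <- norm$values
  tum <- labels == "tumour"
  tests <- lapply(seq_len(ncol(x)), function(j)
    mann_whitney(x[tum, j], x[!tum, j]))
  p <- vapply(tests, `[[`, numeric(1), "p")
  q <- by_fdr(p, dependence = dependence)
  l2fc <- vapply(seq_len(ncol(x)), function(j)
    log2_fold_change(x[tum, j], x[!tum, j]), numeric(1))
  mean_int <- colMeans(x)
  iso <- exclude_isotopes(
    data.frame(mz = fm$feature_mz, intensity = mean_int),
    tol = isotope_tol)$isotope
  data.frame(
    mz = fm$feature_mz,
    u_statistic = vapply(tests, `[[`, numeric(1), "u"),
    p = p, q = q, log2_fold_change = l2fc,
    mean_tumour = colMeans(x[tum, , drop = FALSE]),
    mean_normal = colMeans(x[!tum, , drop = FALSE]),
    isotope_excluded = iso,
    significant = q < alpha & !iso,
    stringsAsFactors = FALSE)
}
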