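# PCA-LDA classification with Mahalanobis closest-class recognition,
# outlier gating, and leave-one-patient-out cross-validation.

#' Model configuration
#'
#' @param variance_retained PCA keeps the smallest number of components
#'   whose cumulative explained variance reaches this fraction (capped at
#'   `n_samples - n_classes`).
#' @param outlier_sd_threshold A spectrum whose closest-class Mahalanobis
#'   distance (in SD units) exceeds this is called an outlier rather than
#'   assigned a class. Default 2.
#' @param ridge Relative ridge (times `trace/dim`) added to an
#'   ill-conditioned within-class scatter before inversion.
#' @return Object of class `model_config`.
#' @export
model_config <- function(variance_retained = 0.95, outlier_sd_threshold = 2,
                         ridge = 1e-6) {
  if (variance_retained <= 0 || variance_retained > 1)
    stop("variance_retained must lie in (0, 1]")
  if (outlier_sd_threshold <= 0) stop("outlier_sd_threshold must be > 0")
  structure(list(variance_retained = variance_retained,
                 outlier_sd_threshold = outlier_sd_threshold,
                 ridge = ridge),
            class = "model_config")
}

#' Fit the PCA stage
#'
#' Mean-centres the feature matrix and retains the smallest k components
#' with cumulative explained variance at or above `variance_retained`,
#' capped at `n_samples - n_classes` (the standard guard against a singular
#' LDA scatter when features outnumber samples).
#'
#' @param x Numeric matrix (samples x features) or [feature_matrix()].
#' @param variance_retained Fraction in (0, 1].
#' @param n_classes Number of classes the downstream LDA will see.
#' @return List with `center`, `rotation` (features x k), `explained`
#'   (variance fractions, all components) and `scores` (samples x k).
#' @export
fit_pca <- function(x, variance_retained = 0.95, n_classes = 2) {
  if (inherits(x, "feature_matrix")) x <- x$values
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs at least 2 samples")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  total <- sum(p$sdev^2)
  if (total <= 0) stop("constant feature matrix: no variance to decompose")
  explained <- p$sdev^2 / total
  cap <- max(1L, min(ncol(x), nrow(x) - n_classes))
  k <- which(cumsum(explained) >= variance_retained - 1e-12)[1]
  if (is.na(k)) k <- length(explained)
  k <- min(k, cap)
  # drop numerically null components
  k <- min(k, max(1L, sum(explained > 1e-12)))
  list(center = p$center, rotation = p$rotation[, seq_len(k), drop = FALSE],
       explained = explained, scores = p$x[, seq_len(k), drop = FALSE])
}

#' Fit the LDA stage in PCA-score space
#'
#' Maximises between-class over within-class scatter; for g classes this
#' yields g-1 discriminant axes (one for the two-class normal/tumour
#' problem). Class centroids and the pooled within-class covariance are
#' computed on the training discriminant scores; these drive Mahalanobis
#' classification. A relative ridge is added to an ill-conditioned
#' within-class scatter, with a warning.
#'
#' @param scores PCA scores (samples x k).
#' @param labels Class labels, one per sample; at least 2 classes with at
#'   least 2 samples each.
#' @param ridge Relative ridge term.
#' @return List with `axes` (k x (g-1)), `centroids` ((g-1) x g matrix of
#'   class centroids in LD space, columns named by class), `within_cov`
#'   (pooled within-class covariance in LD space), `classes`.
#' @export
fit_lda <- function(scores, labels, ridge = 1e-6) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  g <- length(classes)
  if (g < 2) stop("LDA needs at least 2 classes")
  counts <- table(labels)
  if (any(counts < 2)) stop("every class needs at least 2 samples")
  n <- nrow(scores)
  k <- ncol(scores)
  mu <- colMeans(scores)
  Sw <- matrix(0, k, k)
  Sb <- matrix(0, k, k)
  class_means <- matrix(0, k, g, dimnames = list(NULL, classes))
  for (cl in classes) {
    xc <- scores[labels == cl, , drop = FALSE]
    mc <- colMeans(xc)
    class_means[, cl] <- mc
    Sw <- Sw + crossprod(sweep(xc, 2, mc))
    Sb <- Sb + nrow(xc) * tcrossprod(mc - mu)
  }
  Sw <- Sw / (n - g)
  if (rcond(Sw) < 1e-10) {
    warning("ill-conditioned within-class scatter: ridge added")
    Sw <- Sw + diag(ridge * sum(diag(Sw)) / k, k)
  }
  if (g == 2) {
    w <- solve(Sw, class_means[, 2] - class_means[, 1])
    axes <- matrix(w / sqrt(sum(w^2)), ncol = 1)
  } else {
    eig <- eigen(solve(Sw, Sb))
    ord <- order(Re(eig$values), decreasing = TRUE)[seq_len(g - 1)]
    axes <- Re(eig$vectors[, ord, drop = FALSE])
    axes <- sweep(axes, 2, sqrt(colSums(axes^2)), "/")
  }
  ld <- scores %*% axes
  centroids <- vapply(classes, function(cl)
    colMeans(ld[labels == cl, , drop = FALSE]), numeric(ncol(axes)))
  centroids <- matrix(centroids, nrow = ncol(axes),
                      dimnames = list(NULL, classes))
  Wld <- matrix(0, ncol(axes), ncol(axes))
  for (cl in classes) {
    xc <- ld[labels == cl, , drop = FALSE]
    Wld <- Wld + crossprod(sweep(xc, 2, centroids[, cl]))
  }
  Wld <- Wld / (n - g)
  if (any(diag(Wld) <= 0) || rcond(Wld) < 1e-12)
    Wld <- Wld + diag(1e-12 * max(1, sum(diag(Wld))), ncol(Wld))
  list(axes = axes, centroids = centroids, within_cov = Wld,
       classes = classes, ld_scores = ld)
}

#' Train a PCA-LDA tissue classification model
#'
#' Runs the preprocessing pipeline on the dataset's non-excluded samples
#' (B1/B2 vs B5a/B5b), fits PCA then LDA, and freezes the preprocessing
#' references alongside the classifier so that any new spectrum is
#' transformed identically at prediction time.
#'
#' @param dataset A [reims_dataset()].
#' @param preprocess A [preprocess_config()].
#' @param config A [model_config()].
#' @return Object of class `reims_model`.
#' @export
train_model <- function(dataset, preprocess = preprocess_config(),
                        config = model_config()) {
  pp <- preprocess_pipeline(dataset, preprocess)
  keep <- pp$meta$tissue_class %in% c("normal", "tumour")
  if (sum(keep) < 4)
    stop("need at least 4 normal/tumour samples to train")
  x <- pp$features$values[keep, , drop = FALSE]
  labels <- pp$meta$tissue_class[keep]
  .fit_model_from_features(x, labels, pp$pipeline, config,
                           n_train = sum(keep))
}

# Squared PCA reconstruction residual (the chemometric Q statistic): how
# far a feature vector sits from the training subspace. Spectra unlike
# anything in training (e.g. pure noise) have huge Q even when their
# discriminant score happens to land between the class centroids.
.q_statistic <- function(pca, x) {
  d <- x - pca$center
  r <- d - pca$rotation %*% crossprod(pca$rotation, d)
  sum(r^2)
}

# Core fit used by both train_model and the cross-validation folds.
.fit_model_from_features <- function(x, labels, pipeline, config,
                                     n_train = nrow(x)) {
  pca <- fit_pca(x, config$variance_retained,
                 n_classes = length(unique(labels)))
  lda <- fit_lda(pca$scores, labels, config$ridge)
  model <- structure(list(
    version = "reims-model-1",
    pipeline = pipeline,
    pca = pca[c("center", "rotation", "explained")],
    lda = lda[c("axes", "centroids", "within_cov", "classes")],
    config = config,
    n_train = n_train), class = "reims_model")
  train_q <- apply(x, 1, function(v) .q_statistic(model$pca, v))
  model$q_threshold <- if (max(train_q) < 1e-12) Inf else 5 * max(train_q)
  model
}

#' @export
print.reims_model <- function(x, ...) {
  cat(sprintf(
    "<reims_model> classes {%s}; %d features -> %d PCs -> %d LD axis(es); trained on %d samples\n",
    paste(x$lda$classes, collapse = ", "),
    length(x$pipeline$feature_mz), ncol(x$pca$rotation),
    ncol(x$lda$axes), x$n_train))
  invisible(x)
}

#' Classify a preprocessed feature vector
#'
#' Projects the vector into the model's discriminant space and assigns the
#' closest class by Mahalanobis squared distance against the pooled
#' within-class covariance. A spectrum is called `"outlier"` instead when
#' the closest class lies more than `outlier_sd_threshold` SD away (square
#' root of the Mahalanobis squared distance), or when its PCA
#' reconstruction residual (Q statistic) exceeds five times the largest
#' training residual — a vector unlike anything in training can otherwise
#' project, by accident, between the class centroids. At exact
#' equidistance the first class in sorted label order wins and the result
#' is flagged `tie`.
#'
#' @param model A `reims_model`.
#' @param features Numeric vector on the model's feature grid (normalised
#'   and logged exactly as in training — use [classify_burn()] for raw
#'   spectra).
#' @return A `classification_result`: list with `predicted`,
#'   `mahalanobis_sq` (named per class), `ld_score`, `outlier`, `tie`.
#' @export
classify <- function(model, features) {
  stopifnot(inherits(model, "reims_model"))
  features <- as.numeric(features)
  if (length(features) != length(model$pca$center))
    stop("feature vector length ", length(features),
         " does not match the model's ", length(model$pca$center),
         " features")
  z <- drop(crossprod(model$pca$rotation, features - model$pca$center))
  ld <- drop(crossprod(model$lda$axes, z))
  Winv <- solve(model$lda$within_cov)
  d2 <- apply(model$lda$centroids, 2, function(mu) {
    d <- ld - mu
    drop(t(d) %*% Winv %*% d)
  })
  dmin <- min(d2)
  tie <- sum(abs(d2 - dmin) < 1e-12) > 1
  predicted <- names(d2)[which.min(d2)] # ties: first in sorted class order
  q <- .q_statistic(model$pca, features)
  q_thr <- model$q_threshold %||% Inf
  outlier <- sqrt(dmin) > model$config$outlier_sd_threshold || q > q_thr
  structure(list(
    predicted = if (outlier) "outlier" else predicted,
    class_call = predicted, mahalanobis_sq = d2, ld_score = ld,
    q_statistic = q,
    outlier = outlier, tie = tie), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification> %s (d = %s)%s\n", x$predicted,
              paste(sprintf("%s: %.2f", names(x$mahalanobis_sq),
                            sqrt(x$mahalanobis_sq)), collapse = ", "),
              if (x$tie) " [tie]" else ""))
  invisible(x)
}

#' Classify a single raw burn spectrum
#'
#' Preprocesses the burn with the model's frozen pipeline (bin, background,
#' lock-mass; normalisation against the stored training reference; stored
#' log offset) and classifies it. A burn without a findable lock-mass peak
#' is returned as an outlier with reason `"uncalibrated"`.
#'
#' @param model A `reims_model`.
#' @param spec A [spectrum()].
#' @param align Align the burn profile to the model's stored alignment
#'   reference (default TRUE; streaming recognition disables this).
#' @return A `classification_result` (with `reason` on failure).
#' @export
classify_burn <- function(model, spec, align = TRUE) {
  profile <- preprocess_burn(spec, model$pipeline$config)
  if (any(c("lockmass_failed", "zero_signal") %in% profile$flags)) {
    return(structure(list(
      predicted = "outlier", class_call = NA_character_,
      mahalanobis_sq = setNames(rep(NA_real_, length(model$lda$classes)),
                                model$lda$classes),
      ld_score = NA_real_, outlier = TRUE, tie = FALSE,
      reason = "uncalibrated"), class = "classification_result"))
  }
  fm <- .apply_feature_stages(list(burn = profile), model$pipeline,
                              align = align)
  classify(model, fm$values[1, ])
}

#' Sample-level classification from multiple burns
#'
#' Each burn is preprocessed and classified individually; the sample is
#' called `"tumour"` if at least one non-outlier burn is tumour,
#' `"normal"` if all non-outlier burns are normal, and `"indeterminate"`
#' if every burn is an outlier.
#'
#' @param model A `reims_model`.
#' @param burns List of [spectrum()] objects (>= 1).
#' @return List with `label` and `burn_results`.
#' @export
classify_sample <- function(model, burns) {
  if (!length(burns)) stop("at least one burn required")
  results <- lapply(burns, function(b) classify_burn(model, b))
  calls <- vapply(results, `[[`, character(1), "predicted")
  informative <- calls[calls != "outlier"]
  label <- if (!length(informative)) "indeterminate"
           else if (any(informative == "tumour")) "tumour"
           else "normal"
  list(label = label, burn_results = results)
}

#' Leave-one-patient-out cross-validation
#'
#' For each patient, the fold-dependent stages (alignment reference, peak
#' picking, normalisation reference, log offset, PCA, LDA) are refit on
#' the remaining patients only; all of the held-out patient's samples are
#' then preprocessed with the fold's frozen references and classified. No
#' information from a held-out patient enters any training stage. The
#' per-spectrum stages (binning, background subtraction, lock-mass
#' correction, burn averaging) are computed once, as they involve no
#' cross-sample information. Folds whose training set loses a class are
#' skipped with a warning and reported.
#'
#' @param dataset A [reims_dataset()]; B3/B4 samples are excluded.
#' @param preprocess A [preprocess_config()].
#' @param config A [model_config()].
#' @return A `cv_result`: list with `predictions` (data.frame sample_id,
#'   patient_id, truth, predicted), `metrics` (a [metrics_report()]),
#'   `folds` (patient -> fold index), `skipped_folds`.
#' @export
lopo_crossval <- function(dataset, preprocess = preprocess_config(),
                          config = model_config()) {
  sp <- .sample_profiles(dataset, preprocess)
  keep <- sp$meta$tissue_class %in% c("normal", "tumour")
  meta <- sp$meta[keep, , drop = FALSE]
  profiles <- sp$profiles[meta$sample_id]
  patients <- unique(meta$patient_id)
  per_class_patients <- tapply(meta$patient_id, meta$tissue_class,
                               function(p) length(unique(p)))
  if (any(per_class_patients < 2))
    warning("fewer than 2 patients in some class; folds may be skipped")
  preds <- list()
  skipped <- character()
  for (fold in seq_along(patients)) {
    held <- patients[fold]
    tr <- meta$patient_id != held
    te <- !tr
    train_labels <- meta$tissue_class[tr]
    if (length(unique(train_labels)) < 2 || any(table(train_labels) < 2)) {
      warning("fold for patient ", held,
              " skipped: a class is missing/degenerate in training")
      skipped <- c(skipped, held)
      next
    }
    fit <- .fit_feature_stages(profiles[meta$sample_id[tr]], preprocess)
    fold_model <- .fit_model_from_features(
      fit$features$values, train_labels, fit$pipeline, config)
    test_fm <- .apply_feature_stages(profiles[meta$sample_id[te]],
                                     fit$pipeline, align = TRUE)
    for (i in seq_len(sum(te))) {
      r <- classify(fold_model, test_fm$values[i, ])
      preds[[length(preds) + 1L]] <- data.frame(
        sample_id = meta$sample_id[te][i],
        patient_id = held, fold = fold,
        truth = meta$tissue_class[te][i],
        predicted = r$predicted, stringsAsFactors = FALSE)
    }
  }
  if (!length(preds))
    return(structure(list(predictions = NULL, metrics = NULL,
                          folds = setNames(seq_along(patients), patients),
                          skipped_folds = skipped), class = "cv_result"))
  predictions <- do.call(rbind, preds)
  metrics <- metrics_report(predictions$truth, predictions$predicted,
                            n_patients = length(setdiff(patients, skipped)))
  structure(list(predictions = predictions, metrics = metrics,
                 folds = setNames(seq_along(patients), patients),
                 skipped_folds = skipped), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Leave-one-patient-out cross-validation\n")
  if (length(x$skipped_folds))
    cat("  skipped folds:", paste(x$skipped_folds, collapse = ", "), "\n")
  if (is.null(x$metrics)) {
    cat("  no scorable folds\n")
  } else {
    print(x$metrics)
  }
  invisible(x)
}

#' Streaming recognition of a scan sequence
#'
#' Each incoming scan is preprocessed independently (per-scan lock-mass
#' correction and normalisation against the model's stored training
#' reference; no cross-scan alignment) and classified, in input order.
#' Intended for models trained at the 0.1 Da recognition grain.
#'
#' @param model A `reims_model`.
#' @param scans List of [spectrum()] objects, in acquisition order.
#' @param smooth_window Odd integer >= 1; a running majority vote over this
#'   many scans is reported in `smoothed` (1 = off).
#' @return data.frame with one row per scan: `scan`, `predicted`,
#'   `outlier`, `running_interpretable` (fraction of non-outlier scans so
#'   far), `smoothed`.
#' @export
stream_recognize <- function(model, scans, smooth_window = 1) {
  stopifnot(smooth_window >= 1, smooth_window %% 2 == 1)
  results <- lapply(scans, function(s)
    classify_burn(model, s, align = FALSE))
  labels <- vapply(results, `[[`, character(1), "predicted")
  outlier <- vapply(results, `[[`, logical(1), "outlier")
  running <- cumsum(!outlier) / seq_along(outlier)
  smoothed <- labels
  if (smooth_window > 1 && length(labels) >= smooth_window) {
    half <- smooth_window %/% 2
    for (i in seq_along(labels)) {
      win <- labels[max(1, i - half):min(length(labels), i + half)]
      win <- win[win != "outlier"]
      if (length(win))
        smoothed[i] <- names(which.max(table(win)))
    }
  }
  data.frame(scan = seq_along(labels), predicted = labels,
             outlier = outlier, running_interpretable = running,
             smoothed = smoothed, stringsAsFactors = FALSE)
}

# --------------------------------------------------------------------------
# Serialization: a model round-trips through a single versioned JSON file.

#' Save a model to a JSON file
#' @param model A `reims_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "reims_model"))
  obj <- model
  class(obj) <- NULL
  obj$pipeline <- unclass(obj$pipeline)
  obj$pipeline$config <- unclass(obj$pipeline$config)
  obj$config <- unclass(obj$config)
  # matrices are stored with explicit dims; JSON nesting does not preserve
  # shape reliably for 1-row/1-column matrices
  pack <- function(m) list(dim = dim(m), data = as.numeric(m))
  obj$pca$rotation <- pack(obj$pca$rotation)
  obj$lda$axes <- pack(obj$lda$axes)
  obj$lda$within_cov <- pack(obj$lda$within_cov)
  obj$lda$centroids <- pack(obj$lda$centroids)
  if (is.infinite(obj$q_threshold %||% Inf)) obj$q_threshold <- NULL
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model saved by [save_model()]
#' @param path JSON file path.
#' @return A `reims_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$version, "reims-model-1"))
    stop("unrecognised model version: ", obj$version)
  unpack <- function(m) matrix(as.numeric(m$data), m$dim[1], m$dim[2])
  obj$pca$rotation <- unpack(obj$pca$rotation)
  obj$lda$axes <- unpack(obj$lda$axes)
  obj$lda$within_cov <- unpack(obj$lda$within_cov)
  obj$lda$centroids <- unpack(obj$lda$centroids)
  colnames(obj$lda$centroids) <- obj$lda$classes
  obj$q_threshold <- as.numeric(obj$q_threshold %||% Inf)
  obj$pca$center <- as.numeric(obj$pca$center)
  cfg <- obj$pipeline$config
  obj$pipeline$config <- preprocess_config(
    mz_lo = cfg$mz_lo, mz_hi = cfg$mz_hi, bin_width = cfg$bin_width,
    lockmass_mz = cfg$lockmass_mz, lockmass_tol = cfg$lockmass_tol,
    background_method = cfg$background_method,
    peak_min_snr = cfg$peak_min_snr,
    log_offset_policy = cfg$log_offset_policy,
    align_max_shift = cfg$align_max_shift,
    feature_half_window = cfg$feature_half_window)
  obj$pipeline$align_reference <- as.numeric(obj$pipeline$align_reference)
  obj$pipeline$feature_mz <- as.numeric(obj$pipeline$feature_mz)
  obj$pipeline$norm_reference <- as.numeric(obj$pipeline$norm_reference)
  class(obj$pipeline) <- "reims_pipeline"
  obj$config <- model_config(obj$config$variance_retained,
                             obj$config$outlier_sd_threshold,
                             obj$config$ridge)
  structure(obj, class = "reims_model")
}
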