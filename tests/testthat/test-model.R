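# PCA-LDA model: fitting, Mahalanobis classification, outlier gating,
# cross-validation mechanics, streaming recognition.

test_that("PCA retains variance as configured and caps components", {
  # rank-1 data: one component explains everything
  set.seed(1)
  t_ <- rnorm(20)
  x <- cbind(t_, 2 * t_, -t_) + 1e-8 * matrix(rnorm(60), 20)
  p <- fit_pca(x, 0.95)
  expect_identical(ncol(p$rotation), 1L)
  expect_gt(p$explained[1], 0.999)

  # variance_retained = 1 hits the n - classes cap
  x2 <- matrix(rnorm(8 * 30), 8)
  p2 <- fit_pca(x2, 1.0, n_classes = 2)
  expect_identical(ncol(p2$rotation), 6L) # 8 samples - 2 classes

  expect_error(fit_pca(matrix(1, 5, 3), 0.95), "constant")
})

test_that("PCA reconstruction error decreases monotonically in k", {
  set.seed(2)
  x <- matrix(rnorm(30 * 10), 30) %*% diag(sqrt(10:1))
  xc <- scale(x, scale = FALSE)
  # oracle: eigendecomposition of the covariance
  eig <- eigen(stats::cov(xc), symmetric = TRUE)
  errs <- vapply(1:10, function(k) {
    v <- eig$vectors[, 1:k, drop = FALSE]
    sum((xc - xc %*% v %*% t(v))^2)
  }, numeric(1))
  expect_true(all(diff(errs) < 1e-8))
  # package PCA spans the same leading subspace (compare reconstruction)
  p <- fit_pca(x, 1.0, n_classes = 0)
  k <- ncol(p$rotation)
  recon_pkg <- sum((xc - xc %*% p$rotation %*% t(p$rotation))^2)
  expect_equal(recon_pkg, errs[k], tolerance = 1e-6)
})

test_that("two-class LDA matches the closed-form discriminant", {
  set.seed(3)
  n <- 40
  x <- rbind(matrix(rnorm(n * 3, 0), n),
             matrix(rnorm(n * 3, 6), n))
  labels <- rep(c("normal", "tumour"), each = n)
  fit <- fit_lda(x, labels)
  # oracle: w proportional to pooled-covariance^-1 (mu2 - mu1)
  s1 <- stats::cov(x[1:n, ])
  s2 <- stats::cov(x[(n + 1):(2 * n), ])
  sp <- ((n - 1) * s1 + (n - 1) * s2) / (2 * n - 2)
  w <- solve(sp, colMeans(x[(n + 1):(2 * n), ]) - colMeans(x[1:n, ]))
  w <- w / sqrt(sum(w^2))
  cosang <- abs(sum(w * fit$axes[, 1]))
  expect_equal(cosang, 1, tolerance = 1e-8)

  # well-separated clouds: training accuracy 100%
  ld <- x %*% fit$axes
  mid <- mean(fit$centroids[1, ])
  calls <- ifelse(ld[, 1] > mid, colnames(fit$centroids)[
    which.max(fit$centroids[1, ])], colnames(fit$centroids)[
      which.min(fit$centroids[1, ])])
  expect_identical(unname(calls), labels)

  expect_error(fit_lda(x, rep("a", 2 * n)), "2 classes")
})

test_that("classification follows the Mahalanobis closest-class rule", {
  gen <- generate_dataset(tiny_config(n_patients = 6))
  model <- train_model(gen$dataset)

  # a vector at a class centroid: that class, distance 0, no outlier
  for (cl in model$lda$classes) {
    # invert the projection approximately: centroid -> feature space
    ld_target <- model$lda$centroids[, cl]
    v <- model$pca$center +
      drop(model$pca$rotation %*% (model$lda$axes %*% ld_target))
    r <- classify(model, v)
    expect_identical(r$predicted, cl)
    expect_lt(min(r$mahalanobis_sq), 1e-9)
    expect_false(r$outlier)
  }

  # equidistant vector: deterministic tie to first sorted class, flagged
  mid <- rowMeans(model$lda$centroids)
  v <- model$pca$center +
    drop(model$pca$rotation %*% (model$lda$axes %*% mid))
  r <- classify(model, v)
  expect_true(r$tie)
  expect_identical(r$class_call, sort(model$lda$classes)[1])

  # far beyond both centroids: outlier
  sd_ld <- sqrt(model$lda$within_cov[1, 1])
  span <- model$lda$centroids[1, 2] - model$lda$centroids[1, 1]
  far <- model$lda$centroids[, 2] + (abs(span) + 10 * sd_ld)
  v <- model$pca$center +
    drop(model$pca$rotation %*% (model$lda$axes %*% far))
  r <- classify(model, v)
  expect_identical(r$predicted, "outlier")
  expect_true(r$outlier)

  expect_error(classify(model, 1:3), "does not match")
})

test_that("classification agrees with a brute-force nearest-centroid oracle", {
  gen <- generate_dataset(tiny_config(n_patients = 6))
  model <- train_model(gen$dataset)
  set.seed(11)
  for (i in 1:20) {
    v <- model$pca$center + rnorm(length(model$pca$center), 0, 0.5)
    r <- classify(model, v)
    # independent recomputation of the decision
    z <- drop(t(model$pca$rotation) %*% (v - model$pca$center))
    ld <- drop(t(model$lda$axes) %*% z)
    d2 <- vapply(model$lda$classes, function(cl) {
      d <- ld - model$lda$centroids[, cl]
      drop(t(d) %*% solve(model$lda$within_cov) %*% d)
    }, numeric(1))
    expect_equal(unname(r$mahalanobis_sq), unname(d2), tolerance = 1e-9)
    expect_identical(r$class_call, names(which.min(d2)))
    # 2-class boundary is the centroid midpoint in LD space
    mid <- mean(model$lda$centroids[1, ])
    lower <- colnames(model$lda$centroids)[which.min(
      model$lda$centroids[1, ])]
    upper <- colnames(model$lda$centroids)[which.max(
      model$lda$centroids[1, ])]
    expect_identical(r$class_call, if (ld[1] < mid) lower else upper)
  }
})

test_that("classification is invariant to global intensity scaling", {
  gen <- generate_dataset(tiny_config(n_patients = 6))
  model <- train_model(gen$dataset)
  set.seed(12)
  s <- generate_spectrum("tumour", "cut", 1, tiny_config())
  r1 <- classify_burn(model, s)
  r2 <- classify_burn(model, spectrum(s$mz, s$intensity * 37.5,
                                      mode = s$mode))
  expect_identical(r1$predicted, r2$predicted)
  expect_equal(r1$mahalanobis_sq, r2$mahalanobis_sq, tolerance = 1e-9)
})

test_that("the sample-level decision rule is any-tumour", {
  cfg <- tiny_config(n_patients = 8, burns_per_sample = 2)
  gen <- generate_dataset(cfg)
  model <- train_model(gen$dataset, preprocess_config(bin_width = 0.1))
  set.seed(13)
  s_n1 <- generate_spectrum("normal", "cut", 1, cfg)
  s_n2 <- generate_spectrum("normal", "coag", 1, cfg)
  s_t <- generate_spectrum("tumour", "cut", 1, cfg)
  mzg <- seq(600.005, 999.995, 0.01)
  noise_int <- rexp(length(mzg))
  noise_int[abs(mzg - 699.497) < 0.3] <- 0 # no lock-mass peak
  noise <- spectrum(mzg, noise_int)

  expect_identical(classify_sample(model, list(s_n1, s_n2, s_t))$label,
                   "tumour")
  expect_identical(classify_sample(model, list(s_n1, s_n2))$label,
                   "normal")
  res <- classify_sample(model, list(noise, noise))
  expect_identical(res$label, "indeterminate")
  expect_identical(res$burn_results[[1]]$reason, "uncalibrated")
})

test_that("LOPO folds are patient-disjoint and cover every sample once", {
  gen <- generate_dataset(tiny_config(n_patients = 8,
                                      samples_per_patient = 2))
  cv <- lopo_crossval(gen$dataset)
  preds <- cv$predictions
  expect_false(any(duplicated(preds$sample_id)))
  meta <- summary(gen$dataset)
  expect_setequal(preds$sample_id, meta$sample_id)
  # every prediction's patient matches its fold's held-out patient
  expect_identical(preds$patient_id,
                   names(cv$folds)[preds$fold])
  # a patient's samples all share one fold
  expect_true(all(tapply(preds$fold, preds$patient_id,
                         function(f) length(unique(f))) == 1))
})

test_that("degenerate LOPO folds are skipped with a report", {
  # exactly one patient per class: every fold trains on a single class
  cfg <- tiny_config()
  set.seed(14)
  mk <- function(sid, pid, cls, hist)
    sample_record(sid, pid, list(
      generate_spectrum(cls, "cut", 1, cfg),
      generate_spectrum(cls, "cut", 1, cfg)), hist)
  ds <- reims_dataset(list(mk("s1", "p1", "normal", "B1"),
                           mk("s2", "p2", "tumour", "B5b")))
  ws <- capture_warnings(cv <- lopo_crossval(ds))
  expect_true(any(grepl("skipped", ws)))
  expect_identical(length(cv$skipped_folds), 2L)
  expect_null(cv$predictions)
})

test_that("LOPO accuracy grows with effect size and shrinks with noise", {
  acc <- function(effect, noise = 0.2, seed = 77) {
    gen <- generate_dataset(tiny_config(
      n_patients = 8, samples_per_patient = 2, effect_factor = effect,
      noise_cv = noise, seed = seed))
    cv <- suppressWarnings(lopo_crossval(gen$dataset))
    cv$metrics$accuracy
  }
  a1 <- acc(1)
  a4 <- acc(4)
  expect_gte(a4, a1)
  expect_gte(a4, 90)
  # heavy multiplicative noise degrades accuracy
  a4_noisy <- acc(4, noise = 3)
  expect_gte(a4, a4_noisy)
})

test_that("streaming recognition is stateless and flags uncalibrated scans", {
  cfg <- tiny_config(n_patients = 8, burns_per_sample = 2)
  gen <- generate_dataset(cfg)
  model <- train_model(gen$dataset, preprocess_config(bin_width = 0.1))
  set.seed(21)
  scan <- generate_spectrum("tumour", "cut", 1, cfg)
  res <- stream_recognize(model, list(scan, scan, scan))
  expect_identical(res$predicted[1], res$predicted[2])
  expect_identical(res$predicted[2], res$predicted[3])

  # an all-noise stream is ~100% outliers
  noise_scans <- replicate(5, spectrum(seq(600, 999.99, 0.01),
                                       rexp(40000)), simplify = FALSE)
  res_n <- stream_recognize(model, noise_scans)
  expect_true(all(res_n$outlier))
  expect_equal(res_n$running_interpretable[5], 0)

  # a normal -> tumour -> normal dissection line segments correctly after
  # majority smoothing
  set.seed(22)
  line <- c(replicate(6, generate_spectrum("normal", "coag", 1, cfg),
                      simplify = FALSE),
            replicate(6, generate_spectrum("tumour", "coag", 1, cfg),
                      simplify = FALSE),
            replicate(6, generate_spectrum("normal", "coag", 1, cfg),
                      simplify = FALSE))
  res_l <- stream_recognize(model, line, smooth_window = 3)
  seg <- rle(res_l$smoothed[res_l$smoothed != "outlier"])$values
  expect_identical(seg, c("normal", "tumour", "normal"))
})

test_that("models survive a JSON round trip", {
  gen <- generate_dataset(tiny_config(n_patients = 6))
  model <- train_model(gen$dataset, preprocess_config(bin_width = 0.1))
  d <- withr::local_tempdir()
  f <- file.path(d, "model.json")
  save_model(model, f)
  m2 <- load_model(f)
  set.seed(31)
  v <- model$pca$center + rnorm(length(model$pca$center), 0, 0.3)
  r1 <- classify(model, v)
  r2 <- classify(m2, v)
  expect_identical(r1$predicted, r2$predicted)
  expect_equal(r1$mahalanobis_sq, r2$mahalanobis_sq, tolerance = 1e-12)
  bad <- file.path(d, "bad.json")
  jsonlite::write_json(list(version = "x"), bad, auto_unbox = TRUE)
  expect_error(load_model(bad), "version")
})
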