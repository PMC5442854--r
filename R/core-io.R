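# Domain types and I/O: profile-mode spectra, burn/sample/patient datasets,
# CSV manifests, TSV and minimal mzML spectrum files.

.HISTOLOGY_CODES <- c("B1", "B2", "B3", "B4", "B5a", "B5b")
.MODES <- c("cut", "coag")

#' Construct a profile-mode spectrum
#'
#' @param mz Numeric vector of m/z values (Da). Out-of-order input is
#'   sorted; duplicate m/z values are merged by summing intensities.
#' @param intensity Non-negative intensities, same length as `mz`.
#' @param mode Electrosurgical mode, `"cut"` or `"coag"`.
#' @param burn_id Opaque identifier for the burn.
#' @return Object of class `reims_spectrum` with strictly increasing `mz`.
#' @export
spectrum <- function(mz, intensity, mode = "cut", burn_id = "") {
  mode <- match.arg(mode, .MODES)
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (anyNA(mz) || anyNA(intensity))
    stop("mz and intensity must not contain NA")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (is.unsorted(mz, strictly = TRUE)) {
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
    if (anyDuplicated(mz)) {
      intensity <- as.numeric(rowsum(intensity, group = mz))
      mz <- sort(unique(mz))
    }
  }
  structure(list(mz = mz, intensity = intensity, mode = mode,
                 burn_id = as.character(burn_id)),
            class = "reims_spectrum")
}

#' @export
print.reims_spectrum <- function(x, ...) {
  cat(sprintf("<reims_spectrum> %d points, mode=%s%s\n", length(x$mz),
              x$mode,
              if (length(x$mz))
                sprintf(", m/z %.4f-%.4f", min(x$mz), max(x$mz)) else ""))
  invisible(x)
}

#' Map a histology B-code to its tissue class
#'
#' B1 (normal) and B2 (benign) map to `"normal"`; B5a (in-situ) and B5b
#' (invasive) to `"tumour"`; B3 (uncertain malignant potential) and B4
#' (suspicious) load but are flagged `"excluded"` and take no part in
#' two-class model building.
#'
#' @param histology Character vector of B-codes.
#' @return Character vector in `c("normal", "tumour", "excluded")`.
#' @export
tissue_class_of <- function(histology) {
  bad <- setdiff(unique(histology), .HISTOLOGY_CODES)
  if (length(bad))
    stop("unknown histology code(s): ", paste(bad, collapse = ", "))
  out <- rep("excluded", length(histology))
  out[histology %in% c("B1", "B2")] <- "normal"
  out[histology %in% c("B5a", "B5b")] <- "tumour"
  out
}

#' Construct a sample record (one tissue sample, one or more burns)
#'
#' @param sample_id,patient_id Identifiers.
#' @param burns List of [spectrum()] objects, at least one.
#' @param histology One of `B1, B2, B3, B4, B5a, B5b`.
#' @return Object of class `sample_record` with derived `tissue_class`.
#' @export
sample_record <- function(sample_id, patient_id, burns, histology) {
  if (!length(burns)) stop("a sample needs at least one burn")
  if (!all(vapply(burns, inherits, logical(1), "reims_spectrum")))
    stop("burns must be reims_spectrum objects")
  structure(list(sample_id = as.character(sample_id),
                 patient_id = as.character(patient_id),
                 burns = burns,
                 histology = match.arg(histology, .HISTOLOGY_CODES),
                 tissue_class = tissue_class_of(histology)),
            class = "sample_record")
}

#' Construct a dataset (collection of sample records)
#'
#' @param samples List of [sample_record()] objects with unique sample ids.
#' @param provenance Free-text metadata.
#' @return Object of class `reims_dataset`.
#' @export
reims_dataset <- function(samples, provenance = "") {
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids))
    stop("duplicate sample_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  pid <- vapply(samples, `[[`, character(1), "patient_id")
  if (any(!nzchar(pid))) stop("every sample needs a patient_id")
  structure(list(samples = samples, provenance = provenance),
            class = "reims_dataset")
}

#' @export
print.reims_dataset <- function(x, ...) {
  cls <- vapply(x$samples, `[[`, character(1), "tissue_class")
  cat(sprintf(
    "<reims_dataset> %d samples (%d normal, %d tumour, %d excluded), %d patients, %d burns\n",
    length(x$samples), sum(cls == "normal"), sum(cls == "tumour"),
    sum(cls == "excluded"),
    length(unique(vapply(x$samples, `[[`, character(1), "patient_id"))),
    sum(vapply(x$samples, function(s) length(s$burns), integer(1)))))
  invisible(x)
}

#' Summarise a dataset as a data.frame
#'
#' @param object A [reims_dataset()].
#' @param ... Unused.
#' @return One row per sample: sample_id, patient_id, histology,
#'   tissue_class, n_burns.
#' @export
summary.reims_dataset <- function(object, ...) {
  data.frame(
    sample_id = vapply(object$samples, `[[`, character(1), "sample_id"),
    patient_id = vapply(object$samples, `[[`, character(1), "patient_id"),
    histology = vapply(object$samples, `[[`, character(1), "histology"),
    tissue_class = vapply(object$samples, `[[`, character(1),
                          "tissue_class"),
    n_burns = vapply(object$samples, function(s) length(s$burns),
                     integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Preprocessing configuration
#'
#' Defaults follow the published workflow: 600-1000 m/z window, 0.01 Da
#' bins for model building (0.1 Da for on-line recognition), lock-mass
#' recalibration to the deprotonated PA(36:2) ion at 699.497 m/z,
#' background subtraction, prominence-based peak picking.
#'
#' @param mz_lo,mz_hi Mass window (Da), half-open `[mz_lo, mz_hi)`.
#' @param bin_width Bin width (Da); 0.01 for model building, 0.1 for
#'   recognition.
#' @param lockmass_mz Lock-mass m/z, default 699.497.
#' @param lockmass_tol Half-width of the lock-mass search window (Da).
#' @param background_method `"constant_percentile"` (default; subtracts the
#'   25th percentile of nonzero bins) or `"rolling_min"`.
#' @param peak_min_snr Peak prominence threshold in units of the robust
#'   noise level (MAD of nonzero bins).
#' @param log_offset_policy `"min_positive"` (default: offset is the
#'   smallest positive matrix value) or `"none"` (plain log; requires
#'   strictly positive input).
#' @param align_max_shift Maximum rigid alignment shift (Da).
#' @param feature_half_window Half-width (Da) of the window summed around
#'   each picked peak to form a feature.
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(mz_lo = 600, mz_hi = 1000, bin_width = 0.01,
                              lockmass_mz = 699.497, lockmass_tol = 0.25,
                              background_method = c("constant_percentile",
                                                    "rolling_min"),
                              peak_min_snr = 5,
                              log_offset_policy = c("min_positive", "none"),
                              align_max_shift = 0.1,
                              feature_half_window = 0.05) {
  background_method <- match.arg(background_method)
  log_offset_policy <- match.arg(log_offset_policy)
  if (!(mz_lo < mz_hi)) stop("mz_lo must be < mz_hi")
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (lockmass_mz < mz_lo || lockmass_mz > mz_hi)
    stop("lockmass_mz must lie within [mz_lo, mz_hi]")
  if (lockmass_tol <= 0 || peak_min_snr <= 0 || align_max_shift < 0 ||
      feature_half_window <= 0)
    stop("tolerances and thresholds must be positive")
  structure(list(mz_lo = mz_lo, mz_hi = mz_hi, bin_width = bin_width,
                 lockmass_mz = lockmass_mz, lockmass_tol = lockmass_tol,
                 background_method = background_method,
                 peak_min_snr = peak_min_snr,
                 log_offset_policy = log_offset_policy,
                 align_max_shift = align_max_shift,
                 feature_half_window = feature_half_window),
            class = "preprocess_config")
}

# --------------------------------------------------------------------------
# Spectrum files: two-column TSV (comments with '#') and minimal mzML.

#' Read a spectrum from disk
#'
#' Supports the package's two-column TSV dialect (m/z, intensity; `#`
#' comments and blank lines allowed) and mzML files containing at least one
#' MS1 profile scan (the first spectrum is read; 64- and 32-bit float
#' arrays, uncompressed or zlib where the platform supports it).
#'
#' @param path File path.
#' @param format `"tsv"` or `"mzml"`; default guesses from the extension.
#' @param mode,burn_id Metadata attached to the returned spectrum.
#' @return A [spectrum()]; m/z sorted, duplicates merged by intensity sum.
#' @export
read_spectrum <- function(path, format = c("auto", "tsv", "mzml"),
                          mode = "cut", burn_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml"
              else "tsv"
  if (is.null(burn_id))
    burn_id <- tools::file_path_sans_ext(basename(path))
  if (format == "tsv") .read_spectrum_tsv(path, mode, burn_id)
  else .read_spectrum_mzml(path, mode, burn_id)
}

.read_spectrum_tsv <- function(path, mode, burn_id) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(spectrum(numeric(), numeric(), mode = mode, burn_id = burn_id))
  parts <- strsplit(lines, "[\t ,]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("%s: malformed record on data line %d (expected 2 columns)",
                 path, bad[1]))
  mat <- suppressWarnings(
    matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE))
  if (anyNA(mat)) {
    bad <- which(apply(is.na(mat), 1, any))[1]
    stop(sprintf("%s: non-numeric value on data line %d", path, bad))
  }
  spectrum(mat[, 1], mat[, 2], mode = mode, burn_id = burn_id)
}

#' Write a spectrum to disk
#'
#' TSV output uses fixed `%.8g` formatting so identical spectra produce
#' byte-identical files; mzML output is a minimal single-spectrum MS1
#' profile document with uncompressed 64-bit little-endian arrays.
#' `read_spectrum(write_spectrum(s, p), p)` reproduces `mz`/`intensity` to
#' better than 6 significant figures.
#'
#' @param spec A [spectrum()].
#' @param path Output path.
#' @param format `"tsv"` or `"mzml"`; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path, format = c("auto", "tsv", "mzml")) {
  stopifnot(inherits(spec, "reims_spectrum"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml"
              else "tsv"
  if (format == "tsv") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(c("# m/z\tintensity",
                 sprintf("%.8g\t%.8g", spec$mz, spec$intensity)),
               con, sep = "\n")
  } else {
    .write_spectrum_mzml(spec, path)
  }
  invisible(path)
}

# Minimal mzML: enough structure for round-tripping MS1 profile scans and
# for reading files that follow the same core layout. Not a full PSI
# implementation.
.write_spectrum_mzml <- function(spec, path) {
  enc <- function(x) {
    if (!length(x)) return("")
    jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                  endian = "little"))
  }
  n <- length(spec$mz)
  doc <- sprintf(
'<?xml version="1.0" encoding="utf-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">
  <run id="%s">
    <spectrumList count="1">
      <spectrum index="0" id="scan=1" defaultArrayLength="%d">
        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>
        <cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>
        <binaryDataArrayList count="2">
          <binaryDataArray encodedLength="0">
            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
            <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>
            <binary>%s</binary>
          </binaryDataArray>
          <binaryDataArray encodedLength="0">
            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
            <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>
            <binary>%s</binary>
          </binaryDataArray>
        </binaryDataArrayList>
      </spectrum>
    </spectrumList>
  </run>
</mzML>',
    xml_escape(spec$burn_id), n, enc(spec$mz), enc(spec$intensity))
  writeLines(doc, path, sep = "\n")
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.read_spectrum_mzml <- function(path, mode, burn_id) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop(sprintf("%s: not parseable as mzML (%s)",
                                 path, conditionMessage(e))))
  nss <- tryCatch(as.character(xml2::xml_ns(doc)[[1]]),
                  error = function(e) character())
  has_ns <- length(nss) > 0
  ns <- if (has_ns) c(d1 = nss)
  find_all <- function(node, tag) {
    if (has_ns) xml2::xml_find_all(node, paste0(".//d1:", tag), ns)
    else xml2::xml_find_all(node, paste0(".//", tag))
  }
  find_first <- function(node, tag) {
    if (has_ns) xml2::xml_find_first(node, paste0(".//d1:", tag), ns)
    else xml2::xml_find_first(node, paste0(".//", tag))
  }
  specs <- find_all(doc, "spectrum")
  if (!length(specs)) stop(path, ": no <spectrum> elements found")
  # first MS1 spectrum if annotated, else the first spectrum
  pick <- NULL
  for (s in specs) {
    lvl <- find_first(s, "cvParam[@accession='MS:1000511']")
    if (inherits(lvl, "xml_missing") ||
        identical(xml2::xml_attr(lvl, "value"), "1")) {
      pick <- s
      break
    }
  }
  if (is.null(pick)) stop(path, ": no MS1 spectrum found")
  arrays <- find_all(pick, "binaryDataArray")
  mz <- intensity <- NULL
  for (a in arrays) {
    acc <- xml2::xml_attr(find_all(a, "cvParam"), "accession")
    vals <- .decode_binary_array(
      xml2::xml_text(find_first(a, "binary")), acc, path)
    if ("MS:1000514" %in% acc) mz <- vals
    if ("MS:1000515" %in% acc) intensity <- vals
  }
  if (is.null(mz) || is.null(intensity))
    stop(path, ": spectrum lacks m/z or intensity binary arrays")
  if (length(mz) != length(intensity))
    stop(path, ": m/z and intensity arrays differ in length")
  spectrum(mz, intensity, mode = mode, burn_id = burn_id)
}

.decode_binary_array <- function(b64, accessions, path) {
  raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", b64))
  if ("MS:1000574" %in% accessions) { # zlib
    raw <- tryCatch(memDecompress(raw, type = "gzip"),
                    error = function(e)
                      stop(path, ": zlib-compressed array could not be ",
                           "decompressed (", conditionMessage(e), ")"))
  }
  size <- if ("MS:1000521" %in% accessions) 4L else 8L
  readBin(raw, what = "double", n = length(raw) %/% size, size = size,
          endian = "little")
}

# --------------------------------------------------------------------------
# Dataset manifest: CSV, one row per burn, fixed header.

.MANIFEST_COLS <- c("sample_id", "patient_id", "histology", "mode",
                    "spectrum_path")

#' Load a dataset from a CSV manifest
#'
#' The manifest has one row per burn with columns `sample_id, patient_id,
#' histology, mode, spectrum_path`; burns sharing a `sample_id` are grouped
#' into one sample. Relative `spectrum_path`s are resolved against the
#' manifest's directory. B3/B4 samples load with `tissue_class =
#' "excluded"` rather than being rejected.
#'
#' @param manifest Path to the manifest CSV.
#' @return A [reims_dataset()].
#' @export
load_dataset <- function(manifest) {
  if (!file.exists(manifest)) stop("no such manifest: ", manifest)
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(.MANIFEST_COLS, names(df))
  if (length(missing_cols))
    stop("manifest missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("empty manifest: ", manifest)
    return(reims_dataset(list(), provenance = manifest))
  }
  tissue_class_of(df$histology) # validates codes
  bad_mode <- setdiff(unique(df$mode), .MODES)
  if (length(bad_mode))
    stop("unknown mode(s): ", paste(bad_mode, collapse = ", "))
  base <- dirname(manifest)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", df$spectrum_path),
                  df$spectrum_path, file.path(base, df$spectrum_path))
  absent <- !file.exists(paths)
  if (any(absent))
    stop("manifest references missing spectrum file(s): ",
         paste(unique(paths[absent]), collapse = ", "))
  samples <- lapply(split(seq_len(nrow(df)), df$sample_id), function(idx) {
    rows <- df[idx, , drop = FALSE]
    if (length(unique(rows$patient_id)) != 1L)
      stop("sample ", rows$sample_id[1], " maps to multiple patient_ids")
    if (length(unique(rows$histology)) != 1L)
      stop("sample ", rows$sample_id[1], " maps to multiple histologies")
    burns <- lapply(idx, function(i)
      read_spectrum(paths[i], mode = df$mode[i],
                    burn_id = paste0(df$sample_id[i], "_b",
                                     which(idx == i))))
    sample_record(rows$sample_id[1], rows$patient_id[1], burns,
                  rows$histology[1])
  })
  # preserve first-appearance order
  first <- vapply(split(seq_len(nrow(df)), df$sample_id), min, numeric(1))
  reims_dataset(unname(samples[order(first)]), provenance = manifest)
}

#' Write a dataset to disk as manifest + TSV spectra
#'
#' @param dataset A [reims_dataset()].
#' @param dir Output directory (created if needed); spectra go to
#'   `dir/spectra/`.
#' @return Path to the written manifest CSV, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "reims_dataset"))
  spectra_dir <- file.path(dir, "spectra")
  dir.create(spectra_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in dataset$samples) {
    for (k in seq_along(s$burns)) {
      fname <- sprintf("%s_b%d.tsv", s$sample_id, k)
      write_spectrum(s$burns[[k]], file.path(spectra_dir, fname), "tsv")
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s$sample_id, patient_id = s$patient_id,
        histology = s$histology, mode = s$burns[[k]]$mode,
        spectrum_path = file.path("spectra", fname),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE,
                   quote = FALSE)
  invisible(manifest)
}
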