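# Theoretical monoisotopic m/z for the negative-mode lipid ions observed in
# REIMS spectra of breast tissue: diacyl/ether/plasmalogen glycerophospholipids
# (PA, PE, PC, PS, PG) and triglycerides (TG), with the adducts seen in
# electrosurgical aerosol ([M-H]-, [M+Cl]-, [M-CH3-H]-, [M-NH3-H]-,
# [M-H2O-H]-).

# Monoisotopic masses of the most abundant isotopes (CODATA/AME), Da.
.ELEMENT_MASS <- c(
  C  = 12,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  Cl = 34.96885268
)
.ELECTRON_MASS <- 0.00054857991
.PROTON_MASS   <- 1.007276467
# 13C - 12C spacing: the isotope satellite offset used throughout.
.ISOTOPE_DELTA <- 1.00335

.LIPID_CLASSES <- c("PA", "PE", "PC", "PS", "PG", "TG")
.LINKAGES <- c("diacyl", "O-", "P-")
.ION_TYPES <- c("[M-H]-", "[M+Cl]-", "[M-CH3-H]-", "[M-NH3-H]-", "[M-H2O-H]-")

#' Define a lipid species by class and summed acyl composition
#'
#' Species are keyed by lipid class, the summed number of acyl-chain carbons
#' and the summed number of double bonds (the "C:N" shorthand); sn-position
#' does not affect mass and is deliberately not represented. Phospholipids
#' may carry an ether (`"O-"`) or plasmalogen / vinyl-ether (`"P-"`) linkage
#' on one chain.
#'
#' @param lipid_class One of `"PA"`, `"PE"`, `"PC"`, `"PS"`, `"PG"`, `"TG"`.
#' @param carbons Total acyl-chain carbons (sum over chains), a positive
#'   integer.
#' @param double_bonds Total acyl double bonds, a non-negative integer. For
#'   plasmalogens this counts the acyl double bonds only; the vinyl-ether
#'   double bond is implied by the linkage.
#' @param linkage `"diacyl"` (default), `"O-"` or `"P-"`. Triglycerides are
#'   diacyl (triacyl) only.
#' @return An object of class `lipid_species`.
#' @examples
#' lipid_species("PA", 36, 2)
#' lipid_species("PG", 34, 1, linkage = "P-")
#' @export
lipid_species <- function(lipid_class, carbons, double_bonds,
                          linkage = "diacyl") {
  lipid_class <- match.arg(lipid_class, .LIPID_CLASSES)
  linkage <- match.arg(linkage, .LINKAGES)
  stopifnot(length(carbons) == 1L, length(double_bonds) == 1L)
  if (carbons <= 0 || carbons != round(carbons))
    stop("`carbons` must be a positive integer")
  if (double_bonds < 0 || double_bonds != round(double_bonds))
    stop("`double_bonds` must be a non-negative integer")
  if (lipid_class == "TG" && linkage != "diacyl")
    stop("TG species support only the diacyl (triacyl) linkage")
  structure(
    list(lipid_class = lipid_class, carbons = as.integer(carbons),
         double_bonds = as.integer(double_bonds), linkage = linkage),
    class = "lipid_species"
  )
}

#' @export
format.lipid_species <- function(x, ...) {
  link <- switch(x$linkage, diacyl = "", `O-` = "O-", `P-` = "P-")
  sprintf("%s(%s%d:%d)", x$lipid_class, link, x$carbons, x$double_bonds)
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Elemental formula of a lipid species
#'
#' Composition rules, anchored on the diacyl phosphatidic acid backbone
#' `PA(C:N) = C(C+3) H(2C-2N+5) O8 P`:
#' head-group deltas PE `+C2H5N`, PC `+C5H11N`, PS `+C3H5NO2`, PG `+C3H6O2`;
#' triglyceride `TG(C:N) = C(C+3) H(2C-2N+2) O6`. An ether (`O-`) linkage
#' replaces one ester bond (`+2H, -1O` vs diacyl); a plasmalogen (`P-`)
#' linkage is an ether with one additional double-bond equivalent (`-1O` vs
#' diacyl, hydrogens unchanged).
#'
#' @param species A [lipid_species()].
#' @return Named integer vector of element counts (class
#'   `elemental_formula`).
#' @examples
#' formula_of(lipid_species("TG", 48, 0)) # tripalmitin, C51H98O6
#' @export
formula_of <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  C <- species$carbons
  N <- species$double_bonds
  f <- c(C = 0L, H = 0L, N = 0L, O = 0L, P = 0L, Cl = 0L)
  if (species$lipid_class == "TG") {
    f[c("C", "H", "O")] <- c(C + 3L, 2L * C - 2L * N + 2L, 6L)
    return(structure(f, class = "elemental_formula"))
  }
  # diacyl PA backbone
  f[c("C", "H", "O", "P")] <- c(C + 3L, 2L * C - 2L * N + 5L, 8L, 1L)
  head_delta <- switch(species$lipid_class,
    PA = c(C = 0L, H = 0L, N = 0L, O = 0L),
    PE = c(C = 2L, H = 5L, N = 1L, O = 0L),
    PC = c(C = 5L, H = 11L, N = 1L, O = 0L),
    PS = c(C = 3L, H = 5L, N = 1L, O = 2L),
    PG = c(C = 3L, H = 6L, N = 0L, O = 2L)
  )
  f[names(head_delta)] <- f[names(head_delta)] + head_delta
  if (species$linkage == "O-") {
    f["H"] <- f["H"] + 2L
    f["O"] <- f["O"] - 1L
  } else if (species$linkage == "P-") {
    f["O"] <- f["O"] - 1L
  }
  if (any(f < 0L))
    stop("unsupported composition: ", format(species),
         " implies negative element counts")
  structure(f, class = "elemental_formula")
}

#' Monoisotopic mass of an elemental formula
#'
#' Sum of most-abundant-isotope masses; additive over formulas.
#'
#' @param formula Named numeric vector of element counts; names must be
#'   drawn from C, H, N, O, P, Cl. An empty formula has mass 0.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(c(H = 2, O = 1)) # water, 18.010565
#' @export
monoisotopic_mass <- function(formula) {
  if (length(formula) == 0L) return(0)
  if (is.null(names(formula)) || any(!nzchar(names(formula))))
    stop("formula must be a named vector of element counts")
  unknown <- setdiff(names(formula), names(.ELEMENT_MASS))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  if (any(formula < 0)) stop("negative element counts")
  sum(.ELEMENT_MASS[names(formula)] * as.numeric(formula))
}

#' Theoretical m/z of a singly charged negative-mode lipid ion
#'
#' Supported ion types and their mass deltas relative to the neutral
#' monoisotopic mass M (all ions carry charge -1, so m/z equals the ion
#' mass):
#' * `[M-H]-`: loss of a proton, `M - 1.007276`;
#' * `[M+Cl]-`: chloride attachment, `M + 34.968853 (+ electron)`;
#' * `[M-CH3-H]-`: demethylation of the choline head group (loss of CH3+),
#'   `M - 15.023475 (+ electron)`;
#' * `[M-NH3-H]-`: combined ammonia and proton loss,
#'   `M - 17.026549 - 1.007276`;
#' * `[M-H2O-H]-`: combined water and proton loss,
#'   `M - 18.010565 - 1.007276`.
#'
#' The electron mass (0.000549 Da) is included in anion masses by default;
#' both conventions agree with 2-decimal literature values.
#'
#' @param species A [lipid_species()].
#' @param ion Ion type string, one of
#'   `c("[M-H]-", "[M+Cl]-", "[M-CH3-H]-", "[M-NH3-H]-", "[M-H2O-H]-")`.
#' @param include_electron Include the electron mass in the anion. Default
#'   `TRUE`.
#' @return m/z in Da.
#' @examples
#' ion_mz(lipid_species("PA", 36, 2), "[M-H]-")   # 699.497, the lock mass
#' ion_mz(lipid_species("TG", 52, 2), "[M+Cl]-")  # 893.74
#' @export
ion_mz <- function(species, ion = "[M-H]-", include_electron = TRUE) {
  ion <- match.arg(ion, .ION_TYPES)
  M <- monoisotopic_mass(formula_of(species))
  e <- if (include_electron) .ELECTRON_MASS else 0
  ch3 <- monoisotopic_mass(c(C = 1, H = 3))
  nh3 <- monoisotopic_mass(c(N = 1, H = 3))
  h2o <- monoisotopic_mass(c(H = 2, O = 1))
  switch(ion,
    "[M-H]-"     = M - .PROTON_MASS,
    "[M+Cl]-"    = M + .ELEMENT_MASS[["Cl"]] + e,
    "[M-CH3-H]-" = M - ch3 + e,
    "[M-NH3-H]-" = M - nh3 - .PROTON_MASS,
    "[M-H2O-H]-" = M - h2o - .PROTON_MASS
  )
}

#' Annotate an observed peak with candidate lipid ions
#'
#' Enumerates a grid of lipid species and ion types and returns every
#' candidate whose theoretical m/z falls within `tol` of the observed peak,
#' sorted by absolute mass error.
#'
#' @param mz Observed peak m/z (Da).
#' @param tol Mass tolerance (Da), > 0.
#' @param classes Lipid classes to search.
#' @param carbons Integer vector of total acyl carbons to search.
#' @param double_bonds Integer vector of total double bonds to search.
#' @param linkages Linkages to search (phospholipids only; TG is always
#'   diacyl).
#' @param ions Ion types to search.
#' @param include_electron Passed to [ion_mz()].
#' @return A data.frame with columns `species`, `lipid_class`, `carbons`,
#'   `double_bonds`, `linkage`, `ion`, `theoretical_mz`, `delta_mz`, sorted
#'   by `abs(delta_mz)`; zero rows when nothing matches.
#' @examples
#' annotate_peak(699.50, tol = 0.01, classes = c("PA", "PE"),
#'               carbons = 30:40, double_bonds = 0:4,
#'               ions = c("[M-H]-", "[M-NH3-H]-"))
#' @export
annotate_peak <- function(mz, tol = 0.02,
                          classes = c("PA", "PE", "PC", "PS", "PG"),
                          carbons = 32:46, double_bonds = 0:7,
                          linkages = .LINKAGES, ions = .ION_TYPES,
                          include_electron = TRUE) {
  stopifnot(length(mz) == 1L, tol > 0)
  classes <- match.arg(classes, .LIPID_CLASSES, several.ok = TRUE)
  grid <- expand.grid(
    lipid_class = classes, carbons = carbons, double_bonds = double_bonds,
    linkage = linkages, ion = ions,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  grid <- grid[grid$lipid_class != "TG" | grid$linkage == "diacyl", ,
               drop = FALSE]
  if (nrow(grid) == 0L) return(.empty_annotation())
  theo <- vapply(seq_len(nrow(grid)), function(i) {
    sp <- lipid_species(grid$lipid_class[i], grid$carbons[i],
                        grid$double_bonds[i], grid$linkage[i])
    ion_mz(sp, grid$ion[i], include_electron = include_electron)
  }, numeric(1))
  delta <- theo - mz
  keep <- abs(delta) <= tol
  if (!any(keep)) return(.empty_annotation())
  out <- grid[keep, , drop = FALSE]
  out$theoretical_mz <- theo[keep]
  out$delta_mz <- delta[keep]
  out$species <- vapply(seq_len(nrow(out)), function(i) {
    format(lipid_species(out$lipid_class[i], out$carbons[i],
                         out$double_bonds[i], out$linkage[i]))
  }, character(1))
  out <- out[order(abs(out$delta_mz)), c("species", "lipid_class", "carbons",
                                         "double_bonds", "linkage", "ion",
                                         "theoretical_mz", "delta_mz")]
  rownames(out) <- NULL
  out
}

.empty_annotation <- function() {
  data.frame(species = character(), lipid_class = character(),
             carbons = integer(), double_bonds = integer(),
             linkage = character(), ion = character(),
             theoretical_mz = numeric(), delta_mz = numeric(),
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Published reference peaks (inputs): the significant negative-mode peaks of
# breast tissue REIMS spectra, 18 phospholipids elevated in tumour
# (600-850 m/z) and 6 triglyceride chloride adducts elevated in normal
# tissue (850-1000 m/z), with one representative species assignment per
# peak, summed-composition notation.

#' Reference marker peaks for breast tissue REIMS spectra
#'
#' The 24 published differential peaks: 18 phospholipid-range peaks elevated
#' in tumour and 6 triglyceride chloride adducts elevated in normal tissue.
#' Each row carries the printed m/z, one representative species assignment
#' (summed C:N composition) and its ion type. The representative assignments
#' reproduce the printed m/z within 0.02 Da with one known exception
#' (printed 717.51, best theoretical candidate 0.03-0.05 Da away), which is
#' reported as printed.
#'
#' @param range Restrict to `"phospholipid"` (600-850), `"triglyceride"`
#'   (850-1000) or `"all"` (default).
#' @return data.frame with columns `published_mz`, `lipid_class`, `carbons`,
#'   `double_bonds`, `linkage`, `ion`, `range`, `direction`.
#' @export
reference_marker_peaks <- function(range = c("all", "phospholipid",
                                             "triglyceride")) {
  range <- match.arg(range)
  pl <- data.frame(
    published_mz = c(671.47, 673.48, 687.50, 699.50, 713.51, 714.51, 716.52,
                     717.51, 735.47, 742.54, 744.55, 747.51, 766.54, 768.55,
                     770.57, 772.58, 792.55, 794.57),
    lipid_class = c("PA", "PA", "PA", "PA", "PG", "PE", "PE", "PC", "PA",
                    "PE", "PE", "PA", "PE", "PE", "PE", "PE", "PC", "PC"),
    carbons = c(34L, 34L, 36L, 36L, 34L, 34L, 34L, 32L, 36L, 36L, 36L, 40L,
                38L, 38L, 38L, 38L, 34L, 38L),
    double_bonds = c(2L, 1L, 0L, 2L, 1L, 2L, 1L, 0L, 2L, 2L, 1L, 6L, 4L, 3L,
                     2L, 1L, 2L, 4L),
    linkage = c("diacyl", "diacyl", "P-", "diacyl", "P-", "diacyl", "diacyl",
                "diacyl", "diacyl", "diacyl", "diacyl", "diacyl", "diacyl",
                "diacyl", "diacyl", "diacyl", "diacyl", "diacyl"),
    ion = c("[M-H]-", "[M-H]-", "[M-H]-", "[M-H]-", "[M-H2O-H]-", "[M-H]-",
            "[M-H]-", "[M-CH3-H]-", "[M+Cl]-", "[M-H]-", "[M-H]-", "[M-H]-",
            "[M-H]-", "[M-H]-", "[M-H]-", "[M-H]-", "[M+Cl]-", "[M-CH3-H]-"),
    range = "phospholipid", direction = "up_in_tumour",
    stringsAsFactors = FALSE
  )
  tg <- data.frame(
    published_mz = c(865.70, 891.72, 893.73, 917.73, 919.75, 921.76),
    lipid_class = "TG",
    carbons = c(50L, 52L, 52L, 54L, 54L, 54L),
    double_bonds = c(2L, 3L, 2L, 4L, 3L, 2L),
    linkage = "diacyl", ion = "[M+Cl]-",
    range = "triglyceride", direction = "down_in_tumour",
    stringsAsFactors = FALSE
  )
  out <- rbind(pl, tg)
  switch(range,
    all = out,
    phospholipid = out[out$range == "phospholipid", , drop = FALSE],
    triglyceride = out[out$range == "triglyceride", , drop = FALSE]
  )
}

#' Default lipid panel for the synthetic generator
#'
#' One representative species per reference marker peak (18 phospholipids +
#' 6 triglycerides), as a list of `lipid_species` with an `ion` attribute
#' per entry.
#'
#' @return A data.frame like [reference_marker_peaks()] but keyed by the
#'   representative species (one row per synthetic panel peak).
#' @export
default_lipid_panel <- function() {
  reference_marker_peaks("all")
}
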