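# DART-MS juvenoid quantification: signature-ion m/z from molecular
# formulae, peak extraction from spectra, replicate averaging, haemolymph
# weight normalisation and calibration-curve inversion.

# Monoisotopic atomic masses (u), CODATA/AME2020 values.
MONOISOTOPIC_MASS <- c(
  H = 1.00782503207, C = 12.0, N = 14.0030740048, O = 15.9949146196,
  S = 31.97207100, P = 30.97376163, Na = 22.9897692809, K = 38.96370668,
  Cl = 34.96885268, F = 18.99840322)
PROTON_MASS <- 1.00727646688  # u
WATER_MASS <- 2 * MONOISOTOPIC_MASS[["H"]] + MONOISOTOPIC_MASS[["O"]]

# Formulae of the juvenoids profiled in haemolymph.
JUVENOID_FORMULAE <- list(
  JHIII = "C16H26O3",            # juvenile hormone III
  methylfarnesoate = "C16H26O2",
  JHB3 = "C16H26O4")             # JHIII bisepoxide

#' Molecular formula
#'
#' Parses a Hill-style formula string (e.g. `"C16H26O3"`) into element
#' counts, or validates a named count vector.
#'
#' @param x formula string or named integer vector of element counts.
#' @return An object of class `molecular_formula` (named integer vector).
#' @export
molecular_formula <- function(x) {
  if (inherits(x, "molecular_formula")) return(x)
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    parts <- regmatches(x, gregexpr("[A-Z][a-z]?[0-9]*", x))[[1]]
    parts <- parts[nzchar(parts)]
    if (!length(parts) || paste(parts, collapse = "") != x)
      stopf("cannot parse formula '%s'", x)
    el <- sub("[0-9]*$", "", parts)
    ct <- as.integer(ifelse(grepl("[0-9]+$", parts),
                            sub("^[A-Za-z]+", "", parts), "1"))
    counts <- tapply(ct, el, sum)
    x <- setNames(as.integer(counts), names(counts))
  }
  if (is.null(names(x)) || any(!names(x) %in% names(MONOISOTOPIC_MASS)))
    stopf("unknown element in formula (supported: %s)",
          paste(names(MONOISOTOPIC_MASS), collapse = ", "))
  counts <- setNames(as.integer(x), names(x))
  if (any(counts < 0L)) stopf("element counts must be >= 0")
  counts <- counts[counts > 0L]
  if (!length(counts)) stopf("formula must contain at least one atom")
  structure(counts, class = "molecular_formula")
}

#' Monoisotopic mass of a neutral molecule
#'
#' @param formula a [molecular_formula] or formula string.
#' @return Monoisotopic mass in u.
#' @export
monoisotopic_mass <- function(formula) {
  f <- molecular_formula(formula)
  sum(MONOISOTOPIC_MASS[names(f)] * as.numeric(f))
}

#' Signature-ion m/z for DART ionisation
#'
#' DART produces protonated molecules; labile hydroxy/epoxide compounds such
#' as juvenile hormone III additionally show the water-loss fragment. The
#' m/z is the monoisotopic neutral mass plus one proton, minus one H2O in
#' the loss mode.
#'
#' @param formula a [molecular_formula], formula string, or one of the
#'   built-in juvenoid names `"JHIII"`, `"methylfarnesoate"`, `"JHB3"`.
#' @param mode `"protonated"` (\[M+H\]+) or `"protonated_minus_water"`
#'   (\[M-H2O+H\]+).
#' @return m/z in Th, full precision (compare at 2 decimals).
#' @export
signature_mz <- function(formula, mode = c("protonated", "protonated_minus_water")) {
  mode <- match.arg(mode)
  if (is.character(formula) && length(formula) == 1L &&
      formula %in% names(JUVENOID_FORMULAE))
    formula <- JUVENOID_FORMULAE[[formula]]
  f <- molecular_formula(formula)
  mz <- monoisotopic_mass(f) + PROTON_MASS
  if (mode == "protonated_minus_water") {
    if (is.na(f["O"]) || f["O"] < 1L || is.na(f["H"]) || f["H"] < 2L)
      stopf("water loss needs at least one O and two H in the formula")
    mz <- mz - WATER_MASS
  }
  unname(mz)
}

#' Mass spectrum
#'
#' @param mz strictly ascending m/z values (Th).
#' @param intensity matched non-negative intensities.
#' @return An object of class `mass_spectrum` (data.frame with `mz`,
#'   `intensity`).
#' @export
mass_spectrum <- function(mz, intensity) {
  if (length(mz) != length(intensity)) stopf("mz and intensity must match in length")
  if (length(mz) && any(diff(mz) <= 0)) stopf("mz must be strictly ascending")
  if (any(intensity < 0)) stopf("intensities must be >= 0")
  structure(data.frame(mz = as.numeric(mz), intensity = as.numeric(intensity)),
            class = c("mass_spectrum", "data.frame"))
}

#' Read a two-column (mz, intensity) CSV spectrum
#'
#' @param path CSV path with columns `mz` and `intensity` (or two unnamed
#'   columns in that order).
#' @return A [mass_spectrum].
#' @export
read_spectrum_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("mz", "intensity") %in% names(d))) names(d)[1:2] <- c("mz", "intensity")
  mass_spectrum(d$mz, d$intensity)
}

#' @export
plot.mass_spectrum <- function(x, ...) {
  graphics::plot(x$mz, x$intensity, type = "h", xlab = "m/z (Th)",
                 ylab = "intensity", ...)
  invisible(x)
}

#' Extract a signature-ion intensity
#'
#' Peak abundance is the maximum intensity among spectrum points within
#' `tol` of the target m/z (the maximum is robust to window width, unlike an
#' integral). An empty window yields 0 with attribute `no_peak = TRUE`.
#'
#' @param spec a [mass_spectrum].
#' @param target_mz target m/z (Th).
#' @param tol half-window in Th (default 0.05, matching ~0.04 Th FWHM at
#'   resolving power 6000 near m/z 250).
#' @return Intensity (numeric scalar, possibly with `no_peak` attribute).
#' @export
extract_ion_intensity <- function(spec, target_mz, tol = 0.05) {
  if (tol <= 0) stopf("tol must be > 0")
  sel <- abs(spec$mz - target_mz) <= tol
  if (!any(sel)) return(structure(0, no_peak = TRUE))
  max(spec$intensity[sel])
}

#' Fit a calibration curve
#'
#' Ordinary least squares of intensity on standard amount, intercept free.
#'
#' @param standards data.frame (or matrix) with columns `amount_ng` and
#'   `intensity`, at least two distinct amounts.
#' @return An object of class `calibration_curve` with `slope` (intensity
#'   per ng), `intercept`, `r_squared` and the standards.
#' @export
fit_calibration <- function(standards) {
  standards <- as.data.frame(standards)
  if (!all(c("amount_ng", "intensity") %in% names(standards)))
    names(standards)[1:2] <- c("amount_ng", "intensity")
  if (length(unique(standards$amount_ng)) < 2L)
    stopf("need >= 2 distinct standard amounts")
  fit <- lm(intensity ~ amount_ng, data = standards)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((standards$intensity - mean(standards$intensity))^2)
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 standards = standards),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration: intensity = %.6g * ng + %.6g  (r^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, nrow(x$standards)))
  invisible(x)
}

#' @export
plot.calibration_curve <- function(x, ...) {
  graphics::plot(x$standards$amount_ng, x$standards$intensity,
                 xlab = "amount (ng)", ylab = "intensity", ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}

#' Haemolymph sample (technical replicate spectra + weight)
#'
#' @param replicate_spectra list of [mass_spectrum]s, the 4-5 technical
#'   measurements of one extract.
#' @param haemolymph_weight_mg total haemolymph weight (mg), `> 0`.
#' @return An object of class `haemolymph_sample`.
#' @export
haemolymph_sample <- function(replicate_spectra, haemolymph_weight_mg) {
  if (inherits(replicate_spectra, "mass_spectrum"))
    replicate_spectra <- list(replicate_spectra)
  if (!length(replicate_spectra)) stopf("need >= 1 replicate spectrum")
  if (!is.numeric(haemolymph_weight_mg) || haemolymph_weight_mg <= 0)
    stopf("haemolymph_weight_mg must be > 0")
  structure(list(replicate_spectra = replicate_spectra,
                 haemolymph_weight_mg = haemolymph_weight_mg),
            class = "haemolymph_sample")
}

#' Quantify a haemolymph sample against a calibration curve
#'
#' Replicate signature-ion intensities are averaged, converted to an
#' absolute amount by inverting the calibration line
#' (`(mean - intercept) / slope`, clipped at 0 and flagged `below_lod` when
#' the mean falls below the intercept), then normalised to the haemolymph
#' weight.
#'
#' @param sample a [haemolymph_sample].
#' @param curve a fitted [calibration_curve] with positive slope.
#' @param target_mz signature-ion m/z (Th).
#' @param tol extraction half-window (Th).
#' @return Amount per weight (ng/mg); attributes `mean_intensity` and
#'   `below_lod`.
#' @export
quantify_sample <- function(sample, curve, target_mz, tol = 0.05) {
  if (!inherits(curve, "calibration_curve")) stopf("curve must be a calibration_curve")
  if (!is.finite(curve$slope) || curve$slope <= 0)
    stopf("invalid calibration: slope must be > 0")
  ints <- vapply(sample$replicate_spectra, extract_ion_intensity, 0,
                 target_mz = target_mz, tol = tol)
  m <- mean(ints)
  amount <- (m - curve$intercept) / curve$slope
  below <- amount < 0
  structure(max(0, amount) / sample$haemolymph_weight_mg,
            mean_intensity = m, below_lod = below)
}
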