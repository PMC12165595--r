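# Counts -> reflectance -> peak-normalized -> (r543, r578) features.
# All wavelength lookups interpolate linearly, so results do not depend on the
# spectrometer's pixel grid (which never falls exactly on 543/561/578 nm on
# real hardware).

interp_at <- function(wavelength, values, lambda) {
  n <- length(wavelength)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda)) {
    abort_parameter("lambda must be a single finite wavelength in nm")
  }
  if (lambda < wavelength[1L] || lambda > wavelength[n]) {
    abort_range(sprintf("wavelength %g nm is outside the grid [%g, %g] nm",
                        lambda, wavelength[1L], wavelength[n]))
  }
  if (is.vector(values)) values <- matrix(values, ncol = 1L)
  i <- findInterval(lambda, wavelength, rightmost.closed = TRUE)
  out <- if (wavelength[i] == lambda) {
    values[i, ]
  } else {
    w <- (lambda - wavelength[i]) / (wavelength[i + 1L] - wavelength[i])
    (1 - w) * values[i, ] + w * values[i + 1L, ]
  }
  if (any(!is.finite(out))) {
    abort_range(sprintf(
      "value at %g nm is not finite (flagged degenerate reference region)",
      lambda))
  }
  out
}

#' Interpolated spectrum value at a wavelength
#'
#' Linear interpolation between the two bracketing grid points; an exact grid
#' hit returns the stored value unchanged. Raises a range error outside the
#' grid, and when the bracketing values are non-finite (the flag used for
#' degenerate reference points outside the analysis band).
#'
#' @param spectrum a [spectra_set], [reference_set], or any list with numeric
#'   `wavelength` and `values` elements.
#' @param lambda single wavelength, nm.
#' @return Numeric vector with one value per spectrum in the container (a
#'   scalar for single-spectrum input).
#' @export
value_at_wavelength <- function(spectrum, lambda) {
  if (inherits(spectrum, "reference_set")) {
    return(c(dark = interp_at(spectrum$wavelength, spectrum$dark, lambda),
             white = interp_at(spectrum$wavelength, spectrum$white, lambda)))
  }
  if (is.null(spectrum$wavelength) || is.null(spectrum$values)) {
    abort_parameter("spectrum must carry 'wavelength' and 'values'")
  }
  interp_at(spectrum$wavelength, spectrum$values, lambda)
}

#' Convert raw counts to reflectance with dark/white references
#'
#' Pointwise `(raw - dark) / (white - dark)`. The references must strictly
#' dominate (`white > dark`) at every grid point inside the 535-585 nm
#' analysis band; a violation there is a degenerate-reference error. Outside
#' the band, non-positive `white - dark` points are set to `NaN` and flagged:
#' any later interpolated lookup touching them raises.
#'
#' @param raw a [spectra_set] of raw counts (or a [spectra_dataset], whose own
#'   references are then used).
#' @param refs a [reference_set] on the same grid.
#' @return A [spectra_set] with stage "reflectance".
#' @export
reference_correct <- function(raw, refs = NULL) {
  if (inherits(raw, "spectra_dataset")) {
    if (is.null(refs)) refs <- raw$references
    raw <- raw$spectra
  }
  if (!inherits(raw, "spectra_set") || !inherits(refs, "reference_set")) {
    abort_validation("need a spectra_set of counts and a reference_set")
  }
  if (!isTRUE(all.equal(raw$wavelength, refs$wavelength, tolerance = 0))) {
    abort_validation("raw spectra and references must share one grid")
  }
  denom <- refs$white - refs$dark
  band <- band_index(raw$wavelength)
  if (any(denom[band] <= 0)) {
    abort_reference(
      "white - dark <= 0 inside the 535-585 nm analysis band: degenerate references")
  }
  bad <- denom <= 0
  denom[bad] <- NA_real_
  refl <- (raw$values - refs$dark) / denom
  refl[bad, ] <- NaN
  spectra_set(raw$wavelength, refl, raw$meta, stage = "reflectance")
}

#' Normalize reflectance at the 561 nm oxyhemoglobin peak
#'
#' Divides every spectrum by its interpolated reflectance at 561 nm so the
#' central peak equals 1, the convention under which between-tissue variance
#' concentrates in the 543 and 578 nm troughs. Idempotent; raises a
#' normalization error if any spectrum is non-positive at 561 nm.
#'
#' @param refl a [spectra_set] with stage "reflectance" or "normalized".
#' @return A [spectra_set] with stage "normalized".
#' @export
peak_normalize <- function(refl) {
  if (!inherits(refl, "spectra_set") || refl$stage == "counts") {
    abort_validation("peak_normalize expects reference-corrected reflectance")
  }
  peak <- interp_at(refl$wavelength, refl$values, PEAK_NM)
  if (any(peak <= 0)) {
    abort_normalize("reflectance at 561 nm must be positive to normalize")
  }
  norm <- sweep(refl$values, 2L, peak, "/")
  spectra_set(refl$wavelength, norm, refl$meta, stage = "normalized")
}

#' Extract the two-trough feature vector
#'
#' Reads the normalized reflectance at the 543 and 578 nm oxyhemoglobin
#' absorption troughs (linear interpolation), the 2-D space in which the
#' classifiers operate. Deeper troughs (more pronounced oxyhemoglobin
#' signature, characteristic of trachea) give smaller feature values.
#'
#' @param norm a [spectra_set] with stage "normalized".
#' @return A data.frame with the acquisition metadata plus columns `r543` and
#'   `r578`.
#' @export
extract_features <- function(norm) {
  if (!inherits(norm, "spectra_set") || norm$stage != "normalized") {
    abort_validation("extract_features expects a peak-normalized spectra_set")
  }
  out <- norm$meta
  out$r543 <- as.numeric(interp_at(norm$wavelength, norm$values, TROUGH_NM[1L]))
  out$r578 <- as.numeric(interp_at(norm$wavelength, norm$values, TROUGH_NM[2L]))
  out
}

#' Full preprocessing: counts to features
#'
#' Convenience wrapper running [reference_correct], [peak_normalize], and
#' [extract_features] on a dataset.
#'
#' @param ds a [spectra_dataset].
#' @return Feature data.frame as from [extract_features].
#' @export
compute_features <- function(ds) {
  extract_features(peak_normalize(reference_correct(ds)))
}
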