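# Validated containers shared by the simulator, I/O layer, and pipeline.

check_grid <- function(wavelength) {
  if (!is.numeric(wavelength) || length(wavelength) < 2L ||
      any(!is.finite(wavelength))) {
    abort_validation("wavelength grid must be a finite numeric vector (>= 2 points)")
  }
  if (any(diff(wavelength) <= 0)) {
    abort_validation("wavelength grid must be strictly increasing")
  }
  if (wavelength[1L] > ANALYSIS_BAND[1L] ||
      wavelength[length(wavelength)] < ANALYSIS_BAND[2L]) {
    abort_validation(sprintf(
      "wavelength grid must cover the analysis band [%g, %g] nm",
      ANALYSIS_BAND[1L], ANALYSIS_BAND[2L]))
  }
  invisible(wavelength)
}

check_meta <- function(meta, n_spectra) {
  required <- c("pair_id", "organ", "acq_index")
  if (!is.data.frame(meta) || !all(required %in% names(meta))) {
    abort_validation("meta must be a data.frame with pair_id, organ, acq_index")
  }
  if (nrow(meta) != n_spectra) {
    abort_validation("meta rows must match the number of spectra")
  }
  if (n_spectra == 0L) return(invisible(meta))
  if (!all(meta$organ %in% ORGANS)) {
    abort_validation(sprintf("organ must be one of: %s",
                             paste(ORGANS, collapse = ", ")))
  }
  ids <- meta[, required]
  if (anyDuplicated(ids)) {
    abort_validation("(pair_id, organ, acq_index) must be unique within a dataset")
  }
  if (any(meta$pair_id < 1L) || any(meta$acq_index < 1L) ||
      any(meta$pair_id != round(meta$pair_id)) ||
      any(meta$acq_index != round(meta$acq_index))) {
    abort_validation("pair_id and acq_index must be positive integers")
  }
  invisible(meta)
}

band_index <- function(wavelength) {
  which(wavelength >= ANALYSIS_BAND[1L] & wavelength <= ANALYSIS_BAND[2L])
}

#' Collection of spectra on a shared wavelength grid
#'
#' Holds one or more spectra as columns of a values matrix, with one metadata
#' row per spectrum. The same container carries raw detector counts,
#' reference-corrected reflectance, and peak-normalized reflectance; `stage`
#' records which, and validation depends on it: counts must be finite and
#' non-negative everywhere, reflectance stages must be finite inside the
#' 535-585 nm analysis band (non-finite values outside the band flag
#' degenerate reference points and any lookup there raises).
#'
#' @param wavelength strictly increasing numeric grid (nm) covering 535-585 nm.
#' @param values numeric matrix, `length(wavelength)` rows, one column per
#'   spectrum (a plain vector is accepted for a single spectrum).
#' @param meta data.frame with columns `pair_id` (integer), `organ`
#'   ("trachea"/"esophagus"), `acq_index` (integer); one row per column of
#'   `values`, unique triples.
#' @param stage one of "counts", "reflectance", "normalized".
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(wavelength, values, meta,
                        stage = c("counts", "reflectance", "normalized")) {
  stage <- match.arg(stage)
  check_grid(wavelength)
  if (is.vector(values) && is.numeric(values)) {
    values <- matrix(values, ncol = 1L)
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_validation("values must be a numeric matrix (grid points x spectra)")
  }
  if (nrow(values) != length(wavelength)) {
    abort_validation("values must have one row per wavelength grid point")
  }
  check_meta(meta, ncol(values))
  if (stage == "counts") {
    if (ncol(values) > 0L && (any(!is.finite(values)) || any(values < 0))) {
      abort_validation("raw counts must be finite and non-negative")
    }
  } else {
    band <- band_index(wavelength)
    if (ncol(values) > 0L && any(!is.finite(values[band, , drop = FALSE]))) {
      abort_validation(
        "reflectance must be finite inside the 535-585 nm analysis band")
    }
  }
  structure(list(wavelength = wavelength, values = values,
                 meta = as.data.frame(meta), stage = stage),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra (%s), grid %g-%g nm (%d points)\n",
              ncol(x$values), x$stage, min(x$wavelength), max(x$wavelength),
              length(x$wavelength)))
  invisible(x)
}

#' Paired dark and white reference spectra
#'
#' The dark reference is acquired with the source blocked; the white reference
#' against a diffuse reflectance standard. Both live on the same grid as the
#' tissue spectra. White must exceed dark at every grid point inside the
#' 535-585 nm analysis band.
#'
#' @param wavelength strictly increasing numeric grid (nm).
#' @param dark,white numeric intensity vectors on the grid (detector counts).
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(wavelength, dark, white) {
  check_grid(wavelength)
  if (length(dark) != length(wavelength) || length(white) != length(wavelength)) {
    abort_validation("dark and white must match the wavelength grid length")
  }
  if (any(!is.finite(dark)) || any(!is.finite(white))) {
    abort_validation("reference spectra must be finite")
  }
  band <- band_index(wavelength)
  if (any(white[band] <= dark[band])) {
    abort_validation(
      "white reference must exceed dark at every grid point in 535-585 nm")
  }
  structure(list(wavelength = wavelength, dark = as.numeric(dark),
                 white = as.numeric(white)),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> grid %g-%g nm (%d points)\n",
              min(x$wavelength), max(x$wavelength), length(x$wavelength)))
  invisible(x)
}

#' Spectra dataset: acquisitions plus their references
#'
#' Bundles a [spectra_set] of raw counts with the [reference_set] acquired in
#' the same session and a provenance record (free text plus the simulation
#' seed when the data are synthetic). All spectra must share the references'
#' wavelength grid.
#'
#' @param spectra a [spectra_set] with stage "counts".
#' @param references a [reference_set] on the same grid.
#' @param provenance list; free-form description, seed, config echo.
#' @return An object of class `spectra_dataset`.
#' @export
spectra_dataset <- function(spectra, references, provenance = list()) {
  if (!inherits(spectra, "spectra_set") || spectra$stage != "counts") {
    abort_validation("spectra must be a spectra_set of raw counts")
  }
  if (!inherits(references, "reference_set")) {
    abort_validation("references must be a reference_set")
  }
  if (!isTRUE(all.equal(spectra$wavelength, references$wavelength,
                        tolerance = 0))) {
    abort_validation("all spectra must share the references' wavelength grid")
  }
  structure(list(spectra = spectra, references = references,
                 provenance = provenance),
            class = "spectra_dataset")
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat(sprintf("<spectra_dataset> %d spectra, grid %g-%g nm (%d points)\n",
              ncol(x$spectra$values), min(x$spectra$wavelength),
              max(x$spectra$wavelength), length(x$spectra$wavelength)))
  if (!is.null(x$provenance$text)) cat(" provenance:", x$provenance$text, "\n")
  invisible(x)
}
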