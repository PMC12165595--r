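# On-disk dialect: a dataset is a directory holding
#   spectra.csv      pair_id, organ, acq_index, wavelength_nm, counts  (long)
#   references.csv   wavelength_nm, dark, white
#   provenance.json  free text + seed record
# UTF-8, header row mandatory, '.' decimal point. Numeric columns are written
# at full double precision (>= 15 significant digits), so a round trip
# preserves values well beyond the documented 9-significant-digit contract.

SPECTRA_COLS <- c("pair_id", "organ", "acq_index", "wavelength_nm", "counts")
REFERENCE_COLS <- c("wavelength_nm", "dark", "white")

#' Write a spectra dataset to a directory
#'
#' Serializes the dataset in the package's long-format CSV dialect (see
#' [read_dataset]). An optional ground-truth table (as produced by
#' [simulate_cohort]) is written alongside as `ground_truth.csv`.
#'
#' @param ds a [spectra_dataset].
#' @param path directory to create/write into.
#' @param ground_truth optional data.frame of realized trough depths.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, ground_truth = NULL) {
  if (!inherits(ds, "spectra_dataset")) {
    abort_validation("ds must be a spectra_dataset")
  }
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok || !dir.exists(path)) abort_io(sprintf("cannot create directory '%s'", path))

  n_wl <- length(ds$spectra$wavelength)
  n_sp <- ncol(ds$spectra$values)
  meta <- ds$spectra$meta
  long <- if (n_sp == 0L) {
    data.table::data.table(pair_id = integer(0), organ = character(0),
                           acq_index = integer(0), wavelength_nm = numeric(0),
                           counts = numeric(0))
  } else {
    data.table::data.table(
      pair_id = rep(meta$pair_id, each = n_wl),
      organ = rep(as.character(meta$organ), each = n_wl),
      acq_index = rep(meta$acq_index, each = n_wl),
      wavelength_nm = rep(ds$spectra$wavelength, times = n_sp),
      counts = as.vector(ds$spectra$values)
    )
  }
  data.table::fwrite(long, file.path(path, "spectra.csv"))
  data.table::fwrite(
    data.table::data.table(wavelength_nm = ds$references$wavelength,
                           dark = ds$references$dark,
                           white = ds$references$white),
    file.path(path, "references.csv"))
  jsonlite::write_json(ds$provenance, file.path(path, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(ground_truth)) {
    data.table::fwrite(ground_truth, file.path(path, "ground_truth.csv"))
  }
  invisible(path)
}

#' Read a spectra dataset from a directory
#'
#' Reads the dialect written by [write_dataset] and validates every container
#' invariant: strictly increasing grid covering 535-585 nm, white > dark
#' inside the analysis band, finite non-negative counts, unique
#' (pair_id, organ, acq_index) triples, and a shared grid across spectra.
#' Malformed input raises a classed format or validation error; nothing is
#' silently coerced.
#'
#' @param path directory containing `spectra.csv` and `references.csv`.
#' @return A validated [spectra_dataset].
#' @export
read_dataset <- function(path) {
  sp_file <- file.path(path, "spectra.csv")
  ref_file <- file.path(path, "references.csv")
  if (!file.exists(sp_file) || !file.exists(ref_file)) {
    abort_format(sprintf("'%s' must contain spectra.csv and references.csv", path))
  }
  refs_dt <- data.table::fread(ref_file)
  if (!all(REFERENCE_COLS %in% names(refs_dt))) {
    abort_format(sprintf("references.csv must have columns: %s",
                         paste(REFERENCE_COLS, collapse = ", ")))
  }
  grid <- as.numeric(refs_dt$wavelength_nm)
  refs <- reference_set(grid, refs_dt$dark, refs_dt$white)

  sp_dt <- data.table::fread(sp_file)
  if (!all(SPECTRA_COLS %in% names(sp_dt))) {
    abort_format(sprintf("spectra.csv must have columns: %s",
                         paste(SPECTRA_COLS, collapse = ", ")))
  }

  prov_file <- file.path(path, "provenance.json")
  provenance <- if (file.exists(prov_file)) {
    jsonlite::read_json(prov_file, simplifyVector = TRUE)
  } else list()

  if (nrow(sp_dt) == 0L) {
    empty <- spectra_set(grid, matrix(numeric(0), nrow = length(grid), ncol = 0L),
                         data.frame(pair_id = integer(0), organ = character(0),
                                    acq_index = integer(0)))
    return(spectra_dataset(empty, refs, provenance))
  }

  key <- paste(sp_dt$pair_id, sp_dt$organ, sp_dt$acq_index, sep = "\r")
  groups <- split(seq_len(nrow(sp_dt)), factor(key, levels = unique(key)))
  n_wl <- length(grid)
  values <- matrix(NA_real_, nrow = n_wl, ncol = length(groups))
  meta <- data.frame(pair_id = integer(length(groups)),
                     organ = character(length(groups)),
                     acq_index = integer(length(groups)))
  for (j in seq_along(groups)) {
    rows <- groups[[j]]
    if (length(rows) != n_wl) {
      abort_format("each acquisition must have exactly one row per grid point")
    }
    wl <- as.numeric(sp_dt$wavelength_nm[rows])
    ord <- order(wl)
    if (!isTRUE(all.equal(wl[ord], grid, tolerance = 1e-9))) {
      abort_validation("all spectra must share the references' wavelength grid")
    }
    values[, j] <- as.numeric(sp_dt$counts[rows][ord])
    meta$pair_id[j] <- as.integer(sp_dt$pair_id[rows[1L]])
    meta$organ[j] <- as.character(sp_dt$organ[rows[1L]])
    meta$acq_index[j] <- as.integer(sp_dt$acq_index[rows[1L]])
  }
  spectra_dataset(spectra_set(grid, values, meta), refs, provenance)
}
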