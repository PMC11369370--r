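#' Labeled spectra set
#'
#' The central container of the package: a matrix of reflectance (or
#' SNV-normalized) spectra together with per-measurement metadata. One row per
#' measurement; all measurements share one wavelength grid.
#'
#' @param spectra Numeric matrix, one row per measurement, one column per
#'   wavelength.
#' @param wavelengths Numeric vector of wavelengths (nm), strictly increasing,
#'   length equal to `ncol(spectra)`.
#' @param meta Data frame with columns `patient_id`, `location_id`, `label`
#'   (one of `"tumor"`, `"healthy"`, `"unlabeled"`), one row per measurement.
#' @return An object of class `drs_set` with elements `spectra`,
#'   `wavelengths`, `meta`.
#' @export
drs_set <- function(spectra, wavelengths, meta) {
  spectra <- as.matrix(spectra)
  assert_grid(wavelengths)
  if (ncol(spectra) != length(wavelengths)) {
    stop("spectra columns must match wavelength grid length")
  }
  if (!all(is.finite(spectra))) stop("spectra must be finite")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  req <- c("patient_id", "location_id", "label")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("meta missing columns: ", paste(miss, collapse = ", "))
  if (nrow(meta) != nrow(spectra)) stop("meta rows must match spectra rows")
  meta$patient_id <- as.character(meta$patient_id)
  meta$location_id <- as.character(meta$location_id)
  meta$label <- as.character(meta$label)
  if (any(!nzchar(meta$patient_id))) stop("patient ids must be non-empty")
  bad <- which(!meta$label %in% DRS_LABELS)
  if (length(bad)) {
    stop("invalid label(s) at row(s) ", paste(bad, collapse = ", "),
         "; expected one of: ", paste(DRS_LABELS, collapse = ", "))
  }
  structure(list(spectra = spectra, wavelengths = wavelengths, meta = meta),
            class = "drs_set")
}

#' @export
print.drs_set <- function(x, ...) {
  n <- nrow(x$spectra)
  tab <- table(factor(x$meta$label, levels = DRS_LABELS))
  cat(sprintf(
    "<drs_set> %d measurements, %d patients, grid %g-%g nm (%d points)\n",
    n, length(unique(x$meta$patient_id)),
    min(x$wavelengths), max(x$wavelengths), length(x$wavelengths)))
  cat(sprintf("  tumor %d / healthy %d / unlabeled %d\n",
              tab[["tumor"]], tab[["healthy"]], tab[["unlabeled"]]))
  invisible(x)
}

#' Subset a spectra set by row index
#'
#' @param set A `drs_set`.
#' @param idx Integer or logical row index.
#' @return A `drs_set` with the selected measurements.
#' @export
subset_measurements <- function(set, idx) {
  stopifnot(inherits(set, "drs_set"))
  drs_set(set$spectra[idx, , drop = FALSE], set$wavelengths,
          set$meta[idx, , drop = FALSE])
}

#' Keep only labeled (tumor/healthy) measurements
#'
#' Measurements marked `unlabeled` correspond to locations whose tissue type
#' could not be established with certainty; they are excluded from all
#' training and evaluation.
#'
#' @param set A `drs_set`.
#' @return A `drs_set` containing only tumor/healthy rows.
#' @export
labeled_subset <- function(set) {
  subset_measurements(set, set$meta$label %in% c("tumor", "healthy"))
}
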