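#' Standard normal variate (SNV) normalization
#'
#' Per-spectrum z-scoring: each spectrum has its own mean subtracted and is
#' divided by its own sample standard deviation (n-1 divisor). SNV removes
#' multiplicative scaling and additive offsets unrelated to tissue type
#' (probe contact pressure, source drift), so downstream features compare
#' spectral shape only.
#'
#' @param x Numeric vector (one spectrum) or matrix (one spectrum per row).
#' @return Object of the same shape; every spectrum has mean 0 and sample SD 1.
#' @export
snv_normalize <- function(x) {
  if (is.matrix(x)) {
    t(apply(x, 1, snv_normalize))
  } else {
    if (length(x) < 2L) stop("SNV needs at least 2 points")
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("SNV undefined for a constant spectrum (zero variance)")
    }
    (x - mean(x)) / s
  }
}

#' SNV-normalize every spectrum in a set
#'
#' @param set A `drs_set`.
#' @return A `drs_set` whose spectra are SNV-normalized.
#' @export
snv_set <- function(set) {
  stopifnot(inherits(set, "drs_set"))
  drs_set(snv_normalize(set$spectra), set$wavelengths, set$meta)
}

#' Per-class mean and SD spectra
#'
#' Computes, for each tissue class present, the per-wavelength arithmetic mean
#' and sample SD over all its (labeled) measurements. Unlabeled measurements
#' are excluded. These class profiles drive landmark discovery and the
#' mean +/- SD spectra figure.
#'
#' @param set A `drs_set` (normally SNV-normalized).
#' @param classes Classes to profile; default tumor and healthy.
#' @return Named list of `class_profile` objects, each with `label`,
#'   `mean_spectrum`, `sd_spectrum`, `n`, `wavelengths`.
#' @export
class_profiles <- function(set, classes = c("tumor", "healthy")) {
  stopifnot(inherits(set, "drs_set"))
  out <- list()
  for (cl in classes) {
    idx <- set$meta$label == cl
    n <- sum(idx)
    if (n < 2L) {
      stop(sprintf("class '%s' has %d measurement(s); need >= 2 for a profile",
                   cl, n))
    }
    m <- set$spectra[idx, , drop = FALSE]
    out[[cl]] <- structure(list(
      label = cl,
      mean_spectrum = colMeans(m),
      sd_spectrum = apply(m, 2, stats::sd),
      n = n,
      wavelengths = set$wavelengths
    ), class = "class_profile")
  }
  out
}

#' Export class profiles in the spectra-table dialect
#'
#' Mean and SD rows are written with labels `mean_<class>` / `sd_<class>` in
#' the `location_id` column and label `unlabeled`, so the file remains a valid
#' spectra table.
#'
#' @param profiles Result of [class_profiles()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_class_profiles <- function(profiles, path) {
  wl <- profiles[[1]]$wavelengths
  rows <- list(); ids <- character(0)
  for (p in profiles) {
    rows[[length(rows) + 1L]] <- p$mean_spectrum
    ids <- c(ids, paste0("mean_", p$label))
    rows[[length(rows) + 1L]] <- p$sd_spectrum
    ids <- c(ids, paste0("sd_", p$label))
  }
  set <- drs_set(do.call(rbind, rows), wl,
                 data.frame(patient_id = "__profile__", location_id = ids,
                            label = "unlabeled"))
  write_spectra_table(set, path)
}
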