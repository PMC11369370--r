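#' Canonical wavelength grid
#'
#' The analysis operates on a fixed wavelength grid of 400--1600 nm at 1 nm
#' spacing, endpoint-inclusive, i.e. exactly 1201 wavelengths. All spectra are
#' resampled onto this grid before normalization and feature extraction.
#'
#' @return Numeric vector of wavelengths in nm, length 1201.
#' @export
canonical_grid <- function() {
  seq(400, 1600, by = 1)
}

#' Construct a uniform wavelength grid
#'
#' @param start_nm,stop_nm Endpoints in nm (inclusive).
#' @param step_nm Spacing in nm.
#' @return Numeric vector of wavelengths.
#' @export
wavelength_grid <- function(start_nm, stop_nm, step_nm = 1) {
  stopifnot(is.numeric(start_nm), is.numeric(stop_nm), is.numeric(step_nm))
  if (step_nm <= 0) stop("step_nm must be positive")
  if (stop_nm <= start_nm) stop("stop_nm must exceed start_nm")
  seq(start_nm, stop_nm, by = step_nm)
}

assert_grid <- function(wl) {
  if (!is.numeric(wl) || length(wl) < 2L) {
    stop("wavelength grid must be a numeric vector of length >= 2")
  }
  d <- diff(wl)
  if (any(d <= 0)) stop("wavelength grid must be strictly increasing")
  invisible(wl)
}

# Labels used throughout: tumor is the positive class clinically
DRS_LABELS <- c("tumor", "healthy", "unlabeled")
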