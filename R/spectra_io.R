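#' Raw single-channel spectrum
#'
#' A detector-count (or calibrated-reflectance) spectrum from one of the two
#' spectrometers: the visible channel (nominally 200--1160 nm) or the
#' near-infrared channel (900--1750 nm).
#'
#' @param channel `"VIS"` or `"NIR"`.
#' @param wavelengths Strictly increasing numeric vector (nm).
#' @param values Counts or reflectance per wavelength; finite.
#' @param meta Optional free-form metadata list.
#' @return Object of class `raw_spectrum`.
#' @export
raw_spectrum <- function(channel, wavelengths, values, meta = list()) {
  channel <- match.arg(channel, c("VIS", "NIR"))
  assert_grid(wavelengths)
  if (length(values) != length(wavelengths)) {
    stop("values and wavelengths must have the same length")
  }
  if (!all(is.finite(values))) stop("values must be finite")
  structure(list(channel = channel, wavelengths = wavelengths,
                 values = as.numeric(values), meta = meta),
            class = "raw_spectrum")
}

#' Calibrate raw counts to reflectance with white/dark references
#'
#' Applies the standard diffuse-reflectance calibration
#' \deqn{R(\lambda) = \frac{S(\lambda) - D(\lambda)}{W(\lambda) - D(\lambda)}}
#' where S is the sample, W a white (Spectralon) reference and D a dark
#' reference, all acquired on the same channel and wavelength grid.
#'
#' @param sample,white,dark `raw_spectrum` objects sharing channel and grid.
#' @return A `raw_spectrum` whose values are dimensionless reflectance.
#' @export
calibrate_reflectance <- function(sample, white, dark) {
  for (s in list(sample, white, dark)) stopifnot(inherits(s, "raw_spectrum"))
  if (white$channel != sample$channel || dark$channel != sample$channel) {
    stop("sample, white and dark must share the same channel")
  }
  if (!isTRUE(all.equal(sample$wavelengths, white$wavelengths)) ||
      !isTRUE(all.equal(sample$wavelengths, dark$wavelengths))) {
    stop("sample, white and dark must share the same wavelength grid")
  }
  denom <- white$values - dark$values
  bad <- which(denom <= 0)
  if (length(bad)) {
    stop(sprintf("white minus dark is non-positive at %g nm: cannot calibrate",
                 sample$wavelengths[bad[1]]))
  }
  raw_spectrum(sample$channel, sample$wavelengths,
               (sample$values - dark$values) / denom, sample$meta)
}

#' Stitch calibrated VIS and NIR spectra into one continuous spectrum
#'
#' Combines the two spectrometer channels into a single spectrum covering (at
#' most) 400--1600 nm. Outside the overlap region each channel passes through
#' unchanged; inside the overlap the default policy is a linear cross-fade in
#' which the VIS weight falls linearly from 1 to 0, guaranteeing continuity.
#' A hard-cut policy (VIS below a splice wavelength, NIR above) is available.
#'
#' @param vis,nir Calibrated `raw_spectrum` objects, channels VIS and NIR.
#' @param policy `"crossfade"` (default) or `"cut"`.
#' @param overlap Numeric length-2: overlap region used by the cross-fade;
#'   defaults to the intersection of the channel spans.
#' @param splice_nm Splice wavelength for the `"cut"` policy (default: middle
#'   of the overlap).
#' @return A list of class `spectrum` with `wavelengths` and `values`.
#' @export
stitch_spectra <- function(vis, nir, policy = c("crossfade", "cut"),
                           overlap = NULL, splice_nm = NULL) {
  stopifnot(inherits(vis, "raw_spectrum"), inherits(nir, "raw_spectrum"))
  if (vis$channel != "VIS" || nir$channel != "NIR") {
    stop("stitching expects a VIS and an NIR channel, in that order")
  }
  lo <- max(min(vis$wavelengths), min(nir$wavelengths))
  hi <- min(max(vis$wavelengths), max(nir$wavelengths))
  if (lo >= hi) stop("channels do not overlap: cannot stitch")
  if (is.null(overlap)) overlap <- c(lo, hi)
  if (overlap[1] < lo || overlap[2] > hi || overlap[1] >= overlap[2]) {
    stop("overlap must lie within the channel intersection")
  }
  policy <- match.arg(policy)

  wl <- sort(unique(c(vis$wavelengths, nir$wavelengths)))
  wl <- wl[wl >= max(400, min(vis$wavelengths)) &
             wl <= min(1600, max(nir$wavelengths))]
  v <- rep(NA_real_, length(wl))
  in_vis <- wl >= min(vis$wavelengths) & wl <= max(vis$wavelengths)
  in_nir <- wl >= min(nir$wavelengths) & wl <= max(nir$wavelengths)
  vis_v <- rep(NA_real_, length(wl))
  nir_v <- rep(NA_real_, length(wl))
  vis_v[in_vis] <- stats::approx(vis$wavelengths, vis$values,
                                 xout = wl[in_vis])$y
  nir_v[in_nir] <- stats::approx(nir$wavelengths, nir$values,
                                 xout = wl[in_nir])$y

  if (policy == "crossfade") {
    w <- rep(NA_real_, length(wl))
    w[wl <= overlap[1]] <- 1
    w[wl >= overlap[2]] <- 0
    mid <- wl > overlap[1] & wl < overlap[2]
    w[mid] <- (overlap[2] - wl[mid]) / (overlap[2] - overlap[1])
    v <- ifelse(in_vis & !in_nir, vis_v,
                ifelse(in_nir & !in_vis, nir_v,
                       w * vis_v + (1 - w) * nir_v))
  } else {
    if (is.null(splice_nm)) splice_nm <- mean(overlap)
    v <- ifelse(wl < splice_nm, ifelse(in_vis, vis_v, nir_v),
                ifelse(in_nir, nir_v, vis_v))
  }
  structure(list(wavelengths = wl, values = as.numeric(v)), class = "spectrum")
}

#' Resample a spectrum onto a target wavelength grid
#'
#' Linear interpolation; no smoothing. Resampling onto the canonical grid
#' yields exactly 1201 values.
#'
#' @param wavelengths,values Source spectrum.
#' @param grid Target wavelengths; must lie within the source span.
#' @return Numeric vector of interpolated values on `grid`.
#' @export
resample_spectrum <- function(wavelengths, values, grid = canonical_grid()) {
  assert_grid(wavelengths)
  if (min(grid) < min(wavelengths) || max(grid) > max(wavelengths)) {
    stop(sprintf(
      "target grid [%g, %g] outside source span [%g, %g]: refusing to extrapolate",
      min(grid), max(grid), min(wavelengths), max(wavelengths)))
  }
  stats::approx(wavelengths, values, xout = grid)$y
}

# ---- tabular spectra files ----------------------------------------------

wl_colnames <- function(wavelengths) {
  # wl_970 for integers, wl_970.5 otherwise
  paste0("wl_", vapply(wavelengths, function(w) format(w, trim = TRUE), ""))
}

#' Write a spectra set to a delimited text file
#'
#' One row per measurement; header `patient_id, location_id, label` followed
#' by one column per wavelength named `wl_<nm>`. Values are written with 17
#' significant digits so a write/read round trip is lossless.
#'
#' @param set A `drs_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(set, path) {
  stopifnot(inherits(set, "drs_set"))
  vals <- apply(set$spectra, c(1, 2), function(x) sprintf("%.17g", x))
  df <- cbind(set$meta[, c("patient_id", "location_id", "label")],
              as.data.frame(vals, stringsAsFactors = FALSE))
  names(df) <- c("patient_id", "location_id", "label",
                 wl_colnames(set$wavelengths))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectra set from a delimited text file
#'
#' Inverse of [write_spectra_table()]. Errors name the offending row for
#' missing columns, non-numeric reflectance, invalid labels and duplicated
#' `(patient_id, location_id)` keys.
#'
#' @param path Input file path.
#' @return A `drs_set`.
#' @export
read_spectra_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  req <- c("patient_id", "location_id", "label")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("spectra table missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  wl_cols <- grep("^wl_", names(df), value = TRUE)
  if (!length(wl_cols)) stop("spectra table has no wl_<nm> columns")
  wl <- as.numeric(sub("^wl_", "", wl_cols))
  if (anyNA(wl)) stop("unparseable wavelength column name(s)")
  o <- order(wl)
  wl <- wl[o]; wl_cols <- wl_cols[o]

  mat <- matrix(NA_real_, nrow(df), length(wl_cols))
  for (j in seq_along(wl_cols)) {
    x <- suppressWarnings(as.numeric(df[[wl_cols[j]]]))
    bad <- which(is.na(x) & !is.na(df[[wl_cols[j]]]))
    if (length(bad)) {
      stop(sprintf("non-numeric reflectance in column %s, data row %d",
                   wl_cols[j], bad[1]))
    }
    mat[, j] <- x
  }
  bad_lab <- which(!df$label %in% DRS_LABELS)
  if (length(bad_lab)) {
    stop(sprintf("invalid label '%s' at data row %d",
                 df$label[bad_lab[1]], bad_lab[1]))
  }
  key <- paste(df$patient_id, df$location_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("duplicated (patient_id, location_id) at data row %d", dup[1]))
  }
  drs_set(mat, wl, df[, req])
}
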