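#' Moving-average smoothing with partial windows at the edges
#'
#' @param y Numeric vector.
#' @param window_nm Window width in nm (full width).
#' @param step_nm Grid spacing in nm.
#' @return Smoothed vector of the same length.
#' @keywords internal
moving_average <- function(y, window_nm, step_nm) {
  if (window_nm <= 0) return(y)
  half <- max(0L, floor(window_nm / (2 * step_nm)))
  n <- length(y)
  if (2L * half + 1L > n) {
    stop("smoothing window larger than the spectrum")
  }
  if (half == 0L) return(y)
  cs <- cumsum(c(0, y))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Topographic prominence of the local maximum at index i: height above the
# higher of the two minima separating it from higher ground (or the ends).
peak_prominence <- function(y, i) {
  n <- length(y)
  lmin <- y[i]
  j <- i
  while (j > 1L && y[j - 1L] <= y[i]) {
    j <- j - 1L
    if (y[j] < lmin) lmin <- y[j]
  }
  rmin <- y[i]
  j <- i
  while (j < n && y[j + 1L] <= y[i]) {
    j <- j + 1L
    if (y[j] < rmin) rmin <- y[j]
  }
  y[i] - max(lmin, rmin)
}

#' Detect landmark wavelengths (local extrema) on a class mean spectrum
#'
#' The mean spectrum is optionally smoothed with a centered moving average,
#' then interior local minima and maxima are located by neighbor comparison.
#' Extrema whose topographic prominence falls below `min_prominence` are
#' discarded; grid endpoints are never reported.
#'
#' @param profile A `class_profile` (from [class_profiles()]).
#' @param smooth_window Moving-average full width in nm (default 15); 0
#'   disables smoothing.
#' @param min_prominence Minimum prominence, in the units of the spectrum
#'   (SNV units for normalized input; default 0.05).
#' @return Data frame with columns `wavelength_nm`, `kind` (`"min"`/`"max"`),
#'   `prominence`, `source_class`, sorted by wavelength.
#' @export
detect_landmarks <- function(profile, smooth_window = 15,
                             min_prominence = 0.05) {
  stopifnot(inherits(profile, "class_profile"))
  wl <- profile$wavelengths
  step <- wl[2] - wl[1]
  y <- moving_average(profile$mean_spectrum, smooth_window, step)
  n <- length(y)
  out <- list()
  for (i in 2:(n - 1L)) {
    if (y[i] > y[i - 1L] && y[i] > y[i + 1L]) {
      p <- peak_prominence(y, i)
      if (p >= min_prominence) {
        out[[length(out) + 1L]] <- data.frame(
          wavelength_nm = wl[i], kind = "max", prominence = p)
      }
    } else if (y[i] < y[i - 1L] && y[i] < y[i + 1L]) {
      p <- peak_prominence(-y, i)
      if (p >= min_prominence) {
        out[[length(out) + 1L]] <- data.frame(
          wavelength_nm = wl[i], kind = "min", prominence = p)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(wavelength_nm = numeric(0), kind = character(0),
                      prominence = numeric(0), source_class = character(0)))
  }
  res <- do.call(rbind, out)
  res$source_class <- profile$label
  res[order(res$wavelength_nm), , drop = FALSE]
}

#' Propose slope wavelength pairs from detected landmarks
#'
#' Pairs are formed from the deduplicated union of landmark wavelengths over
#' both classes: every pair of consecutive landmark wavelengths, plus each
#' minimum paired with its flanking maxima. Pairs closer than
#' `min_separation` are dropped (near-degenerate difference quotients), the
#' list is sorted lexicographically and truncated deterministically to
#' `max_pairs`.
#'
#' @param landmarks Data frame as returned by [detect_landmarks()], possibly
#'   row-bound over several classes.
#' @param max_pairs Maximum number of pairs to keep (default unlimited).
#' @param min_separation Minimum wavelength separation in nm (default 20).
#' @return Data frame with columns `lambda1_nm`, `lambda2_nm` (`lambda1 <
#'   lambda2`); empty if fewer than two distinct landmark wavelengths exist.
#' @export
propose_slope_pairs <- function(landmarks, max_pairs = Inf,
                                min_separation = 20) {
  empty <- data.frame(lambda1_nm = numeric(0), lambda2_nm = numeric(0))
  wls <- sort(unique(landmarks$wavelength_nm))
  if (length(wls) < 2L) return(empty)

  pairs <- cbind(wls[-length(wls)], wls[-1])  # consecutive
  maxima <- sort(unique(landmarks$wavelength_nm[landmarks$kind == "max"]))
  minima <- sort(unique(landmarks$wavelength_nm[landmarks$kind == "min"]))
  for (mn in minima) {
    left <- maxima[maxima < mn]
    right <- maxima[maxima > mn]
    if (length(left)) pairs <- rbind(pairs, c(max(left), mn))
    if (length(right)) pairs <- rbind(pairs, c(mn, min(right)))
  }
  pairs <- unique(pairs)
  pairs <- pairs[pairs[, 2] - pairs[, 1] >= min_separation, , drop = FALSE]
  if (!nrow(pairs)) return(empty)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  if (nrow(pairs) > max_pairs) pairs <- pairs[seq_len(max_pairs), , drop = FALSE]
  data.frame(lambda1_nm = pairs[, 1], lambda2_nm = pairs[, 2])
}

#' Assemble a feature specification
#'
#' Fixes the candidate feature set: landmark intensity features (value of the
#' normalized spectrum at each landmark wavelength) followed by slope
#' features (difference quotient between a wavelength pair, per nm). Feature
#' names are stable identifiers; ordering is deterministic (landmarks by
#' wavelength then kind, pairs lexicographically).
#'
#' @param landmarks Data frame with `wavelength_nm`, `kind` (duplicated
#'   wavelengths of the same kind are collapsed).
#' @param pairs Data frame with `lambda1_nm`, `lambda2_nm`.
#' @return Object of class `feature_spec` with `landmarks`, `pairs`, `names`.
#' @export
feature_spec <- function(landmarks, pairs) {
  lm <- unique(data.frame(wavelength_nm = landmarks$wavelength_nm,
                          kind = landmarks$kind))
  lm <- lm[order(lm$wavelength_nm, lm$kind), , drop = FALSE]
  pr <- unique(data.frame(lambda1_nm = pairs$lambda1_nm,
                          lambda2_nm = pairs$lambda2_nm))
  pr <- pr[order(pr$lambda1_nm, pr$lambda2_nm), , drop = FALSE]
  if (nrow(pr) && any(pr$lambda1_nm >= pr$lambda2_nm)) {
    stop("slope pairs require lambda1 < lambda2")
  }
  nm <- c(sprintf("lm_%s_%s", format(lm$wavelength_nm, trim = TRUE), lm$kind),
          sprintf("sl_%s_%s", format(pr$lambda1_nm, trim = TRUE),
                  format(pr$lambda2_nm, trim = TRUE)))
  if (anyDuplicated(nm)) stop("feature names must be unique")
  structure(list(landmarks = lm, pairs = pr, names = nm),
            class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("<feature_spec> %d landmarks + %d slopes = %d features\n",
              nrow(x$landmarks), nrow(x$pairs), length(x$names)))
  invisible(x)
}

#' Derive the feature specification from a set's class profiles
#'
#' Convenience wrapper: class mean spectra (tumor, healthy) -> landmark
#' detection per class -> union -> slope pairs -> [feature_spec()]. When used
#' inside the evaluation loop this must be called on training data only.
#'
#' @param set SNV-normalized `drs_set`.
#' @param smooth_window,min_prominence Passed to [detect_landmarks()].
#' @param min_separation,max_pairs Passed to [propose_slope_pairs()].
#' @return A `feature_spec`.
#' @export
derive_feature_spec <- function(set, smooth_window = 15, min_prominence = 0.05,
                                min_separation = 20, max_pairs = Inf) {
  profs <- class_profiles(set)
  lms <- do.call(rbind, lapply(profs, detect_landmarks,
                               smooth_window = smooth_window,
                               min_prominence = min_prominence))
  pairs <- propose_slope_pairs(lms, max_pairs = max_pairs,
                               min_separation = min_separation)
  feature_spec(lms, pairs)
}

#' Evaluate a feature specification on every measurement
#'
#' Landmark features are the (normalized) intensity at the landmark
#' wavelength; slope features are `(z(l2) - z(l1)) / (l2 - l1)` per nm. Row
#' order follows the input set.
#'
#' @param set `drs_set` on the grid the spec was derived on.
#' @param spec A `feature_spec`.
#' @return Data frame: `patient_id`, `location_id`, `label`, then one column
#'   per feature in spec order.
#' @export
compute_features <- function(set, spec) {
  stopifnot(inherits(set, "drs_set"), inherits(spec, "feature_spec"))
  wl <- set$wavelengths
  idx_of <- function(w) {
    i <- match(TRUE, abs(wl - w) < 1e-9)
    if (is.na(i)) stop(sprintf("wavelength %g nm is not on the set's grid", w))
    i
  }
  out <- set$meta[, c("patient_id", "location_id", "label")]
  for (r in seq_len(nrow(spec$landmarks))) {
    i <- idx_of(spec$landmarks$wavelength_nm[r])
    out[[spec$names[r]]] <- set$spectra[, i]
  }
  off <- nrow(spec$landmarks)
  for (r in seq_len(nrow(spec$pairs))) {
    i1 <- idx_of(spec$pairs$lambda1_nm[r])
    i2 <- idx_of(spec$pairs$lambda2_nm[r])
    out[[spec$names[off + r]]] <-
      (set$spectra[, i2] - set$spectra[, i1]) /
      (spec$pairs$lambda2_nm[r] - spec$pairs$lambda1_nm[r])
  }
  out
}

#' Write / read a feature specification as plain text
#'
#' One feature per line: `landmark <nm> <kind>` or `slope <nm1> <nm2>`, so a
#' frozen spec can be reapplied to new data.
#'
#' @param spec A `feature_spec`.
#' @param path File path.
#' @return `path` (write) or a `feature_spec` (read).
#' @export
write_feature_spec <- function(spec, path) {
  lines <- c(
    sprintf("landmark %s %s", format(spec$landmarks$wavelength_nm, trim = TRUE),
            spec$landmarks$kind),
    sprintf("slope %s %s", format(spec$pairs$lambda1_nm, trim = TRUE),
            format(spec$pairs$lambda2_nm, trim = TRUE)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_feature_spec
#' @export
read_feature_spec <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "\\s+")
  lm <- list(); pr <- list()
  for (k in seq_along(toks)) {
    t <- toks[[k]]
    if (t[1] == "landmark" && length(t) == 3L) {
      lm[[length(lm) + 1L]] <- data.frame(wavelength_nm = as.numeric(t[2]),
                                          kind = t[3])
    } else if (t[1] == "slope" && length(t) == 3L) {
      pr[[length(pr) + 1L]] <- data.frame(lambda1_nm = as.numeric(t[2]),
                                          lambda2_nm = as.numeric(t[3]))
    } else {
      stop(sprintf("unparseable feature spec line %d: '%s'", k, lines[k]))
    }
  }
  feature_spec(
    if (length(lm)) do.call(rbind, lm) else
      data.frame(wavelength_nm = numeric(0), kind = character(0)),
    if (length(pr)) do.call(rbind, pr) else
      data.frame(lambda1_nm = numeric(0), lambda2_nm = numeric(0)))
}

#' Restrict a feature spec to a subset of its features
#'
#' Used after top-k selection: keeps only the named features while preserving
#' the original declaration order.
#'
#' @param spec A `feature_spec`.
#' @param names Character vector of feature names to keep.
#' @return A `feature_spec` containing only those features.
#' @export
restrict_feature_spec <- function(spec, names) {
  stopifnot(all(names %in% spec$names))
  keep <- spec$names %in% names
  n_lm <- nrow(spec$landmarks)
  keep_lm <- keep[seq_len(n_lm)]
  keep_pr <- keep[seq_len(length(keep) - n_lm) + n_lm]
  feature_spec(spec$landmarks[keep_lm, , drop = FALSE],
               spec$pairs[keep_pr, , drop = FALSE])
}
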