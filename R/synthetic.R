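#' Synthetic chromophore absorption templates
#'
#' Fixed, version-stamped absorption templates for the five chromophores the
#' generator models (oxy-/deoxyhemoglobin, water, lipid, collagen), built as
#' sums of Gaussians at the well-known band positions: hemoglobin Soret and
#' Q bands in the visible, water bands near 970/1190/1450 nm, lipid bands
#' near 930/1210 nm, a broad collagen contribution. These are qualitative
#' stand-ins (relative units), not literature extinction coefficients; they
#' exist so synthetic spectra carry realistic band structure.
#'
#' @param wavelengths Wavelength grid in nm (default canonical).
#' @return Matrix (length(grid) x 5) with columns `oxyHb`, `deoxyHb`,
#'   `water`, `lipid`, `collagen`; attribute `version`.
#' @export
chromophore_templates <- function(wavelengths = canonical_grid()) {
  g <- function(center, width, amp) amp * exp(-0.5 * ((wavelengths - center) / width)^2)
  tmpl <- cbind(
    oxyHb    = g(414, 20, 10) + g(542, 15, 1.5) + g(577, 12, 1.6),
    deoxyHb  = g(430, 22, 10) + g(555, 18, 1.5) + g(760, 30, 0.35),
    water    = g(970, 35, 0.5) + g(1190, 45, 1.0) + g(1450, 60, 3.0),
    lipid    = g(930, 25, 0.6) + g(1210, 40, 1.2),
    collagen = g(1030, 60, 0.4) + g(1510, 70, 1.0)
  )
  attr(tmpl, "wavelengths") <- wavelengths
  attr(tmpl, "version") <- "1.0"
  tmpl
}

#' Absorption coefficient from a tissue composition
#'
#' Linear mixing: `mu_a(lambda) = sum_i c_i * eps_i(lambda)`.
#'
#' @param concentrations Named nonnegative vector over the template columns.
#' @param templates Chromophore template matrix
#'   (default [chromophore_templates()]).
#' @return Nonnegative absorption spectrum (cm^-1, relative scale) on the
#'   template grid.
#' @export
absorption_spectrum <- function(concentrations,
                                templates = chromophore_templates()) {
  nm <- colnames(templates)
  if (is.null(names(concentrations))) names(concentrations) <- nm
  miss <- setdiff(nm, names(concentrations))
  if (length(miss)) stop("missing concentration(s): ", paste(miss, collapse = ", "))
  conc <- concentrations[nm]
  if (any(conc < 0)) stop("concentrations must be nonnegative")
  as.numeric(templates %*% conc)
}

#' Diffusion-style forward model for diffuse reflectance
#'
#' Analytic surrogate mapping optical properties to reflectance at a fixed
#' source-detector separation:
#' \deqn{R(\lambda) = S \exp(-\mu_{eff}(\lambda)\,\rho)/\rho^2, \quad
#'   \mu_{eff} = \sqrt{3\mu_a(\mu_a + \mu_s')}, \quad
#'   \mu_s'(\lambda) = a (\lambda/500)^{-b}.}
#' Reflectance is positive and strictly decreasing in absorption; with zero
#' absorption the exponential term is identically 1. This is a smooth,
#' monotone surrogate carrying chromophore band structure into spectra, not
#' a quantitative photon-transport model.
#'
#' @param mu_a Absorption spectrum (cm^-1) on `wavelengths`.
#' @param wavelengths Grid in nm.
#' @param a Scattering amplitude at 500 nm (cm^-1), `> 0`.
#' @param b Scattering power, `> 0`.
#' @param rho Source-detector separation in cm (default 0.2, i.e. 2 mm).
#' @param S Source/system constant; defaults to `rho^2` so the zero-absorption
#'   reflectance is 1.
#' @return Positive reflectance spectrum.
#' @export
reflectance_forward <- function(mu_a, wavelengths = canonical_grid(),
                                a = 10, b = 1.2, rho = 0.2, S = rho^2) {
  if (length(mu_a) != length(wavelengths)) {
    stop("mu_a must match the wavelength grid")
  }
  if (any(mu_a < 0)) stop("mu_a must be nonnegative")
  if (a <= 0 || b <= 0 || rho <= 0) stop("a, b, rho must be positive")
  mus_p <- a * (wavelengths / 500)^(-b)
  mu_eff <- sqrt(3 * mu_a * (mu_a + mus_p))
  S * exp(-mu_eff * rho) / rho^2
}

#' Generator configuration
#'
#' Defaults emulate the study cohort shape: 59 patients, 5--10 measurement
#' locations each, roughly balanced tumor/healthy labels, and only ~28% of
#' measurements (152/542) retaining a confident label. The class contrast
#' (tumor: more blood and water, less lipid) is a generator assumption made
#' to give the two classes distinguishable band structure; it is not a claim
#' about prostate biology. `delta` in [0, 1] scales the between-class
#' composition difference: `delta = 0` makes the classes identically
#' distributed.
#'
#' @param n_patients Number of patients (default 59).
#' @param meas_per_patient Integer range of measurements per patient
#'   (default `c(5, 10)`).
#' @param tumor_prior Probability a measurement location is tumor (default
#'   0.53, the labeled-set tumor share).
#' @param delta Class-separation scale in `[0, 1]` (default 1, the "easy"
#'   preset).
#' @param patient_sd Patient-level log-normal effect SD on concentrations
#'   (default 0.10).
#' @param within_sd Within-patient measurement jitter SD (default 0.05).
#' @param noise_mult_sd Multiplicative instrument noise SD (default 0.02).
#' @param noise_add_sd Additive instrument noise SD (default 5e-4).
#' @param label_certainty Fraction of measurements keeping their label
#'   (default 152/542).
#' @param two_channel Simulate separate VIS/NIR channels with independent
#'   noise and stitch them (default FALSE: emit canonical-grid spectra).
#' @param seed Integer seed.
#' @return Named list of class `generator_config`.
#' @export
generator_config <- function(n_patients = 59, meas_per_patient = c(5, 10),
                             tumor_prior = 0.53, delta = 1,
                             patient_sd = 0.10, within_sd = 0.05,
                             noise_mult_sd = 0.02, noise_add_sd = 5e-4,
                             label_certainty = 152 / 542,
                             two_channel = FALSE, seed = 1L) {
  cfg <- list(n_patients = n_patients, meas_per_patient = meas_per_patient,
              tumor_prior = tumor_prior, delta = delta,
              patient_sd = patient_sd, within_sd = within_sd,
              noise_mult_sd = noise_mult_sd, noise_add_sd = noise_add_sd,
              label_certainty = label_certainty, two_channel = two_channel,
              seed = as.integer(seed))
  if (cfg$n_patients < 1) stop("n_patients must be >= 1")
  if (length(cfg$meas_per_patient) != 2L ||
      cfg$meas_per_patient[1] > cfg$meas_per_patient[2] ||
      cfg$meas_per_patient[1] < 1) {
    stop("meas_per_patient must be an increasing range of positive counts")
  }
  if (cfg$tumor_prior < 0 || cfg$tumor_prior > 1) stop("tumor_prior in [0,1]")
  if (cfg$delta < 0 || cfg$delta > 1) stop("delta must lie in [0, 1]")
  for (f in c("patient_sd", "within_sd", "noise_mult_sd", "noise_add_sd")) {
    if (cfg[[f]] < 0) stop(f, " must be >= 0")
  }
  if (cfg$label_certainty < 0 || cfg$label_certainty > 1) {
    stop("label_certainty in [0,1]")
  }
  structure(cfg, class = "generator_config")
}

# Baseline composition (relative concentration units) and the direction of
# the tumor-vs-healthy contrast. Tumor tissue is given more blood and water
# and less lipid -- a generator assumption, not a literature value.
GEN_BASE_COMP <- c(oxyHb = 1.2, deoxyHb = 0.8, water = 5.0,
                   lipid = 3.0, collagen = 1.5)
GEN_CLASS_DIFF <- c(oxyHb = 0.8, deoxyHb = 0.5, water = 2.0,
                    lipid = -1.8, collagen = 0.0)

#' Generate a labeled synthetic DRS dataset
#'
#' Hierarchical sampling: each measurement location is tumor or healthy with
#' probability `tumor_prior`; its chromophore composition is the class mean
#' (baseline +/- `delta`/2 times the class contrast) perturbed by a shared
#' patient-level log-normal effect and a within-patient jitter; the
#' diffusion-style forward model converts composition to reflectance, which
#' then receives multiplicative and additive instrument noise. A
#' `1 - label_certainty` fraction of measurements is relabeled `unlabeled`
#' (locations that could not be matched to histology with certainty); the
#' true class and composition of every measurement are retained in the truth
#' table. Fully reproducible from the seed.
#'
#' @param cfg A `generator_config`.
#' @return List: `set` (a `drs_set`) and `truth` (data frame with
#'   `patient_id`, `location_id`, `true_class` and per-chromophore
#'   concentrations).
#' @export
generate_dataset <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  wl <- canonical_grid()
  tmpl <- chromophore_templates(wl)
  chroms <- colnames(tmpl)
  mean_comp <- list(
    tumor = pmax(GEN_BASE_COMP + cfg$delta * GEN_CLASS_DIFF / 2, 0),
    healthy = pmax(GEN_BASE_COMP - cfg$delta * GEN_CLASS_DIFF / 2, 0))

  rows <- list(); meta <- list(); truth <- list()
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%03d", p)
    n_meas <- sample(seq(cfg$meas_per_patient[1], cfg$meas_per_patient[2]), 1)
    patient_eff <- stats::rnorm(length(chroms), 0, cfg$patient_sd)
    a_p <- 10 * exp(stats::rnorm(1, 0, cfg$patient_sd))
    b_p <- 1.2 * exp(stats::rnorm(1, 0, cfg$patient_sd / 2))
    for (m in seq_len(n_meas)) {
      cls <- if (stats::runif(1) < cfg$tumor_prior) "tumor" else "healthy"
      conc <- mean_comp[[cls]] *
        exp(patient_eff + stats::rnorm(length(chroms), 0, cfg$within_sd))
      mu_a <- absorption_spectrum(conc, tmpl)
      if (cfg$two_channel) {
        refl <- simulate_two_channel(mu_a, wl, a_p, b_p, cfg)
      } else {
        refl <- reflectance_forward(mu_a, wl, a = a_p, b = b_p)
        refl <- refl * (1 + stats::rnorm(length(wl), 0, cfg$noise_mult_sd)) +
          stats::rnorm(length(wl), 0, cfg$noise_add_sd)
      }
      keep_label <- stats::runif(1) < cfg$label_certainty
      rows[[length(rows) + 1L]] <- refl
      meta[[length(meta) + 1L]] <- data.frame(
        patient_id = pid, location_id = sprintf("L%02d", m),
        label = if (keep_label) cls else "unlabeled")
      truth[[length(truth) + 1L]] <- data.frame(
        patient_id = pid, location_id = sprintf("L%02d", m),
        true_class = cls, t(conc))
    }
  }
  list(set = drs_set(do.call(rbind, rows), wl, do.call(rbind, meta)),
       truth = do.call(rbind, truth))
}

# Two-channel mode: render the spectrum on the VIS (400-1160 nm) and NIR
# (900-1750 nm) grids with independent instrument noise, then stitch and
# resample back to the canonical grid, exercising the calibration-side code
# path end to end.
simulate_two_channel <- function(mu_a_canonical, wl, a_p, b_p, cfg) {
  wl_ext <- seq(400, 1750, by = 1)
  tmpl_ext <- chromophore_templates(wl_ext)
  # recompute absorption on the extended grid from the canonical one by
  # linear interpolation (adequate: templates are smooth)
  mu_a_ext <- stats::approx(wl, mu_a_canonical, xout = pmin(wl_ext, max(wl)),
                            rule = 2)$y
  refl_ext <- reflectance_forward(mu_a_ext, wl_ext, a = a_p, b = b_p)
  noisy <- function(v) {
    v * (1 + stats::rnorm(length(v), 0, cfg$noise_mult_sd)) +
      stats::rnorm(length(v), 0, cfg$noise_add_sd)
  }
  vis_idx <- wl_ext <= 1160
  nir_idx <- wl_ext >= 900
  vis <- raw_spectrum("VIS", wl_ext[vis_idx], noisy(refl_ext[vis_idx]))
  nir <- raw_spectrum("NIR", wl_ext[nir_idx], noisy(refl_ext[nir_idx]))
  st <- stitch_spectra(vis, nir)
  resample_spectrum(st$wavelengths, st$values, wl)
}
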