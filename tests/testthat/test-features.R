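test_that("landmark detection ignores monotone spectra and endpoints", {
  prof <- profile_from_fun(function(wl) 0.002 * wl)
  lm <- detect_landmarks(prof, smooth_window = 15, min_prominence = 0)
  expect_equal(nrow(lm), 0)
})

test_that("a single Gaussian bump yields one maximum near its center", {
  prof <- profile_from_fun(function(wl) exp(-0.5 * ((wl - 970) / 30)^2))
  lm <- detect_landmarks(prof, smooth_window = 15, min_prominence = 0.05)
  expect_equal(nrow(lm[lm$kind == "max", ]), 1)
  expect_lt(abs(lm$wavelength_nm[lm$kind == "max"] - 970), 2)
})

test_that("unsmoothed extrema match the brute-force neighbor oracle", {
  wl <- canonical_grid()
  # symmetric double well plus gentle tilt: 2 minima, 1 interior maximum
  y <- (cos((wl - 1000) / 90) + 1e-4 * (wl - 1000) / 600)
  prof <- profile_from_fun(function(w) y)
  lm <- detect_landmarks(prof, smooth_window = 0, min_prominence = 0)
  orc <- oracle_extrema(y)
  expect_equal(lm$wavelength_nm, wl[orc$index])
  expect_equal(lm$kind, orc$kind)
})

test_that("prominence threshold suppresses shallow ripples", {
  prof <- profile_from_fun(function(wl)
    sin((wl - 400) / 50) + 0.01 * sin((wl - 400) / 3))
  weak <- detect_landmarks(prof, smooth_window = 0, min_prominence = 0.5)
  all_ <- detect_landmarks(prof, smooth_window = 0, min_prominence = 0)
  expect_lt(nrow(weak), nrow(all_))
  expect_true(all(weak$prominence >= 0.5))
})

test_that("slope pairs follow the consecutive + min-flanking rule", {
  lms <- data.frame(wavelength_nm = c(540, 970, 1210),
                    kind = c("max", "min", "max"),
                    prominence = 1, source_class = "tumor")
  pr <- propose_slope_pairs(lms)
  # consecutive pairs already include min-to-flanking-max here
  expect_equal(pr, data.frame(lambda1_nm = c(540, 970),
                              lambda2_nm = c(970, 1210)))

  # a min flanked by non-adjacent maxima adds the spanning pairs
  lms2 <- data.frame(wavelength_nm = c(500, 600, 700, 800),
                     kind = c("max", "min", "min", "max"),
                     prominence = 1, source_class = "tumor")
  pr2 <- propose_slope_pairs(lms2)
  expect_true(all(c("500:600", "600:700", "700:800", "500:700", "600:800")
                  %in% paste(pr2$lambda1_nm, pr2$lambda2_nm, sep = ":")))

  # duplicated landmarks from a second class do not duplicate pairs
  pr3 <- propose_slope_pairs(rbind(lms, transform(lms, source_class = "healthy")))
  expect_equal(pr3, pr)

  # single landmark or short separation -> empty
  expect_equal(nrow(propose_slope_pairs(lms[2, ])), 0)
  lms4 <- data.frame(wavelength_nm = c(900, 910), kind = c("max", "min"),
                     prominence = 1, source_class = "tumor")
  expect_equal(nrow(propose_slope_pairs(lms4, min_separation = 20)), 0)
})

test_that("feature evaluation returns landmark intensities and difference quotients", {
  wl <- seq(900, 1100, by = 50)
  spec <- feature_spec(
    data.frame(wavelength_nm = c(950, 1050), kind = c("max", "min")),
    data.frame(lambda1_nm = 950, lambda2_nm = 1050))

  # a linear spectrum: every slope feature equals its slope coefficient
  set <- drs_set(rbind(0.01 * (wl - 1000), 2 - 0.03 * wl), wl,
                 data.frame(patient_id = c("A", "B"),
                            location_id = c("L1", "L2"),
                            label = c("tumor", "healthy")))
  ft <- compute_features(set, spec)
  expect_equal(ft$sl_950_1050, c(0.01, -0.03))
  expect_equal(ft$lm_950_max, set$spectra[, wl == 950])

  # hand-computed difference quotient on an arbitrary 5-point spectrum
  v <- c(0.2, 0.9, 0.4, 1.3, 0.7)
  set2 <- drs_set(rbind(v), wl, data.frame(patient_id = "A",
                                           location_id = "L1",
                                           label = "tumor"))
  ft2 <- compute_features(set2, spec)
  expect_equal(ft2$sl_950_1050, (1.3 - 0.9) / 100)

  # off-grid landmark -> spec error
  bad <- feature_spec(data.frame(wavelength_nm = 957, kind = "max"),
                      data.frame(lambda1_nm = numeric(0),
                                 lambda2_nm = numeric(0)))
  expect_error(compute_features(set, bad), "not on the set's grid")
})

test_that("feature extraction is deterministic and order-stable", {
  set <- snv_set(toy_set(n = 6, wl = seq(400, 1600, by = 10),
                         fun = function(wl, i)
                           exp(-0.5 * ((wl - 900 - 10 * i) / 80)^2) + wl / 4000))
  spec <- derive_feature_spec(set, smooth_window = 15, min_prominence = 0.01)
  ft1 <- compute_features(set, spec)
  ft2 <- compute_features(set, spec)
  expect_identical(ft1, ft2)
  expect_equal(names(ft1)[-(1:3)], spec$names)
})

test_that("feature specs survive the plain-text round trip", {
  spec <- feature_spec(
    data.frame(wavelength_nm = c(542, 970, 1450), kind = c("max", "min", "min")),
    data.frame(lambda1_nm = c(542, 970), lambda2_nm = c(970, 1450)))
  path <- withr::local_tempfile(fileext = ".txt")
  write_feature_spec(spec, path)
  back <- read_feature_spec(path)
  expect_equal(back$landmarks, spec$landmarks, ignore_attr = TRUE)
  expect_equal(back$pairs, spec$pairs, ignore_attr = TRUE)
  expect_equal(back$names, spec$names)

  sub <- restrict_feature_spec(spec, c("lm_970_min", "sl_970_1450"))
  expect_equal(sub$names, c("lm_970_min", "sl_970_1450"))
})
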