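test_that("white/dark calibration reproduces the standard ratio", {
  wl <- seq(400, 500, by = 10)
  W <- raw_spectrum("VIS", wl, rep(9, length(wl)))
  D <- raw_spectrum("VIS", wl, rep(1, length(wl)))

  # S = W -> 1 everywhere; S = D -> 0 everywhere
  expect_equal(calibrate_reflectance(W, W, D)$values, rep(1, length(wl)))
  expect_equal(calibrate_reflectance(D, W, D)$values, rep(0, length(wl)))

  # forced arithmetic (5 - 1) / (9 - 1) = 0.5
  S <- raw_spectrum("VIS", wl, rep(5, length(wl)))
  expect_equal(calibrate_reflectance(S, W, D)$values, rep(0.5, length(wl)))

  # scale invariance: common positive factor on all counts cancels
  k <- 3.7
  Sk <- raw_spectrum("VIS", wl, k * S$values)
  Wk <- raw_spectrum("VIS", wl, k * W$values)
  Dk <- raw_spectrum("VIS", wl, k * D$values)
  expect_equal(calibrate_reflectance(Sk, Wk, Dk)$values,
               calibrate_reflectance(S, W, D)$values)
})

test_that("calibration rejects mismatched grids and non-positive references", {
  wl <- seq(400, 500, by = 10)
  S <- raw_spectrum("VIS", wl, rep(5, length(wl)))
  W2 <- raw_spectrum("VIS", wl + 1, rep(9, length(wl)))
  D <- raw_spectrum("VIS", wl, rep(1, length(wl)))
  expect_error(calibrate_reflectance(S, W2, D), "grid")

  Wbad <- raw_spectrum("VIS", wl, c(rep(9, length(wl) - 1), 1))
  expect_error(calibrate_reflectance(S, Wbad, D), "500")
})

test_that("stitching cross-fades the overlap and passes channels through", {
  wl_vis <- seq(400, 1160, by = 2)
  wl_nir <- seq(900, 1750, by = 2)

  # identical values on the overlap -> output equals either input there
  f <- function(wl) 0.5 + 0.3 * sin(wl / 200)
  vis <- raw_spectrum("VIS", wl_vis, f(wl_vis))
  nir <- raw_spectrum("NIR", wl_nir, f(wl_nir))
  st <- stitch_spectra(vis, nir)
  expect_equal(range(st$wavelengths), c(400, 1600))
  expect_equal(st$values, f(st$wavelengths), tolerance = 1e-12)

  # constant 1 vs 0 -> overlap midpoint (1030 nm) is exactly 0.5
  vis1 <- raw_spectrum("VIS", wl_vis, rep(1, length(wl_vis)))
  nir0 <- raw_spectrum("NIR", wl_nir, rep(0, length(wl_nir)))
  st2 <- stitch_spectra(vis1, nir0)
  expect_equal(st2$values[st2$wavelengths == 1030], 0.5)
  expect_equal(st2$values[st2$wavelengths == 800], 1)
  expect_equal(st2$values[st2$wavelengths == 1400], 0)
})

test_that("cross-fade matches hand-computed weights on piecewise-linear input", {
  wl_vis <- seq(400, 1160, by = 1)
  wl_nir <- seq(900, 1750, by = 1)
  vis <- raw_spectrum("VIS", wl_vis, 0.001 * wl_vis)        # line A
  nir <- raw_spectrum("NIR", wl_nir, 2 - 0.0005 * wl_nir)   # line B
  st <- stitch_spectra(vis, nir)
  for (w in c(950, 1030, 1100)) {
    wgt <- (1160 - w) / (1160 - 900)
    expect_equal(st$values[st$wavelengths == w],
                 wgt * 0.001 * w + (1 - wgt) * (2 - 0.0005 * w),
                 tolerance = 1e-12)
  }
  # no overlap -> stitch error
  vis_short <- raw_spectrum("VIS", seq(400, 800, 1), rep(1, 401))
  expect_error(stitch_spectra(vis_short, nir), "overlap")
})

test_that("resampling interpolates linearly and hits the canonical length", {
  wl <- seq(390, 1700, by = 5)
  vals <- 2 + 0.003 * wl
  expect_equal(resample_spectrum(wl, vals, wl), vals)          # identity
  out <- resample_spectrum(wl, vals, canonical_grid())
  expect_length(out, 1201)
  expect_equal(out, 2 + 0.003 * canonical_grid(), tolerance = 1e-12)
  expect_error(resample_spectrum(wl, vals, seq(100, 200, 1)), "extrapolate")
})

test_that("spectra-table round trip is lossless and validates its input", {
  set <- toy_set(n = 3, fun = function(wl, i) exp(sin(wl / 17)) + i / 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_table(set, path)
  back <- read_spectra_table(path)
  expect_equal(back$spectra, set$spectra, ignore_attr = TRUE)
  expect_equal(back$wavelengths, set$wavelengths)
  expect_equal(back$meta$label, set$meta$label)
  expect_equal(back$meta$patient_id, set$meta$patient_id)

  # missing label column
  df <- utils::read.csv(path, check.names = FALSE)
  df$label <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE)
  expect_error(read_spectra_table(path2), "label")

  # non-numeric reflectance names the row
  lines <- readLines(path)
  lines[2] <- sub("^([^,]*,[^,]*,[^,]*,)[^,]*", "\\1oops", lines[2])
  writeLines(lines, path2)
  expect_error(read_spectra_table(path2), "row 1")
})

test_that("a cohort-shaped file reports the expected class counts", {
  # 152 labeled rows: 80 tumor / 72 healthy, as in the study's labeled set
  n <- 152
  labels <- c(rep("tumor", 80), rep("healthy", 72))
  set <- toy_set(n = n, labels = labels,
                 patients = paste0("P", rep(1:38, each = 4)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_table(set, path)
  s <- summarize_dataset(read_spectra_table(path))
  expect_equal(s$classes$n, c(80, 72))
  expect_equal(s$n_labeled, 152)
})
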