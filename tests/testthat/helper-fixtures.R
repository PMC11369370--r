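# Shared fixtures and independent oracles for the test suite.

# Small labeled spectra set built directly in code. `fun(wl, i)` gives the
# i-th spectrum; labels/patients cycle deterministically.
toy_set <- function(n = 6, wl = seq(400, 500, by = 10),
                    labels = rep(c("tumor", "healthy"), length.out = n),
                    patients = paste0("P", rep(seq_len(ceiling(n / 2)),
                                               each = 2, length.out = n)),
                    fun = function(wl, i) sin(wl / 30) + i / 10) {
  mat <- t(vapply(seq_len(n), function(i) fun(wl, i), numeric(length(wl))))
  drs_set(mat, wl, data.frame(patient_id = patients,
                              location_id = paste0("L", seq_len(n)),
                              label = labels))
}

# Brute-force ReliefF: every hit/miss pair found by explicit per-pair diff
# sums, no vectorized distance matrix. Written independently of the package
# implementation; m = all instances.
oracle_relieff <- function(x, y, k) {
  x <- as.matrix(x); y <- as.character(y)
  n <- nrow(x); p <- ncol(x)
  rng <- vapply(seq_len(p), function(f) max(x[, f]) - min(x[, f]), 0)
  diff_f <- function(f, a, b) {
    if (rng[f] == 0) 0 else abs(x[a, f] - x[b, f]) / rng[f]
  }
  dist_ab <- function(a, b) sum(vapply(seq_len(p), diff_f, 0, a = a, b = b))
  W <- numeric(p)
  for (i in seq_len(n)) {
    d <- vapply(seq_len(n), dist_ab, 0, a = i)
    cand <- order(d, seq_len(n))          # ties by row order
    cand <- cand[cand != i]
    hits <- cand[y[cand] == y[i]][seq_len(k)]
    misses <- cand[y[cand] != y[i]][seq_len(k)]
    for (f in seq_len(p)) {
      for (h in hits) W[f] <- W[f] - diff_f(f, i, h) / (n * k)
      for (m in misses) W[f] <- W[f] + diff_f(f, i, m) / (n * k)
    }
  }
  names(W) <- colnames(x)
  W
}

# Pairwise-concordance AUC with ties counted one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "tumor"]
  neg <- scores[labels == "healthy"]
  conc <- 0
  for (a in pos) for (b in neg) {
    conc <- conc + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  conc / (length(pos) * length(neg))
}

# All strict interior local extrema by direct neighbor comparison.
oracle_extrema <- function(y) {
  n <- length(y)
  kind <- rep(NA_character_, n)
  for (i in 2:(n - 1)) {
    if (y[i] > y[i - 1] && y[i] > y[i + 1]) kind[i] <- "max"
    if (y[i] < y[i - 1] && y[i] < y[i + 1]) kind[i] <- "min"
  }
  data.frame(index = which(!is.na(kind)), kind = kind[!is.na(kind)])
}

# A class_profile built directly from a function of wavelength.
profile_from_fun <- function(fun, wl = canonical_grid(), label = "tumor") {
  structure(list(label = label, mean_spectrum = fun(wl),
                 sd_spectrum = rep(0, length(wl)), n = 2, wavelengths = wl),
            class = "class_profile")
}
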