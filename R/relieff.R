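#' ReliefF feature ranking
#'
#' Instance-based feature weighting (Kononenko's ReliefF). For each sampled
#' instance the k nearest neighbours of the same class (hits) and of the
#' other class (misses) are located under Manhattan distance on
#' min-max-scaled features, and each feature's weight is decreased by its
#' mean normalized difference to the hits and increased by its mean
#' normalized difference to the misses:
#' \deqn{W_f \leftarrow W_f - \sum_{h} \frac{\mathrm{diff}(f, i, h)}{m k}
#'                       + \sum_{m'} \frac{\mathrm{diff}(f, i, m')}{m k}}
#' with \eqn{\mathrm{diff}(f, a, b) = |x_{af} - x_{bf}| / (\max_f - \min_f)}.
#' A feature that is constant across the table has \eqn{\mathrm{diff} \equiv 0}
#' and receives weight exactly 0. Weights lie in \eqn{[-1, 1]}; features that
#' differ across classes but not within them score high.
#'
#' By default every instance is used (`m_samples = NULL`, deterministic, no
#' randomness); a seeded subsample of instances can be requested instead.
#' Neighbour-distance ties are broken by row order. `k_neighbors` larger than
#' the smallest class allows is clamped with a warning.
#'
#' @param x Numeric matrix or data frame of features (rows = instances).
#' @param y Class labels, length `nrow(x)`; at least two classes.
#' @param k_neighbors Number of hits and misses per instance (default 10).
#' @param m_samples Number of sampled instances; `NULL` (default) uses all
#'   instances in row order.
#' @param seed Seed for instance subsampling (only used when `m_samples` is
#'   not `NULL`).
#' @return Object of class `ranked_features`: `weights` (named numeric),
#'   `order` (feature names by descending weight, ties broken by declaration
#'   order), `params`.
#' @export
relieff_rank <- function(x, y, k_neighbors = 10, m_samples = NULL,
                         seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.character(y)
  if (nrow(x) != length(y)) stop("x rows must match length of y")
  classes <- unique(y)
  if (length(classes) < 2L) stop("ReliefF needs at least 2 classes")
  class_sizes <- table(y)
  k_max <- min(class_sizes) - 1L
  if (k_max < 1L) stop("every class needs at least 2 instances")
  if (k_neighbors > k_max) {
    warning(sprintf("k_neighbors = %d exceeds smallest class - 1; clamped to %d",
                    k_neighbors, k_max))
    k_neighbors <- k_max
  }
  n <- nrow(x); p <- ncol(x)
  feat_names <- colnames(x)
  if (is.null(feat_names)) feat_names <- paste0("f", seq_len(p))

  rng <- apply(x, 2, function(v) max(v) - min(v))
  active <- rng > 0
  # diff on min-max-scaled features == |scaled difference|; constant features
  # contribute 0 everywhere and keep weight 0 by definition
  xs <- x
  xs[, active] <- sweep(
    sweep(x[, active, drop = FALSE], 2,
          apply(x[, active, drop = FALSE], 2, min), "-"),
    2, rng[active], "/")
  xs[, !active] <- 0

  if (is.null(m_samples)) {
    sample_idx <- seq_len(n)
  } else {
    if (!is.null(seed)) set.seed(seed)
    sample_idx <- sample.int(n, min(m_samples, n))
  }
  m <- length(sample_idx)
  k <- k_neighbors

  # Manhattan distances on scaled features; ties broken by row order
  W <- numeric(p)
  for (i in sample_idx) {
    d <- rowSums(abs(xs - matrix(xs[i, ], n, p, byrow = TRUE)))
    same <- which(y == y[i]); same <- same[same != i]
    other <- which(y != y[i])
    hits <- same[order(d[same], same)][seq_len(k)]
    misses <- other[order(d[other], other)][seq_len(k)]
    dh <- colSums(abs(xs[hits, , drop = FALSE] -
                        matrix(xs[i, ], k, p, byrow = TRUE)))
    dm <- colSums(abs(xs[misses, , drop = FALSE] -
                        matrix(xs[i, ], k, p, byrow = TRUE)))
    W <- W - dh / (m * k) + dm / (m * k)
  }
  names(W) <- feat_names
  # descending weight; equal weights keep declaration order
  ord <- feat_names[order(-W, seq_len(p))]
  structure(list(weights = W, order = ord,
                 params = list(k_neighbors = k, m_samples = m_samples,
                               seed = seed)),
            class = "ranked_features")
}

#' @export
print.ranked_features <- function(x, ...) {
  cat(sprintf("<ranked_features> %d features, k = %d\n",
              length(x$weights), x$params$k_neighbors))
  top <- utils::head(x$order, 5)
  cat("  top:", paste(sprintf("%s (%.3f)", top, x$weights[top]),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Select the top-k ranked features
#'
#' Keeps the `k` features with the largest ReliefF weights (ties broken by
#' declaration order) and returns their names in declaration order, so a
#' restricted feature spec preserves the original feature ordering.
#'
#' @param ranked A `ranked_features` object.
#' @param k Number of features to keep (default 20).
#' @return Character vector of `k` feature names in declaration order.
#' @export
select_top_k <- function(ranked, k = 20) {
  stopifnot(inherits(ranked, "ranked_features"))
  nm <- names(ranked$weights)
  if (k > length(nm)) {
    stop(sprintf("cannot select %d features from %d available", k, length(nm)))
  }
  top <- ranked$order[seq_len(k)]
  nm[nm %in% top]
}

#' Write ranked feature weights as two-column delimited text
#'
#' @param ranked A `ranked_features` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranked_features <- function(ranked, path) {
  df <- data.frame(feature = ranked$order,
                   weight = ranked$weights[ranked$order])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
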