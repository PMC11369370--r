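#' Pipeline configuration
#'
#' Collects every tunable of the classification workflow with the defaults of
#' the study design: 20 selected features, patient-wise 70/30 split, tenfold
#' cross-validation, ten iterations. Unknown keys are rejected, guarding
#' against silent typos in config files.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    smooth_window = 15,        # nm, moving-average width for extrema detection
    min_prominence = 0.05,     # SNV units
    min_separation = 20,       # nm, minimum slope-pair span
    max_pairs = Inf,
    k_neighbors = 10,          # ReliefF
    m_samples = NULL,          # NULL = all instances (deterministic)
    top_k = 20,
    ratio = 0.70,
    folds = 10,
    C_grid = c(0.01, 0.1, 1, 10, 100),
    n_iter = 10,
    base_seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

# Per-stage seeds fan out from the base seed via a fixed counter scheme so
# individual iterations are reproducible in isolation.
iteration_seed <- function(base_seed, iter) {
  as.integer(base_seed) + 1000L * as.integer(iter)
}

#' Fit the full feature/selection/classifier chain on one training split
#'
#' Everything after the split — class profiles, landmark/slope feature
#' derivation, ReliefF ranking, top-k selection, SVM training — uses training
#' rows only, so test patients cannot leak into the fitted model.
#'
#' @param set SNV-normalized labeled `drs_set`.
#' @param plan A `split_plan` from [patient_split()].
#' @param cfg A `pipeline_config`.
#' @param seed Seed for CV fold assignment.
#' @return List: `model`, `spec` (full candidate spec), `selected_spec`,
#'   `ranked`, `selected` (feature names).
#' @export
fit_split <- function(set, plan, cfg = pipeline_config(), seed = 1L) {
  train <- subset_measurements(set, set$meta$patient_id %in% plan$train_patients)
  spec <- derive_feature_spec(train,
                              smooth_window = cfg$smooth_window,
                              min_prominence = cfg$min_prominence,
                              min_separation = cfg$min_separation,
                              max_pairs = cfg$max_pairs)
  ft <- compute_features(train, spec)
  xcols <- spec$names
  ranked <- relieff_rank(ft[, xcols, drop = FALSE], ft$label,
                         k_neighbors = cfg$k_neighbors,
                         m_samples = cfg$m_samples, seed = seed)
  k <- cfg$top_k
  if (k > length(xcols)) {
    warning(sprintf("top_k = %d exceeds %d candidate features; using all",
                    k, length(xcols)))
    k <- length(xcols)
  }
  selected <- select_top_k(ranked, k)
  model <- train_classifier(ft[, selected, drop = FALSE], ft$label,
                            C_grid = cfg$C_grid, folds = cfg$folds,
                            seed = seed)
  list(model = model, spec = spec,
       selected_spec = restrict_feature_spec(spec, selected),
       ranked = ranked, selected = selected)
}

#' Repeated patient-wise evaluation
#'
#' Runs `n_iter` independent iterations. Each iteration draws a fresh
#' patient-wise 70/30 split, re-derives the feature spec and ReliefF ranking
#' from the training side only, trains the cross-validated linear SVM, and
#' evaluates on the held-out patients. Metrics are aggregated as mean and
#' sample SD (n-1) over iterations; with a single iteration the SD is
#' reported as 0 by convention.
#'
#' @param set A `drs_set` (raw reflectance; SNV is applied internally).
#' @param cfg A `pipeline_config`.
#' @return Object of class `evaluation_report`: `iterations` (list of
#'   per-iteration results), `metrics` (data frame), `mean`, `sd`, `config`.
#' @export
run_repeated <- function(set, cfg = pipeline_config()) {
  stopifnot(inherits(set, "drs_set"))
  labeled <- labeled_subset(set)
  norm <- snv_set(labeled)
  iters <- vector("list", cfg$n_iter)
  for (i in seq_len(cfg$n_iter)) {
    seed_i <- iteration_seed(cfg$base_seed, i)
    res <- tryCatch({
      plan <- patient_split(norm, ratio = cfg$ratio, seed = seed_i)
      fitted <- fit_split(norm, plan, cfg, seed = seed_i + 1L)
      test <- subset_measurements(
        norm, norm$meta$patient_id %in% plan$test_patients)
      ft_test <- compute_features(test, fitted$selected_spec)
      ev <- evaluate_model(fitted$model, ft_test[, fitted$selected, drop = FALSE],
                           ft_test$label)
      list(eval = ev, plan = plan, selected = fitted$selected,
           ranked = fitted$ranked, spec = fitted$selected_spec,
           n_candidates = length(fitted$spec$names),
           C = fitted$model$C, seed = seed_i)
    }, error = function(e) {
      stop(sprintf("iteration %d failed: %s", i, conditionMessage(e)))
    })
    iters[[i]] <- res
  }
  metrics <- data.frame(
    iteration = seq_len(cfg$n_iter),
    sensitivity = vapply(iters, function(r) r$eval$sensitivity, 0),
    specificity = vapply(iters, function(r) r$eval$specificity, 0),
    accuracy = vapply(iters, function(r) r$eval$accuracy, 0),
    auc = vapply(iters, function(r) r$eval$auc, 0),
    cutoff = vapply(iters, function(r) r$eval$cutoff, 0)
  )
  agg_cols <- c("sensitivity", "specificity", "accuracy", "auc")
  mu <- vapply(metrics[agg_cols], mean, 0)
  sdv <- if (cfg$n_iter > 1L) vapply(metrics[agg_cols], stats::sd, 0) else
    stats::setNames(rep(0, length(agg_cols)), agg_cols)
  structure(list(iterations = iters, metrics = metrics,
                 mean = mu, sd = sdv, config = unclass(cfg)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d iterations\n", nrow(x$metrics)))
  for (m in names(x$mean)) {
    cat(sprintf("  %-12s %.3f (SD %.3f)\n", m, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}

#' Dataset summary table
#'
#' Labeled count, per-class counts with round-half-up integer percentages,
#' and the number of unlabeled (discarded) measurements.
#'
#' @param set A `drs_set`.
#' @return List with `n_total`, `n_labeled`, `n_unlabeled`, and a `classes`
#'   data frame (`label`, `n`, `percent`; percent is `NA` when no
#'   measurements are labeled).
#' @export
summarize_dataset <- function(set) {
  stopifnot(inherits(set, "drs_set"))
  lab <- set$meta$label
  n_total <- length(lab)
  n_unlab <- sum(lab == "unlabeled")
  n_labeled <- n_total - n_unlab
  round_half_up <- function(x) floor(x + 0.5)
  cls <- data.frame(label = c("tumor", "healthy"),
                    n = c(sum(lab == "tumor"), sum(lab == "healthy")))
  cls$percent <- if (n_labeled > 0) round_half_up(100 * cls$n / n_labeled) else
    NA_real_
  list(n_total = n_total, n_labeled = n_labeled, n_unlabeled = n_unlab,
       classes = cls)
}

#' Run the full pipeline and write its reports
#'
#' Orchestrates SNV normalization, repeated patient-wise evaluation and
#' report writing. Outputs under `out_dir`: `report.json` (per-iteration and
#' aggregate metrics with a config echo), `ranked_features.tsv` and
#' `feature_spec.txt` (from the first iteration), and `roc.csv` (first
#' iteration's ROC points). Deterministic given config and seed; no
#' timestamps are written.
#'
#' @param set A `drs_set`.
#' @param cfg A `pipeline_config`.
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @return The `evaluation_report`, invisibly when writing.
#' @export
run_pipeline <- function(set, cfg = pipeline_config(), out_dir = NULL) {
  report <- run_repeated(set, cfg)
  if (is.null(out_dir)) return(report)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_echo <- report$config
  cfg_echo$C_grid <- as.numeric(cfg_echo$C_grid)
  cfg_echo$m_samples <- if (is.null(cfg_echo$m_samples)) "ALL" else
    cfg_echo$m_samples
  cfg_echo$max_pairs <- if (is.infinite(cfg_echo$max_pairs)) "ALL" else
    cfg_echo$max_pairs
  payload <- list(
    summary = summarize_dataset(set),
    iterations = report$metrics,
    mean = as.list(report$mean),
    sd = as.list(report$sd),
    config = cfg_echo
  )
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  it1 <- report$iterations[[1]]
  write_ranked_features(it1$ranked, file.path(out_dir, "ranked_features.tsv"))
  write_feature_spec(it1$spec, file.path(out_dir, "feature_spec.txt"))
  utils::write.csv(it1$eval$roc, file.path(out_dir, "roc.csv"),
                   row.names = FALSE)
  invisible(report)
}
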