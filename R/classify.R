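#' Patient-wise train/test split
#'
#' Patients (not measurements) are partitioned so that no patient contributes
#' to both sides; every measurement inherits its patient's side. The number
#' of training patients is `round(ratio * n_patients)`. If either side ends
#' up missing a class entirely, the split is redrawn with a new derived seed,
#' up to `max_retries` times.
#'
#' @param set A labeled `drs_set`.
#' @param ratio Training fraction of patients (default 0.70).
#' @param seed Integer seed.
#' @param max_retries Redraws allowed when a class is absent from one side.
#' @return List of class `split_plan`: `train_patients`, `test_patients`,
#'   `ratio`, `seed`.
#' @export
patient_split <- function(set, ratio = 0.70, seed = 1L, max_retries = 25L) {
  stopifnot(inherits(set, "drs_set"))
  lab <- set$meta$label %in% c("tumor", "healthy")
  meta <- set$meta[lab, , drop = FALSE]
  patients <- sort(unique(meta$patient_id))
  if (length(patients) < 2L) stop("need at least 2 labeled patients to split")
  n_train <- round(ratio * length(patients))
  if (n_train < 1L || n_train >= length(patients)) {
    stop("ratio leaves an empty training or test side")
  }
  for (attempt in 0:max_retries) {
    set.seed(seed + attempt * 1000003L)
    train <- sort(sample(patients, n_train))
    test <- setdiff(patients, train)
    lab_train <- meta$label[meta$patient_id %in% train]
    lab_test <- meta$label[meta$patient_id %in% test]
    if (all(c("tumor", "healthy") %in% lab_train) &&
        all(c("tumor", "healthy") %in% lab_test)) {
      return(structure(list(train_patients = train, test_patients = test,
                            ratio = ratio, seed = seed),
                       class = "split_plan"))
    }
  }
  stop("could not produce a split with both classes on both sides")
}

as_label_factor <- function(y) {
  y <- as.character(y)
  bad <- setdiff(unique(y), c("tumor", "healthy"))
  if (length(bad)) stop("unexpected label(s): ", paste(bad, collapse = ", "))
  factor(y, levels = c("healthy", "tumor"))
}

stratified_folds <- function(y, folds, seed) {
  # per-class shuffled round-robin assignment
  set.seed(seed)
  f <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

#' Train a linear SVM with cross-validated regularization
#'
#' Fits a linear-kernel support vector machine (hinge loss, L2 penalty).
#' Features are standardized with training-set mean/SD (stored in the model).
#' The cost parameter C is chosen from `C_grid` by mean accuracy over
#' `folds`-fold cross-validation, stratified by class; the model is then
#' refit on the full training data with the winning C. Decision values are
#' oriented so that larger values indicate tumor.
#'
#' @param x Feature matrix/data frame (training rows only).
#' @param y Labels (`"tumor"` / `"healthy"`).
#' @param C_grid Candidate cost values (default `c(0.01, 0.1, 1, 10, 100)`).
#' @param folds CV folds (default 10); clamped to the smallest class size.
#' @param seed Seed for fold assignment.
#' @return Object of class `linear_svm`: the fitted model plus `center`,
#'   `scale`, `C`, `cv_accuracy`, `features`, `flip`.
#' @export
train_classifier <- function(x, y, C_grid = c(0.01, 0.1, 1, 10, 100),
                             folds = 10, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as_label_factor(y)
  if (nlevels(droplevels(y)) < 2L) stop("training data contain a single class")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0)) {
    stop("degenerate (constant) feature(s): ",
         paste(colnames(x)[scl == 0], collapse = ", "))
  }
  xs <- scale(x, center = ctr, scale = scl)

  min_class <- min(table(y))
  if (folds > min_class) folds <- max(2L, min_class)
  fold_id <- stratified_folds(as.character(y), folds, seed)

  cv_acc <- vapply(C_grid, function(C) {
    acc <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      if (nlevels(droplevels(y[tr])) < 2L) return(NA_real_)
      fit <- e1071::svm(xs[tr, , drop = FALSE], y[tr], kernel = "linear",
                        cost = C, scale = FALSE)
      mean(predict(fit, xs[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1))
    mean(acc, na.rm = TRUE)
  }, numeric(1))
  C <- C_grid[which.max(cv_acc)]  # ties -> smallest C

  fit <- e1071::svm(xs, y, kernel = "linear", cost = C, scale = FALSE)
  # libsvm's decision-value sign depends on training order; orient tumor-high
  dv <- attr(predict(fit, xs, decision.values = TRUE), "decision.values")[, 1]
  flip <- if (mean(dv[y == "tumor"]) >= mean(dv[y == "healthy"])) 1 else -1
  structure(list(fit = fit, center = ctr, scale = scl, C = C,
                 cv_accuracy = stats::setNames(cv_acc, C_grid),
                 folds = folds, features = colnames(x), flip = flip),
            class = "linear_svm")
}

#' Decision values of a fitted linear SVM
#'
#' Signed distance-like score, oriented so that positive values predict
#' tumor; 0 is the classifier's native threshold.
#'
#' @param model A `linear_svm`.
#' @param x Feature matrix with the model's features.
#' @return Numeric vector of decision values.
#' @export
decision_values <- function(model, x) {
  stopifnot(inherits(model, "linear_svm"))
  x <- as.matrix(x[, model$features, drop = FALSE])
  xs <- scale(x, center = model$center, scale = model$scale)
  dv <- attr(predict(model$fit, xs, decision.values = TRUE),
             "decision.values")[, 1]
  model$flip * dv
}

#' Evaluate a classifier on a test set
#'
#' Confusion counts and the headline sensitivity/specificity/accuracy are
#' computed at the classifier's native threshold (decision value 0), with
#' tumor as the positive class. The ROC curve is built threshold-free by
#' sweeping the decision value over the test scores; AUC is the trapezoidal
#' area and the optimal cutoff maximizes Youden's J = sensitivity +
#' specificity - 1.
#'
#' @param model A `linear_svm`.
#' @param x Test feature matrix.
#' @param y Test labels; both classes must be present.
#' @return Object of class `iteration_result` with `sensitivity`,
#'   `specificity`, `accuracy`, `auc`, `roc` (data frame FPR/TPR),
#'   `cutoff`, `confusion` (TP/FP/TN/FN).
#' @export
evaluate_model <- function(model, x, y) {
  y <- as_label_factor(y)
  if (nlevels(droplevels(y)) < 2L) {
    stop("test set contains a single class; sensitivity or specificity undefined")
  }
  scores <- decision_values(model, x)
  pos <- y == "tumor"
  pred_pos <- scores > 0
  TP <- sum(pred_pos & pos); FN <- sum(!pred_pos & pos)
  TN <- sum(!pred_pos & !pos); FP <- sum(pred_pos & !pos)

  ra <- roc_analysis(scores, y)
  structure(list(
    sensitivity = TP / (TP + FN),
    specificity = TN / (TN + FP),
    accuracy = (TP + TN) / length(y),
    auc = ra$auc,
    roc = ra$roc,
    cutoff = ra$cutoff,
    confusion = c(TP = TP, FP = FP, TN = TN, FN = FN)
  ), class = "iteration_result")
}

#' ROC curve, trapezoidal AUC and Youden-optimal cutoff
#'
#' Builds the ROC curve by sweeping the score over all observed values (via
#' pROC), with tumor as the positive, high-score class. The trapezoidal AUC
#' equals the pairwise-concordance probability with ties counted one half.
#'
#' @param scores Numeric classifier scores (larger = more tumor-like).
#' @param labels Labels (`"tumor"` / `"healthy"`), or a factor thereof.
#' @return List: `auc`, `roc` (data frame `FPR`, `TPR`, both nondecreasing),
#'   `cutoff` (score threshold maximizing sensitivity + specificity - 1).
#' @export
roc_analysis <- function(scores, labels) {
  y <- as_label_factor(labels)
  if (nlevels(droplevels(y)) < 2L) stop("both classes required for a ROC curve")
  roc <- pROC::roc(response = y, predictor = scores,
                   levels = c("healthy", "tumor"), direction = "<",
                   quiet = TRUE)
  cut <- pROC::coords(roc, "best", best.method = "youden",
                      ret = "threshold", transpose = FALSE)
  list(auc = as.numeric(pROC::auc(roc)),
       roc = data.frame(FPR = rev(1 - roc$specificities),
                        TPR = rev(roc$sensitivities)),
       cutoff = cut$threshold[1])
}
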