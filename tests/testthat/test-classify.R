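make_feature_set <- function(n_patients = 10, per_patient = 4, sep = 2,
                             seed = 1) {
  # simple 2-feature cohort: class shifts feature means, patient effect shared
  set.seed(seed)
  rows <- list()
  for (p in seq_len(n_patients)) {
    eff <- rnorm(2, 0, 0.3)
    for (m in seq_len(per_patient)) {
      cls <- if (runif(1) < 0.5) "tumor" else "healthy"
      mu <- if (cls == "tumor") c(sep / 2, -sep / 2) else c(-sep / 2, sep / 2)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = sprintf("P%02d", p), location_id = paste0("L", m),
        label = cls, x1 = mu[1] + eff[1] + rnorm(1, 0, 0.3),
        x2 = mu[2] + eff[2] + rnorm(1, 0, 0.3))
    }
  }
  do.call(rbind, rows)
}

test_that("patient-wise splits partition patients at the requested ratio", {
  set <- toy_set(n = 20, labels = rep(c("tumor", "healthy"), 10),
                 patients = paste0("P", rep(1:10, each = 2)))
  plan <- patient_split(set, ratio = 0.7, seed = 4)
  expect_length(plan$train_patients, 7)
  expect_length(plan$test_patients, 3)
  expect_length(intersect(plan$train_patients, plan$test_patients), 0)
  expect_setequal(c(plan$train_patients, plan$test_patients),
                  unique(set$meta$patient_id))

  big <- toy_set(n = 200, labels = rep(c("tumor", "healthy"), 100),
                 patients = paste0("P", rep(1:100, each = 2)))
  expect_length(patient_split(big, seed = 1)$train_patients, 70)
})

test_that("splitting redraws until both classes appear on both sides", {
  # patients are single-class: naive splits frequently strand a class
  set <- toy_set(n = 8, labels = rep(c("tumor", "healthy"), each = 4),
                 patients = paste0("P", 1:8))
  for (s in 1:10) {
    plan <- patient_split(set, ratio = 0.5, seed = s)
    lab_tr <- set$meta$label[set$meta$patient_id %in% plan$train_patients]
    lab_te <- set$meta$label[set$meta$patient_id %in% plan$test_patients]
    expect_setequal(unique(lab_tr), c("tumor", "healthy"))
    expect_setequal(unique(lab_te), c("tumor", "healthy"))
  }
})

test_that("a separable training set is fit perfectly and scoring is tumor-high", {
  ft <- make_feature_set(sep = 4, seed = 2)
  model <- train_classifier(ft[, c("x1", "x2")], ft$label, seed = 1)
  scores <- decision_values(model, ft[, c("x1", "x2")])
  pred <- ifelse(scores > 0, "tumor", "healthy")
  expect_equal(mean(pred == ft$label), 1.0)
  expect_gt(mean(scores[ft$label == "tumor"]),
            mean(scores[ft$label == "healthy"]))
})

test_that("label-permuted data yield chance-level CV accuracy", {
  set.seed(10)
  accs <- replicate(20, {
    y <- rep(c("tumor", "healthy"), each = 20)
    x <- matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, c("x1", "x2")))
    m <- train_classifier(x, sample(y), C_grid = 1, folds = 5,
                          seed = sample.int(1e6, 1))
    max(m$cv_accuracy)
  })
  expect_gt(mean(accs), 0.3)
  expect_lt(mean(accs), 0.7)
})

test_that("training rejects single-class and constant-feature input", {
  ft <- make_feature_set()
  expect_error(train_classifier(ft[, c("x1", "x2")],
                                rep("tumor", nrow(ft))), "single class")
  ft$x2 <- 1
  expect_error(train_classifier(ft[, c("x1", "x2")], ft$label), "degenerate")
})

test_that("confusion metrics follow their definitions at threshold zero", {
  # train on widely separated 1-feature data so sign(x) decides the class,
  # then craft a test set that lands TP=8 FN=2 TN=9 FP=1
  set.seed(8)
  xtr <- matrix(c(rnorm(20, 10, 0.5), rnorm(20, -10, 0.5)), ncol = 1,
                dimnames = list(NULL, "s"))
  ytr <- c(rep("tumor", 20), rep("healthy", 20))
  model <- train_classifier(xtr, ytr, C_grid = 1, folds = 5, seed = 1)

  xte <- matrix(c(rep(5, 8), rep(-5, 2), rep(-5, 9), rep(5, 1)), ncol = 1,
                dimnames = list(NULL, "s"))
  yte <- c(rep("tumor", 10), rep("healthy", 10))
  res <- evaluate_model(model, xte, yte)
  expect_equal(res$confusion, c(TP = 8, FP = 1, TN = 9, FN = 2))
  expect_equal(res$sensitivity, 0.8)
  expect_equal(res$specificity, 0.9)
  expect_equal(res$accuracy, 0.85)

  # one-class test set is rejected
  expect_error(evaluate_model(model, xte, rep("tumor", 20)), "single class")
})

test_that("ROC analysis reproduces limiting cases and the concordance oracle", {
  y <- c(rep("tumor", 6), rep("healthy", 6))
  expect_equal(roc_analysis(c(1:6 + 10, 1:6), y)$auc, 1.0)   # separated
  expect_equal(roc_analysis(rep(5, 12), y)$auc, 0.5)         # all tied

  # one inversion among 6 scores: AUC = pairwise concordance
  s <- c(5, 4, 3, 2.5, 6, 1)
  y6 <- c("tumor", "tumor", "tumor", "healthy", "healthy", "healthy")
  expect_equal(roc_analysis(s, y6)$auc, oracle_auc(s, y6))

  expect_error(roc_analysis(1:5, rep("tumor", 5)), "both classes")
})

test_that("trapezoidal AUC equals the pairwise-concordance oracle on random scores", {
  set.seed(123)
  for (trial in 1:100) {
    n <- sample(4:12, 1)
    y <- c("tumor", "healthy",
           sample(c("tumor", "healthy"), n - 2, replace = TRUE))
    s <- sample(seq(0, 5, by = 0.5), n, replace = TRUE)  # ties likely
    expect_equal(roc_analysis(s, y)$auc, oracle_auc(s, y), tolerance = 1e-12)
  }
})

test_that("the Youden-optimal cutoff maximizes sensitivity + specificity", {
  s <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.2, 0.6, 0.1)
  y <- c(rep("tumor", 4), rep("healthy", 4))
  cut <- roc_analysis(s, y)$cutoff
  j_at <- function(t) {
    mean(s[y == "tumor"] > t) + mean(s[y == "healthy"] <= t) - 1
  }
  j_best <- max(sapply(sort(unique(s)) - 1e-9, j_at))
  expect_equal(j_at(cut), j_best)
})

test_that("the ROC curve is monotone nondecreasing in both coordinates", {
  set.seed(5)
  s <- rnorm(30)
  y <- sample(c("tumor", "healthy"), 30, replace = TRUE, prob = c(0.5, 0.5))
  roc <- roc_analysis(s, y)$roc
  expect_true(all(diff(roc$FPR) >= 0))
  expect_true(all(diff(roc$TPR) >= 0))
})
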