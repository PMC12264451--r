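sim_feature_matrix <- function(n_per_group = 25, delta = 0, seed = 1,
                               p_informative = 4) {
  set.seed(seed)
  n <- 2 * n_per_group
  X <- matrix(rnorm(n * 22), n, 22, dimnames = list(
    sprintf("P%03d", 1:n), feature_columns()))
  y <- rep(c(0L, 1L), each = n_per_group)
  X[y == 1, seq_len(p_informative)] <- X[y == 1, seq_len(p_informative)] + delta
  structure(list(X = X, y = y, subject_ids = rownames(X), positive = "TPE"),
            class = "feature_matrix")
}

test_that("feature matrix assembly: order, shape, and error paths", {
  set.seed(2)
  ids <- sprintf("P%02d", 1:6)
  g <- matrix(rnorm(54), 6, 9, dimnames = list(ids, feature_columns()[1:9]))
  r <- matrix(rnorm(78), 6, 13,
              dimnames = list(ids, tpenet:::rqa_feature_names()))
  labels <- stats::setNames(rep(c("TLE", "TPE"), 3), ids)
  fm <- assemble_feature_matrix(g, r, labels)
  expect_equal(dim(fm$X), c(6, 22))
  expect_identical(colnames(fm$X), feature_columns())
  expect_equal(fm$y, as.integer(labels[fm$subject_ids] == "TPE"))
  # single subject still yields 1 x 22
  fm1 <- assemble_feature_matrix(g[1, , drop = FALSE], r[1, , drop = FALSE],
                                 labels[1])
  expect_equal(dim(fm1$X), c(1, 22))
  # missing subject named in the error
  expect_error(assemble_feature_matrix(g, r[-2, ], labels), ids[2])
  # column names survive a write/read round-trip
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(subject_id = rownames(fm$X), fm$X,
                              check.names = FALSE), path, row.names = FALSE)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_identical(colnames(back)[-1], colnames(fm$X))
})

test_that("confusion metrics reproduce the defining formulas", {
  cm <- tpenet:::confusion_metrics(tp = 20, fn = 5, tn = 18, fp = 7)
  expect_equal(cm$accuracy, 0.76)
  expect_equal(cm$sensitivity, 0.80)
  expect_equal(cm$specificity, 0.72)
  expect_equal(cm$precision, 20 / 27)
  expect_equal(cm$f1, 40 / 52)
})

test_that("AUC equals the Mann-Whitney normalization on pooled scores", {
  set.seed(3)
  for (i in 1:10) {
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- rnorm(40) + y * runif(1, 0, 2)
    auc <- roc_curve(s, y)$auc
    u <- mean(outer(s[y == 1], s[y == 0],
                    function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(auc, u, tolerance = 1e-12)
  }
})

test_that("cross-validation: separable data, permuted labels, determinism", {
  # trivially separable data; logistic is excluded here because complete
  # separation makes its MLE degenerate by construction
  fm <- sim_feature_matrix(15, delta = 6, seed = 4)
  for (model in c("xgboost", "naive-bayes", "random-forest")) {
    rep <- crossval_evaluate(fm, model, k = 5, seed = 9)
    expect_gte(rep$auc, 0.95)
    expect_gte(rep$accuracy, 0.9)
    # metrics always recompute from stored counts
    expect_equal(rep$accuracy,
                 (rep$tp + rep$tn) / (rep$tp + rep$fn + rep$tn + rep$fp))
    expect_equal(rep$f1, 2 * rep$tp / (2 * rep$tp + rep$fp + rep$fn))
    expect_equal(rep$tp + rep$fn + rep$tn + rep$fp, length(fm$y))
  }
  # null features: AUC near chance over a few seeds
  aucs <- vapply(1:5, function(s) {
    crossval_evaluate(sim_feature_matrix(25, 0, seed = 20 + s),
                      "logistic", k = 10, seed = s)$auc
  }, numeric(1))
  expect_gte(mean(aucs > 0.35 & aucs < 0.65), 0.8)
  # determinism under a fixed seed
  r1 <- crossval_evaluate(fm, "xgboost", k = 5, seed = 11)
  r2 <- crossval_evaluate(fm, "xgboost", k = 5, seed = 11)
  expect_identical(r1$scores, r2$scores)
  expect_error(crossval_evaluate(fm, "svm", k = 16), "class size")
  # stratification keeps both classes in every training fold
  folds <- tpenet:::stratified_folds(fm$y, 5, seed = 3)
  for (f in 1:5) expect_length(unique(fm$y[folds != f]), 2)
})

test_that("all five models produce valid reports on one dataset", {
  fm <- sim_feature_matrix(10, delta = 1.5, seed = 6)
  for (model in classifier_models()) {
    rep <- crossval_evaluate(fm, model, k = 5, seed = 13)
    expect_true(all(rep$scores >= 0 & rep$scores <= 1))
    expect_true(rep$auc >= 0 && rep$auc <= 1)
    expect_equal(length(rep$scores), 20)
  }
})

test_that("DeLong test matches the placement-value oracle and pROC", {
  set.seed(7)
  y <- rep(c(1, 0), c(12, 14))
  sa <- rnorm(26) + y
  sb <- rnorm(26) + 0.5 * y
  res <- delong_compare(sa, sb, y)
  orc <- oracle_delong(sa, sb, y)
  expect_equal(res$auc_a, orc$auc_a, tolerance = 1e-12)
  expect_equal(res$auc_b, orc$auc_b, tolerance = 1e-12)
  expect_equal(res$z, orc$z, tolerance = 1e-12)
  expect_equal(res$p, orc$p, tolerance = 1e-12)
  # cross-check against the field-standard implementation
  pr <- pROC::roc.test(pROC::roc(y, sa, quiet = TRUE),
                       pROC::roc(y, sb, quiet = TRUE), method = "delong")
  expect_equal(res$p, pr$p.value, tolerance = 1e-9)
  # identical scores: z = 0, p = 1
  same <- delong_compare(sa, sa, y)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  expect_error(delong_compare(sa, sb, rep(1, 26)), "class")
})

test_that("SHAP: additivity, null feature, planted signal ranks first", {
  fm <- sim_feature_matrix(15, delta = 2, seed = 8, p_informative = 1)
  fm$X[, 22] <- 1   # constant feature carries no signal
  sh <- shap_analysis(fm, "xgboost", seed = 2)
  # additivity: per-subject SHAP + base = margin output
  expect_equal(rowSums(sh$shap) + sh$base_value, sh$pred, tolerance = 1e-5)
  # constant feature has exactly zero attribution
  expect_equal(unname(sh$importance[feature_columns()[22]]), 0)
  # the planted informative feature ranks first
  expect_equal(names(sh$importance)[1], feature_columns()[1])
  expect_equal(dim(sh$interaction), c(22, 22))
  # sampling approximation path for a non-tree model
  sh2 <- shap_analysis(fm, "logistic", seed = 3, n_perm = 10)
  expect_true(sh2$approximate)
  expect_null(sh2$interaction)
  expect_gte(which(names(sh2$importance) == feature_columns()[1]), 1)
})
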