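#' Canonical feature-matrix column order
#'
#' 9 graph-theoretical features followed by the 13 RQA features.
#' @return Character vector of 22 names.
#' @export
feature_columns <- function() {
  c("sigma", "gamma", "lambda", "e_global", "e_local",
    "dc_aIns", "dc_pIns", "ncf_aIns", "ncf_pIns",
    rqa_feature_names())
}

#' Assemble the subjects x 22 feature matrix
#'
#' Joins per-subject graph features (9) and RQA features (13) into one
#' matrix in the canonical column order, rows ordered by subject id.
#'
#' @param graph_feats Matrix/data.frame (subjects x 9) with rownames =
#'   subject ids and the graph feature columns.
#' @param rqa_feats Matrix/data.frame (subjects x 13) with rownames =
#'   subject ids and the RQA feature columns.
#' @param labels Named vector (by subject id) of group labels; `positive`
#'   marks the positive class.
#' @param positive Label treated as the positive class (default `"TPE"`).
#' @return Object of class `feature_matrix`: `X` (subjects x 22), `y`
#'   (0/1 integer, positive = 1), `subject_ids`, `positive`.
#' @export
assemble_feature_matrix <- function(graph_feats, rqa_feats, labels,
                                    positive = "TPE") {
  graph_feats <- as.matrix(graph_feats)
  rqa_feats <- as.matrix(rqa_feats)
  ids <- sort(rownames(graph_feats))
  missing_rqa <- setdiff(ids, rownames(rqa_feats))
  missing_graph <- setdiff(rownames(rqa_feats), ids)
  if (length(missing_rqa) || length(missing_graph)) {
    stop("subjects missing from ",
         if (length(missing_rqa)) paste("RQA set:", paste(missing_rqa, collapse = ", ")),
         if (length(missing_graph)) paste("graph set:", paste(missing_graph, collapse = ", ")))
  }
  gcols <- feature_columns()[1:9]
  rcols <- rqa_feature_names()
  X <- cbind(graph_feats[ids, gcols, drop = FALSE],
             rqa_feats[ids, rcols, drop = FALSE])
  if (any(!is.finite(X))) stop("feature matrix contains non-finite values")
  y <- as.integer(labels[ids] == positive)
  if (anyNA(y)) stop("labels missing for some subjects")
  structure(list(X = X, y = y, subject_ids = ids, positive = positive),
            class = "feature_matrix")
}

#' The five benchmarked classifier names
#' @return Character vector accepted by [crossval_evaluate()].
#' @export
classifier_models <- function() {
  c("xgboost", "logistic", "svm", "random-forest", "naive-bayes")
}

# Fit one model on (X, y) and return a scoring closure.
fit_model <- function(X, y, model, seed) {
  with_seed(seed, switch(
    model,
    "xgboost" = {
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3,
                      eta = 0.1, nthread = 1),
        data = xgboost::xgb.DMatrix(X, label = y), nrounds = 100,
        verbose = 0)
      function(newX) predict(fit, xgboost::xgb.DMatrix(newX))
    },
    "logistic" = {
      df <- data.frame(X, check.names = TRUE)
      fit <- suppressWarnings(glm(y ~ ., data = cbind(y = y, df),
                                  family = binomial()))
      function(newX) {
        # rank-deficiency warnings are structural when p approaches n
        suppressWarnings(as.numeric(
          predict(fit, data.frame(newX, check.names = TRUE),
                  type = "response")))
      }
    },
    "svm" = {
      fit <- e1071::svm(X, factor(y, levels = c(0, 1)), probability = TRUE,
                        kernel = "radial")
      function(newX) {
        pr <- attr(predict(fit, newX, probability = TRUE), "probabilities")
        as.numeric(pr[, "1"])
      }
    },
    "random-forest" = {
      fit <- randomForest::randomForest(X, factor(y, levels = c(0, 1)))
      function(newX) as.numeric(predict(fit, newX, type = "prob")[, "1"])
    },
    "naive-bayes" = {
      fit <- e1071::naiveBayes(data.frame(X), factor(y, levels = c(0, 1)))
      function(newX) {
        as.numeric(predict(fit, data.frame(newX), type = "raw")[, "1"])
      }
    },
    stop("unknown model: ", model)
  ))
}

# Stratified k-fold assignment (1..k per subject), seeded.
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' ROC curve and AUC from scores
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param y 0/1 labels.
#' @return List: `points` (data.frame `fpr`, `tpr` over all thresholds),
#'   `auc` (trapezoid area).
#' @export
roc_curve <- function(scores, y) {
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]
  # collapse tied scores to one threshold step
  steps <- c(diff(scores[o]) != 0, TRUE)
  tpr <- cumsum(ys) / sum(y)
  fpr <- cumsum(1 - ys) / sum(1 - y)
  tpr <- c(0, tpr[steps]); fpr <- c(0, fpr[steps])
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

confusion_metrics <- function(tp, fn, tn, fp) {
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       accuracy = (tp + tn) / (tp + fn + tn + fp),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_)
}

#' Cross-validated evaluation of one classifier
#'
#' Stratified k-fold cross-validation; out-of-fold scores are pooled,
#' thresholded at 0.5 into hard labels, and summarized by the confusion
#' matrix (positives = cases), accuracy, sensitivity, specificity,
#' precision, F1 and the pooled ROC/AUC.
#'
#' @param fm A `feature_matrix`.
#' @param model One of `"xgboost"`, `"logistic"`, `"svm"`,
#'   `"random-forest"`, `"naive-bayes"`.
#' @param k Folds (default 10).
#' @param seed Integer seed controlling folds and model randomness.
#' @return Object of class `classifier_report`: `model`, `scores`
#'   (out-of-fold, aligned to `fm$subject_ids`), `pred`, confusion counts
#'   and metrics, `roc`, `auc`, `folds`, `seed`.
#' @export
crossval_evaluate <- function(fm, model = classifier_models(), k = 10, seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  model <- match.arg(model)
  y <- fm$y
  if (k > min(table(y))) stop("k = ", k, " exceeds the smaller class size")
  folds <- stratified_folds(y, k, seed)
  fit_seeds <- split_seed(seed, k)
  scores <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- folds != f
    scorer <- fit_model(fm$X[tr, , drop = FALSE], y[tr], model, fit_seeds[f])
    scores[!tr] <- scorer(fm$X[!tr, , drop = FALSE])
  }
  pred <- as.integer(scores >= 0.5)
  cm <- confusion_metrics(tp = sum(pred == 1 & y == 1),
                          fn = sum(pred == 0 & y == 1),
                          tn = sum(pred == 0 & y == 0),
                          fp = sum(pred == 1 & y == 0))
  roc <- roc_curve(scores, y)
  structure(c(list(model = model, scores = scores, pred = pred,
                   subject_ids = fm$subject_ids, y = y,
                   roc = roc$points, auc = roc$auc, folds = folds,
                   seed = seed), cm),
            class = "classifier_report")
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of two classifiers' AUCs on the same subjects via
#' placement values: the variance of the AUC difference is estimated from
#' the empirical covariance of case and control placements, and the
#' two-sided p-value from the normal reference.
#'
#' @param scores_a,scores_b Score vectors aligned to the same subjects.
#' @param y 0/1 labels (1 = positive).
#' @return List: `auc_a`, `auc_b`, `z`, `p`, `var_diff`.
#' @export
delong_compare <- function(scores_a, scores_b, y) {
  stopifnot(length(scores_a) == length(y), length(scores_b) == length(y))
  if (length(unique(y)) != 2) stop("both classes must be present")
  pos <- y == 1
  m <- sum(pos); n <- sum(!pos)
  psi <- function(x_pos, x_neg) {
    outer(x_pos, x_neg, function(a, b) (a > b) + 0.5 * (a == b))
  }
  comp <- lapply(list(scores_a, scores_b), function(s) {
    P <- psi(s[pos], s[!pos])
    list(auc = mean(P), v10 = rowMeans(P), v01 = colMeans(P))
  })
  auc <- vapply(comp, `[[`, numeric(1), "auc")
  S10 <- cov(cbind(comp[[1]]$v10, comp[[2]]$v10))
  S01 <- cov(cbind(comp[[1]]$v01, comp[[2]]$v01))
  var_diff <- (S10[1, 1] + S10[2, 2] - 2 * S10[1, 2]) / m +
    (S01[1, 1] + S01[2, 2] - 2 * S01[1, 2]) / n
  if (var_diff <= 0) {
    z <- 0; p <- 1
  } else {
    z <- (auc[1] - auc[2]) / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  list(auc_a = auc[1], auc_b = auc[2], z = z, p = p, var_diff = var_diff)
}

#' SHAP importance and interactions
#'
#' For the boosted-tree model, exact TreeSHAP per-subject attributions and
#' pairwise interaction strengths; for other models a sampling
#' approximation of Shapley values (flagged in the result) with no
#' interaction matrix.
#'
#' @param fm A `feature_matrix`.
#' @param model Model name (see [crossval_evaluate()]).
#' @param seed Integer seed.
#' @param n_perm Permutations per subject for the sampling approximation.
#' @return List: `shap` (subjects x features attribution matrix),
#'   `base_value`, `importance` (mean |SHAP| per feature, sorted),
#'   `interaction` (features x features mean |interaction|, tree model
#'   only), `approximate` flag, `pred` (model output per subject).
#' @export
shap_analysis <- function(fm, model = "xgboost", seed = 1, n_perm = 50) {
  stopifnot(inherits(fm, "feature_matrix"))
  X <- fm$X
  if (model == "xgboost") {
    fit <- with_seed(seed, xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3,
                    eta = 0.1, nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = fm$y), nrounds = 100,
      verbose = 0))
    dm <- xgboost::xgb.DMatrix(X)
    contrib <- predict(fit, dm, predcontrib = TRUE)
    shap <- contrib[, colnames(X), drop = FALSE]
    base <- contrib[, ncol(contrib)]     # bias/intercept column
    inter <- predict(fit, dm, predinteraction = TRUE)
    imat <- apply(abs(inter[, colnames(X), colnames(X)]), c(2, 3), mean)
    pred_margin <- predict(fit, dm, outputmargin = TRUE)
    approx <- FALSE
  } else {
    scorer <- fit_model(X, fm$y, model, seed)
    base_pred <- mean(scorer(X))
    p <- ncol(X)
    shap <- matrix(0, nrow(X), p, dimnames = dimnames(X))
    perms <- with_seed(seed, replicate(n_perm, sample(p), simplify = FALSE))
    ref <- colMeans(X)
    for (i in seq_len(nrow(X))) {
      phi <- numeric(p)
      for (pm in perms) {
        cur <- ref
        prev <- scorer(matrix(cur, 1, dimnames = list(NULL, colnames(X))))
        for (j in pm) {
          cur[j] <- X[i, j]
          now <- scorer(matrix(cur, 1, dimnames = list(NULL, colnames(X))))
          phi[j] <- phi[j] + (now - prev)
          prev <- now
        }
      }
      shap[i, ] <- phi / n_perm
    }
    base <- rep(base_pred, nrow(X))
    imat <- NULL
    pred_margin <- scorer(X)
    approx <- TRUE
  }
  importance <- sort(colMeans(abs(shap)), decreasing = TRUE)
  list(shap = shap, base_value = base, importance = importance,
       interaction = imat, approximate = approx, pred = pred_margin)
}
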