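# Suckling-block detection: evaluation metrics, stratified splits, a native
# AdaBoost.M1 over depth-limited rpart trees, repeated holdout, a CV
# model-selection harness, leave-one-individual-out evaluation and
# random-forest Gini-importance feature pruning.

.positive_class <- "suckling"

#' Confusion counts from labels
#'
#' @param truth,pred character/factor vectors; positive class is
#'   `"suckling"`.
#' @param positive positive class label.
#' @return Named integer vector `c(tp, tn, fp, fn)`.
#' @export
confusion_counts <- function(truth, pred, positive = .positive_class) {
  t_pos <- truth == positive
  p_pos <- pred == positive
  c(tp = sum(t_pos & p_pos), tn = sum(!t_pos & !p_pos),
    fp = sum(!t_pos & p_pos), fn = sum(t_pos & !p_pos))
}

#' Evaluation metrics from confusion counts
#'
#' Sensitivity = TP/(TP+FN); Precision = TP/(TP+FP);
#' FPR = 1 - Specificity with Specificity = TN/(TN+FP);
#' F-score = 2TP/(2TP+FP+FN) (the harmonic mean of precision and
#' sensitivity); Global accuracy = (TP+TN)/total. Metrics with a zero
#' denominator are returned as `NA` (an explicit undefined flag), never as
#' a silent 0.
#'
#' @param counts named vector with `tp`, `tn`, `fp`, `fn`.
#' @return Named list: `sensitivity`, `precision`, `fpr`, `specificity`,
#'   `f_score`, `global_accuracy`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts[["tp"]]; tn <- counts[["tn"]]
  fp <- counts[["fp"]]; fn <- counts[["fn"]]
  total <- tp + tn + fp + fn
  if (total == 0) stop("no evaluated blocks: all confusion counts are zero")
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  spec <- div(tn, tn + fp)
  list(
    sensitivity = div(tp, tp + fn),
    precision = div(tp, tp + fp),
    fpr = if (is.na(spec)) NA_real_ else 1 - spec,
    specificity = spec,
    f_score = div(2 * tp, 2 * tp + fp + fn),
    global_accuracy = (tp + tn) / total
  )
}

#' Stratified train/test split
#'
#' Shuffles each class independently under the seed and assigns
#' `round(train_frac * class size)` blocks per class to the training set,
#' so the class ratio is maintained to within one block.
#'
#' @param labels class label vector.
#' @param train_frac training fraction.
#' @param seed RNG seed.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(labels, train_frac, seed) {
  set.seed(seed)
  train <- integer(0)
  for (cl in sort(unique(as.character(labels)))) {
    idx <- which(labels == cl)
    if (length(idx) < 2L) stop("class '", cl, "' has fewer than 2 members")
    idx <- sample(idx)
    n_train <- round(train_frac * length(idx))
    train <- c(train, idx[seq_len(n_train)])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Train an AdaBoost.M1 ensemble
#'
#' Standard AdaBoost.M1 with depth-limited classification trees as weak
#' learners: uniform initial weights; each round fits a tree on the weighted
#' sample, the weighted error `e_m` is computed, the round coefficient is
#' `alpha_m = ln((1 - e_m)/e_m)`, weights of misclassified samples are
#' multiplied by `exp(alpha_m)` and renormalized. Training stops early when
#' `e_m >= 0.5` (the learner is no better than chance; with no accepted
#' round a warning is raised) or when `e_m = 0` (alpha capped at
#' `ln((1 - 1e-10)/1e-10)`). Prediction is the sign of the
#' alpha-weighted vote.
#'
#' @param x feature `data.frame` (numeric columns).
#' @param y class labels (2 classes; `"suckling"` is the positive class
#'   when present, otherwise the second factor level).
#' @param n_rounds maximum boosting rounds.
#' @param max_depth weak-learner tree depth.
#' @param seed RNG seed (tree fitting is deterministic; the seed pins any
#'   tie-breaking).
#' @return Object of class `adaboost_m1` with `trees`, `alphas`, `classes`
#'   (negative, positive) and training metadata.
#' @export
train_adaboost_m1 <- function(x, y, n_rounds = 40, max_depth = 2, seed = 1) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2L) {
    stop("AdaBoost.M1 needs exactly 2 classes, got ", length(classes))
  }
  pos <- if (.positive_class %in% classes) .positive_class else classes[2]
  neg <- setdiff(classes, pos)
  yy <- ifelse(y == pos, 1, -1)
  n <- length(yy)
  set.seed(seed)
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  errors <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0, minsplit = 4,
                               minbucket = 2, xval = 0, maxcompete = 0,
                               maxsurrogate = 0, usesurrogate = 0)
  dat <- data.frame(.y = factor(yy, levels = c(-1, 1)), x,
                    check.names = FALSE)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = dat, weights = w * n, method = "class",
                        control = ctrl)
    h <- as.numeric(as.character(predict(fit, dat, type = "class")))
    mis <- h != yy
    eps <- sum(w[mis])
    if (eps >= 0.5) {
      if (!length(trees)) {
        warning("first weak learner no better than chance; empty ensemble")
      }
      break
    }
    if (eps <= 0) {
      alpha <- log((1 - 1e-10) / 1e-10)
      trees[[length(trees) + 1L]] <- fit
      alphas <- c(alphas, alpha)
      errors <- c(errors, eps)
      break
    }
    alpha <- log((1 - eps) / eps)
    trees[[length(trees) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    errors <- c(errors, eps)
    w[mis] <- w[mis] * exp(alpha)
    w <- w / sum(w)
  }
  structure(
    list(trees = trees, alphas = alphas, round_errors = errors,
         classes = c(negative = neg, positive = pos),
         features = names(x),
         meta = list(n_rounds = n_rounds, max_depth = max_depth, seed = seed)),
    class = "adaboost_m1"
  )
}

#' Predict with an AdaBoost.M1 ensemble
#'
#' @param object an `adaboost_m1` model.
#' @param newdata feature `data.frame`.
#' @param type `"class"` for labels, `"score"` for the signed weighted vote.
#' @param ... unused.
#' @return Labels or scores; an empty ensemble predicts the negative class
#'   everywhere (score 0).
#' @export
predict.adaboost_m1 <- function(object, newdata, type = c("class", "score"),
                                ...) {
  type <- match.arg(type)
  score <- numeric(nrow(newdata))
  dat <- data.frame(newdata, check.names = FALSE)
  for (m in seq_along(object$trees)) {
    h <- as.numeric(as.character(predict(object$trees[[m]], dat,
                                         type = "class")))
    score <- score + object$alphas[m] * h
  }
  if (type == "score") return(score)
  ifelse(score > 0, object$classes[["positive"]], object$classes[["negative"]])
}

#' @export
print.adaboost_m1 <- function(x, ...) {
  cat(sprintf("<adaboost_m1> %d rounds (depth %d trees), %d features\n",
              length(x$trees), x$meta$max_depth, length(x$features)))
  invisible(x)
}

# Stratified k-fold assignment.
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in sort(unique(as.character(labels)))) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Hyperparameter selection by cross-validated error
#'
#' Seeded random search over a candidate list: each evaluation measures the
#' mean stratified `k`-fold cross-validation misclassification rate of an
#' AdaBoost.M1 with the candidate's `n_rounds`/`max_depth`; exactly
#' `budget` evaluations are spent (candidates are drawn in a seeded random
#' order, cycling when the budget exceeds the candidate count) and the
#' configuration with the lowest error is returned.
#'
#' @param x feature `data.frame`.
#' @param y class labels.
#' @param candidates list of lists with `n_rounds` and `max_depth`.
#' @param k folds.
#' @param budget number of objective evaluations.
#' @param seed RNG seed.
#' @return List: `best` (the winning candidate), `cv_error`,
#'   `n_evaluations` and the full `history` data frame.
#' @export
select_model <- function(x, y, candidates, k = 5, budget = length(candidates),
                         seed = 1) {
  if (!length(candidates)) stop("no candidate configurations")
  if (budget < 1) stop("budget must be at least 1")
  fold <- stratified_folds(y, k, derive_seed(seed, 77))
  cv_error <- function(cand) {
    errs <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      model <- train_adaboost_m1(x[tr, , drop = FALSE], y[tr],
                                 n_rounds = cand$n_rounds,
                                 max_depth = cand$max_depth,
                                 seed = derive_seed(seed, f))
      mean(predict(model, x[!tr, , drop = FALSE]) != y[!tr])
    }, numeric(1))
    mean(errs)
  }
  set.seed(derive_seed(seed, 13))
  order_idx <- rep_len(sample(seq_along(candidates)), budget)
  history <- data.frame(candidate = order_idx, cv_error = NA_real_)
  for (i in seq_len(budget)) {
    history$cv_error[i] <- cv_error(candidates[[order_idx[i]]])
  }
  best_row <- which.min(history$cv_error)
  list(best = candidates[[history$candidate[best_row]]],
       cv_error = history$cv_error[best_row],
       n_evaluations = budget,
       history = history)
}

# Evaluate one trained model on a test set.
evaluate_model <- function(model, x_test, y_test) {
  compute_metrics(confusion_counts(y_test, predict(model, x_test)))
}

#' Repeated stratified holdout evaluation
#'
#' For each run: stratified split at `train_frac`, AdaBoost.M1 training on
#' the training portion, metric evaluation on the held-out portion.
#' Undefined metrics (zero denominators) are dropped from the mean/SD with
#' their count noted.
#'
#' @param blocks block table (retained rows) with `label` and the feature
#'   columns.
#' @param train_frac training fraction (0.6 for a 60:40 split).
#' @param runs number of repeated runs.
#' @param seed experiment seed; per-run seeds are derived by fixed offsets.
#' @param n_rounds,max_depth AdaBoost.M1 hyperparameters.
#' @param feature_cols feature columns to use (default all 43).
#' @return List: `summary` (per-metric mean, sd over defined runs,
#'   n_defined) and `runs` (per-run metric data frame).
#' @export
repeated_holdout <- function(blocks, train_frac = 0.6, runs = 30, seed = 1,
                             n_rounds = 40, max_depth = 2,
                             feature_cols = block_feature_names()) {
  x <- blocks[, feature_cols, drop = FALSE]
  y <- blocks$label
  per_run <- vector("list", runs)
  for (r in seq_len(runs)) {
    sp <- stratified_split(y, train_frac, derive_seed(seed, r))
    model <- train_adaboost_m1(x[sp$train, , drop = FALSE], y[sp$train],
                               n_rounds = n_rounds, max_depth = max_depth,
                               seed = derive_seed(seed, 1000 + r))
    met <- evaluate_model(model, x[sp$test, , drop = FALSE], y[sp$test])
    per_run[[r]] <- as.data.frame(met)
  }
  runs_df <- do.call(rbind, per_run)
  summ <- do.call(rbind, lapply(names(runs_df), function(mname) {
    v <- runs_df[[mname]]
    ok <- !is.na(v)
    data.frame(metric = mname,
               mean = if (any(ok)) mean(v[ok]) else NA_real_,
               sd = if (sum(ok) > 1L) stats::sd(v[ok]) else NA_real_,
               n_defined = sum(ok))
  }))
  list(summary = summ, runs = runs_df)
}

#' Leave-one-individual-out evaluation
#'
#' One experiment per individual: train on all other individuals' retained
#' blocks, evaluate on the held-out individual. Reports the metrics plus
#' the block counts and class balances of each combination. An individual
#' with no suckling blocks in its test set yields undefined-flag metrics,
#' not an error.
#'
#' @param blocks block table with `individual`, `label` and features.
#' @param feature_cols feature columns to use.
#' @param n_rounds,max_depth AdaBoost.M1 hyperparameters.
#' @param seed RNG seed.
#' @return `data.frame` with one row per held-out individual: metrics,
#'   `n_train`, `n_test`, `train_suckling_pct`, `test_suckling_pct`.
#' @export
leave_one_individual_out <- function(blocks,
                                     feature_cols = block_feature_names(),
                                     n_rounds = 40, max_depth = 2, seed = 1) {
  inds <- sort(unique(blocks$individual))
  if (length(inds) < 2L) stop("need at least 2 individuals")
  rows <- lapply(seq_along(inds), function(i) {
    ind <- inds[i]
    tr <- blocks$individual != ind
    model <- train_adaboost_m1(blocks[tr, feature_cols, drop = FALSE],
                               blocks$label[tr], n_rounds = n_rounds,
                               max_depth = max_depth,
                               seed = derive_seed(seed, i))
    met <- evaluate_model(model, blocks[!tr, feature_cols, drop = FALSE],
                          blocks$label[!tr])
    data.frame(
      held_out = ind,
      as.data.frame(met),
      n_train = sum(tr), n_test = sum(!tr),
      train_suckling_pct = 100 * mean(blocks$label[tr] == .positive_class),
      test_suckling_pct = 100 * mean(blocks$label[!tr] == .positive_class),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Rank features by their contribution to inter-individual differences
#'
#' Trains a random forest to classify the individual from the 43 features
#' of suckling blocks only, and returns the out-of-bag error together with
#' each feature's mean Gini (impurity) decrease. A low OOB error means the
#' individuals are easily told apart from their suckling kinematics; the
#' top-ranked features are the ones carrying that individual signal.
#'
#' @param blocks suckling blocks with `individual` and feature columns.
#' @param feature_cols feature columns.
#' @param seed RNG seed (forest growth is seeded, so the ranking is
#'   deterministic).
#' @param ntree forest size.
#' @return List of class `importance_ranking`: `importance` (named,
#'   sorted decreasing), `ranking` (feature names in rank order),
#'   `oob_error` (fraction).
#' @export
rank_features_by_individual <- function(blocks,
                                        feature_cols = block_feature_names(),
                                        seed = 1, ntree = 500) {
  y <- factor(blocks$individual)
  if (nlevels(y) < 2L) stop("need at least 2 individuals")
  if (any(table(y) < 2L)) stop("every individual needs >= 2 suckling blocks")
  set.seed(seed)
  rf <- randomForest::randomForest(x = blocks[, feature_cols, drop = FALSE],
                                   y = y, ntree = ntree, importance = FALSE)
  imp <- rf$importance[, "MeanDecreaseGini"]
  imp <- sort(imp, decreasing = TRUE)
  structure(
    list(importance = imp, ranking = names(imp),
         oob_error = unname(rf$err.rate[ntree, "OOB"])),
    class = "importance_ranking"
  )
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat(sprintf("<importance_ranking> OOB error %.2f%%; top features: %s\n",
              100 * x$oob_error,
              paste(utils::head(x$ranking, 5), collapse = ", ")))
  invisible(x)
}

#' Exclude top features at the importance knee
#'
#' Mode `"knee"` cuts the importance profile at the largest consecutive
#' drop of the sorted importances and excludes everything above the cut
#' (flat profiles exclude nothing, with a warning); mode `"threshold"`
#' excludes all features with importance above `tau`.
#'
#' @param ranking an `importance_ranking`.
#' @param mode `"knee"` or `"threshold"`.
#' @param tau importance threshold for mode `"threshold"`.
#' @return List: `excluded` and `retained` feature name vectors.
#' @export
exclude_by_knee <- function(ranking, mode = c("knee", "threshold"),
                            tau = NULL) {
  mode <- match.arg(mode)
  imp <- ranking$importance
  if (length(imp) < 3L) stop("need at least 3 ranked features")
  if (mode == "threshold") {
    if (is.null(tau)) stop("mode 'threshold' needs tau")
    excluded <- names(imp)[imp > tau]
  } else {
    drops <- -diff(imp)
    if (max(drops) <= 1e-12) {
      warning("flat importance profile: no knee, nothing excluded")
      excluded <- character(0)
    } else {
      excluded <- names(imp)[seq_len(which.max(drops))]
    }
  }
  list(excluded = excluded, retained = setdiff(names(imp), excluded))
}
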