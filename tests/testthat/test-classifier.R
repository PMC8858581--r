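# Detection machinery: evaluation metrics and their identities, stratified
# splitting, the native AdaBoost.M1 (weight math, stopping rules, boosting
# behavior on toys), model selection, holdout/LOIO harnesses, random-forest
# importance ranking and the knee/threshold exclusion rule.

test_that("metrics reproduce the worked confusion example", {
  m <- compute_metrics(c(tp = 90, tn = 2998, fp = 8, fn = 34))
  expect_equal(m$sensitivity, 0.7258, tolerance = 1e-4)
  expect_equal(m$precision, 0.9184, tolerance = 1e-4)
  expect_equal(m$f_score, 0.8108, tolerance = 1e-4)
  expect_equal(m$fpr, 1 - 2998 / 3006)
  expect_equal(m$global_accuracy, (90 + 2998) / 3130)
})

test_that("perfect and undefined cases are flagged, never silent zeros", {
  p <- compute_metrics(c(tp = 7, tn = 13, fp = 0, fn = 0))
  expect_equal(p$sensitivity, 1)
  expect_equal(p$precision, 1)
  expect_equal(p$f_score, 1)
  u <- compute_metrics(c(tp = 0, tn = 10, fp = 0, fn = 0))
  expect_true(is.na(u$sensitivity)) # TP + FN = 0
  expect_true(is.na(u$precision))   # TP + FP = 0
  expect_error(compute_metrics(c(tp = 0, tn = 0, fp = 0, fn = 0)), "zero")
})

test_that("metric identities hold on random confusion counts", {
  set.seed(8)
  for (rep in 1:25) {
    cc <- c(tp = rpois(1, 40) + 1, tn = rpois(1, 400) + 1,
            fp = rpois(1, 10) + 1, fn = rpois(1, 15) + 1)
    m <- compute_metrics(cc)
    expect_equal(m$fpr, 1 - m$specificity)
    # F equals the harmonic mean of precision and sensitivity
    expect_equal(m$f_score,
                 2 / (1 / m$precision + 1 / m$sensitivity))
    # global accuracy invariant under swapping both truth and prediction
    sw <- compute_metrics(c(tp = cc[["tn"]], tn = cc[["tp"]],
                            fp = cc[["fn"]], fn = cc[["fp"]]))
    expect_equal(m$global_accuracy, sw$global_accuracy)
  }
})

test_that("confusion counts sum to the number of evaluated blocks", {
  set.seed(9)
  truth <- sample(c("suckling", "non-suckling"), 200, replace = TRUE)
  pred <- sample(c("suckling", "non-suckling"), 200, replace = TRUE)
  expect_equal(sum(confusion_counts(truth, pred)), 200)
})

test_that("stratified splits keep class ratios and are seeded", {
  labels <- rep(c("suckling", "non-suckling"), c(50, 50))
  sp <- stratified_split(labels, 0.6, seed = 4)
  expect_length(sp$train, 60)
  expect_equal(sum(labels[sp$train] == "suckling"), 30)
  expect_identical(sp, stratified_split(labels, 0.6, seed = 4))
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  # unbalanced: train ratio within one block of the global ratio
  lab2 <- rep(c("suckling", "non-suckling"), c(37, 263))
  sp2 <- stratified_split(lab2, 0.6, seed = 4)
  got <- sum(lab2[sp2$train] == "suckling")
  expect_lte(abs(got - 0.6 * 37), 1)
  expect_error(stratified_split(c("a", "b", "b"), 0.6, 1), "fewer than 2")
})

test_that("adaboost round weights follow alpha = ln((1-e)/e)", {
  # 1-D data separable except one flipped point: the stump errs on exactly
  # that point, a weighted error of 1/10
  x <- data.frame(f = c(1:5, 6:10))
  y <- c(rep("non-suckling", 5), rep("suckling", 5))
  y[1] <- "suckling" # flipped
  m <- train_adaboost_m1(x, y, n_rounds = 1, max_depth = 1, seed = 1)
  expect_equal(m$round_errors[1], 0.1)
  expect_equal(m$alphas[1], log(9), tolerance = 1e-10)
})

test_that("boosting drives training error to zero on separable toys", {
  set.seed(13)
  n <- 120
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  # a quadrant rule a depth-2 tree can express exactly
  y <- ifelse(x$a > 0 & x$b > 0, "suckling", "non-suckling")
  m <- train_adaboost_m1(x, y, n_rounds = 10, max_depth = 2, seed = 1)
  expect_lte(length(m$trees), 10)
  expect_equal(mean(predict(m, x) != y), 0)
  expect_true(all(m$alphas > 0))
  expect_true(all(m$round_errors < 0.5))
  # on a diagonal boundary (not axis-expressible) the weighted-error bound
  # still shrinks and the ensemble improves monotonically overall
  yd <- ifelse(x$a + x$b > 0, "suckling", "non-suckling")
  md <- train_adaboost_m1(x, yd, n_rounds = 25, max_depth = 2, seed = 1)
  errs <- vapply(seq_along(md$trees), function(k) {
    part <- md
    part$trees <- md$trees[1:k]
    part$alphas <- md$alphas[1:k]
    mean(predict(part, x) != yd)
  }, numeric(1))
  expect_lt(errs[length(errs)], errs[1])
  expect_true(all(md$round_errors < 0.5))
  # the exponential training-error bound is strictly decreasing
  bound <- cumprod(2 * sqrt(md$round_errors * (1 - md$round_errors)))
  expect_true(all(diff(bound) < 0))
  expect_true(all(errs <= bound + 1e-12))
})

test_that("an unlearnable round stops training with a warning", {
  x <- data.frame(f = rep(1, 40)) # constant feature: no split possible
  y <- rep(c("suckling", "non-suckling"), 20)
  expect_warning(m <- train_adaboost_m1(x, y, n_rounds = 5, seed = 1),
                 "chance")
  expect_length(m$trees, 0)
  expect_true(all(predict(m, x) == "non-suckling")) # empty ensemble: negative
  expect_error(train_adaboost_m1(x, rep("suckling", 40)), "2 classes")
})

test_that("a perfect round caps alpha and stops", {
  x <- data.frame(f = c(rep(0, 20), rep(1, 20)))
  y <- rep(c("non-suckling", "suckling"), each = 20)
  m <- train_adaboost_m1(x, y, n_rounds = 10, max_depth = 1, seed = 1)
  expect_length(m$trees, 1)
  expect_equal(m$alphas[1], log((1 - 1e-10) / 1e-10))
})

test_that("model selection spends its budget and picks the winner", {
  blocks <- fake_blocks(n = 200, signal = 0)
  # plant an interaction only depth-2 trees can express
  set.seed(17)
  blocks$f1 <- rnorm(200)
  blocks$f2 <- rnorm(200)
  blocks$label <- ifelse(xor(blocks$f1 > 0, blocks$f2 > 0),
                         "suckling", "non-suckling")
  x <- blocks[, paste0("f", 1:6)]
  cands <- list(list(n_rounds = 1, max_depth = 1),
                list(n_rounds = 20, max_depth = 2))
  wins <- vapply(1:5, function(s) {
    sel <- select_model(x, blocks$label, cands, k = 5, budget = 4, seed = s)
    expect_equal(sel$n_evaluations, 4)
    sel$best$max_depth
  }, numeric(1))
  expect_true(all(wins == 2)) # the dominant configuration wins every run
  one <- select_model(x, blocks$label, cands[1], budget = 1, seed = 1)
  expect_equal(one$best, cands[[1]])
  expect_error(select_model(x, blocks$label, cands, budget = 0), "budget")
})

test_that("repeated holdout aggregates seeded runs", {
  blocks <- fake_blocks(n = 300, signal = 3)
  rh <- repeated_holdout(blocks, 0.6, runs = 3, seed = 2,
                         n_rounds = 10, max_depth = 1,
                         feature_cols = paste0("f", 1:6))
  expect_equal(nrow(rh$runs), 3)
  expect_true(all(c("sensitivity", "precision", "fpr", "f_score") %in%
                    rh$summary$metric))
  rh2 <- repeated_holdout(blocks, 0.6, runs = 3, seed = 2,
                          n_rounds = 10, max_depth = 1,
                          feature_cols = paste0("f", 1:6))
  expect_identical(rh$summary, rh2$summary)
  one <- repeated_holdout(blocks, 0.6, runs = 1, seed = 2, n_rounds = 5,
                          max_depth = 1, feature_cols = paste0("f", 1:6))
  expect_true(all(is.na(one$summary$sd))) # no SD from a single run
})

test_that("LOIO builds one combination per individual", {
  blocks <- fake_blocks(n = 300, signal = 3,
                        individuals = c("A", "B", "C"))
  lo <- leave_one_individual_out(blocks, feature_cols = paste0("f", 1:6),
                                 n_rounds = 10, max_depth = 1, seed = 3)
  expect_equal(nrow(lo), 3)
  expect_setequal(lo$held_out, c("A", "B", "C"))
  expect_equal(lo$n_train + lo$n_test, rep(300, 3))
  two <- leave_one_individual_out(fake_blocks(n = 200, signal = 3),
                                  feature_cols = paste0("f", 1:6),
                                  n_rounds = 10, max_depth = 1, seed = 3)
  expect_equal(nrow(two), 2)
  # an individual with no suckling blocks in test gets NA flags, not a crash
  blocks3 <- fake_blocks(n = 300, signal = 3,
                         individuals = c("A", "B", "C"))
  blocks3$label[blocks3$individual == "C"] <- "non-suckling"
  lo3 <- leave_one_individual_out(blocks3, feature_cols = paste0("f", 1:6),
                                  n_rounds = 10, max_depth = 1, seed = 3)
  expect_true(is.na(lo3$sensitivity[lo3$held_out == "C"]))
  expect_error(leave_one_individual_out(fake_blocks(individuals = "A")),
               "2 individuals")
})

test_that("importance ranking finds planted individual signal", {
  set.seed(19)
  n <- 240
  blocks <- data.frame(individual = rep(c("A", "B", "C"), each = n / 3))
  for (f in paste0("f", 1:8)) blocks[[f]] <- rnorm(n)
  blocks$f3 <- blocks$f3 + 3 * as.integer(factor(blocks$individual))
  rk <- rank_features_by_individual(blocks, feature_cols = paste0("f", 1:8),
                                    seed = 7, ntree = 300)
  expect_equal(rk$ranking[1], "f3")
  expect_lt(rk$oob_error, 0.25) # far below the 2/3 chance level
  rk2 <- rank_features_by_individual(blocks, feature_cols = paste0("f", 1:8),
                                     seed = 7, ntree = 300)
  expect_identical(rk$importance, rk2$importance)
  # pure noise, 3 balanced classes: OOB error near chance (2/3)
  noise <- blocks
  noise$f3 <- rnorm(n)
  rkn <- rank_features_by_individual(noise, feature_cols = paste0("f", 1:8),
                                     seed = 7, ntree = 300)
  expect_equal(rkn$oob_error, 2 / 3, tolerance = 0.15)
  expect_error(rank_features_by_individual(blocks[blocks$individual == "A", ],
                                           feature_cols = paste0("f", 1:8)),
               "2 individuals")
})

test_that("knee and threshold exclusion agree on the constructed profile", {
  imp <- c(10, 9, 8, 7, 6, 5.5, 5, 4.5, 4.2, 1.2, 1.1, 1.0, 0.9)
  names(imp) <- paste0("f", seq_along(imp))
  rk <- structure(list(importance = imp, ranking = names(imp),
                       oob_error = 0.05), class = "importance_ranking")
  knee <- exclude_by_knee(rk, mode = "knee")
  expect_length(knee$excluded, 9) # the largest drop sits after the 9th
  expect_identical(knee$excluded, paste0("f", 1:9))
  thr <- exclude_by_knee(rk, mode = "threshold", tau = 4)
  expect_identical(sort(thr$excluded), sort(knee$excluded))
  expect_setequal(c(knee$excluded, knee$retained), names(imp))

  flat <- rk
  flat$importance <- setNames(rep(2, 5), paste0("f", 1:5))
  expect_warning(none <- exclude_by_knee(flat), "flat")
  expect_length(none$excluded, 0)
  short <- rk
  short$importance <- imp[1:2]
  expect_error(exclude_by_knee(short), "3 ranked")
})
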