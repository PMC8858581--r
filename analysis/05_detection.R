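# Supervised detection of suckling blocks: hyperparameter selection by
# stratified cross-validation, repeated 60:40 holdout evaluation, and the
# training-set-size curve (60:40 down to 10:90). Writes
# results/holdout_curve.csv.

source("analysis/00_common.R")

ret <- get_retained_blocks()$retained
cat(sprintf("Retained blocks: %d (%.1f%% suckling)\n\n",
            nrow(ret), 100 * mean(ret$label == "suckling")))

# Model selection over a small AdaBoost.M1 grid (the weak-learner depth and
# the number of rounds), minimizing 5-fold stratified CV error on one 60%
# training split -- the in-distribution procedure a field study would run.
sp <- stratified_split(ret$label, 0.6, seed = 11)
cands <- list(list(n_rounds = 20, max_depth = 1),
              list(n_rounds = 40, max_depth = 2),
              list(n_rounds = 40, max_depth = 3),
              list(n_rounds = 60, max_depth = 3))
sel <- select_model(ret[sp$train, block_feature_names()],
                    ret$label[sp$train], cands, k = 5,
                    budget = length(cands), seed = 11)
cat(sprintf("Selected: %d rounds of depth-%d trees (CV error %.4f)\n\n",
            sel$best$n_rounds, sel$best$max_depth, sel$cv_error))

fracs <- c(0.6, 0.5, 0.4, 0.3, 0.2, 0.1)
curve <- do.call(rbind, lapply(fracs, function(fr) {
  rh <- repeated_holdout(ret, fr, runs = 6, seed = 11,
                         n_rounds = sel$best$n_rounds,
                         max_depth = sel$best$max_depth)
  s <- rh$summary
  data.frame(train_frac = fr,
             sensitivity = s$mean[s$metric == "sensitivity"],
             precision = s$mean[s$metric == "precision"],
             f_score = s$mean[s$metric == "f_score"],
             f_score_sd = s$sd[s$metric == "f_score"],
             fpr_pct = 100 * s$mean[s$metric == "fpr"])
}))
print(curve, digits = 3)
write.csv(curve, "results/holdout_curve.csv", row.names = FALSE)

cat(sprintf(
  "\nAt 60:40 the detector reaches F = %.2f with FPR = %.2f%%; shrinking\n",
  curve$f_score[1], curve$fpr_pct[1]
))
cat("the training set degrades performance gradually and inflates the SD,\n")
cat("but even a 10% training share keeps a usable detector.\n")
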