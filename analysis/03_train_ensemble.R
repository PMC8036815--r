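#!/usr/bin/env Rscript
# Train the four-submodel voting ensemble on the synthetic cohort.
#
# Reads results/features.csv and results/labels.csv (from 02), drops
# excluded patients, makes a stratified 75/25 split, tunes and fits the
# reference ensemble composition (linear SVM on image features, DT on
# image+clinical, logistic model on image+spatial, RF on all features),
# and writes predictions, model summaries and post-hoc importance
# tables under results/.

suppressMessages(library(immunocontext))

seed <- 1L
n_configs <- 40  # hyperparameter draws per submodel search

features <- read.csv("results/features.csv", check.names = FALSE)
labels <- read.csv("results/labels.csv")
stopifnot(identical(features$patient_id, labels$patient_id))

keep <- labels$label != "excluded"
feats <- features[keep, ]
y <- labels$label[keep]
split <- stratified_split(y, test_fraction = 0.25, seed = seed)
cat(sprintf("%d labelled patients -> %d train / %d test\n",
            length(y), length(split$train), length(split$test)))

audit_start()
t0 <- Sys.time()
ensemble <- build_ensemble(feats[split$train, ], y[split$train],
                           n_configs = n_configs, seed = seed)
touched <- audit_stop()
leaks <- intersect(touched, feats$patient_id[split$test])
cat(sprintf("ensemble trained in %.0f s; test rows touched during tuning: %d\n",
            as.numeric(Sys.time() - t0, units = "secs"), length(leaks)))

for (sm in ensemble$submodels)
  cat(sprintf("  %-15s on %-28s train AUROC %.1f%%, CV %.1f%%\n",
              sm$family, sQuote(sm$feature_set),
              100 * sm$train_auroc, 100 * sm$cv_mean))

dir.create("results", showWarnings = FALSE)
pred <- rbind(
  data.frame(patient_id = feats$patient_id[split$train], subset = "train",
             ensemble_predict(ensemble, feats[split$train, ])),
  data.frame(patient_id = feats$patient_id[split$test], subset = "test",
             ensemble_predict(ensemble, feats[split$test, ])))
write.csv(pred, "results/ensemble_predictions.csv", row.names = FALSE)

imp_tables <- lapply(ensemble$submodels, function(sm) {
  imp <- feature_importance(sm)
  data.frame(family = sm$family, feature_set = sm$feature_set,
             rule = imp$rule, threshold = imp$threshold,
             head(imp$ranked, 25),
             retained = head(imp$ranked$feature, 25) %in% imp$retained)
})
write.csv(do.call(rbind, imp_tables), "results/feature_importance.csv",
          row.names = FALSE)
for (sm in ensemble$submodels) {
  imp <- feature_importance(sm)
  cat(sprintf("  %s retains %d features (%s rule); top: %s\n",
              sm$family, length(imp$retained), imp$rule,
              paste(head(imp$ranked$feature, 3), collapse = ", ")))
}
cat("wrote results/ensemble_predictions.csv and results/feature_importance.csv\n")
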