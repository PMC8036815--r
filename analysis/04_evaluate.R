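#!/usr/bin/env Rscript
# Evaluate ensemble risk stratification against the TNM baseline.
#
# Reads the predictions from 03 plus the cohort clinical records, and
# reports -- separately on the training and testing subsets -- AUROC,
# accuracy, sensitivity, specificity, F1, the log-rank test and the
# univariate Cox hazard ratio of high- vs low-risk groups, for both the
# ensemble and TNM staging (stage IV = high risk).  Writes a metric
# table and per-group Kaplan-Meier curves under results/.

suppressMessages(library(immunocontext))

pred <- read.csv("results/ensemble_predictions.csv")
labels <- read.csv("results/labels.csv")
clinical <- read.csv("results/cohort/clinical.csv")

df <- merge(merge(pred, labels, by = "patient_id"), clinical, by = "patient_id")
df$event <- as.integer(df$event_cause == "mibc_death")
df$tnm_risk <- tnm_stratify(df$stage)

rows <- list(); km_rows <- list()
for (subset in c("train", "test")) {
  d <- df[df$subset == subset, ]
  for (model in c("ensemble", "tnm")) {
    risk <- if (model == "ensemble") d$risk else d$tnm_risk
    scores <- if (model == "ensemble") d$votes else as.numeric(d$tnm_risk == "high")
    ev <- evaluate_stratification(risk, d$label, d$survival_months, d$event,
                                  scores = scores)
    hr_txt <- if (is.null(ev$hr)) "NA"
      else sprintf("%.1f (%.1f, %.1f)", ev$hr$hr, ev$hr$ci[1], ev$hr$ci[2])
    p_txt <- if (is.null(ev$logrank)) NA_real_ else ev$logrank$p
    cat(sprintf("%-5s %-8s AUROC %5.1f  acc %5.1f  sens %5.1f  spec %5.1f  F1 %5.1f  HR %s  logrank p %s\n",
                subset, model, ev$auroc, ev$metrics[["accuracy"]],
                ev$metrics[["sensitivity"]], ev$metrics[["specificity"]],
                ev$metrics[["f1"]], hr_txt, format(p_txt, digits = 2)))
    rows[[paste(subset, model)]] <- data.frame(
      subset = subset, model = model, auroc = ev$auroc,
      accuracy = ev$metrics[["accuracy"]],
      sensitivity = ev$metrics[["sensitivity"]],
      specificity = ev$metrics[["specificity"]], f1 = ev$metrics[["f1"]],
      hr = if (is.null(ev$hr)) NA else ev$hr$hr,
      hr_lo = if (is.null(ev$hr)) NA else ev$hr$ci[1],
      hr_hi = if (is.null(ev$hr)) NA else ev$hr$ci[2],
      logrank_p = p_txt,
      n_low = ev$group_sizes[["low"]], n_high = ev$group_sizes[["high"]])
    if (!is.null(ev$km))
      for (grp in names(ev$km))
        km_rows[[paste(subset, model, grp)]] <- data.frame(
          subset = subset, model = model, group = grp, ev$km[[grp]])
  }
}
write.csv(do.call(rbind, rows), "results/evaluation_metrics.csv", row.names = FALSE)
write.csv(do.call(rbind, km_rows), "results/km_curves.csv", row.names = FALSE)
cat("wrote results/evaluation_metrics.csv and results/km_curves.csv\n")
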