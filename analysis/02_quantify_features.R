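#!/usr/bin/env Rscript
# Quantify immune-contexture features for every patient.
#
# Re-derives the seed-1 cohort (generation is deterministic), runs the
# measurement pipeline per slide -- region partition, tumour-bud
# identification, phenotyping, counts/densities, cross-type L curves --
# and writes the 201-column feature matrix plus prognosis labels.

suppressMessages(library(immunocontext))

seed <- 1L
cfg <- cohort_config(n_patients = 78, seed = seed)
cohort <- generate_cohort(cfg)

t0 <- Sys.time()
features <- cohort_features(cohort)
cat(sprintf("quantified %d features for %d patients in %.0f s\n",
            ncol(features) - 1, nrow(features),
            as.numeric(Sys.time() - t0, units = "secs")))

dir.create("results", showWarnings = FALSE)
write.csv(features, "results/features.csv", row.names = FALSE)

lab <- binarize_survival(cohort$clinical)
write.csv(data.frame(patient_id = cohort$clinical$patient_id,
                     label = lab$labels, reason = lab$reason),
          "results/labels.csv", row.names = FALSE)
cat(sprintf("labels: %d bad, %d good, %d excluded (%.0f%% exclusion)\n",
            lab$report$n_bad, lab$report$n_good, lab$report$n_excluded,
            100 * lab$report$excluded_fraction))

# a glance at the spatial block: population-averaged L curves
radii <- feature_schema()$radii
lcols <- paste0("L_TB_CD3_r", radii)
cat("mean L(TB <- CD3) across the cohort (CSR reference = r):\n")
print(round(setNames(colMeans(features[lcols]), paste0("r", radii)), 1))
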