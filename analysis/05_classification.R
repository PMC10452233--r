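#!/usr/bin/env Rscript
# Stage 5: leave-one-subject-out classification of HC vs CS from the PEC
# edge features, over the full 4 x 4 grid of feature-selection methods and
# classifiers, with occurrence-rate feature ranking at the optimal K.

source("analysis/_common.R")

cfg <- study_config()
run <- run_pipeline(cfg, RUN_DIR,
                    stages = c("simulate", "preprocess", "inverse", "pec",
                               "graph", "stats", "classify"))
cl <- run$results$classify

invisible(file.copy(file.path(RUN_DIR, "classification.tsv"),
          file.path(RESULTS, "classification.tsv"), overwrite = TRUE))
message("Accuracy (+/- SEM) per feature-selection x classifier combination:")
print(cl$table[, c("fs", "classifier", "acc", "sem", "K")], row.names = FALSE)

best <- cl$table[cl$table$best, ]
best_run <- cl$results[[rownames(best)]]
message(sprintf(
  "Best cell: %s + %s, accuracy %.3f +/- %.3f at K = %d features",
  best$fs, best$classifier, best$acc, best$sem, best$K))
message("Confusion matrix (rows = truth):")
print(best_run$confusion)

idx <- upper_tri_index(cfg$sim$n_rois)
sel <- data.frame(feature = best_run$optimal_features,
                  roi_i = idx[best_run$optimal_features, 1],
                  roi_j = idx[best_run$optimal_features, 2],
                  occurrence = best_run$occurrence[best_run$optimal_features])
write.table(sel, file.path(RESULTS, "selected_features.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
message("Occurrence-ranked selected edges written to results/selected_features.tsv")
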