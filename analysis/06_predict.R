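#!/usr/bin/env Rscript
# Build the k-NN transcriptomic ploidy predictor on early (<30 h)
# labelled blastomeres: stringent Mann-Whitney feature selection
# (p < 0.005), stratified 2/3-1/3 split, 5-fold cross-validation repeated
# 20 times over odd k, hold-out validation, then classification of the
# cells lacking ploidy calls.

library(zygotrace)

expr_df <- read.csv("results/expression.csv", check.names = FALSE)
expr <- as.matrix(expr_df[, -1]); rownames(expr) <- expr_df$gene
samples <- read.csv("results/cohort/samples.csv", stringsAsFactors = FALSE)
samples <- samples[match(colnames(expr), samples$cell_id), ]
truth <- jsonlite::read_json("results/cohort/truth.json",
                             simplifyVector = TRUE)

early <- samples$time_h < 30
labelled <- early & samples$ploidy %in% c("euploid", "aneuploid")
unlabelled <- early & samples$ploidy == "unknown"
cat(sprintf("early-window cells: %d labelled, %d without ploidy calls\n",
            sum(labelled), sum(unlabelled)))

model <- train_ploidy_predictor(expr[, labelled], samples$ploidy[labelled],
                                alpha = 0.005, folds = 5, repeats = 20,
                                seed = 1)
print(model)
write.csv(model$cv, "results/predictor_cv.csv", row.names = FALSE)
write_predictor(model, "results/predictor_model.json")

planted <- truth$genes$gene[truth$genes$signature]
cat(sprintf("signature overlap with planted truth: %d/%d genes\n",
            sum(model$signature$gene %in% planted), nrow(model$signature)))

if (any(unlabelled)) {
  pred <- predict_unlabeled(model, expr[, unlabelled, drop = FALSE])
  write.csv(pred$calls, "results/predicted_unlabeled.csv",
            row.names = FALSE)
  hidden <- truth$cells$ploidy[match(pred$calls$cell_id,
                                     truth$cells$cell_id)]
  cat(sprintf(
    "prediction group: %d cells, predicted aneuploidy incidence %.1f%% (hidden truth %.1f%%, per-cell agreement %.0f%%)\n",
    nrow(pred$calls), pred$incidence, 100 * mean(hidden == "aneuploid"),
    100 * mean(pred$calls$class == hidden)))
}
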