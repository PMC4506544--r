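#!/usr/bin/env Rscript
# Generate the synthetic study cohort analysed by the rest of the
# workflow: 57 embryos, ~50% aneuploid (one abnormal embryo in ten
# mosaic-mixed), 87-gene panel with a 12-gene ploidy signature shifted by
# 2 expression units before 30 h, 20% of embryos left without ploidy
# calls to serve as the prediction group.

library(zygotrace)

seed <- 1
cfg <- sim_config(n_embryos = 57, unlabeled_fraction = 0.2, seed = seed)
print(cfg)

cohort <- simulate_cohort(cfg)
print(cohort)

paths <- write_cohort(cohort, "results/cohort")
emb <- cohort$truth$embryos
cat(sprintf("abnormal divisions: %d/%d aneuploid vs %d/%d euploid embryos\n",
            sum(emb$abnormal_division & emb$kinetic_group == "aneuploid"),
            sum(emb$kinetic_group == "aneuploid"),
            sum(emb$abnormal_division & emb$kinetic_group == "euploid"),
            sum(emb$kinetic_group == "euploid")))
cat("written:", paste(basename(paths), collapse = ", "),
    "-> results/cohort/\n")
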