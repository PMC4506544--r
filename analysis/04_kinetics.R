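#!/usr/bin/env Rscript
# Translate frame annotations (5-min imaging interval) into morphokinetic
# parameters, compare euploid versus aneuploid embryos overall and
# stratified by division type, and test the fragmentation-ploidy
# association.

library(zygotrace)

frames <- read.csv("results/cohort/frames.csv", stringsAsFactors = FALSE)
truth <- jsonlite::read_json("results/cohort/truth.json",
                             simplifyVector = TRUE)

params <- derive_parameters(frames, interval_min = 5)
emb <- truth$embryos
ploidy <- emb$ploidy[match(params$embryo_id, emb$embryo_id)]

summary_tab <- kinetics_summary(params, ploidy, stratify = TRUE)
write.csv(summary_tab, "results/kinetics_summary.csv", row.names = FALSE)

r <- summary_tab[summary_tab$parameter == "pnd_to_cytokinesis" &
                   summary_tab$stratum == "all", ]
cat(sprintf(
  "PNd to first cytokinesis: euploid median %.2f h (n=%d) vs aneuploid %.2f h (n=%d), Mann-Whitney p = %.3f\n",
  r$median_euploid, r$n_euploid, r$median_aneuploid, r$n_aneuploid, r$p))

frag <- fragmentation_association(params$fragmentation_degree,
                                  ifelse(ploidy == "mosaic-mixed",
                                         "aneuploid", ploidy))
cat("fragmentation (low <25% vs high >=25%) by ploidy:\n")
print(frag$table)
cat(sprintf("Fisher exact p = %.3f\n", frag$p))

ab <- table(division = ifelse(params$abnormal_division, "abnormal",
                              "normal"),
            ploidy = ploidy)
cat("division type by ploidy consensus:\n"); print(ab)
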