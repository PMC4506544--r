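#!/usr/bin/env Rscript
# Run the whole analysis in order. Each stage is a standalone script
# reading the previous stage's outputs from results/.
for (s in sprintf("analysis/0%d_%s.R", 1:6,
                  c("simulate", "preprocess", "trajectories", "kinetics",
                    "diffexp", "predict"))) {
  cat("\n==>", s, "\n")
  source(s, echo = FALSE)
}
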