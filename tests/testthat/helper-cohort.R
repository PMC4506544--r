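# Shared simulated cohorts, built once per test run.
.cohorts <- new.env(parent = emptyenv())

cached_cohort <- function(key, ...) {
  if (is.null(.cohorts[[key]]))
    .cohorts[[key]] <- simulate_cohort(sim_config(...))
  .cohorts[[key]]
}

# Default-conditions cohort with a planted ploidy effect (delta = 2).
effect_cohort <- function()
  cached_cohort("effect", n_embryos = 57, seed = 101)

# Matched null cohort: no ploidy effect.
null_cohort <- function()
  cached_cohort("null", n_embryos = 57, effect_size_delta = 0, seed = 101)

# Expression + aligned sample sheet; synthetic cohorts are analysed
# without cross-cell normalization (all simulated cells already share one
# Ct scale; see the methods vignette).
# Two-class 2-D toy set with tunable separation.
toy_data <- function(n_per = 10, sep = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * 2, 0, 1), ncol = 2),
             matrix(rnorm(n_per * 2, sep, 1), ncol = 2))
  y <- rep(c("euploid", "aneuploid"), each = n_per)
  list(x = x, y = y)
}

cohort_expr <- function(cohort, normalize = FALSE) {
  pp <- preprocess_ct(cohort$ct, normalize = normalize)
  samp <- cohort$samples[match(colnames(pp$expr), cohort$samples$cell_id), ]
  list(expr = pp$expr, samples = samp, pp = pp)
}
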