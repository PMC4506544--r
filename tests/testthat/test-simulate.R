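test_that("invalid configurations are rejected", {
  expect_error(sim_config(aneuploidy_rate = 1.5), "probability")
  expect_error(sim_config(mosaic_mixed_rate = -0.1), "probability")
  expect_error(sim_config(n_embryos = -3), "positive")
  expect_error(sim_config(effect_size_delta = -1), ">= 0")
  expect_error(sim_config(noise_sd = -0.5), ">= 0")
  expect_error(sim_config(cluster_proportions = c(0.5, 0.5, 0.3, 0.2)),
               "sum")
})

test_that("the same seed reproduces the cohort byte-for-byte", {
  a <- simulate_cohort(sim_config(n_embryos = 8, seed = 42))
  b <- simulate_cohort(sim_config(n_embryos = 8, seed = 42))
  d <- simulate_cohort(sim_config(n_embryos = 8, seed = 43))
  expect_identical(a$ct, b$ct)
  expect_identical(a$samples, b$samples)
  expect_identical(a$frames, b$frames)
  expect_false(identical(a$ct$ct, d$ct$ct))
})

test_that("a zero aneuploidy rate yields an all-euploid cohort", {
  co <- simulate_cohort(sim_config(n_embryos = 15, aneuploidy_rate = 0,
                                   seed = 7))
  expect_true(all(co$truth$embryos$ploidy == "euploid"))
  expect_true(all(co$truth$cells$ploidy == "euploid"))
})

test_that("noise-free, dropout-free expression equals the archetype", {
  co <- simulate_cohort(sim_config(n_embryos = 6, noise_sd = 0,
                                   dropout = FALSE, seed = 9))
  pp <- preprocess_ct(co$ct, normalize = FALSE)
  gt <- co$truth$genes
  cells <- co$truth$cells
  for (j in colnames(pp$expr)) {
    ci <- cells[cells$cell_id == j, ]
    E <- gt$a * ci$time_h^2 + gt$b * ci$time_h + gt$c
    if (ci$ploidy == "aneuploid" && ci$time_h < 30)
      E <- E + 2 * gt$direction
    expect_equal(unname(pp$expr[, j]), pmax(E, 0), tolerance = 1e-10)
  }
})

test_that("expression at time zero reproduces each archetype intercept", {
  co <- simulate_cohort(sim_config(n_embryos = 4, noise_sd = 0,
                                   dropout = FALSE, aneuploidy_rate = 0,
                                   collection_time_range = c(0, 0),
                                   seed = 5))
  pp <- preprocess_ct(co$ct, normalize = FALSE)
  gt <- co$truth$genes
  for (j in seq_len(ncol(pp$expr)))
    expect_equal(unname(pp$expr[, j]), gt$c, tolerance = 1e-10)
})

test_that("archetypes satisfy their own cluster rule noise-free", {
  set.seed(31)
  gt <- draw_archetypes(default_gene_table())
  E0 <- gt$c
  Ef <- gt$a * 56^2 + gt$b * 56 + gt$c
  lab <- assign_cluster(E0, Ef - E0, p = rep(0, nrow(gt)))
  real <- gt$cluster != "unclassified"
  expect_identical(lab[real], gt$cluster[real])
  expect_identical(classify_origin(E0, Ef), gt$origin)
})

test_that("cluster proportions follow the configured panel split", {
  gt <- default_gene_table()
  expect_equal(as.vector(table(gt$cluster)[c("1", "2", "3", "4")]),
               c(29L, 4L, 10L, 12L))
  expect_equal(sum(gt$signature), 12)
  expect_equal(sum(gt$direction == 1), 4)   # up in aneuploid
  expect_equal(sum(gt$direction == -1), 8)  # down in aneuploid
})

test_that("aneuploid labelling converges to the configured rate", {
  co <- simulate_cohort(sim_config(n_embryos = 400, mosaic_mixed_rate = 0,
                                   seed = 77))
  frac <- mean(co$truth$embryos$ploidy == "aneuploid")
  se <- sqrt(0.5 * 0.5 / 400)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("mosaic-mixed embryos carry both euploid and aneuploid cells", {
  co <- simulate_cohort(sim_config(n_embryos = 60, mosaic_mixed_rate = 1,
                                   aneuploidy_rate = 1,
                                   cells_per_embryo = 4, seed = 13))
  emb <- co$truth$embryos
  expect_true(all(emb$ploidy == "mosaic-mixed"))
  for (e in emb$embryo_id) {
    calls <- co$truth$cells$ploidy[co$truth$cells$embryo_id == e]
    expect_setequal(unique(calls), c("euploid", "aneuploid"))
  }
})

test_that("sampled kinetic medians match the reference table", {
  set.seed(2024)
  eu_norm <- sample_kinetics(10000, "euploid", "normal")
  an_norm <- sample_kinetics(10000, "aneuploid", "normal")
  eu_all <- sample_kinetics(10000, "euploid", "all")
  an_all <- sample_kinetics(10000, "aneuploid", "all")
  expect_lt(abs(median(eu_norm$pnd_to_cytokinesis) - 2.3), 0.1)
  expect_lt(abs(median(an_norm$pnd_to_cytokinesis) - 2.8), 0.1)
  expect_lt(abs(median(eu_all$pnd_to_cytokinesis) - 2.4), 0.1)
  expect_lt(abs(median(an_all$pnd_to_cytokinesis) - 2.8), 0.1)
  expect_lt(abs(median(an_all$cytokinesis_duration) - 20), 1)
})

test_that("zero spread collapses every kinetic draw onto the median", {
  d <- sample_kinetics(50, "euploid", "normal", spread = 0)
  expect_true(all(d$pnd_to_cytokinesis == 2.3))
  expect_true(all(d$cytokinesis_duration == 15))
})

test_that("frame annotations are consistent with the imaging interval", {
  co <- effect_cohort()
  fr <- co$frames
  # derived parameter equals the generating draw up to frame rounding
  par <- derive_parameters(fr)
  emb <- co$truth$embryos
  ok <- !is.na(par$pnd_to_cytokinesis)
  expect_true(all(par$pnd_to_cytokinesis[ok] >= 0))
  # 5-min frames: any timing is a multiple of 1/12 h
  expect_true(all(abs(par$pnd_to_cytokinesis[ok] * 12 -
                        round(par$pnd_to_cytokinesis[ok] * 12)) < 1e-9))
})

test_that("written cohort files round-trip through the readers", {
  co <- simulate_cohort(sim_config(n_embryos = 4, seed = 3))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  ct <- read_ct_csv(file.path(dir, "ct.csv"))
  expect_equal(nrow(ct), nrow(co$ct))
  expect_equal(is.na(ct$ct), is.na(co$ct$ct))
  expect_equal(ct$ct[!is.na(ct$ct)], co$ct$ct[!is.na(co$ct$ct)],
               tolerance = 1e-6)
})
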