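test_that("frames convert linearly to hours", {
  expect_equal(frames_to_hours(12), 1)
  expect_equal(frames_to_hours(0), 0)
  expect_equal(frames_to_hours(33), 2.75)
  expect_equal(frames_to_hours(10, interval_min = 6), 1)
  expect_error(frames_to_hours(-1), "nonnegative")
  a <- sample(0:500, 20); b <- sample(0:500, 20)
  expect_equal(frames_to_hours(a + b), frames_to_hours(a) + frames_to_hours(b))
})

frame_row <- function(id, event, frame, value = NA_character_)
  data.frame(embryo_id = id, event = event, frame = frame, value = value,
             stringsAsFactors = FALSE)

test_that("parameters derive from bounding event frames", {
  fr <- rbind(frame_row("E1", "pnd", 100),
              frame_row("E1", "cytokinesis_start", 133),
              frame_row("E1", "cytokinesis_end", 137),
              frame_row("E1", "reach_2", 137),
              frame_row("E1", "reach_3", 270),
              frame_row("E1", "division1", 137, "1to2"))
  p <- derive_parameters(fr)
  expect_equal(p$pnd_to_cytokinesis, 2.75)
  expect_equal(p$cytokinesis_duration, 4 * 5)  # minutes
  expect_equal(p$t2_3, frames_to_hours(270 - 137))
  expect_true(is.na(p$t3_4))                   # removed before 4 cells
  expect_false(p$abnormal_division)
})

test_that("direct-cleavage annotations raise the abnormal flag", {
  fr <- rbind(frame_row("E2", "pnd", 50),
              frame_row("E2", "cytokinesis_start", 90),
              frame_row("E2", "cytokinesis_end", 95),
              frame_row("E2", "reach_3", 95),
              frame_row("E2", "division1", 95, "1to3"))
  p <- derive_parameters(fr)
  expect_true(p$abnormal_division)
  expect_true(is.na(p$t2_3))  # never at 2 cells
})

test_that("out-of-order frames are rejected with the embryo named", {
  fr <- rbind(frame_row("E9", "pnd", 200),
              frame_row("E9", "cytokinesis_start", 150))
  expect_error(derive_parameters(fr), "E9")
})

test_that("group comparison reports medians, IQR and Mann-Whitney p", {
  r <- compare_groups(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$median_a, 2)
  expect_equal(r$q1_a, 1.5)  # linear-interpolation quantiles
  expect_equal(r$q3_b, 11.5)
  expect_equal(r$p, 0.1)     # minimal attainable exact two-sided p
  same <- suppressWarnings(compare_groups(1:6, 1:6))
  expect_gt(same$p, 0.99)
  expect_error(compare_groups(numeric(0), 1:3), "at least one")
  expect_true(is.na(compare_groups(1, 2:5)$p))
})

test_that("exact Mann-Whitney p matches full enumeration on small n", {
  set.seed(12)
  for (i in 1:8) {
    a <- round(runif(sample(3:6, 1), 0, 20), 3)
    b <- round(runif(sample(3:6, 1), 0, 20), 3)
    expect_equal(compare_groups(a, b)$p, mw_enum_p(a, b), tolerance = 1e-9)
  }
})

test_that("fragmentation association reproduces the Fisher exact test", {
  # 19/41 aneuploid among low-fragmentation, 10/16 among high
  frag <- c(rep(10, 41), rep(40, 16))
  pl <- c(rep("aneuploid", 19), rep("euploid", 22),
          rep("aneuploid", 10), rep("euploid", 6))
  r <- fragmentation_association(frag, pl)
  expect_equal(unname(r$table["low", "aneuploid"]), 19)
  expect_equal(unname(r$table["high", "aneuploid"]), 10)
  expect_gt(r$p, 0.05)  # trend, not significant
  expect_equal(r$p, fisher_enum_p(r$table), tolerance = 1e-9)
  # perfect separation
  r2 <- fragmentation_association(c(rep(10, 10), rep(40, 10)),
                                  rep(c("euploid", "aneuploid"), each = 10))
  expect_lt(r2$p, 0.001)
})

test_that("Fisher p matches hypergeometric enumeration on random tables", {
  set.seed(3)
  for (i in 1:10) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(stats::fisher.test(tab)$p.value, fisher_enum_p(tab),
                 tolerance = 1e-9)
  }
})

test_that("ploidy consensus follows the blastomere calls", {
  expect_equal(ploidy_consensus(c("euploid", "euploid")), "euploid")
  expect_equal(ploidy_consensus(c("aneuploid", "aneuploid")), "aneuploid")
  expect_equal(ploidy_consensus(c("euploid", "aneuploid")), "mosaic-mixed")
  expect_equal(ploidy_consensus(character(0)), "unknown")
  expect_equal(ploidy_consensus(c("unknown", "unknown")), "unknown")
})

test_that("normal and abnormal strata reconcile with the full cohort", {
  co <- effect_cohort()
  par <- derive_parameters(co$frames)
  emb <- co$truth$embryos
  pl <- emb$ploidy[match(par$embryo_id, emb$embryo_id)]
  s <- kinetics_summary(par, pl, stratify = TRUE)
  for (pn in unique(s$parameter)) {
    r <- s[s$parameter == pn, ]
    if (!all(c("all", "normal", "abnormal") %in% r$stratum)) next
    expect_equal(r$n_euploid[r$stratum == "all"],
                 sum(r$n_euploid[r$stratum != "all"]))
    expect_equal(r$n_aneuploid[r$stratum == "all"],
                 sum(r$n_aneuploid[r$stratum != "all"]))
  }
})

test_that("cohort summary reproduces the configured group medians", {
  co <- cached_cohort("kin", n_embryos = 300, seed = 909)
  par <- derive_parameters(co$frames)
  emb <- co$truth$embryos
  pl <- emb$kinetic_group[match(par$embryo_id, emb$embryo_id)]
  s <- kinetics_summary(par, pl, stratify = FALSE)
  r <- s[s$parameter == "pnd_to_cytokinesis", ]
  expect_lt(abs(r$median_euploid - 2.4), 0.3)
  expect_lt(abs(r$median_aneuploid - 2.8), 0.3)
})
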