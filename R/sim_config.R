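#' Reference morphokinetic parameter table
#'
#' Median and interquartile range (Q1; Q3) of each timing parameter per
#' ploidy group and division type, used to parameterize the log-normal
#' sampling distributions of the cohort generator. The defaults are the
#' published reference values for euploid (n = 22) versus aneuploid
#' (n = 26) cleavage-stage embryos, overall and stratified into normal and
#' abnormal (direct 1-to-3 / 1-to-4 cleavage) divisions. Units are hours
#' except `cytokinesis_duration`, reported in minutes.
#'
#' @return A data.frame with columns `parameter`, `group`, `division`, `n`,
#'   `median`, `q1`, `q3`.
#' @export
default_kinetic_params <- function() {
  long <- rbind(
    c("pnd_to_cytokinesis", "euploid",   "all",      22, 2.4, 2.1, 2.9),
    c("pnd_to_cytokinesis", "aneuploid", "all",      26, 2.8, 2.5, 3.3),
    c("pnd_to_cytokinesis", "euploid",   "normal",   18, 2.3, 2.1, 2.9),
    c("pnd_to_cytokinesis", "aneuploid", "normal",   14, 2.8, 2.5, 3.3),
    c("pnd_to_cytokinesis", "euploid",   "abnormal",  4, 2.9, 0.9, 3.1),
    c("pnd_to_cytokinesis", "aneuploid", "abnormal", 12, 2.9, 2.5, 7.9),
    c("cytokinesis_duration", "euploid",   "all",      22, 15.0, 13.8, 26.3),
    c("cytokinesis_duration", "aneuploid", "all",      26, 20.0, 13.8, 31.3),
    c("cytokinesis_duration", "euploid",   "normal",   18, 15.0, 10.0, 21.3),
    c("cytokinesis_duration", "aneuploid", "normal",   14, 20.0, 10.0, 31.3),
    c("cytokinesis_duration", "euploid",   "abnormal",  4, 25.0, 16.3, 60.0),
    c("cytokinesis_duration", "aneuploid", "abnormal", 12, 22.5, 15.0, 37.5),
    c("t2_3", "euploid",   "all",      14, 11.3, 1.4, 12.2),
    c("t2_3", "aneuploid", "all",      23, 11.4, 0.8, 12.6),
    c("t2_3", "euploid",   "normal",   10, 11.7, 11.1, 12.6),
    c("t2_3", "aneuploid", "normal",   11, 12.5, 11.8, 12.9),
    c("t2_3", "euploid",   "abnormal",  4, 1.3, 0.5, 4.3),
    c("t2_3", "aneuploid", "abnormal", 12, 0.8, 0.1, 2.4),
    c("t3_4", "euploid",   "all",      12, 0.8, 0.2, 1.3),
    c("t3_4", "aneuploid", "all",      20, 2.4, 0.9, 8.4),
    c("t3_4", "euploid",   "normal",   10, 0.8, 0.4, 1.3),
    c("t3_4", "aneuploid", "normal",   11, 1.7, 0.8, 2.7),
    c("t3_4", "euploid",   "abnormal",  2, 5.4, 0.1, NA),
    c("t3_4", "aneuploid", "abnormal",  9, 4.4, 1.6, 12.3),
    c("t4_5", "euploid",   "all",       5, 5.3, 1.0, 13.8),
    c("t4_5", "aneuploid", "all",      25, 9.9, 0.8, 12.3),
    c("t4_5", "euploid",   "normal",    4, 8.8, 2.9, 14.6),
    c("t4_5", "aneuploid", "normal",    6, 12.8, 11.7, 15.7),
    c("t4_5", "euploid",   "abnormal",  1, 0.0, 0.0, 11.2),
    c("t4_5", "aneuploid", "abnormal",  9, 2.7, 0.3, 9.0),
    c("t5_6", "euploid",   "all",       5, 7.2, 1.4, 9.3),
    c("t5_6", "aneuploid", "all",      12, 1.6, 0.4, 3.8),
    c("t5_6", "euploid",   "normal",    4, 4.9, 0.7, 7.4),
    c("t5_6", "aneuploid", "normal",    6, 1.6, 0.5, 2.7),
    c("t5_6", "euploid",   "abnormal",  1, 11.2, 11.2, NA),
    c("t5_6", "aneuploid", "abnormal",  6, 1.6, 0.3, 13.8),
    c("t6_7", "euploid",   "all",       4, 1.0, 0.6, 3.5),
    c("t6_7", "aneuploid", "all",      12, 2.0, 1.0, 8.5),
    c("t6_7", "euploid",   "normal",    3, 0.8, 0.5, NA),
    c("t6_7", "aneuploid", "normal",    6, 1.5, 0.5, 3.9),
    c("t6_7", "euploid",   "abnormal",  1, 4.3, 4.3, NA),
    c("t6_7", "aneuploid", "abnormal",  6, 5.1, 1.2, 13.2),
    c("t7_8", "euploid",   "all",       4, 0.8, 0.6, 1.1),
    c("t7_8", "aneuploid", "all",      10, 0.7, 0.4, 3.4),
    c("t7_8", "euploid",   "normal",    3, 0.8, 0.5, NA),
    c("t7_8", "aneuploid", "normal",    6, 1.5, 0.4, 3.4),
    c("t7_8", "euploid",   "abnormal",  1, 0.8, 0.8, NA),
    c("t7_8", "aneuploid", "abnormal",  4, 0.6, 0.3, 4.9),
    c("t8_9", "euploid",   "all",       1, 0.5, 0.5, 0.5),
    c("t8_9", "aneuploid", "all",       2, 2.5, 1.6, NA),
    c("t8_9", "euploid",   "abnormal",  1, 0.5, 0.5, NA),
    c("t8_9", "aneuploid", "abnormal",  2, 2.5, 1.6, NA)
  )
  out <- data.frame(parameter = long[, 1], group = long[, 2],
                    division = long[, 3], stringsAsFactors = FALSE)
  out$n <- as.integer(long[, 4])
  out$median <- as.numeric(long[, 5])
  out$q1 <- as.numeric(long[, 6])
  out$q3 <- as.numeric(long[, 7])
  out
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic-cohort
#' generator. Defaults emulate the reference cohort: roughly half of the
#' embryos chromosomally abnormal, about one abnormal embryo in ten mosaic
#' (mixed euploid/aneuploid blastomeres), abnormal direct cleavages in
#' 12/26 aneuploid versus 4/22 euploid embryos with 85% of abnormal events
#' at the first mitosis, an 87-gene panel split 29/4/10/12 across the four
#' trajectory clusters, and a 12-gene ploidy signature shifted by
#' `effect_size_delta` expression units in aneuploid blastomeres collected
#' before 30 h post PNd.
#'
#' @param n_embryos Number of embryos to simulate.
#' @param aneuploidy_rate Probability an embryo is chromosomally abnormal.
#' @param mosaic_mixed_rate Probability an abnormal embryo is mosaic-mixed
#'   (its blastomeres split between euploid and aneuploid calls).
#' @param n_genes Panel size.
#' @param cluster_proportions Fractions of the panel in clusters 1-4.
#' @param gene_table Optional pre-built archetype panel; by default
#'   [default_gene_table()] with `n_genes` and `cluster_proportions`.
#' @param effect_size_delta Expression-unit shift applied to signature
#'   genes in aneuploid blastomeres collected before `effect_window_h`.
#' @param effect_window_h Hours post PNd during which the ploidy shift
#'   applies (default 30).
#' @param noise_sd Standard deviation (expression units, i.e. cycles) of
#'   the Gaussian technical noise added per replicate.
#' @param dropout Logical; if `TRUE`, replicate Ct values above
#'   `dropout_baseline` are recorded as undetected.
#' @param dropout_baseline Detection baseline in cycles (default 28).
#' @param replicate_count Technical qPCR replicates per assay (default 3).
#' @param collection_time_range Range (hours post PNd) from which each
#'   embryo's collection time is drawn uniformly.
#' @param cells_per_embryo `NULL` to derive the blastomere count from the
#'   simulated division tree at collection time, or a fixed integer.
#' @param assay_fraction Fraction of an embryo's blastomeres assayed by
#'   qPCR (at least one per embryo); the rest are assumed used for
#'   chromosomal analysis.
#' @param unlabeled_fraction Fraction of embryos whose cells carry no
#'   ploidy call in the sample sheet (truth retained in the ground-truth
#'   record); emulates samples lacking aCGH results.
#' @param abnormal_division_prob Named probabilities of an abnormal direct
#'   cleavage per ploidy group.
#' @param abnormal_first_mitosis_frac Fraction of abnormal events placed at
#'   the first mitosis.
#' @param kinetic_params Timing reference table, see
#'   [default_kinetic_params()].
#' @param kinetic_spread Multiplier on the log-scale spread of the timing
#'   distributions (0 collapses every draw onto its group median).
#' @param n_failed_cells Number of planted fully failed cells (all assays
#'   undetected), appended for QC testing.
#' @param frame_interval_min Imaging frame interval in minutes (default 5).
#' @param seed RNG seed fixing the full cohort byte-for-byte.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_embryos = 57,
                       aneuploidy_rate = 0.5,
                       mosaic_mixed_rate = 0.1,
                       n_genes = 87,
                       cluster_proportions = c(29, 4, 10, 12) / 87,
                       gene_table = NULL,
                       effect_size_delta = 2,
                       effect_window_h = 30,
                       noise_sd = 1,
                       dropout = TRUE,
                       dropout_baseline = 28,
                       replicate_count = 3,
                       collection_time_range = c(0, 56),
                       cells_per_embryo = NULL,
                       assay_fraction = 0.5,
                       unlabeled_fraction = 0,
                       abnormal_division_prob = c(euploid = 4 / 22,
                                                  aneuploid = 12 / 26),
                       abnormal_first_mitosis_frac = 0.85,
                       kinetic_params = default_kinetic_params(),
                       kinetic_spread = 1,
                       n_failed_cells = 0,
                       frame_interval_min = 5,
                       seed = 1L) {
  chk_prob <- function(p, what) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
      stop(sprintf("%s must be a probability in [0, 1]", what), call. = FALSE)
  }
  if (!is.numeric(n_embryos) || n_embryos < 1)
    stop("n_embryos must be a positive count", call. = FALSE)
  chk_prob(aneuploidy_rate, "aneuploidy_rate")
  chk_prob(mosaic_mixed_rate, "mosaic_mixed_rate")
  chk_prob(assay_fraction, "assay_fraction")
  chk_prob(unlabeled_fraction, "unlabeled_fraction")
  chk_prob(abnormal_division_prob, "abnormal_division_prob")
  chk_prob(abnormal_first_mitosis_frac, "abnormal_first_mitosis_frac")
  if (any(cluster_proportions < 0) || sum(cluster_proportions) > 1 + 1e-12)
    stop("cluster_proportions must be nonnegative and sum to at most 1",
         call. = FALSE)
  if (effect_size_delta < 0) stop("effect_size_delta must be >= 0",
                                  call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (n_genes < 1 || replicate_count < 1 || n_failed_cells < 0)
    stop("counts must be positive", call. = FALSE)
  structure(list(
    n_embryos = as.integer(n_embryos),
    aneuploidy_rate = aneuploidy_rate,
    mosaic_mixed_rate = mosaic_mixed_rate,
    n_genes = as.integer(n_genes),
    cluster_proportions = cluster_proportions,
    gene_table = gene_table,
    effect_size_delta = effect_size_delta,
    effect_window_h = effect_window_h,
    noise_sd = noise_sd,
    dropout = dropout,
    dropout_baseline = dropout_baseline,
    replicate_count = as.integer(replicate_count),
    collection_time_range = collection_time_range,
    cells_per_embryo = cells_per_embryo,
    assay_fraction = assay_fraction,
    unlabeled_fraction = unlabeled_fraction,
    abnormal_division_prob = abnormal_division_prob,
    abnormal_first_mitosis_frac = abnormal_first_mitosis_frac,
    kinetic_params = kinetic_params,
    kinetic_spread = kinetic_spread,
    n_failed_cells = as.integer(n_failed_cells),
    frame_interval_min = frame_interval_min,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic embryo cohort configuration\n")
  cat(sprintf("  embryos: %d  aneuploidy rate: %.3f  mosaic-mixed: %.3f\n",
              x$n_embryos, x$aneuploidy_rate, x$mosaic_mixed_rate))
  cat(sprintf("  genes: %d  signature delta: %.2f (< %g h)  noise sd: %.2f\n",
              x$n_genes, x$effect_size_delta, x$effect_window_h, x$noise_sd))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
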