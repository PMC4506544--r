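#' Sample morphokinetic timing parameters
#'
#' Draws timing parameters for one ploidy group and division type from
#' log-normal distributions whose median and interquartile range match the
#' reference table row. Timings are positive and right-skewed (observed
#' ranges span a quarter hour to over twenty hours), which the log-normal
#' reproduces; the log-scale spread is `sigma = log(Q3/Q1) / (2 z_0.75)`,
#' falling back to the one-sided quartile when a quartile is missing or
#' nonpositive. A `spread` of 0 collapses every draw onto the group median.
#'
#' @param n Number of parameter sets to draw.
#' @param group `"euploid"` or `"aneuploid"`.
#' @param division `"normal"` or `"abnormal"`; rows absent for the
#'   requested division type fall back to the `"all"` stratum.
#' @param kinetic_params Reference table, see [default_kinetic_params()].
#' @param spread Multiplier on the log-scale spread.
#' @return A data.frame with `n` rows, one column per timing parameter
#'   (hours, except `cytokinesis_duration` in minutes). Parameters with no
#'   usable reference median are `NA`.
#' @export
sample_kinetics <- function(n, group, division = "normal",
                            kinetic_params = default_kinetic_params(),
                            spread = 1) {
  group <- match.arg(group, c("euploid", "aneuploid"))
  division <- match.arg(division, c("normal", "abnormal", "all"))
  params <- unique(kinetic_params$parameter)
  z75 <- stats::qnorm(0.75)
  out <- lapply(params, function(p) {
    row <- kinetic_params[kinetic_params$parameter == p &
                            kinetic_params$group == group &
                            kinetic_params$division == division, ]
    if (nrow(row) == 0)
      row <- kinetic_params[kinetic_params$parameter == p &
                              kinetic_params$group == group &
                              kinetic_params$division == "all", ]
    if (nrow(row) == 0 || is.na(row$median[1])) return(rep(NA_real_, n))
    m <- row$median[1]; q1 <- row$q1[1]; q3 <- row$q3[1]
    if (m <= 0) return(rep(0, n))
    sigma <- if (!is.na(q1) && !is.na(q3) && q1 > 0) {
      log(q3 / q1) / (2 * z75)
    } else if (!is.na(q3) && q3 > 0) {
      log(q3 / m) / z75
    } else if (!is.na(q1) && q1 > 0) {
      log(m / q1) / z75
    } else 0.25
    sigma <- max(sigma, 0) * spread
    stats::rlnorm(n, meanlog = log(m), sdlog = sigma)
  })
  names(out) <- params
  as.data.frame(out)
}

# Stage reach times (hours post PNd) for one embryo's division tree.
# Abnormal direct cleavages skip stages: 1to3 at mitosis m jumps the cell
# count by two at the transition that mitosis drives; 1to4 (first mitosis
# only) jumps from one to four cells.
.division_schedule <- function(draws, abnormal, type, mitosis) {
  reach <- rep(NA_real_, 9)           # reach[k] = time embryo attains k cells
  reach[1] <- 0
  cyto_start <- draws$pnd_to_cytokinesis
  cyto_end <- cyto_start + draws$cytokinesis_duration / 60
  trans <- c(NA, draws$t2_3, draws$t3_4, draws$t4_5, draws$t5_6,
             draws$t6_7, draws$t7_8, draws$t8_9)  # trans[k]: k -> k+1 cells
  if (is.na(cyto_end)) return(list(reach = reach, cyto_start = cyto_start,
                                   cyto_end = NA_real_))
  first_to <- if (abnormal && mitosis == 1) {
    if (type == "1to4") 4L else 3L
  } else 2L
  reach[first_to] <- cyto_end
  k <- first_to
  mit <- 2L
  while (k < 9) {
    step <- if (abnormal && mitosis == mit && k < 8) 2L else 1L
    dt <- trans[k]
    if (is.na(dt)) break
    if (k + step > 9) break
    reach[k + step] <- reach[k] + dt
    k <- k + step
    mit <- mit + 1L
  }
  list(reach = reach, cyto_start = cyto_start, cyto_end = cyto_end)
}

#' Simulate a synthetic embryo cohort
#'
#' Generates a full synthetic study: per-embryo ploidy consensus, division
#' trees with log-normal timings (abnormal direct 1-to-3 / 1-to-4 cleavages
#' more frequent in aneuploid embryos), fragmentation, frame annotations at
#' the imaging interval, per-blastomere collection times, and a raw Ct
#' matrix in which each gene follows its quadratic trajectory archetype
#' with a ploidy-dependent shift on the signature genes before the effect
#' window closes. Replicate Ct values are `baseline - E + noise`; values
#' above the baseline are recorded as undetected when dropout is enabled.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `embryo_cohort`: a list with elements
#'   \describe{
#'     \item{ct}{long data.frame `cell_id`, `gene`, `replicate`, `ct`
#'       (`NA` = undetected).}
#'     \item{samples}{sample sheet: `cell_id`, `embryo_id`, `time_h`,
#'       `ploidy` (per-blastomere call: euploid/aneuploid/unknown).}
#'     \item{frames}{frame annotations: `embryo_id`, `event`, `frame`,
#'       `value` (5-min frames by default).}
#'     \item{truth}{ground truth: `genes` (archetypes), `embryos`,
#'       `cells`.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gt <- config$gene_table
  if (is.null(gt))
    gt <- default_gene_table(config$n_genes, config$cluster_proportions)
  if (is.null(gt$a)) gt <- draw_archetypes(gt)

  fpm <- config$frame_interval_min
  to_frame <- function(pnd_frame, h) pnd_frame + round(h * 60 / fpm)

  embryos <- list(); cells <- list(); frames <- list()
  cell_counter <- 0L
  for (e in seq_len(config$n_embryos)) {
    eid <- sprintf("E%03d", e)
    abnormal_chrom <- stats::runif(1) < config$aneuploidy_rate
    mosaic <- abnormal_chrom && stats::runif(1) < config$mosaic_mixed_rate
    consensus <- if (!abnormal_chrom) "euploid"
                 else if (mosaic) "mosaic-mixed" else "aneuploid"
    kin_group <- if (abnormal_chrom) "aneuploid" else "euploid"

    abnormal_div <- stats::runif(1) <
      config$abnormal_division_prob[[kin_group]]
    div_type <- if (abnormal_div)
      sample(c("1to3", "1to4"), 1, prob = c(17, 3)) else "1to2"
    mitosis <- if (abnormal_div && div_type == "1to3") {
      if (stats::runif(1) < config$abnormal_first_mitosis_frac) 1L
      else sample(2:3, 1)
    } else 1L

    draws <- sample_kinetics(1, kin_group,
                             division = if (abnormal_div) "abnormal"
                                        else "normal",
                             kinetic_params = config$kinetic_params,
                             spread = config$kinetic_spread)
    sched <- .division_schedule(draws, abnormal_div, div_type, mitosis)
    t_collect <- stats::runif(1, config$collection_time_range[1],
                              config$collection_time_range[2])

    reached <- which(!is.na(sched$reach) & sched$reach <= t_collect)
    n_cells <- if (length(reached)) max(reached) else 1L

    pnd_frame <- sample(10:40, 1)
    ev <- data.frame(embryo_id = eid, event = "pnd", frame = pnd_frame,
                     value = NA_character_, stringsAsFactors = FALSE)
    add_ev <- function(name, h, value = NA_character_) {
      if (!is.na(h) && h <= t_collect)
        ev <<- rbind(ev, data.frame(embryo_id = eid, event = name,
                                    frame = to_frame(pnd_frame, h),
                                    value = value, stringsAsFactors = FALSE))
    }
    add_ev("cytokinesis_start", sched$cyto_start)
    add_ev("cytokinesis_end", sched$cyto_end)
    mit_no <- 0L
    for (k in 2:9) {
      if (!is.na(sched$reach[k]) && sched$reach[k] <= t_collect) {
        add_ev(sprintf("reach_%d", k), sched$reach[k])
        mit_no <- mit_no + 1L
        dtype <- if (abnormal_div && mitosis == mit_no) div_type else "1to2"
        add_ev(sprintf("division%d", mit_no), sched$reach[k], dtype)
      }
    }

    has_frag <- stats::runif(1) < 64 / 85
    frag_deg <- 0; frag_tim <- "none"
    if (has_frag) {
      p_high <- if (kin_group == "aneuploid") 10 / 29 else 6 / 28
      high <- stats::runif(1) < p_high
      frag_deg <- if (high) stats::runif(1, 25, 60) else stats::runif(1, 1, 25)
      frag_tim <- sample(c("during", "before", "after"), 1,
                         prob = c(0.688, 0.219, 0.094))
      frag_h <- switch(frag_tim,
        before = if (is.na(sched$cyto_start)) 0.5
                 else stats::runif(1, 0, sched$cyto_start),
        during = if (is.na(sched$cyto_end)) 1
                 else stats::runif(1, sched$cyto_start, sched$cyto_end),
        after  = if (is.na(sched$cyto_end)) 2
                 else sched$cyto_end + stats::runif(1, 0.1, 2))
      if (frag_h <= t_collect)
        ev <- rbind(ev, data.frame(embryo_id = eid, event = "fragmentation",
                                   frame = to_frame(pnd_frame, frag_h),
                                   value = sprintf("%.1f", frag_deg),
                                   stringsAsFactors = FALSE))
    }
    frames[[e]] <- ev

    n_assayed <- if (is.null(config$cells_per_embryo))
      max(1L, round(config$assay_fraction * n_cells))
    else as.integer(config$cells_per_embryo)
    cell_ploidy <- switch(consensus,
      euploid = rep("euploid", n_assayed),
      aneuploid = rep("aneuploid", n_assayed),
      `mosaic-mixed` = {
        p <- sample(c("euploid", "aneuploid"), n_assayed, replace = TRUE)
        if (n_assayed >= 2) { p[1] <- "euploid"; p[2] <- "aneuploid" }
        p
      })
    unlabeled <- stats::runif(1) < config$unlabeled_fraction
    ids <- sprintf("C%04d", cell_counter + seq_len(n_assayed))
    cell_counter <- cell_counter + n_assayed
    cells[[e]] <- data.frame(
      cell_id = ids, embryo_id = eid, time_h = t_collect,
      ploidy = cell_ploidy, unlabeled = unlabeled, failed = FALSE,
      stringsAsFactors = FALSE)

    embryos[[e]] <- data.frame(
      embryo_id = eid, ploidy = consensus, kinetic_group = kin_group,
      abnormal_division = abnormal_div, division_type = div_type,
      abnormal_mitosis = if (abnormal_div) mitosis else NA_integer_,
      collection_time_h = t_collect, n_cells = n_cells,
      n_assayed = n_assayed, fragmentation_degree = frag_deg,
      fragmentation_timing = frag_tim, unlabeled = unlabeled,
      stringsAsFactors = FALSE)
  }
  embryos <- do.call(rbind, embryos)
  cells <- do.call(rbind, cells)
  frames <- do.call(rbind, frames)

  if (config$n_failed_cells > 0) {
    ids <- sprintf("C%04d", cell_counter + seq_len(config$n_failed_cells))
    host <- sample(embryos$embryo_id, config$n_failed_cells, replace = TRUE)
    cells <- rbind(cells, data.frame(
      cell_id = ids, embryo_id = host,
      time_h = embryos$collection_time_h[match(host, embryos$embryo_id)],
      ploidy = "unknown", unlabeled = TRUE, failed = TRUE,
      stringsAsFactors = FALSE))
  }

  # expression truth and Ct matrix
  base <- config$dropout_baseline
  ct_rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ci <- cells[i, ]
    if (ci$failed) {
      ct <- rep(NA_real_, nrow(gt) * config$replicate_count)
    } else {
      t <- ci$time_h
      E <- gt$a * t^2 + gt$b * t + gt$c
      if (ci$ploidy == "aneuploid" && t < config$effect_window_h)
        E <- E + config$effect_size_delta * gt$direction
      ct <- rep(base - E, each = config$replicate_count) +
        stats::rnorm(nrow(gt) * config$replicate_count, 0, config$noise_sd)
      ct <- pmax(ct, 0.1)
      if (config$dropout) ct[ct > base] <- NA_real_
    }
    ct_rows[[i]] <- data.frame(
      cell_id = ci$cell_id,
      gene = rep(gt$gene, each = config$replicate_count),
      replicate = rep(seq_len(config$replicate_count), times = nrow(gt)),
      ct = ct, stringsAsFactors = FALSE)
  }
  ct <- do.call(rbind, ct_rows)
  rownames(ct) <- NULL

  samples <- cells[, c("cell_id", "embryo_id", "time_h", "ploidy")]
  samples$ploidy[cells$unlabeled] <- "unknown"
  rownames(samples) <- NULL

  structure(list(ct = ct, samples = samples, frames = frames,
                 truth = list(genes = gt, embryos = embryos, cells = cells),
                 config = config),
            class = "embryo_cohort")
}

#' @export
print.embryo_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic embryo cohort: %d embryos, %d assayed blastomeres, %d genes\n",
    nrow(x$truth$embryos), nrow(x$truth$cells), nrow(x$truth$genes)))
  tab <- table(x$truth$embryos$ploidy)
  cat("  ploidy consensus:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulated cohort to plain-text files
#'
#' @param cohort An `embryo_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written: `ct.csv`, `samples.csv`,
#'   `frames.csv`, `truth.json`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "embryo_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("ct.csv", "samples.csv", "frames.csv",
                            "truth.json"))
  ct <- cohort$ct
  ct$ct <- ifelse(is.na(ct$ct), "ND", format(ct$ct, digits = 8))
  utils::write.csv(ct, paths[1], row.names = FALSE)
  utils::write.csv(cohort$samples, paths[2], row.names = FALSE)
  utils::write.csv(cohort$frames, paths[3], row.names = FALSE)
  jsonlite::write_json(cohort$truth, paths[4], auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(paths)
}
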