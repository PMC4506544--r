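#' Default pipeline configuration
#'
#' Parameter blocks for every stage of the workflow, merged with any
#' user-supplied overrides (a nested list or a YAML file path).
#'
#' @param overrides Named list (or YAML path) of values overriding the
#'   defaults; unknown names are rejected.
#' @return A named list of stage parameter blocks plus a global `seed`.
#' @export
pipeline_config <- function(overrides = NULL) {
  cfg <- list(
    seed = 1L,
    out_dir = NULL,
    simulate = list(n_embryos = 57, aneuploidy_rate = 0.5,
                    mosaic_mixed_rate = 0.1, effect_size_delta = 2,
                    noise_sd = 1, unlabeled_fraction = 0.2),
    # normalization off by default: the simulated cohorts the pipeline
    # analyses share one Ct scale, so there is no chip effect to remove
    # (see the methods vignette); enable for real multi-chip data
    preprocess = list(baseline = 28, max_failed_fraction = 0.7,
                      normalize = FALSE),
    trajectory = list(t_final = 56, alpha = 0.05, presence_threshold = 2),
    kinetics = list(frame_interval_min = 5, stratify = TRUE,
                    merge_mosaic = FALSE),
    diffexp = list(cutoff = 30, method = "moderated", aggregate = "cell"),
    predict = list(alpha = 0.005, fraction = 2 / 3, folds = 5,
                   repeats = 20, k_values = seq(1, 15, 2),
                   metric = "euclidean")
  )
  if (is.character(overrides) && length(overrides) == 1)
    overrides <- yaml::read_yaml(overrides)
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (!nm %in% names(cfg))
        stop("unknown config block: ", nm, call. = FALSE)
      if (is.list(cfg[[nm]])) {
        bad <- setdiff(names(overrides[[nm]]), names(cfg[[nm]]))
        if (length(bad))
          stop("unknown option(s) in '", nm, "': ",
               paste(bad, collapse = ", "), call. = FALSE)
        cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
      } else cfg[[nm]] <- overrides[[nm]]
    }
  }
  cfg
}

# md5 of the canonical deparse of a config; changes iff a parameter changes
.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg[sort(names(cfg))]), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate, preprocess, trajectory, kinetics, differential
#' expression and ploidy prediction as one reproducible run. The global
#' seed drives every stochastic stage; rerunning with an identical
#' configuration reproduces every output. Stage failures abort with the
#' failing stage named; outputs of completed stages are retained in the
#' error condition.
#'
#' @param config From [pipeline_config()] (a list, or a YAML path).
#' @param cohort Optionally, a pre-built `embryo_cohort` to analyse
#'   instead of simulating one.
#' @return A list with per-stage results (`cohort`, `expr`, `trajectory`,
#'   `kinetics`, `diffexp`, `predictor`, `unlabeled`) and a `manifest`
#'   (package version, seed, parameter hash, per-stage timing in
#'   seconds). If `config$out_dir` is set, stage tables are written there
#'   as CSV/JSON.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  if (is.character(config)) config <- pipeline_config(config)
  results <- list()
  timing <- c()
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timing[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  results$cohort <- stage("simulate", function() {
    if (!is.null(cohort)) return(cohort)
    sc <- do.call(sim_config, c(config$simulate, list(seed = config$seed)))
    simulate_cohort(sc)
  })
  co <- results$cohort

  results$preprocess <- stage("preprocess", function() {
    preprocess_ct(co$ct, baseline = config$preprocess$baseline,
                  max_failed_fraction = config$preprocess$max_failed_fraction,
                  normalize = config$preprocess$normalize)
  })
  expr <- results$preprocess$expr
  samp <- co$samples[match(colnames(expr), co$samples$cell_id), ]

  results$trajectory <- stage("trajectory", function() {
    fit_trajectories(expr, samp$time_h,
                     t_final = config$trajectory$t_final,
                     alpha = config$trajectory$alpha,
                     presence_threshold = config$trajectory$presence_threshold)
  })

  results$kinetics <- stage("kinetics", function() {
    par <- derive_parameters(co$frames,
                             interval_min = config$kinetics$frame_interval_min)
    emb <- co$truth$embryos
    pl <- emb$ploidy[match(par$embryo_id, emb$embryo_id)]
    list(parameters = par,
         summary = kinetics_summary(par, pl,
                                    stratify = config$kinetics$stratify,
                                    merge_mosaic = config$kinetics$merge_mosaic),
         fragmentation = fragmentation_association(
           par$fragmentation_degree,
           ifelse(pl == "mosaic-mixed" & config$kinetics$merge_mosaic,
                  "aneuploid", pl)))
  })

  results$diffexp <- stage("diffexp", function() {
    run_diffexp(expr, samp$time_h, samp$ploidy,
                cutoff = config$diffexp$cutoff,
                method = config$diffexp$method,
                aggregate = config$diffexp$aggregate,
                embryo_id = samp$embryo_id)
  })

  results$predictor <- stage("predict", function() {
    early <- samp$time_h < config$diffexp$cutoff
    labelled <- early & samp$ploidy %in% c("euploid", "aneuploid")
    if (sum(labelled) < 12 ||
        length(unique(samp$ploidy[labelled])) < 2) {
      message("too few labelled early cells; predictor skipped")
      return(NULL)
    }
    train_ploidy_predictor(expr[, labelled, drop = FALSE],
                           samp$ploidy[labelled],
                           alpha = config$predict$alpha,
                           fraction = config$predict$fraction,
                           k_values = config$predict$k_values,
                           folds = config$predict$folds,
                           repeats = config$predict$repeats,
                           metric = config$predict$metric,
                           seed = config$seed)
  })

  results$unlabeled <- stage("predict_unlabeled", function() {
    if (is.null(results$predictor)) return(NULL)
    early <- samp$time_h < config$diffexp$cutoff
    unlab <- early & samp$ploidy == "unknown"
    if (!any(unlab)) return(NULL)
    predict_unlabeled(results$predictor, expr[, unlab, drop = FALSE])
  })

  results$manifest <- list(
    package_version = as.character(utils::packageVersion("zygotrace")),
    seed = config$seed,
    config_hash = .config_hash(config),
    timing_s = timing,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    od <- config$out_dir
    write_cohort(co, file.path(od, "cohort"))
    utils::write.csv(results$trajectory,
                     file.path(od, "trajectory_fits.csv"), row.names = FALSE)
    utils::write.csv(results$kinetics$summary,
                     file.path(od, "kinetics_summary.csv"), row.names = FALSE)
    utils::write.csv(results$diffexp,
                     file.path(od, "diffexp.csv"), row.names = FALSE)
    if (!is.null(results$predictor)) {
      utils::write.csv(results$predictor$cv,
                       file.path(od, "predictor_cv.csv"), row.names = FALSE)
      write_predictor(results$predictor,
                      file.path(od, "predictor_model.json"))
    }
    if (!is.null(results$unlabeled) && !is.null(results$unlabeled$calls))
      utils::write.csv(results$unlabeled$calls,
                       file.path(od, "predicted_unlabeled.csv"),
                       row.names = FALSE)
    jsonlite::write_json(results$manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  results
}
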