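#' Fit a quadratic expression trajectory for one gene
#'
#' Least-squares fit of `E(t) = a t^2 + b t + c` with `t` in hours post
#' pronuclear disappearance, pooling all cells. Significance is the
#' overall regression F-test (model versus intercept-only), the standard
#' ANOVA assessment of regression accuracy. Endpoint values are always
#' evaluated from the fitted curve at `t = 0` and `t = t_final`, even when
#' some cells carry negative (pre-PNd) times.
#'
#' @param time Collection times in hours post PNd.
#' @param expr Expression values for one gene, same length as `time`.
#' @param t_final Final time point in hours (default 56).
#' @return A one-row data.frame: `a`, `b`, `c`, `p`, `n`, `E0`, `E_final`,
#'   `delta` (`E_final - E0`), `fold_change` (`2^|delta|`).
#' @export
fit_quadratic <- function(time, expr, t_final = 56) {
  ok <- is.finite(time) & is.finite(expr)
  time <- time[ok]; expr <- expr[ok]
  if (length(time) < 4)
    stop("quadratic fit needs at least 4 points", call. = FALSE)
  if (length(unique(time)) < 3)
    stop("quadratic fit needs at least 3 distinct times", call. = FALSE)
  fit <- stats::lm(expr ~ time + I(time^2))
  cf <- stats::coef(fit)
  a <- unname(cf[3]); b <- unname(cf[2]); c0 <- unname(cf[1])
  sm <- suppressWarnings(summary(fit))  # noise-free data fits exactly
  fs <- sm$fstatistic
  p <- if (is.null(fs) || any(!is.finite(fs))) 1
       else stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  # constant response: no model sum of squares, regression uninformative
  mss <- sum((stats::fitted(fit) - mean(expr))^2)
  if (mss < 1e-12) { p <- 1 }
  E0 <- c0
  Ef <- a * t_final^2 + b * t_final + c0
  data.frame(a = a, b = b, c = c0, p = unname(p), n = length(time),
             E0 = E0, E_final = Ef, delta = Ef - E0,
             fold_change = 2^abs(Ef - E0))
}

#' Assign a trajectory cluster from fitted endpoints
#'
#' Rule-based taxonomy of significant trajectories on the log2-like
#' expression scale (twofold = 1 unit), using the fitted values at time
#' zero (`E0`) and at the final time point (`delta = E_final - E0`):
#'
#' * cluster 1: present in the zygote (`E0 >= 2`) and decreased at least
#'   twofold (`delta <= -1`);
#' * cluster 2: roughly constant (`|delta| < 1`);
#' * cluster 3: absent at time zero (`E0 < 2`) and at least a twofold
#'   difference at the final time point (`delta >= 1`);
#' * cluster 4: present at time zero (`E0 >= 2`) and twofold or more up at
#'   the final time point (`delta >= 1`).
#'
#' Non-significant fits (`p >= alpha`), and significant fits matching no
#' rule (`E0 < 2` with `delta <= -1`), are unclassified.
#'
#' @param E0 Fitted expression at time zero (vectorized).
#' @param delta Fitted change `E_final - E0`.
#' @param p Regression p-value.
#' @param alpha Significance threshold (default 0.05, per gene,
#'   unadjusted).
#' @return Character vector in `c("1","2","3","4","unclassified")`.
#' @export
assign_cluster <- function(E0, delta, p, alpha = 0.05) {
  out <- rep("unclassified", length(E0))
  sig <- p < alpha
  out[sig & abs(delta) < 1] <- "2"
  out[sig & E0 >= 2 & delta <= -1] <- "1"
  out[sig & E0 < 2 & delta >= 1] <- "3"
  out[sig & E0 >= 2 & delta >= 1] <- "4"
  out
}

#' Classify transcript origin from fitted endpoints
#'
#' A fitted value above the presence threshold at an endpoint means the
#' transcript is present there: present only at time zero implies gametic
#' (inherited) origin, present only at the final time point implies
#' embryonic-genome activation (EGA), present at both implies inheritance
#' plus re-activation, and neither means the transcript is effectively
#' absent throughout. Thresholds are strict (`> 2`).
#'
#' @param E0,E_final Fitted endpoint expression values (vectorized).
#' @param presence_threshold Presence threshold (default 2).
#' @return Character vector in `c("gametic","EGA","both","neither")`.
#' @export
classify_origin <- function(E0, E_final, presence_threshold = 2) {
  start <- E0 > presence_threshold
  end <- E_final > presence_threshold
  out <- rep("neither", length(E0))
  out[start & !end] <- "gametic"
  out[!start & end] <- "EGA"
  out[start & end] <- "both"
  out
}

#' Activation time of an embryonically activated gene
#'
#' For an upward-opening trajectory (`a > 0`) the activation time is the
#' vertex `t* = -b / (2a)` of the quadratic, clamped to `[0, t_final]`: a
#' vertex at or before zero means expression increases from PNd onwards.
#' Concave trajectories have no expression minimum in range, so the
#' activation time is undefined (`NA`). The vertex depends only on `a` and
#' `b`, so the activation time is invariant under vertical shifts.
#'
#' @param a,b Quadratic and linear coefficients (vectorized).
#' @param t_final Final time point in hours (default 56).
#' @return Activation times in hours, `NA` where undefined.
#' @export
activation_time <- function(a, b, t_final = 56) {
  t_star <- ifelse(a > 0, pmin(pmax(-b / (2 * a), 0), t_final), NA_real_)
  t_star
}

#' Fit trajectories for every gene in an expression matrix
#'
#' Per-gene quadratic regression against blastomere collection time, with
#' cluster assignment, origin classification, activation time (clusters 3
#' and 4 only) and a highlight flag for the strongest regressions
#' (fold change > 10 and p < 1e-6).
#'
#' @param expr Genes x cells expression matrix.
#' @param time Collection time (hours post PNd) per cell, aligned with the
#'   columns of `expr`.
#' @param t_final Final time point in hours (default 56).
#' @param alpha Per-gene significance threshold (default 0.05).
#' @param presence_threshold Origin presence threshold (default 2).
#' @return A data.frame with one row per gene: `gene`, `a`, `b`, `c`, `p`,
#'   `n`, `E0`, `E_final`, `delta`, `fold_change`, `cluster`, `origin`,
#'   `activation_time`, `highlight`.
#' @export
fit_trajectories <- function(expr, time, t_final = 56, alpha = 0.05,
                             presence_threshold = 2) {
  stopifnot(is.matrix(expr), length(time) == ncol(expr))
  fits <- do.call(rbind, lapply(seq_len(nrow(expr)), function(i)
    fit_quadratic(time, expr[i, ], t_final)))
  fits <- cbind(data.frame(gene = rownames(expr), stringsAsFactors = FALSE),
                fits)
  fits$cluster <- assign_cluster(fits$E0, fits$delta, fits$p, alpha)
  fits$origin <- classify_origin(fits$E0, fits$E_final, presence_threshold)
  fits$activation_time <- ifelse(fits$cluster %in% c("3", "4"),
                                 activation_time(fits$a, fits$b, t_final),
                                 NA_real_)
  fits$highlight <- fits$fold_change > 10 & fits$p < 1e-6
  rownames(fits) <- NULL
  fits
}

#' Summarize cluster membership of a trajectory fit table
#'
#' @param fits Output of [fit_trajectories()].
#' @return A data.frame with counts per cluster, per origin, the number of
#'   significant genes and the number of EGA genes undetectable in the
#'   zygote.
#' @export
cluster_summary <- function(fits) {
  list(
    n_genes = nrow(fits),
    n_significant = sum(fits$p < 0.05),
    cluster_counts = table(factor(fits$cluster,
                                  c("1", "2", "3", "4", "unclassified"))),
    origin_counts = table(factor(fits$origin,
                                 c("gametic", "EGA", "both", "neither"))),
    n_gametic_source = sum(fits$origin %in% c("gametic", "both")),
    n_ega = sum(fits$origin %in% c("EGA", "both")),
    n_ega_zygote_absent = sum(fits$origin == "EGA")
  )
}
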