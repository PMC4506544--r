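#' Split cells into early and late developmental windows
#'
#' Cells are compared within windows of developmental time to avoid
#' confounding ploidy contrasts with stage: the early window is strictly
#' before the cutoff, the late window at or after it. Cells without a
#' collection time are excluded with a message.
#'
#' @param time Collection times (hours post PNd) per cell.
#' @param cutoff Window boundary in hours (default 30).
#' @return A factor with levels `early`, `late` (`NA` for excluded cells).
#' @export
split_by_window <- function(time, cutoff = 30) {
  miss <- !is.finite(time)
  if (any(miss))
    message(sum(miss), " cell(s) without collection time excluded")
  w <- ifelse(time < cutoff, "early", "late")
  w[miss] <- NA
  factor(w, levels = c("early", "late"))
}

# Newton solve of trigamma(y) = x (decreasing, convex); used for
# moment-matching the variance prior.
.trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif) < 1e-8 * y) break
    }
    y
  }, numeric(1))
}

#' Empirical-Bayes moderated two-sample t-test per gene
#'
#' Gene-wise two-sample t-statistics with the residual variance shrunk
#' toward a common prior: the posterior variance is
#' `s2_tilde = (d0 s0^2 + dg s2_g) / (d0 + dg)` with `dg` the residual
#' degrees of freedom, and the prior `(d0, s0^2)` estimated by moment
#' matching on the log sample variances (mean and variance of
#' `log s2_g`, corrected by the digamma/trigamma moments of the scaled
#' chi-square). The statistic is referred to a t distribution on
#' `dg + d0` degrees of freedom. With a single gene no prior can be
#' estimated (`d0 = 0`) and the test reduces to the ordinary two-sample
#' pooled t-test.
#'
#' @param expr Genes x cells expression matrix.
#' @param labels Per-cell group labels with exactly two levels (cells with
#'   other labels or `NA` are dropped).
#' @return A data.frame per gene: `gene`, `mean_a`, `mean_b` (in sorted
#'   label order), `effect` (`mean_b - mean_a`), `t`, `df`, `p`, and
#'   `flag_zero_var` for genes with no variance in either group (`p = 1`).
#' @export
moderated_test <- function(expr, labels) {
  stopifnot(is.matrix(expr), length(labels) == ncol(expr))
  lv <- sort(unique(stats::na.omit(as.character(labels))))
  if (length(lv) != 2)
    stop("labels must contain exactly two groups", call. = FALSE)
  sel <- !is.na(labels) & labels %in% lv
  expr <- expr[, sel, drop = FALSE]
  g <- as.character(labels[sel])
  n1 <- sum(g == lv[1]); n2 <- sum(g == lv[2])
  if (n1 < 2 || n2 < 2)
    stop("each group needs at least 2 cells", call. = FALSE)
  x1 <- expr[, g == lv[1], drop = FALSE]
  x2 <- expr[, g == lv[2], drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1, stats::var); v2 <- apply(x2, 1, stats::var)
  dg <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dg

  pos <- s2 > 0
  if (sum(pos) >= 2) {
    z <- log(s2[pos])
    e <- z - digamma(dg / 2) + log(dg / 2)
    evar <- stats::var(e)
    rhs <- evar - trigamma(dg / 2)
    if (is.finite(rhs) && rhs > 0) {
      d0 <- 2 * .trigamma_inverse(rhs)
      s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else { d0 <- Inf; s02 <- exp(mean(e)) }
  } else { d0 <- 0; s02 <- 0 }

  if (is.infinite(d0)) {
    s2_tilde <- rep(s02, length(s2))
    df_total <- 1e6
  } else if (d0 == 0) {
    s2_tilde <- s2
    df_total <- dg
  } else {
    s2_tilde <- (d0 * s02 + dg * s2) / (d0 + dg)
    df_total <- dg + d0
  }
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  tt <- (m2 - m1) / se
  p <- 2 * stats::pt(-abs(tt), df_total)
  zero <- s2 == 0 & m1 == m2
  p[zero] <- 1
  tt[zero] <- 0
  out <- data.frame(gene = rownames(expr), mean_a = m1, mean_b = m2,
                    effect = m2 - m1, t = tt, df = df_total, p = p,
                    flag_zero_var = zero, stringsAsFactors = FALSE)
  attr(out, "groups") <- lv
  attr(out, "prior") <- c(d0 = d0, s02 = s02)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; thin validated wrapper around
#' the standard implementation.
#'
#' @param p Raw p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Windowed differential expression between ploidy groups
#'
#' Compares per-cell expression between euploid and aneuploid blastomeres
#' separately within the early (`< cutoff` hours post PNd) and late
#' (`>= cutoff`) windows, using the moderated t-test (or Mann-Whitney)
#' with Benjamini-Hochberg control per window. The unit of analysis is
#' the blastomere by default; `aggregate = "embryo"` averages cells per
#' embryo first to avoid pseudo-replication. Cells whose own ploidy call
#' is unavailable (mosaic embryos without a per-blastomere call, unknowns)
#' are excluded.
#'
#' @param expr Genes x cells expression matrix.
#' @param time Collection time (hours post PNd) per cell.
#' @param ploidy Per-cell ploidy call (`euploid`/`aneuploid`; anything
#'   else excluded).
#' @param cutoff Window boundary in hours (default 30).
#' @param method `"moderated"` (default) or `"mannwhitney"`.
#' @param aggregate `"cell"` (default) or `"embryo"`; the latter requires
#'   `embryo_id`.
#' @param embryo_id Per-cell embryo identifiers (only for embryo
#'   aggregation).
#' @return A data.frame: `gene`, `window`, `mean_euploid`,
#'   `mean_aneuploid`, `effect` (aneuploid - euploid), `direction`, `p`,
#'   `padj`, ordered by window then adjusted p.
#' @export
run_diffexp <- function(expr, time, ploidy, cutoff = 30,
                        method = c("moderated", "mannwhitney"),
                        aggregate = c("cell", "embryo"), embryo_id = NULL) {
  method <- match.arg(method)
  aggregate <- match.arg(aggregate)
  stopifnot(is.matrix(expr), length(time) == ncol(expr),
            length(ploidy) == ncol(expr))
  win <- split_by_window(time, cutoff)
  keep <- ploidy %in% c("euploid", "aneuploid") & !is.na(win)
  res <- list()
  for (w in levels(win)) {
    sel <- keep & win == w
    if (sum(sel) == 0) { message("window '", w, "' is empty"); next }
    ew <- expr[, sel, drop = FALSE]
    pw <- ploidy[sel]
    if (aggregate == "embryo") {
      stopifnot(!is.null(embryo_id))
      eid <- embryo_id[sel]
      grp <- paste(eid, pw, sep = "|")
      ew <- sapply(unique(grp), function(gg)
        rowMeans(ew[, grp == gg, drop = FALSE]))
      ew <- matrix(ew, nrow = nrow(expr), dimnames =
                     list(rownames(expr), unique(grp)))
      pw <- sub("^.*\\|", "", unique(grp))
    }
    if (length(unique(pw)) < 2 || min(table(pw)) < 2) {
      message("window '", w, "' lacks two groups with >= 2 cells; skipped")
      next
    }
    if (method == "moderated") {
      mt <- moderated_test(ew, pw)  # groups sorted: aneuploid, euploid
      tab <- data.frame(gene = mt$gene, window = w,
                        mean_euploid = mt$mean_b,
                        mean_aneuploid = mt$mean_a,
                        effect = mt$mean_a - mt$mean_b,
                        p = mt$p, stringsAsFactors = FALSE)
    } else {
      p <- apply(ew, 1, function(x) {
        a <- x[pw == "aneuploid"]; b <- x[pw == "euploid"]
        if (length(unique(c(a, b))) == 1) return(1)
        suppressWarnings(stats::wilcox.test(a, b)$p.value)
      })
      tab <- data.frame(gene = rownames(ew), window = w,
                        mean_euploid = rowMeans(ew[, pw == "euploid",
                                                   drop = FALSE]),
                        mean_aneuploid = rowMeans(ew[, pw == "aneuploid",
                                                     drop = FALSE]),
                        p = p, stringsAsFactors = FALSE)
      tab$effect <- tab$mean_aneuploid - tab$mean_euploid
    }
    tab$effect <- tab$mean_aneuploid - tab$mean_euploid
    tab$direction <- ifelse(tab$effect >= 0, "up", "down")
    tab$padj <- bh_adjust(tab$p)
    res[[w]] <- tab[order(tab$padj, tab$p), ]
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
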