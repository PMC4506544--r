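#' Convert an imaging frame count to hours
#'
#' @param frame_delta Nonnegative number of frames between two events.
#' @param interval_min Minutes between consecutive frames (default 5).
#' @return Hours.
#' @export
frames_to_hours <- function(frame_delta, interval_min = 5) {
  if (any(frame_delta < 0, na.rm = TRUE))
    stop("frame delta must be nonnegative", call. = FALSE)
  frame_delta * interval_min / 60
}

#' Derive morphokinetic parameters from frame annotations
#'
#' Converts each embryo's annotated event frames into the standard timing
#' parameters: time from pronuclear disappearance (PNd) to the start of
#' the first cytokinesis (h), duration of the first cytokinesis (min), and
#' the pairwise cell-stage intervals from two-to-three up to
#' eight-to-nine cells (h). A missing bounding event leaves the parameter
#' absent (`NA`), never zero. Division annotations of type `1to3` or
#' `1to4` set the abnormal-division flag. Fragmentation degree is read
#' from the `fragmentation` annotation and its timing classed relative to
#' the first cytokinesis.
#'
#' @param frames Frame-annotation table: `embryo_id`, `event`, `frame`,
#'   `value`. Recognized events: `pnd`, `cytokinesis_start`,
#'   `cytokinesis_end`, `reach_2` ... `reach_9`, `division1` ...
#'   (`value` = `1to2`/`1to3`/`1to4`), `fragmentation` (`value` = degree).
#' @param interval_min Minutes per frame (default 5).
#' @return A data.frame, one row per embryo: `embryo_id`,
#'   `pnd_to_cytokinesis`, `cytokinesis_duration`, `t2_3` ... `t8_9`,
#'   `abnormal_division`, `fragmentation_degree`, `fragmentation_timing`.
#' @export
derive_parameters <- function(frames, interval_min = 5) {
  stopifnot(all(c("embryo_id", "event", "frame") %in% names(frames)))
  h <- function(f1, f0) {
    if (is.na(f1) || is.na(f0)) return(NA_real_)
    frames_to_hours(f1 - f0, interval_min)
  }
  out <- lapply(split(frames, frames$embryo_id), function(fr) {
    get1 <- function(ev) {
      f <- fr$frame[fr$event == ev]
      if (length(f) == 0) NA_real_ else f[1]
    }
    pnd <- get1("pnd")
    cs <- get1("cytokinesis_start")
    ce <- get1("cytokinesis_end")
    ord <- c(pnd, cs, ce)
    ord <- ord[!is.na(ord)]
    if (is.unsorted(ord))
      stop(sprintf("out-of-order frames for embryo %s", fr$embryo_id[1]),
           call. = FALSE)
    reach <- vapply(2:9, function(k) get1(sprintf("reach_%d", k)),
                    numeric(1))
    rr <- reach[!is.na(reach)]
    if (is.unsorted(rr))
      stop(sprintf("out-of-order frames for embryo %s", fr$embryo_id[1]),
           call. = FALSE)
    trans <- vapply(1:7, function(i) h(reach[i + 1], reach[i]), numeric(1))
    div_rows <- fr[grepl("^division", fr$event), , drop = FALSE]
    abnormal <- any(div_rows$value %in% c("1to3", "1to4"))
    fragrow <- fr[fr$event == "fragmentation", , drop = FALSE]
    if (nrow(fragrow)) {
      deg <- suppressWarnings(as.numeric(fragrow$value[1]))
      ff <- fragrow$frame[1]
      timing <- if (!is.na(cs) && ff < cs) "before"
                else if (!is.na(ce) && ff <= ce) "during"
                else if (!is.na(ce)) "after" else "unknown"
    } else { deg <- 0; timing <- "none" }
    data.frame(
      embryo_id = fr$embryo_id[1],
      pnd_to_cytokinesis = h(cs, pnd),
      cytokinesis_duration = if (is.na(ce) || is.na(cs)) NA_real_
                             else frames_to_hours(ce - cs, interval_min) * 60,
      t2_3 = trans[1], t3_4 = trans[2], t4_5 = trans[3], t5_6 = trans[4],
      t6_7 = trans[5], t7_8 = trans[6], t8_9 = trans[7],
      abnormal_division = abnormal,
      fragmentation_degree = deg,
      fragmentation_timing = timing,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Compare a timing parameter between two groups
#'
#' Reports each group's median and quartiles (linear-interpolation
#' quantiles, as `(Q1; Q3)`) and a two-sided Mann-Whitney U test: exact
#' when both groups have at most 20 untied observations, normal
#' approximation with continuity and tie correction otherwise.
#'
#' @param values_a,values_b Numeric vectors (NAs dropped).
#' @param exact_max Largest per-group size for the exact test (default 20).
#' @return A list: `n_a`, `median_a`, `q1_a`, `q3_a`, likewise for `b`,
#'   and `p` (`NA` when either group has fewer than 2 values).
#' @export
compare_groups <- function(values_a, values_b, exact_max = 20) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (length(a) == 0 || length(b) == 0)
    stop("both groups must contain at least one value", call. = FALSE)
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), type = 7,
                                    names = FALSE)
  qa <- qs(a); qb <- qs(b)
  p <- if (length(a) < 2 || length(b) < 2) NA_real_ else {
    exact <- length(a) <= exact_max && length(b) <= exact_max &&
      !any(duplicated(c(a, b)))
    suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  }
  list(n_a = length(a), median_a = qa[2], q1_a = qa[1], q3_a = qa[3],
       n_b = length(b), median_b = qb[2], q1_b = qb[1], q3_b = qb[3],
       p = p)
}

#' Association between fragmentation degree and ploidy
#'
#' Dichotomizes fragmentation at 25% (low < 25% versus high >= 25%),
#' cross-tabulates against binary ploidy and applies a two-sided Fisher
#' exact test.
#'
#' @param fragmentation Numeric fragmentation degrees (percent).
#' @param ploidy Character vector, `"euploid"`/`"aneuploid"`, aligned with
#'   `fragmentation`; other labels are dropped.
#' @param high_cutoff Degree at or above which fragmentation is "high".
#' @return A list: `table` (2x2 counts, fragmentation class x ploidy) and
#'   `p` (two-sided Fisher exact).
#' @export
fragmentation_association <- function(fragmentation, ploidy,
                                      high_cutoff = 25) {
  keep <- ploidy %in% c("euploid", "aneuploid") & is.finite(fragmentation)
  fragmentation <- fragmentation[keep]
  ploidy <- ploidy[keep]
  cls <- factor(ifelse(fragmentation >= high_cutoff, "high", "low"),
                levels = c("low", "high"))
  pl <- factor(ploidy, levels = c("aneuploid", "euploid"))
  tab <- table(cls, pl)
  list(table = tab, p = stats::fisher.test(tab)$p.value)
}

#' Embryo ploidy consensus from per-blastomere calls
#'
#' All analysed blastomeres abnormal gives `aneuploid`, all euploid gives
#' `euploid`, a mixture gives `mosaic-mixed` (excluded from binary
#' comparisons by default), and no informative calls gives `unknown`.
#'
#' @param calls Character vector of per-blastomere calls for one embryo.
#' @return One of `"euploid"`, `"aneuploid"`, `"mosaic-mixed"`,
#'   `"unknown"`.
#' @export
ploidy_consensus <- function(calls) {
  calls <- calls[calls %in% c("euploid", "aneuploid")]
  if (length(calls) == 0) return("unknown")
  if (all(calls == "euploid")) return("euploid")
  if (all(calls == "aneuploid")) return("aneuploid")
  "mosaic-mixed"
}

#' Group comparison table of morphokinetic parameters
#'
#' Builds the standard summary: per parameter and ploidy group, the count,
#' median and quartiles with a Mann-Whitney p-value, for all embryos and
#' (optionally) stratified into normal- and abnormal-division subgroups.
#' Mosaic-mixed and unknown embryos are excluded from the binary
#' comparison unless `merge_mosaic = TRUE` folds mosaic-mixed embryos into
#' the aneuploid group.
#'
#' @param params Parameter table from [derive_parameters()].
#' @param ploidy Named or aligned character vector of embryo consensus
#'   ploidy (`euploid`/`aneuploid`/`mosaic-mixed`/`unknown`).
#' @param stratify Also report normal/abnormal division strata.
#' @param merge_mosaic Count mosaic-mixed embryos as aneuploid.
#' @return A data.frame: `parameter`, `stratum`, `n_euploid`,
#'   `median_euploid`, `q1_euploid`, `q3_euploid`, the aneuploid
#'   equivalents, and `p`.
#' @export
kinetics_summary <- function(params, ploidy, stratify = TRUE,
                             merge_mosaic = FALSE) {
  stopifnot(length(ploidy) == nrow(params))
  pl <- ploidy
  if (merge_mosaic) pl[pl == "mosaic-mixed"] <- "aneuploid"
  keep <- pl %in% c("euploid", "aneuploid")
  params <- params[keep, , drop = FALSE]
  pl <- pl[keep]
  pnames <- c("pnd_to_cytokinesis", "cytokinesis_duration",
              "t2_3", "t3_4", "t4_5", "t5_6", "t6_7", "t7_8", "t8_9")
  strata <- list(all = rep(TRUE, nrow(params)))
  if (stratify) {
    strata$normal <- !params$abnormal_division
    strata$abnormal <- params$abnormal_division
  }
  rows <- list()
  for (s in names(strata)) {
    sel <- strata[[s]]
    for (pn in pnames) {
      va <- params[[pn]][sel & pl == "euploid"]
      vb <- params[[pn]][sel & pl == "aneuploid"]
      va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
      if (length(va) == 0 && length(vb) == 0) next
      cmp <- if (length(va) && length(vb)) compare_groups(va, vb)
             else NULL
      qs <- function(x) if (length(x)) stats::quantile(
        x, c(0.25, 0.5, 0.75), type = 7, names = FALSE) else rep(NA_real_, 3)
      qa <- qs(va); qb <- qs(vb)
      rows[[length(rows) + 1]] <- data.frame(
        parameter = pn, stratum = s,
        n_euploid = length(va), median_euploid = qa[2],
        q1_euploid = qa[1], q3_euploid = qa[3],
        n_aneuploid = length(vb), median_aneuploid = qb[2],
        q1_aneuploid = qb[1], q3_aneuploid = qb[3],
        p = if (is.null(cmp)) NA_real_ else cmp$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
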