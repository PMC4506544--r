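#' Convert Ct values to expression values
#'
#' Expression is measured in cycles below the detection baseline,
#' `E = baseline - Ct`, a log2-like scale (one unit is one PCR cycle, i.e.
#' a twofold difference in template). Ct values above the baseline, and
#' undetected reactions (`NA`), are called as no expression (`E = 0`).
#'
#' @param ct Numeric vector of Ct values; `NA` means undetected.
#' @param baseline Detection baseline in cycles (default 28).
#' @return Numeric vector of expression values in `[0, baseline]`.
#' @export
ct_to_expression <- function(ct, baseline = 28) {
  stopifnot(is.numeric(baseline), length(baseline) == 1, baseline > 0)
  if (any(ct < 0, na.rm = TRUE))
    stop("negative Ct values are not valid", call. = FALSE)
  e <- baseline - ct
  e[is.na(ct) | ct > baseline] <- 0
  e
}

#' Average technical replicates into an expression matrix
#'
#' Each replicate Ct is converted to the expression scale first (undetected
#' counted as 0) and replicates are then averaged, so a (cell, gene) assay
#' detected in only some replicates contributes a fractional mean rather
#' than being discarded. Replicates whose Ct range exceeds
#' `discordance_cycles` are flagged but kept.
#'
#' @param ct Long-format Ct data: columns `cell_id`, `gene`, `replicate`,
#'   `ct` (`NA` = undetected).
#' @param baseline Detection baseline in cycles.
#' @param discordance_cycles Replicate Ct range above which an assay is
#'   flagged as discordant.
#' @return A list: `expr`, the genes x cells expression matrix;
#'   `discordant`, a data.frame of flagged (cell, gene) assays.
#' @export
average_replicates <- function(ct, baseline = 28, discordance_cycles = 2) {
  stopifnot(all(c("cell_id", "gene", "replicate", "ct") %in% names(ct)))
  if (nrow(ct) == 0) stop("empty Ct table", call. = FALSE)
  e <- ct_to_expression(ct$ct, baseline)
  genes <- unique(ct$gene)
  cellids <- unique(ct$cell_id)
  gi <- match(ct$gene, genes)
  ci <- match(ct$cell_id, cellids)
  idx <- (ci - 1L) * length(genes) + gi
  sums <- tapply(e, idx, sum)
  cnts <- tapply(e, idx, length)
  expr <- matrix(0, nrow = length(genes), ncol = length(cellids),
                 dimnames = list(genes, cellids))
  pos <- as.integer(names(sums))
  expr[pos] <- sums / cnts

  rng <- tapply(ct$ct, idx, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) 0 else diff(range(x))
  })
  bad <- as.integer(names(rng))[rng > discordance_cycles]
  discordant <- data.frame(
    cell_id = cellids[(bad - 1L) %/% length(genes) + 1L],
    gene = genes[(bad - 1L) %% length(genes) + 1L],
    ct_range = as.numeric(rng[rng > discordance_cycles]),
    stringsAsFactors = FALSE)
  list(expr = expr, discordant = discordant)
}

#' Quantile-normalize an expression matrix across cells
#'
#' Forces every cell (column) onto a common expression distribution: the
#' rank-wise mean of the cells' sorted value vectors. Undetected values
#' (zeros) are structural detection failures, not low measurements, so they
#' are excluded from the rank pool and restored to 0 afterwards; cells with
#' different numbers of detected genes are mapped onto the common
#' distribution by linear interpolation of its quantile function. Tied
#' values within a cell receive the mean of the normalized values at their
#' tied ranks. With no zeros and no ties the sorted vector of every output
#' column is exactly the rank-wise mean of the input sorted vectors, and
#' the operation is idempotent.
#'
#' @param expr Genes x cells expression matrix (0 = undetected).
#' @return Normalized matrix of the same shape, zeros preserved.
#' @export
quantile_normalize <- function(expr) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 2) {
    warning("quantile normalization needs at least 2 cells; returning input")
    return(expr)
  }
  detected <- expr > 0
  n_det <- colSums(detected)
  if (any(n_det == 0)) {
    # all-undetected cells carry no rank information; left as zeros
    usable <- n_det > 0
  } else usable <- rep(TRUE, ncol(expr))

  grid_n <- nrow(expr)
  pgrid <- if (grid_n > 1) (seq_len(grid_n) - 1) / (grid_n - 1) else 0.5
  qmat <- sapply(which(usable), function(j) {
    x <- sort(expr[detected[, j], j])
    if (length(x) == 1) rep(x, grid_n)
    else stats::approx(x = (seq_along(x) - 1) / (length(x) - 1), y = x,
                       xout = pgrid)$y
  })
  qmat <- matrix(qmat, nrow = grid_n)
  ref <- rowMeans(qmat)

  out <- expr
  for (j in which(usable)) {
    x <- expr[detected[, j], j]
    n <- length(x)
    r <- rank(x, ties.method = "first")
    p <- if (n > 1) (r - 1) / (n - 1) else 0.5
    v <- stats::approx(x = pgrid, y = ref, xout = p)$y
    # ties: mean of the normalized values at the tied ranks
    v <- stats::ave(v, match(x, x), FUN = mean)
    out[detected[, j], j] <- v
  }
  out
}

#' Quality-control filter on cells
#'
#' Removes cells whose fraction of undetected assays exceeds the
#' threshold; such disproportionately failed samples indicate degraded
#' material or a failed chip position.
#'
#' @param expr Genes x cells expression matrix (0 = undetected).
#' @param max_failed_fraction Maximum tolerated undetected fraction,
#'   in (0, 1].
#' @return A list: `expr` (retained cells) and `discarded`, a log
#'   data.frame with `cell_id`, `failed_fraction`, `reason`.
#' @export
qc_filter_cells <- function(expr, max_failed_fraction = 0.7) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) == 0 || nrow(expr) == 0)
    stop("empty expression matrix", call. = FALSE)
  stopifnot(max_failed_fraction > 0, max_failed_fraction <= 1)
  frac <- colMeans(expr == 0)
  drop <- frac > max_failed_fraction
  discarded <- data.frame(
    cell_id = colnames(expr)[drop],
    failed_fraction = unname(frac[drop]),
    reason = sprintf("undetected fraction %.2f > %.2f", frac[drop],
                     max_failed_fraction),
    stringsAsFactors = FALSE)
  list(expr = expr[, !drop, drop = FALSE], discarded = discarded)
}

#' Full Ct preprocessing pipeline
#'
#' Replicate averaging on the expression scale, cell-level QC, then
#' quantile normalization across the retained cells.
#'
#' @inheritParams average_replicates
#' @inheritParams qc_filter_cells
#' @param normalize Apply quantile normalization (default `TRUE`).
#' @return A list: `expr` (normalized genes x cells matrix), `discarded`
#'   (QC log), `discordant` (replicate-discordance log).
#' @export
preprocess_ct <- function(ct, baseline = 28, max_failed_fraction = 0.7,
                          normalize = TRUE, discordance_cycles = 2) {
  avg <- average_replicates(ct, baseline, discordance_cycles)
  qc <- qc_filter_cells(avg$expr, max_failed_fraction)
  expr <- qc$expr
  if (normalize && ncol(expr) >= 2) expr <- quantile_normalize(expr)
  list(expr = expr, discarded = qc$discarded, discordant = avg$discordant)
}

#' Read a long-format Ct CSV
#'
#' Columns `cell_id`, `gene`, `replicate`, `ct`; empty fields or `"ND"`
#' mark undetected reactions.
#'
#' @param path CSV path.
#' @return Long-format Ct data.frame with numeric `ct` (`NA` = undetected).
#' @export
read_ct_csv <- function(path) {
  ct <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(ct = "character"))
  need <- c("cell_id", "gene", "replicate", "ct")
  if (!all(need %in% names(ct)))
    stop("Ct CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  raw <- trimws(ct$ct)
  ct$ct <- suppressWarnings(as.numeric(raw))
  ct$ct[raw %in% c("", "ND", "NA")] <- NA_real_
  ct
}
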