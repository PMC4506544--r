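#' Mann-Whitney feature selection for the ploidy signature
#'
#' Per-gene two-sided Mann-Whitney U test between aneuploid and euploid
#' expression profiles; genes below the threshold form the candidate
#' signature, ordered by p-value.
#'
#' @param expr Genes x cells expression matrix.
#' @param labels Per-cell labels (`euploid`/`aneuploid`), both classes
#'   present.
#' @param alpha Selection threshold on the raw p-value (0.05 for the
#'   candidate set, 0.005 for the stringent signature).
#' @return A data.frame `gene`, `p` for selected genes, sorted by `p`;
#'   the full per-gene p-value table is attached as attribute `all`.
#' @export
select_features <- function(expr, labels, alpha = 0.005) {
  stopifnot(is.matrix(expr), length(labels) == ncol(expr))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("both classes must be present for feature selection",
         call. = FALSE)
  p <- apply(expr, 1, function(x) {
    a <- x[labels == "aneuploid"]; b <- x[labels == "euploid"]
    if (length(unique(c(a, b))) == 1) return(1)
    suppressWarnings(stats::wilcox.test(a, b)$p.value)
  })
  all <- data.frame(gene = rownames(expr), p = unname(p),
                    stringsAsFactors = FALSE)
  all <- all[order(all$p), ]
  sel <- if (alpha >= 1) all else all[all$p < alpha, , drop = FALSE]
  rownames(sel) <- rownames(all) <- NULL
  attr(sel, "all") <- all
  sel
}

#' Stratified train/validation split
#'
#' Randomly assigns samples to a training and a validation set,
#' class-stratified so both sets preserve the class balance; per-class
#' training quotas are floors of `fraction * n_class` topped up by largest
#' fractional remainder until the overall training size is
#' `round(fraction * n)`.
#'
#' @param labels Class labels per sample.
#' @param fraction Training fraction (default 2/3).
#' @param seed RNG seed making the split reproducible.
#' @return A list of integer index vectors `train` and `validation`
#'   (disjoint, exhaustive).
#' @export
split_train_validation <- function(labels, fraction = 2 / 3, seed = 1) {
  labels <- as.character(labels)
  n <- length(labels)
  classes <- sort(unique(labels))
  if (any(table(labels) < 3))
    stop("each class needs at least 3 samples to split", call. = FALSE)
  set.seed(seed)
  target <- round(fraction * n)
  quota <- vapply(classes, function(cl) floor(fraction * sum(labels == cl)),
                  numeric(1))
  rem <- vapply(classes, function(cl) fraction * sum(labels == cl),
                numeric(1)) - quota
  short <- target - sum(quota)
  if (short > 0) {
    ord <- order(rem, vapply(classes, function(cl) sum(labels == cl),
                             numeric(1)), decreasing = TRUE)
    quota[ord[seq_len(short)]] <- quota[ord[seq_len(short)]] + 1
  }
  train <- integer(0)
  for (i in seq_along(classes)) {
    idx <- which(labels == classes[i])
    train <- c(train, sample(idx, quota[i]))
  }
  train <- sort(train)
  list(train = train, validation = setdiff(seq_len(n), train))
}

.knn_dist <- function(train_x, query, metric) {
  switch(metric,
    euclidean = sqrt(colSums((t(train_x) - query)^2)),
    manhattan = colSums(abs(t(train_x) - query)),
    cosine = {
      qn <- sqrt(sum(query^2)); tn <- sqrt(rowSums(train_x^2))
      1 - as.numeric(train_x %*% query) / pmax(qn * tn, .Machine$double.eps)
    },
    stop("unknown metric: ", metric, call. = FALSE))
}

#' k-nearest-neighbour class prediction
#'
#' Assigns each query the majority class among its k nearest training
#' samples. The aneuploid vote fraction serves as a continuous score.
#' Distance ties at the k-th position are broken by stable training-sample
#' order; an even split of votes falls back to the class of the single
#' nearest neighbour.
#'
#' @param train_x Training matrix, samples x genes.
#' @param train_y Training labels (`euploid`/`aneuploid`).
#' @param query_x Query matrix, samples x genes (a vector is treated as
#'   one sample).
#' @param k Number of neighbours, `1 <= k <= nrow(train_x)`.
#' @param metric `"euclidean"` (default), `"manhattan"` or `"cosine"`.
#' @return A data.frame per query: `class`, `score` (aneuploid vote
#'   fraction).
#' @export
knn_predict <- function(train_x, train_y, query_x, k = 7,
                        metric = c("euclidean", "manhattan", "cosine")) {
  metric <- match.arg(metric)
  if (is.vector(query_x)) query_x <- matrix(query_x, nrow = 1)
  train_x <- as.matrix(train_x); query_x <- as.matrix(query_x)
  stopifnot(nrow(train_x) == length(train_y), k >= 1, k <= nrow(train_x),
            ncol(train_x) == ncol(query_x))
  train_y <- as.character(train_y)
  out <- lapply(seq_len(nrow(query_x)), function(i) {
    d <- .knn_dist(train_x, query_x[i, ], metric)
    ord <- order(d, seq_along(d))       # stable tie-break
    nb <- train_y[ord[seq_len(k)]]
    votes_an <- sum(nb == "aneuploid")
    cls <- if (votes_an * 2 > k) "aneuploid"
           else if (votes_an * 2 < k) "euploid"
           else train_y[ord[1]]         # even split: nearest neighbour
    data.frame(class = cls, score = votes_an / k, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Binary classification metrics
#'
#' Confusion counts with aneuploid as the positive class, accuracy (%),
#' Matthews correlation coefficient, root mean squared error of the vote
#' score against the 0/1 label, and AUC computed as the normalized
#' Mann-Whitney rank statistic of the scores. With a single-class truth,
#' MCC and AUC are undefined and reported as `NA`.
#'
#' @param truth True labels (`euploid`/`aneuploid`).
#' @param predicted Predicted labels.
#' @param scores Continuous aneuploid scores in `[0, 1]` (optional; RMSE
#'   and AUC are `NA` without them).
#' @return A list: `tp`, `fp`, `tn`, `fn`, `accuracy`, `mcc`, `rmse`,
#'   `auc`.
#' @export
compute_metrics <- function(truth, predicted, scores = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have the same length", call. = FALSE)
  if (length(truth) == 0) stop("empty input", call. = FALSE)
  pos <- "aneuploid"
  tp <- sum(truth == pos & predicted == pos)
  fp <- sum(truth != pos & predicted == pos)
  tn <- sum(truth != pos & predicted != pos)
  fn <- sum(truth == pos & predicted != pos)
  acc <- 100 * (tp + tn) / length(truth)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  single <- length(unique(truth)) < 2
  mcc <- if (single) NA_real_
         else if (denom == 0) 0
         else (tp * tn - fp * fn) / denom
  rmse <- auc <- NA_real_
  if (!is.null(scores)) {
    y <- as.numeric(truth == pos)
    rmse <- sqrt(mean((scores - y)^2))
    if (!single) {
      sa <- scores[truth == pos]; se <- scores[truth != pos]
      r <- rank(c(sa, se))
      u <- sum(r[seq_along(sa)]) - length(sa) * (length(sa) + 1) / 2
      auc <- u / (length(sa) * length(se))
    }
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = acc, mcc = mcc, rmse = rmse, auc = auc)
}

#' Repeated stratified cross-validation of the k-NN model
#'
#' Stratified k-fold cross-validation repeated with fresh fold draws,
#' evaluating each candidate neighbour count; metrics are pooled over the
#' folds of a repeat and averaged over repeats. The best k is chosen by
#' mean accuracy, ties resolved toward the larger (more stringent) k.
#'
#' @param x Samples x genes training matrix.
#' @param y Labels per sample.
#' @param k_values Candidate neighbour counts (odd values avoid vote
#'   ties).
#' @param folds Number of folds (reduced with a warning if it exceeds the
#'   minority class size).
#' @param repeats Number of repetitions.
#' @param seed RNG seed for the fold draws.
#' @param metric Distance metric, see [knn_predict()].
#' @return A list: `metrics`, a data.frame per k (`k`, `accuracy`, `mcc`,
#'   `rmse`, `auc`, each a mean over repeats), and `best_k`.
#' @export
cross_validate <- function(x, y, k_values = seq(1, 15, 2), folds = 5,
                           repeats = 20, seed = 1, metric = "euclidean") {
  x <- as.matrix(x)
  y <- as.character(y)
  stopifnot(nrow(x) == length(y), folds >= 2)
  minc <- min(table(y))
  if (folds > minc) {
    warning("folds reduced to minority class size (", minc, ")")
    folds <- max(2, minc)
  }
  k_values <- k_values[k_values <= nrow(x) - ceiling(nrow(x) / folds)]
  if (length(k_values) == 0) k_values <- 1
  set.seed(seed)
  per_rep <- array(NA_real_, c(repeats, length(k_values), 4),
                   dimnames = list(NULL, k_values,
                                   c("accuracy", "mcc", "rmse", "auc")))
  for (r in seq_len(repeats)) {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
    for (ki in seq_along(k_values)) {
      k <- k_values[ki]
      pred <- character(length(y)); score <- numeric(length(y))
      for (f in seq_len(folds)) {
        te <- fold == f
        if (!any(te)) next
        res <- knn_predict(x[!te, , drop = FALSE], y[!te],
                           x[te, , drop = FALSE],
                           k = min(k, sum(!te)), metric = metric)
        pred[te] <- res$class; score[te] <- res$score
      }
      m <- compute_metrics(y, pred, score)
      per_rep[r, ki, ] <- c(m$accuracy, m$mcc, m$rmse, m$auc)
    }
  }
  metrics <- data.frame(k = k_values,
                        accuracy = colMeans(per_rep[, , 1, drop = FALSE],
                                            na.rm = TRUE),
                        mcc = colMeans(per_rep[, , 2, drop = FALSE],
                                       na.rm = TRUE),
                        rmse = colMeans(per_rep[, , 3, drop = FALSE],
                                        na.rm = TRUE),
                        auc = colMeans(per_rep[, , 4, drop = FALSE],
                                       na.rm = TRUE))
  rownames(metrics) <- NULL
  best <- metrics$k[metrics$accuracy >= max(metrics$accuracy) - 1e-12]
  list(metrics = metrics, best_k = max(best))
}

#' Train the transcriptomic ploidy predictor
#'
#' End-to-end model construction on early-window labelled expression
#' profiles: Mann-Whitney feature selection, stratified train/validation
#' split, repeated stratified cross-validation over candidate k, and
#' evaluation of the chosen model on the held-out validation set. By
#' default features are selected on the full labelled set before the
#' split; `nested_selection = TRUE` reselects features inside each
#' training portion (the leakage-safe alternative) for the CV estimate.
#'
#' @param expr Genes x cells expression matrix (labelled cells).
#' @param labels Per-cell ploidy labels.
#' @param alpha Feature-selection threshold (default 0.005).
#' @param fraction Training fraction (default 2/3).
#' @param k_values Candidate neighbour counts.
#' @param folds,repeats Cross-validation design (default 5 x 20).
#' @param metric Distance metric.
#' @param seed RNG seed (split and fold draws).
#' @param nested_selection Reselect features within each CV training set.
#' @return An object of class `ploidy_predictor`: signature genes with
#'   p-values, `k`, training matrix and labels, CV metric table,
#'   validation metrics and indices.
#' @export
train_ploidy_predictor <- function(expr, labels, alpha = 0.005,
                                   fraction = 2 / 3,
                                   k_values = seq(1, 15, 2), folds = 5,
                                   repeats = 20, metric = "euclidean",
                                   seed = 1, nested_selection = FALSE) {
  stopifnot(is.matrix(expr), length(labels) == ncol(expr))
  sel <- select_features(expr, labels, alpha)
  if (nrow(sel) == 0)
    stop("no gene passed the selection threshold", call. = FALSE)
  sp <- split_train_validation(labels, fraction, seed)
  xt <- t(expr[sel$gene, sp$train, drop = FALSE])
  yt <- as.character(labels[sp$train])
  if (nested_selection) {
    cv <- .cross_validate_nested(expr[, sp$train, drop = FALSE], yt, alpha,
                                 k_values, folds, repeats, seed, metric)
  } else {
    cv <- cross_validate(xt, yt, k_values, folds, repeats, seed, metric)
  }
  xv <- t(expr[sel$gene, sp$validation, drop = FALSE])
  yv <- as.character(labels[sp$validation])
  pv <- knn_predict(xt, yt, xv, k = min(cv$best_k, nrow(xt)), metric)
  val <- compute_metrics(yv, pv$class, pv$score)
  structure(list(signature = sel, k = cv$best_k, metric = metric,
                 train_x = xt, train_y = yt, cv = cv$metrics,
                 validation = val, split = sp, alpha = alpha,
                 nested_selection = nested_selection, seed = seed),
            class = "ploidy_predictor")
}

# nested variant: feature selection redone inside each CV training portion
.cross_validate_nested <- function(expr, y, alpha, k_values, folds,
                                   repeats, seed, metric) {
  set.seed(seed)
  minc <- min(table(y))
  if (folds > minc) folds <- max(2, minc)
  per_rep <- array(NA_real_, c(repeats, length(k_values), 4))
  for (r in seq_len(repeats)) {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
    for (ki in seq_along(k_values)) {
      k <- k_values[ki]
      pred <- character(length(y)); score <- numeric(length(y))
      for (f in seq_len(folds)) {
        te <- fold == f
        sel_f <- select_features(expr[, !te, drop = FALSE], y[!te], alpha)
        genes <- if (nrow(sel_f)) sel_f$gene
                 else attr(sel_f, "all")$gene[1]
        res <- knn_predict(t(expr[genes, !te, drop = FALSE]), y[!te],
                           t(expr[genes, te, drop = FALSE]),
                           k = min(k, sum(!te)), metric = metric)
        pred[te] <- res$class; score[te] <- res$score
      }
      m <- compute_metrics(y, pred, score)
      per_rep[r, ki, ] <- c(m$accuracy, m$mcc, m$rmse, m$auc)
    }
  }
  metrics <- data.frame(k = k_values,
                        accuracy = apply(per_rep[, , 1, drop = FALSE], 2,
                                         mean, na.rm = TRUE),
                        mcc = apply(per_rep[, , 2, drop = FALSE], 2, mean,
                                    na.rm = TRUE),
                        rmse = apply(per_rep[, , 3, drop = FALSE], 2, mean,
                                     na.rm = TRUE),
                        auc = apply(per_rep[, , 4, drop = FALSE], 2, mean,
                                    na.rm = TRUE))
  best <- metrics$k[metrics$accuracy >= max(metrics$accuracy) - 1e-12]
  list(metrics = metrics, best_k = max(best))
}

#' @export
print.ploidy_predictor <- function(x, ...) {
  cat(sprintf("k-NN ploidy predictor: %d signature genes (p < %g), k = %d\n",
              nrow(x$signature), x$alpha, x$k))
  best <- x$cv[x$cv$k == x$k, ]
  cat(sprintf("  CV: accuracy %.1f%%, MCC %.2f, RMSE %.2f, AUC %.2f\n",
              best$accuracy, best$mcc, best$rmse, best$auc))
  cat(sprintf("  validation: accuracy %.1f%% (%d/%d)\n",
              x$validation$accuracy,
              x$validation$tp + x$validation$tn,
              with(x$validation, tp + tn + fp + fn)))
  cat("  genes:", paste(x$signature$gene, collapse = ", "), "\n")
  invisible(x)
}

#' Classify unlabelled expression profiles
#'
#' Applies a trained predictor to new samples and reports the cohort
#' aneuploidy incidence. Samples missing any signature gene are skipped
#' with a log entry.
#'
#' @param model A `ploidy_predictor`.
#' @param expr Genes x cells expression matrix of new samples.
#' @return A list: `calls` (per-sample `cell_id`, `class`, `score`),
#'   `incidence` (percent called aneuploid), `skipped` (cell ids missing
#'   signature genes).
#' @export
predict_unlabeled <- function(model, expr) {
  stopifnot(inherits(model, "ploidy_predictor"), is.matrix(expr))
  genes <- model$signature$gene
  missing <- setdiff(genes, rownames(expr))
  skipped <- character(0)
  if (length(missing) > 0) {
    skipped <- colnames(expr)
    message("samples skipped: signature genes missing (",
            paste(missing, collapse = ", "), ")")
    return(list(calls = NULL, incidence = NA_real_, skipped = skipped))
  }
  q <- t(expr[genes, , drop = FALSE])
  res <- knn_predict(model$train_x, model$train_y, q,
                     k = min(model$k, nrow(model$train_x)), model$metric)
  calls <- data.frame(cell_id = colnames(expr), class = res$class,
                      score = res$score, stringsAsFactors = FALSE)
  list(calls = calls, incidence = 100 * mean(res$class == "aneuploid"),
       skipped = skipped)
}

#' Serialize a ploidy predictor to JSON
#'
#' @param model A `ploidy_predictor`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictor <- function(model, path) {
  stopifnot(inherits(model, "ploidy_predictor"))
  obj <- list(signature = model$signature, k = model$k,
              metric = model$metric, alpha = model$alpha,
              train_y = model$train_y,
              train_x = as.data.frame(model$train_x),
              genes = colnames(model$train_x))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a ploidy predictor from JSON
#'
#' @param path Path written by [write_predictor()].
#' @return A `ploidy_predictor` (without CV/validation history).
#' @export
read_predictor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  xt <- as.matrix(obj$train_x)
  colnames(xt) <- obj$genes
  structure(list(signature = obj$signature, k = obj$k, metric = obj$metric,
                 alpha = obj$alpha, train_x = xt, train_y = obj$train_y,
                 cv = NULL, validation = NULL),
            class = "ploidy_predictor")
}
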