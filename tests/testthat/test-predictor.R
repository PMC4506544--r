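test_that("feature selection keeps genes separating the classes", {
  set.seed(2)
  m <- matrix(rnorm(20 * 16, 5, 1), 20, 16,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  labels <- rep(c("euploid", "aneuploid"), each = 8)
  m[1, labels == "aneuploid"] <- m[1, labels == "aneuploid"] + 5
  m[2, ] <- 3  # constant gene: no information
  all_sel <- select_features(m, labels, alpha = 1)
  expect_equal(nrow(all_sel), 20)
  expect_equal(all_sel$gene[1], "g01")
  some <- select_features(m, labels, alpha = 0.9)
  expect_false("g02" %in% some$gene)
  expect_error(select_features(m, rep("euploid", 16)), "both classes")
})

test_that("the train/validation split is stratified and reproducible", {
  labels <- rep(c("euploid", "aneuploid"), c(25, 16))
  sp <- split_train_validation(labels, 2 / 3, seed = 4)
  expect_equal(length(sp$train), 27)
  expect_equal(length(sp$validation), 14)
  expect_setequal(c(sp$train, sp$validation), seq_along(labels))
  # class proportions preserved within one sample
  p_all <- mean(labels == "aneuploid")
  p_tr <- mean(labels[sp$train] == "aneuploid")
  expect_lt(abs(p_tr - p_all), 1 / length(sp$train) + 1e-9)
  sp2 <- split_train_validation(labels, 2 / 3, seed = 4)
  expect_identical(sp, sp2)
  expect_error(split_train_validation(c("euploid", "euploid", "aneuploid",
                                        "aneuploid", "aneuploid")),
               "at least 3")
})

test_that("k-NN reproduces hand-checkable toy geometry", {
  train <- rbind(c(0, 0), c(1, 0), c(10, 0), c(11, 0))
  y <- c("euploid", "euploid", "aneuploid", "aneuploid")
  r <- knn_predict(train, y, c(0.4, 0), k = 1)
  expect_equal(r$class, "euploid")
  expect_true(r$score %in% c(0, 1))
  # query identical to a training sample
  r2 <- knn_predict(train, y, train[3, ], k = 1)
  expect_equal(r2$class, "aneuploid")
  # k = |train|: overall majority everywhere
  y3 <- c("euploid", "aneuploid", "aneuploid", "aneuploid")
  r3 <- knn_predict(train, y3, rbind(c(0, 0), c(20, 0)), k = 4)
  expect_equal(r3$class, c("aneuploid", "aneuploid"))
  expect_equal(r3$score, c(0.75, 0.75))
})

test_that("k-NN matches the brute-force distance-sort oracle", {
  td <- toy_data(8, sep = 2, seed = 6)
  set.seed(7)
  queries <- matrix(rnorm(20, 1, 2), ncol = 2)
  for (k in c(1, 3, 5)) {
    got <- knn_predict(td$x, td$y, queries, k = k)
    for (i in seq_len(nrow(queries))) {
      ora <- knn_brute(td$x, td$y, queries[i, ], k)
      expect_equal(got$class[i], ora$class)
      expect_equal(got$score[i], ora$score)
    }
  }
})

test_that("distance ties resolve deterministically by sample order", {
  train <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  y <- c("aneuploid", "euploid", "aneuploid", "euploid")
  r1 <- knn_predict(train, y, c(0, 0), k = 2)
  r2 <- knn_predict(train, y, c(0, 0), k = 2)
  expect_identical(r1, r2)
  expect_equal(r1$class, y[1])  # even split: nearest (first) neighbour
})

test_that("classification metrics match their closed forms", {
  # validation-style confusion: 12 of 14 correct, both errors euploid
  truth <- c(rep("aneuploid", 6), rep("euploid", 8))
  pred <- c(rep("aneuploid", 6), rep("aneuploid", 2), rep("euploid", 6))
  m <- compute_metrics(truth, pred)
  expect_equal(m$accuracy, 100 * 12 / 14, tolerance = 1e-9)
  expect_equal(m$tp, 6); expect_equal(m$fp, 2)
  expect_equal(m$tn, 6); expect_equal(m$fn, 0)
  expect_equal(m$mcc, mcc_oracle(6, 2, 6, 0), tolerance = 1e-12)
  # perfect prediction
  sc <- as.numeric(truth == "aneuploid")
  mp <- compute_metrics(truth, truth, sc)
  expect_equal(mp$accuracy, 100)
  expect_equal(mp$mcc, 1)
  expect_equal(mp$rmse, 0)
  expect_equal(mp$auc, 1)
  expect_error(compute_metrics(truth, pred[1:5]), "length")
})

test_that("random confusion tables match the MCC oracle", {
  set.seed(10)
  for (i in 1:10) {
    n <- 40
    truth <- sample(c("euploid", "aneuploid"), n, replace = TRUE)
    pred <- sample(c("euploid", "aneuploid"), n, replace = TRUE)
    m <- compute_metrics(truth, pred)
    expect_equal(m$mcc, mcc_oracle(m$tp, m$fp, m$tn, m$fn),
                 tolerance = 1e-12)
  }
})

test_that("AUC equals the pairwise (Mann-Whitney) rank statistic", {
  set.seed(11)
  for (i in 1:8) {
    truth <- sample(c("euploid", "aneuploid"), 30, replace = TRUE,
                    prob = c(0.6, 0.4))
    if (length(unique(truth)) < 2) next
    scores <- round(runif(30), 2)  # ties included
    m <- compute_metrics(truth, truth, scores)
    expect_equal(m$auc, auc_pairwise(scores[truth == "aneuploid"],
                                     scores[truth == "euploid"]),
                 tolerance = 1e-12)
  }
})

test_that("single-class truth leaves MCC and AUC undefined", {
  m <- compute_metrics(rep("euploid", 5), rep("euploid", 5), rep(0.1, 5))
  expect_true(is.na(m$mcc))
  expect_true(is.na(m$auc))
  expect_equal(m$accuracy, 100)
})

test_that("cross-validation is perfect on separable classes", {
  td <- toy_data(12, sep = 8, seed = 12)
  cv <- cross_validate(td$x, td$y, k_values = c(1, 3, 5, 7), folds = 4,
                       repeats = 3, seed = 5)
  expect_true(all(cv$metrics$accuracy == 100))
  expect_true(all(cv$metrics$mcc == 1))
  expect_true(all(cv$metrics$auc == 1))
})

test_that("permuted labels drop accuracy to the majority rate", {
  td <- toy_data(15, sep = 6, seed = 13)
  set.seed(14)
  yperm <- sample(td$y)
  cv <- cross_validate(td$x, yperm, k_values = 7, folds = 5, repeats = 10,
                       seed = 15)
  maj <- 100 * max(table(yperm)) / length(yperm)
  expect_lt(cv$metrics$accuracy, maj + 15)  # Monte-Carlo slack
})

test_that("cross-validation is deterministic under a fixed seed", {
  td <- toy_data(10, sep = 1.5, seed = 16)
  cv1 <- cross_validate(td$x, td$y, k_values = c(3, 7), folds = 5,
                        repeats = 4, seed = 77)
  cv2 <- cross_validate(td$x, td$y, k_values = c(3, 7), folds = 5,
                        repeats = 4, seed = 77)
  expect_identical(cv1, cv2)
})

test_that("ties in best-k accuracy resolve to the larger k", {
  td <- toy_data(12, sep = 8, seed = 17)
  cv <- cross_validate(td$x, td$y, k_values = c(1, 3, 5), folds = 4,
                       repeats = 2, seed = 1)
  expect_equal(cv$best_k, 5)  # all perfect, most stringent k wins
})

test_that("the trained predictor recovers planted structure end-to-end", {
  co <- effect_cohort()
  ce <- cohort_expr(co)
  early <- ce$samples$time_h < 30 &
    ce$samples$ploidy %in% c("euploid", "aneuploid")
  model <- train_ploidy_predictor(ce$expr[, early],
                                  ce$samples$ploidy[early],
                                  alpha = 0.005, repeats = 5, seed = 101)
  sig_truth <- co$truth$genes$gene[co$truth$genes$signature]
  expect_gte(mean(model$signature$gene %in% sig_truth), 0.8)
  best <- model$cv[model$cv$k == model$k, ]
  maj <- 100 * max(table(ce$samples$ploidy[early])) / sum(early)
  expect_gt(best$accuracy, maj)
  expect_gt(best$auc, 0.8)
})

test_that("a model applied to its own training set with k=1 is exact", {
  td <- toy_data(10, sep = 2, seed = 18)
  r <- knn_predict(td$x, td$y, td$x, k = 1)
  expect_identical(r$class, td$y)
})

test_that("unlabeled cohort incidence tracks the generating rate", {
  # large enough that collection times balance between classes; at small n
  # time-confounded trajectory genes can leak into the signature
  co <- cached_cohort("unlab", n_embryos = 120, unlabeled_fraction = 0.3,
                      seed = 404)
  ce <- cohort_expr(co)
  early <- ce$samples$time_h < 30
  lab <- early & ce$samples$ploidy %in% c("euploid", "aneuploid")
  unlab <- early & ce$samples$ploidy == "unknown" &
    !ce$samples$cell_id %in% co$truth$cells$cell_id[co$truth$cells$failed]
  model <- train_ploidy_predictor(ce$expr[, lab], ce$samples$ploidy[lab],
                                  alpha = 0.005, repeats = 5, seed = 404)
  pr <- predict_unlabeled(model, ce$expr[, unlab, drop = FALSE])
  truth <- co$truth$cells$ploidy[match(colnames(ce$expr[, unlab]),
                                       co$truth$cells$cell_id)]
  true_rate <- 100 * mean(truth == "aneuploid")
  n <- sum(unlab)
  expect_lt(abs(pr$incidence - true_rate),
            100 * 3 * sqrt(0.25 / n) + 10)
  # per-sample calls mostly match the hidden truth
  expect_gt(mean(pr$calls$class == truth), 0.7)
})

test_that("missing signature genes cause samples to be skipped", {
  td <- toy_data(10, sep = 3, seed = 19)
  m <- matrix(rnorm(4 * 6, 5, 1), 4, 6,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:6)))
  labels <- rep(c("euploid", "aneuploid"), each = 3)
  m[1, labels == "aneuploid"] <- m[1, labels == "aneuploid"] + 10
  model <- train_ploidy_predictor(m, labels, alpha = 0.2, folds = 2,
                                  repeats = 2, k_values = 1, seed = 1)
  new <- m[setdiff(rownames(m), model$signature$gene[1]), , drop = FALSE]
  expect_message(r <- predict_unlabeled(model, new), "skipped")
  expect_true(is.na(r$incidence))
})

test_that("validation accuracy does not decrease with the effect size", {
  accs <- sapply(c(0, 1, 2, 4), function(delta) {
    co <- simulate_cohort(sim_config(n_embryos = 45,
                                     effect_size_delta = delta,
                                     seed = 606))
    ce <- cohort_expr(co)
    early <- ce$samples$time_h < 30 &
      ce$samples$ploidy %in% c("euploid", "aneuploid")
    expr <- ce$expr[, early]; y <- ce$samples$ploidy[early]
    sel <- select_features(expr, y, alpha = 1)
    genes <- attr(sel, "all")$gene[1:12]
    sp <- split_train_validation(y, 2 / 3, seed = 606)
    pv <- knn_predict(t(expr[genes, sp$train]), y[sp$train],
                      t(expr[genes, sp$validation]), k = 7)
    compute_metrics(y[sp$validation], pv$class, pv$score)$accuracy
  })
  # allow a 2-point Monte-Carlo slack on each step
  expect_true(all(diff(accs) > -2))
  expect_gt(accs[4], accs[1])
})

test_that("a serialized model predicts identically after reload", {
  td <- toy_data(8, sep = 3, seed = 20)
  m <- matrix(rnorm(5 * 16, 5, 1), 5, 16,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:16)))
  m[1, td$y == "aneuploid"] <- m[1, td$y == "aneuploid"] + 6
  model <- train_ploidy_predictor(m, td$y, alpha = 0.2, folds = 2,
                                  repeats = 2, k_values = c(1, 3), seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_predictor(model, path)
  reloaded <- read_predictor(path)
  q <- m[, 1:4, drop = FALSE]
  expect_equal(predict_unlabeled(model, q)$calls,
               predict_unlabeled(reloaded, q)$calls)
})
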