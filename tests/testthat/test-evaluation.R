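test_that("the metric set honors its boundary identities exactly", {
  for (np in c(3, 10, 475)) for (nn in c(4, 12, 1425)) {
    expect_equal(metrics_from_counts(confusion_counts(np, nn, 0, 1))$sn, 1)
    expect_equal(metrics_from_counts(confusion_counts(np, nn, np, 1))$sn, 0)
    expect_equal(metrics_from_counts(confusion_counts(np, nn, 1, 0))$sp, 1)
    expect_equal(metrics_from_counts(confusion_counts(np, nn, 1, nn))$sp, 0)
    perfect <- metrics_from_counts(confusion_counts(np, nn, 0, 0))
    expect_equal(perfect$acc, 1); expect_equal(perfect$mcc, 1)
    wrong <- metrics_from_counts(confusion_counts(np, nn, np, nn))
    expect_equal(wrong$acc, 0); expect_equal(wrong$mcc, -1)
  }
  # half-and-half misclassification: no better than random guessing
  half <- metrics_from_counts(confusion_counts(10, 40, 5, 20))
  expect_equal(half$acc, 0.5)
  expect_equal(half$mcc, 0)
})

test_that("metrics agree with the classical Matthews formulation", {
  set.seed(13)
  for (i in 1:1000) {
    np <- sample(1:500, 1); nn <- sample(1:1500, 1)
    fn <- sample(0:np, 1);  fp <- sample(0:nn, 1)
    oracle <- matthews_mcc(np, nn, fn, fp)
    m <- suppressWarnings(metrics_from_counts(confusion_counts(np, nn, fn, fp)))
    if (is.na(oracle)) {
      expect_equal(m$mcc, 0)  # zero-denominator convention
    } else {
      expect_equal(m$mcc, oracle, tolerance = 1e-12)
    }
    expect_equal(m$acc, (m$sn * np + m$sp * nn) / (np + nn),
                 tolerance = 1e-12)
  }
})

test_that("the benchmark-scale counts reproduce the headline metric values", {
  m <- metrics_from_counts(confusion_counts(475, 1425, fn = 143, fp = 2))
  expect_equal(round(m$sn, 4), 0.6989)
  expect_equal(round(m$sp, 4), 0.9986)
  expect_equal(round(m$acc, 4), 0.9237)
  expect_equal(round(m$mcc, 4), 0.7935)
})

test_that("one-class predictions trigger the MCC zero convention", {
  expect_warning(m <- metrics_from_counts(confusion_counts(5, 5, 5, 0)),
                 "denominator")
  expect_equal(m$mcc, 0)
})

test_that("counts_from_predictions tallies fn and fp", {
  c1 <- counts_from_predictions(c("pos", "neg"), c("pos", "neg"))
  expect_equal(c(c1$fn, c1$fp), c(0L, 0L))
  c2 <- counts_from_predictions(c("pos", "neg"), c("neg", "pos"))
  expect_equal(c(c2$fn, c2$fp), c(1L, 1L))
  expect_error(counts_from_predictions(character(), character()), "empty")
  expect_error(counts_from_predictions(c("pos"), c("pos", "neg")),
               "length mismatch")
  expect_error(counts_from_predictions(c("pos", "maybe"), c("pos", "neg")),
               "binary")
})

test_that("ROC handles separation, ties, and the worked pair example", {
  perfect <- roc_curve(rep(c("pos", "neg"), each = 3),
                       c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1))
  expect_equal(perfect$auc, 1)
  flat <- roc_curve(c("pos", "pos", "neg", "neg"), rep(0.4, 4))
  expect_equal(flat$auc, 0.5)
  # 6 pos-neg pairs, 5 correctly ordered
  r <- roc_curve(c("pos", "pos", "neg", "neg", "neg"),
                 c(0.9, 0.4, 0.8, 0.2, 0.1))
  expect_equal(r$auc, 5 / 6)
  expect_error(roc_curve(c("pos", "pos"), c(0.1, 0.2)), "both classes")
  expect_error(roc_curve(c("pos", "neg"), c(NA, 1)), "finite")
})

test_that("ROC points climb from (0,0) to (1,1) and trapezoid AUC equals the rank oracle", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(6:40, 1)
    y <- c("pos", "neg", sample(c("pos", "neg"), n - 2, TRUE))
    s <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    r <- roc_curve(y, s)
    expect_equal(r$points$fpr[1], 0); expect_equal(r$points$tpr[1], 0)
    expect_equal(r$points$fpr[nrow(r$points)], 1)
    expect_equal(r$points$tpr[nrow(r$points)], 1)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    expect_equal(r$auc, rank_auc(y, s), tolerance = 1e-12)
  }
})

test_that("trapezoid AUC matches an established ROC implementation", {
  set.seed(19)
  y <- sample(c("pos", "neg"), 60, TRUE)
  s <- round(runif(60), 2)
  ours <- roc_curve(y, s)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                        levels = c("neg", "pos"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("jackknife equals an independently written leave-one-out loop", {
  bm <- simulate_benchmark(n_pos = 10, n_neg = 20, xi = 6,
                           signal_strength = 1, motif = "GCG", seed = 23)
  tab <- standardize_properties(load_property_table())
  lam <- 2L; ntree <- 25L; mtry <- 10L; seed <- 23L
  jk <- m5c_jackknife(bm, lambda = lam, ntree = ntree, mtry = mtry,
                      properties = tab, seed = seed)
  expect_length(jk$scores, nrow(bm))

  # oracle: explicit loop with randomForest, fold seed = seed + i
  X <- encode_benchmark(bm, tab, lambda = lam)
  y <- attr(X, "labels")
  oracle <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    set.seed(seed + i)
    rf <- randomForest::randomForest(X[-i, , drop = FALSE], y[-i],
                                     ntree = ntree, mtry = mtry)
    v <- predict(rf, X[i, , drop = FALSE], type = "vote", norm.votes = TRUE)
    oracle[i] <- v[, "pos"]
  }
  expect_equal(jk$scores, oracle, tolerance = 1e-12)
  oc <- counts_from_predictions(y, ifelse(oracle >= 0.5, "pos", "neg"))
  expect_identical(unclass(jk$metrics$counts), unclass(oc))
  expect_equal(jk$metrics$counts$n_pos + jk$metrics$counts$n_neg, nrow(bm))
})

test_that("k-fold is stratified, covers each sample once, and degenerates to jackknife", {
  bm <- simulate_benchmark(n_pos = 8, n_neg = 16, xi = 6,
                           signal_strength = 1, motif = "GCG", seed = 29)
  cv <- m5c_kfold(bm, k = 4, lambda = 2, ntree = 20, mtry = 8, seed = 29)
  expect_length(cv$scores, nrow(bm))
  expect_equal(cv$metrics$counts$n_pos + cv$metrics$counts$n_neg, nrow(bm))
  # different seeds may shuffle folds differently: metrics may differ
  cv2 <- m5c_kfold(bm, k = 4, lambda = 2, ntree = 20, mtry = 8, seed = 30)
  expect_length(cv2$scores, nrow(bm))

  jk <- m5c_jackknife(bm, lambda = 2, ntree = 20, mtry = 8, seed = 29)
  cvN <- m5c_kfold(bm, k = nrow(bm), lambda = 2, ntree = 20, mtry = 8,
                   seed = 29)
  expect_identical(unclass(cvN$metrics$counts), unclass(jk$metrics$counts))
  expect_error(m5c_kfold(bm, k = nrow(bm) + 1, lambda = 2, ntree = 10,
                         mtry = 8, seed = 1), "2..N")
})
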