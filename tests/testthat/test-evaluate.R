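test_that("k-fold assignment partitions subjects with near-equal sizes", {
  ids <- sprintf("sub-%03d", 1:72)
  labels <- c(rep(1, 51), rep(0, 21))
  folds <- kfold_split(ids, 10, seed = 2, labels = labels)
  expect_setequal(names(folds), ids)
  sizes <- as.integer(table(folds))
  expect_equal(sort(sizes, decreasing = TRUE), c(8, 8, rep(7, 8)))
  # stratification: per-fold positive counts within +-1 of proportionality
  pos_per_fold <- tapply(labels, folds, sum)
  expect_true(all(abs(pos_per_fold - 5.1) <= 1.1))
  # leave-one-out degenerate case
  loo <- kfold_split(ids[1:5], 5, seed = 1)
  expect_equal(sort(as.integer(table(loo))), rep(1L, 5))
  expect_error(kfold_split(ids[1:3], 5), "exceed")
  expect_error(kfold_split(c("a", "a"), 2), "unique")
})

test_that("confusion counts match a brute-force tally", {
  expect_equal(unclass(confusion(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                                 c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)))[1:4],
               list(TP = 5L, TN = 5L, FP = 0L, FN = 0L),
               ignore_attr = TRUE)
  expect_equal(unclass(confusion(c(1, 1, 1, 0, 0), rep(1, 5)))[1:4],
               list(TP = 3L, TN = 0L, FP = 2L, FN = 0L), ignore_attr = TRUE)
  set.seed(20)
  yt <- rbinom(40, 1, 0.4); yp <- rbinom(40, 1, 0.6)
  cc <- confusion(yt, yp)
  tp <- tn <- fp <- fn <- 0
  for (i in 1:40) {
    if (yt[i] == 1 && yp[i] == 1) tp <- tp + 1
    if (yt[i] == 0 && yp[i] == 0) tn <- tn + 1
    if (yt[i] == 0 && yp[i] == 1) fp <- fp + 1
    if (yt[i] == 1 && yp[i] == 0) fn <- fn + 1
  }
  expect_equal(c(cc$TP, cc$TN, cc$FP, cc$FN), c(tp, tn, fp, fn))
  expect_error(confusion(c(1, 0), c(1)), "equal length")
})

test_that("metrics follow their closed forms", {
  cc <- structure(list(TP = 3, TN = 2, FP = 1, FN = 2),
                  class = "confusion_counts")
  m <- metrics(cc)
  expect_equal(m$ACC, 0.625)
  expect_equal(m$SEN, 0.6)
  expect_equal(m$PPV, 0.75)
  expect_equal(m$F1, 2 * 0.45 / 1.35, tolerance = 1e-12)
  expect_equal(m$F1, 0.6667, tolerance = 1e-4)
  expect_identical(m$Recall, m$SEN)
  # AUC: perfect separation and all-ties
  yt <- c(1, 1, 1, 0, 0)
  m1 <- metrics(cc, scores = c(0.9, 0.8, 0.7, 0.2, 0.1), y_true = yt)
  expect_equal(m1$AUC, 1)
  m2 <- metrics(cc, scores = rep(0.5, 5), y_true = yt)
  expect_equal(m2$AUC, 0.5)
  # degenerate denominators report 0, each with its own warning
  none <- confusion(c(0, 0), c(0, 0))
  w <- capture_warnings(m0 <- metrics(none))
  expect_length(w, 3)                    # SEN, PPV and F1 are all undefined
  expect_match(w, "undefined", all = TRUE)
  expect_equal(m0$SEN, 0)
})

test_that("rank-based AUC is invariant to monotone score transforms", {
  set.seed(22)
  yt <- rbinom(30, 1, 0.5)
  sc <- runif(30)
  a1 <- metrics(confusion(yt, as.integer(sc >= 0.5)), sc, yt)$AUC
  a2 <- metrics(confusion(yt, as.integer(sc >= 0.5)), plogis(5 * sc - 2),
                yt)$AUC
  expect_equal(a1, a2, tolerance = 1e-12)
  # agrees with an independent implementation
  skip_if_not_installed("pROC")
  a3 <- as.numeric(pROC::auc(pROC::roc(yt, sc, quiet = TRUE,
                                       direction = "<")))
  expect_equal(a1, a3, tolerance = 1e-10)
})

test_that("cross-validation guards leakage and reports bounded metrics", {
  set.seed(23)
  # small fused-like cohort, moderately separable
  lay <- list(list(branch = "time", kernel_size = 3, start = 1L, end = 24L,
                   dim = c(2L, 4L, 3L)))
  y <- c(rep(1, 14), rep(0, 6))
  X <- t(vapply(y, function(yy) abs(rnorm(24, mean = yy, sd = 0.5)),
                numeric(24)))
  fused <- list(vectors = X, labels = y,
                subject_ids = sprintf("s%02d", 1:20), layout = lay)
  cfg <- stanet_config(folds = 4, hidden = 6, epochs = 30, n_filters = 2)
  rep <- suppressWarnings(cross_validate(fused, cfg, seed = 3))
  for (k in c("ACC", "SEN", "PPV", "F1", "Recall", "AUC")) {
    expect_gte(rep$mean[[k]], 0)
    expect_lte(rep$mean[[k]], 1)
  }
  expect_identical(rep$mean$Recall, rep$mean$SEN)
  expect_length(rep$per_fold, 4)
  # every subject scored exactly once, no synthetic ids among them
  expect_setequal(names(rep$scores), fused$subject_ids)
  # duplicate ids are rejected
  bad <- fused; bad$subject_ids[2] <- bad$subject_ids[1]
  expect_error(cross_validate(bad, cfg, seed = 1), "duplicate")
})
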