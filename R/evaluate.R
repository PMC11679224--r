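# Subject-level cross-validation and performance metrics.

#' Subject-level k-fold assignment
#'
#' Subjects are shuffled and dealt round-robin into `k` folds. With
#' `labels` supplied (the default use), the shuffle happens within class and
#' the deal continues across classes, so each fold keeps approximately the
#' cohort's class ratio while total fold sizes still differ by at most one.
#'
#' @param subject_ids Character vector of unique ids.
#' @param k Number of folds (`k <= length(subject_ids)`).
#' @param seed Integer seed.
#' @param labels Optional 0/1 labels enabling stratification.
#' @return Named integer vector mapping each subject id to a fold in
#'   `1..k`.
#' @export
kfold_split <- function(subject_ids, k, seed = 1L, labels = NULL) {
  n <- length(subject_ids)
  assert_count(k, "k")
  if (k > n) stop("`k` must not exceed the number of subjects", call. = FALSE)
  if (anyDuplicated(subject_ids))
    stop("subject ids must be unique", call. = FALSE)
  ord <- with_seed(seed, {
    if (is.null(labels)) {
      sample.int(n)
    } else {
      stopifnot(length(labels) == n)
      unlist(lapply(sort(unique(labels)), function(cl) {
        i <- which(labels == cl)
        i[sample.int(length(i))]
      }))
    }
  })
  folds <- integer(n)
  folds[ord] <- rep(seq_len(k), length.out = n)
  names(folds) <- subject_ids
  folds
}

#' Binary confusion counts
#'
#' Class 1 is the positive class.
#'
#' @param y_true,y_pred Equal-length 0/1 vectors.
#' @return An object of class `confusion_counts` with `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stop("entries must be 0 or 1", call. = FALSE)
  structure(list(TP = sum(y_true == 1 & y_pred == 1),
                 TN = sum(y_true == 0 & y_pred == 0),
                 FP = sum(y_true == 0 & y_pred == 1),
                 FN = sum(y_true == 1 & y_pred == 0)),
            class = "confusion_counts")
}

# Mann-Whitney AUC with half credit for ties
rank_auc <- function(scores, y_true) {
  pos <- y_true == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined with a single class; reporting 0.5")
    return(0.5)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from confusion counts and scores
#'
#' Computes accuracy `ACC = (TP+TN)/(TP+TN+FP+FN)`, sensitivity
#' `SEN = TP/(TP+FN)`, positive predictive value `PPV = TP/(TP+FP)`,
#' `F1 = 2*SEN*PPV/(SEN+PPV)`, recall (identical to SEN), and the
#' rank-based (Mann-Whitney) AUC with 0.5 credit per tied pair.
#' Undefined ratios (no predicted or actual positives) are reported as 0
#' with a warning.
#'
#' @param counts A [confusion()] result.
#' @param scores Numeric scores in `[0, 1]` (for AUC); optional.
#' @param y_true 0/1 labels aligned with `scores`.
#' @return An object of class `metrics_report` (list with `ACC`, `SEN`,
#'   `PPV`, `F1`, `Recall`, `AUC`).
#' @export
metrics <- function(counts, scores = NULL, y_true = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reporting 0", what))
      0
    } else num / den
  }
  acc <- safe_div(counts$TP + counts$TN,
                  counts$TP + counts$TN + counts$FP + counts$FN, "ACC")
  sen <- safe_div(counts$TP, counts$TP + counts$FN, "SEN")
  ppv <- safe_div(counts$TP, counts$TP + counts$FP, "PPV")
  f1 <- if (sen + ppv == 0) {
    warning("F1 undefined (SEN + PPV = 0); reporting 0")
    0
  } else 2 * sen * ppv / (sen + ppv)
  auc <- if (is.null(scores)) NA_real_ else rank_auc(scores, y_true)
  structure(list(ACC = acc, SEN = sen, PPV = ppv, F1 = f1,
                 Recall = sen, AUC = auc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("ACC %.4f  SEN %.4f  PPV %.4f  F1 %.4f  Recall %.4f  AUC %s\n",
              x$ACC, x$SEN, x$PPV, x$F1, x$Recall,
              ifelse(is.na(x$AUC), "NA", sprintf("%.4f", x$AUC))))
  invisible(x)
}

# ridge-penalised logistic regression baseline on the same fused features
logistic_baseline <- function(train, test_vectors, lambda = 0.05) {
  fit <- glmnet::glmnet(train$vectors, factor(train$labels, levels = c(0, 1)),
                        family = "binomial", alpha = 0, lambda = lambda,
                        standardize = TRUE)
  as.numeric(stats::predict(fit, newx = test_vectors, type = "response"))
}

#' Subject-level cross-validation of the full classifier
#'
#' For each fold: the held-out subjects are set aside, the training fold is
#' balanced with the configured sampler (synthetic samples never reach the
#' test fold; an internal guard asserts this), the AFGRU classifier is
#' trained on the balanced fold, and the held-out subjects are scored.
#' Per-fold metrics are averaged into the mean report.
#'
#' @param fused Output of [fuse_cohort()]: `vectors`, `labels`,
#'   `subject_ids`, `layout`.
#' @param config A [stanet_config()].
#' @param seed Integer seed (folds, samplers and model training all derive
#'   from it).
#' @param baseline If `TRUE`, also evaluate a ridge-logistic baseline on
#'   identical folds.
#' @return A list of class `stanet_cv_report`: `mean` and `per_fold`
#'   metrics, `folds`, `scores`, and (optionally) `baseline` metrics.
#' @export
cross_validate <- function(fused, config = stanet_config(), seed = 1L,
                           baseline = FALSE) {
  ids <- fused$subject_ids
  labels <- fused$labels
  if (anyDuplicated(ids)) stop("duplicate subject ids", call. = FALSE)
  k <- config$folds
  folds <- kfold_split(ids, k, seed = seed,
                       labels = if (config$stratify) labels else NULL)
  per_fold <- vector("list", k)
  base_fold <- vector("list", k)
  all_scores <- numeric(length(ids)); names(all_scores) <- ids
  for (f in seq_len(k)) {
    test_i <- which(folds == f)
    train_i <- which(folds != f)
    if (length(intersect(ids[test_i], ids[train_i])) > 0)
      stop("subject appears in both train and test folds", call. = FALSE)
    train <- labeled_dataset(fused$vectors[train_i, , drop = FALSE],
                             labels[train_i], ids[train_i])
    train_bal <- apply_sampler(train, config$sampler,
                               smote_k = config$smote_k,
                               seed = seed + 1000L + f)
    if (any(train_bal$subject_ids %in% ids[test_i]))
      stop("oversampling leaked a synthetic id into the test fold",
           call. = FALSE)
    # average the scores of `ensemble` independently initialized trainings;
    # tames threshold jitter of single fits on small folds
    sc <- 0
    for (e in seq_len(config$ensemble)) {
      model <- afgru_train(train_bal, fused$layout,
                           hidden = config$hidden, layers = config$layers,
                           lr = config$lr, epochs = config$epochs,
                           seed = seed + 2000L + f + 10000L * e)
      sc <- sc + predict(model, fused$vectors[test_i, , drop = FALSE])
    }
    sc <- sc / config$ensemble
    all_scores[test_i] <- sc
    pred <- as.integer(sc >= 0.5)
    per_fold[[f]] <- suppressWarnings(
      metrics(confusion(labels[test_i], pred), sc, labels[test_i]))
    if (baseline) {
      bsc <- logistic_baseline(train_bal,
                               fused$vectors[test_i, , drop = FALSE])
      base_fold[[f]] <- suppressWarnings(
        metrics(confusion(labels[test_i], as.integer(bsc >= 0.5)),
                bsc, labels[test_i]))
    }
  }
  mean_of <- function(reports) {
    vals <- sapply(reports, function(r)
      unlist(r[c("ACC", "SEN", "PPV", "F1", "Recall", "AUC")]))
    as.list(rowMeans(vals))
  }
  out <- list(mean = mean_of(per_fold), per_fold = per_fold,
              folds = folds, scores = all_scores,
              config = config, seed = seed)
  if (baseline) out$baseline <- list(mean = mean_of(base_fold),
                                     per_fold = base_fold)
  structure(out, class = "stanet_cv_report")
}

#' @export
print.stanet_cv_report <- function(x, ...) {
  cat(sprintf("<stanet_cv_report> %d-fold subject-level CV (seed %d)\n",
              x$config$folds, x$seed))
  m <- x$mean
  cat(sprintf("mean: ACC %.4f  F1 %.4f  Recall %.4f  AUC %.4f\n",
              m$ACC, m$F1, m$Recall, m$AUC))
  if (!is.null(x$baseline))
    cat(sprintf("ridge-logistic baseline: ACC %.4f  AUC %.4f\n",
                x$baseline$mean$ACC, x$baseline$mean$AUC))
  invisible(x)
}
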