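# Training-fold balancing by minority oversampling.
#
# Applied strictly inside the cross-validation loop, after the train/test
# split, so no synthetic sample can leak into a test fold.

#' Construct a labeled dataset
#'
#' @param vectors `n x d` numeric matrix of feature vectors.
#' @param labels Integer vector of 0/1 labels, length `n`.
#' @param subject_ids Character ids, length `n`.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(vectors, labels, subject_ids = NULL) {
  vectors <- as.matrix(vectors)
  if (is.null(subject_ids)) subject_ids <- sprintf("s%03d", seq_len(nrow(vectors)))
  stopifnot(nrow(vectors) == length(labels),
            length(subject_ids) == length(labels),
            all(labels %in% c(0, 1)))
  structure(list(vectors = unname(vectors), labels = as.integer(labels),
                 subject_ids = as.character(subject_ids)),
            class = "labeled_dataset")
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Synthesises minority-class vectors by interpolating between a minority
#' sample and one of its `k` nearest minority neighbours (Euclidean
#' distance): `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)`. Enough
#' synthetics are added to equalise the class counts; original samples are
#' kept unchanged. A minority class of size 1 falls back to duplication
#' (with a warning), and `k` is clipped to `minority size - 1` when needed.
#'
#' @param data A [labeled_dataset()].
#' @param k_neighbors Number of nearest neighbours considered (default 5).
#' @param seed Integer seed.
#' @return A balanced `labeled_dataset`; synthetic rows get ids
#'   `"smote_<i>"`.
#' @export
smote <- function(data, k_neighbors = 5L, seed = 1L) {
  stopifnot(inherits(data, "labeled_dataset"))
  assert_count(k_neighbors, "k_neighbors")
  n1 <- sum(data$labels == 1); n0 <- sum(data$labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present", call. = FALSE)
  if (n1 == n0) return(data)
  minority <- if (n1 < n0) 1L else 0L
  need <- abs(n1 - n0)
  idx <- which(data$labels == minority)
  Xm <- data$vectors[idx, , drop = FALSE]

  if (length(idx) == 1L) {
    warning("minority class has a single sample; duplicating it")
    syn <- Xm[rep(1L, need), , drop = FALSE]
  } else {
    k <- k_neighbors
    if (k >= length(idx)) {
      k <- length(idx) - 1L
      warning(sprintf("k_neighbors clipped to %d (minority size %d)",
                      k, length(idx)))
    }
    D <- as.matrix(stats::dist(Xm))
    diag(D) <- Inf
    nnv <- apply(D, 1, function(d) order(d)[seq_len(k)])
    nn <- if (k == 1L) matrix(nnv, ncol = 1L) else t(nnv)
    syn <- with_seed(seed, {
      base <- sample.int(nrow(Xm), need, replace = TRUE)
      pick <- vapply(base, function(b)
        nn[b, sample.int(k, 1L)], integer(1))
      u <- stats::runif(need)
      Xm[base, , drop = FALSE] +
        u * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE])
    })
  }
  labeled_dataset(rbind(data$vectors, syn),
                  c(data$labels, rep(minority, need)),
                  c(data$subject_ids, sprintf("smote_%03d", seq_len(need))))
}

#' Random oversampling by duplication
#'
#' Duplicates uniformly sampled minority rows until the class counts are
#' equal; every synthetic row is an exact copy of an original minority row.
#'
#' @inheritParams smote
#' @return A balanced `labeled_dataset`; duplicate rows get ids
#'   `"dup_<i>"`.
#' @export
random_oversample <- function(data, seed = 1L) {
  stopifnot(inherits(data, "labeled_dataset"))
  n1 <- sum(data$labels == 1); n0 <- sum(data$labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present", call. = FALSE)
  if (n1 == n0) return(data)
  minority <- if (n1 < n0) 1L else 0L
  need <- abs(n1 - n0)
  idx <- which(data$labels == minority)
  dup <- with_seed(seed, sample(idx, need, replace = TRUE))
  labeled_dataset(rbind(data$vectors, data$vectors[dup, , drop = FALSE]),
                  c(data$labels, rep(minority, need)),
                  c(data$subject_ids, sprintf("dup_%03d", seq_len(need))))
}

# dispatch table used by the CV loop and the CLI
apply_sampler <- function(data, sampler = c("smote", "random", "none"),
                          smote_k = 5L, seed = 1L) {
  sampler <- match.arg(sampler)
  switch(sampler,
         smote = smote(data, k_neighbors = smote_k, seed = seed),
         random = random_oversample(data, seed = seed),
         none = data)
}
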