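# Multi-scale convolutional spatio-temporal feature aggregation.
#
# Each subject contributes two matrices: component time courses (T' x N) and
# spatial-similarity features (R x N). Both pass through a bank of 2D
# convolution kernels at several scales (same zero padding), a ReLU, and a
# max-pooling layer with window = stride = pool_size (ceiling mode, so
# partial edge windows are kept). The pooled maps of every scale and both
# branches are flattened and concatenated into one fused vector per subject.
# Filters are seeded random projections, fixed across the cohort.

#' Create a multi-scale convolution bank
#'
#' Independent filter sets are drawn for the temporal and spatial branches.
#' Filter entries are Gaussian with standard deviation `1/k` for a `k x k`
#' kernel, so responses are on a comparable scale across kernel sizes.
#'
#' @param kernel_sizes Odd kernel sizes (default `c(3, 5, 7, 9, 11)`).
#' @param n_filters Filters per scale and branch (default 8).
#' @param pool_size Max-pooling window and stride (default 6).
#' @param seed Integer seed; banks are deterministic given the seed.
#' @return An object of class `conv_bank`.
#' @export
conv_bank <- function(kernel_sizes = c(3L, 5L, 7L, 9L, 11L),
                      n_filters = 8L, pool_size = 6L, seed = 1L) {
  if (length(kernel_sizes) < 1 || any(kernel_sizes < 1) ||
      any(kernel_sizes %% 2 != 1))
    stop("`kernel_sizes` must be odd positive integers", call. = FALSE)
  assert_count(n_filters, "n_filters")
  assert_count(pool_size, "pool_size")
  # sub-seed per branch and kernel size, so a given scale's filters do not
  # depend on the position of that scale in `kernel_sizes`
  draw <- function(branch_offset) lapply(kernel_sizes, function(k)
    with_seed(seed * 131L + branch_offset * 7919L + k,
              array(stats::rnorm(k * k * n_filters, sd = 1 / k),
                    dim = c(k, k, n_filters))))
  weights <- list(time = draw(1L), spatial = draw(2L))
  structure(list(kernel_sizes = as.integer(kernel_sizes),
                 n_filters = as.integer(n_filters),
                 pool_size = as.integer(pool_size),
                 weights = weights, seed = as.integer(seed)),
            class = "conv_bank")
}

# same-padded 2D cross-correlation, shift-and-add over kernel offsets
conv2d_same <- function(x, kern) {
  k <- nrow(kern)
  p <- (k - 1L) %/% 2L
  H <- nrow(x); W <- ncol(x)
  padded <- matrix(0, H + 2L * p, W + 2L * p)
  padded[p + seq_len(H), p + seq_len(W)] <- x
  out <- matrix(0, H, W)
  for (a in seq_len(k)) {
    rows <- (a - 1L) + seq_len(H)
    for (b in seq_len(k)) {
      w <- kern[a, b]
      if (w != 0)
        out <- out + w * padded[rows, (b - 1L) + seq_len(W)]
    }
  }
  out
}

# max pooling with window = stride = p, ceiling mode (partial edge windows)
maxpool_ceil <- function(x, p) {
  H <- nrow(x); W <- ncol(x)
  ri <- ceiling(seq_len(H) / p)
  ci <- ceiling(seq_len(W) / p)
  pH <- max(ri); pW <- max(ci)
  out <- matrix(-Inf, pH, pW)
  for (i in seq_len(pH)) {
    xr <- x[ri == i, , drop = FALSE]
    for (j in seq_len(pW))
      out[i, j] <- max(xr[, ci == j])
  }
  out
}

#' Apply one convolutional branch
#'
#' Runs same-padded convolution with every filter at every scale, a ReLU,
#' and ceiling-mode max pooling. An `H x W` input yields, per filter, a
#' pooled map of `ceiling(H/pool) x ceiling(W/pool)`.
#'
#' @param mat Input matrix (time courses or spatial features).
#' @param bank A [conv_bank()].
#' @param branch `"time"` or `"spatial"` (selects the filter set).
#' @return A list (one element per scale) of arrays
#'   `n_filters x pooledH x pooledW`.
#' @export
conv_branch <- function(mat, bank, branch = c("time", "spatial")) {
  branch <- match.arg(branch)
  stopifnot(inherits(bank, "conv_bank"))
  assert_finite_matrix(mat, "mat")
  if (nrow(mat) < 1 || ncol(mat) < 1) stop("empty input", call. = FALSE)
  p <- bank$pool_size
  pH <- ceiling(nrow(mat) / p); pW <- ceiling(ncol(mat) / p)
  lapply(seq_along(bank$kernel_sizes), function(si) {
    kerns <- bank$weights[[branch]][[si]]
    out <- array(0, dim = c(bank$n_filters, pH, pW))
    for (f in seq_len(bank$n_filters)) {
      fm <- pmax(conv2d_same(mat, kerns[, , f]), 0)
      out[f, , ] <- maxpool_ceil(fm, p)
    }
    out
  })
}

#' Fuse a subject's temporal and spatial features into one vector
#'
#' Concatenates the flattened pooled maps of all scales for the temporal
#' branch, then all scales for the spatial branch. Within a scale the array
#' is flattened filter-fastest (filter, pooled row, pooled column). The
#' returned `layout` records each branch/scale slice so the vector can be
#' reshaped back into a sequence for the recurrent classifier.
#'
#' @param timecourses `T' x N` matrix.
#' @param spatial_features `R x N` matrix.
#' @param bank A [conv_bank()].
#' @param subject_id,label Carried through to the output.
#' @return An object of class `fused_feature` with `vector`, `layout`,
#'   `subject_id`, `label`.
#' @export
fuse_features <- function(timecourses, spatial_features, bank,
                          subject_id = "", label = NA_integer_) {
  tb <- conv_branch(timecourses, bank, "time")
  sb <- conv_branch(spatial_features, bank, "spatial")
  layout <- list()
  vec <- numeric(0)
  add <- function(branch, maps, layout, vec) {
    for (si in seq_along(maps)) {
      v <- as.vector(maps[[si]])
      layout[[length(layout) + 1L]] <- list(
        branch = branch, kernel_size = bank$kernel_sizes[si],
        start = length(vec) + 1L, end = length(vec) + length(v),
        dim = dim(maps[[si]]))
      vec <- c(vec, v)
    }
    list(layout = layout, vec = vec)
  }
  r <- add("time", tb, layout, vec)
  r <- add("spatial", sb, r$layout, r$vec)
  structure(list(subject_id = subject_id, vector = r$vec,
                 label = label, layout = r$layout),
            class = "fused_feature")
}

#' Fuse a whole cohort of feature sets
#'
#' @param feature_sets List of `subject_feature_set` (from
#'   [extract_feature_sets()]).
#' @param bank A [conv_bank()].
#' @return A list with `vectors` (`n x d` matrix), `labels`, `subject_ids`,
#'   and the shared `layout`.
#' @export
fuse_cohort <- function(feature_sets, bank) {
  fused <- lapply(feature_sets, function(fs)
    fuse_features(fs$timecourses, fs$spatial_features, bank,
                  fs$subject_id, fs$label))
  vectors <- do.call(rbind, lapply(fused, `[[`, "vector"))
  rownames(vectors) <- vapply(fused, `[[`, character(1), "subject_id")
  list(vectors = vectors,
       labels = vapply(fused, `[[`, integer(1), "label"),
       subject_ids = rownames(vectors),
       layout = fused[[1]]$layout)
}

# Reshape a fused vector into the classifier's input sequence. Each
# branch/scale slice (filters x pooledRows x pooledCols) becomes a
# (pooledRows x filters*pooledCols) block; blocks of one branch are joined
# along channels, and the spatial-branch block is appended below the
# time-branch block as extra sequence steps. Both branches share the
# component axis, so their pooled column counts -- and hence channel
# widths -- agree by construction, and the recurrence traverses pooled time
# first, then the pooled network axis. Returns list(seq, n_time_steps,
# n_spatial_steps).
fused_to_sequence <- function(vec, layout) {
  branch_mat <- function(br) {
    sl <- Filter(function(l) l$branch == br, layout)
    if (!length(sl)) return(NULL)
    do.call(cbind, lapply(sl, function(l) {
      arr <- array(vec[l$start:l$end], dim = l$dim)  # filters x pR x pC
      matrix(aperm(arr, c(2, 1, 3)), nrow = l$dim[2])
    }))
  }
  tm <- branch_mat("time")
  sm <- branch_mat("spatial")
  if (!is.null(tm) && !is.null(sm) && ncol(tm) != ncol(sm))
    stop("time and spatial branches have incompatible channel widths",
         call. = FALSE)
  list(seq = rbind(tm, sm),
       n_time_steps = if (is.null(tm)) 0L else nrow(tm),
       n_spatial_steps = if (is.null(sm)) 0L else nrow(sm))
}
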