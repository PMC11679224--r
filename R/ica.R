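# Stage 1: group ICA feature extraction.
#
# The cohort is temporally concatenated, reduced in two PCA stages
# (subject-level, then group-level), whitened, and decomposed with a
# symmetric fixed-point ICA (logcosh contrast). Per-subject time courses are
# recovered by least squares of each scan onto the group spatial sources, and
# spatial-similarity features come from per-component multiple regression
# onto an RSN atlas.

#' Drop the initial volumes of a scan
#'
#' Scanner equilibration makes the first few volumes unreliable; they are
#' discarded before any analysis (default pipeline drops 5 of 100, leaving
#' 95).
#'
#' @param scan A `subject_scan`.
#' @param k Number of leading timepoints to remove (`0 <= k < T`).
#' @return The scan with `T - k` timepoints.
#' @export
discard_initial_volumes <- function(scan, k) {
  stopifnot(inherits(scan, "subject_scan"))
  if (!(is.numeric(k) && length(k) == 1L && k >= 0 && k == round(k)))
    stop("`k` must be a non-negative integer", call. = FALSE)
  if (k >= nrow(scan$data))
    stop("`k` must be smaller than the number of timepoints", call. = FALSE)
  if (k == 0) return(scan)
  subject_scan(scan$subject_id,
               scan$data[-seq_len(k), , drop = FALSE],
               scan$label)
}

#' Temporal concatenation and two-stage PCA whitening of a cohort
#'
#' Each scan is row-centred (every timepoint map has zero mean over voxels),
#' reduced to its top principal time courses, and the reductions are stacked.
#' A group-level SVD then yields an `n_components x V` whitened matrix whose
#' rows are zero-mean with identity covariance (`tcrossprod(Z)/V = I`).
#'
#' @param scans List of `subject_scan` sharing `T` and `V`.
#' @param n_components Number of group components to retain.
#' @param subject_pcs Per-subject reduction size (default
#'   `min(T, 2 * n_components)`).
#' @return A list with `whitened` (`n_components x V`), and `info` (singular
#'   values, retained variance fraction, sizes).
#' @export
group_reduce <- function(scans, n_components, subject_pcs = NULL) {
  stopifnot(is.list(scans), length(scans) >= 1L)
  dims <- vapply(scans, function(s) dim(s$data), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all scans must share the same dimensions", call. = FALSE)
  Tp <- dims[1, 1]; V <- dims[2, 1]
  assert_count(n_components, "n_components")
  if (n_components > Tp)
    stop("`n_components` must not exceed the number of timepoints",
         call. = FALSE)
  if (is.null(subject_pcs)) subject_pcs <- min(Tp, 2L * n_components)
  subject_pcs <- min(subject_pcs, Tp)

  reduced <- lapply(scans, function(s) {
    X <- s$data - rowMeans(s$data)
    if (subject_pcs >= min(dim(X))) return(X)
    sv <- svd(X, nu = 0, nv = subject_pcs)
    d <- sv$d[seq_len(subject_pcs)]
    d * t(sv$v)                                    # subject_pcs x V
  })
  G <- do.call(rbind, reduced)

  sv <- svd(G, nu = 0, nv = n_components)
  if (sv$d[n_components] < 1e-12 * sv$d[1])
    warning("group data are nearly rank deficient at the requested order")
  Z <- sqrt(V) * t(sv$v[, seq_len(n_components), drop = FALSE])
  list(whitened = Z,
       info = list(singular_values = sv$d,
                   retained_variance =
                     sum(sv$d[seq_len(n_components)]^2) / sum(sv$d^2),
                   subject_pcs = subject_pcs,
                   n_subjects = length(scans), T = Tp, V = V))
}

#' Fixed-point ICA on whitened data
#'
#' Symmetric FastICA with the logcosh contrast: all rows of the unmixing
#' matrix are updated in parallel and re-orthogonalised each iteration.
#' Sources are sign-fixed so each component's largest-magnitude voxel is
#' positive, and scaled to unit variance.
#'
#' @param whitened Zero-mean, identity-covariance matrix (`n x V`), e.g. from
#'   [group_reduce()].
#' @param n_components Number of components (default `nrow(whitened)`).
#' @param seed Integer seed for the random orthogonal start.
#' @param tol Convergence tolerance on the update angle (default 1e-4).
#' @param max_iter Iteration cap (default 200); non-convergence warns and
#'   returns the best iterate.
#' @return An object of class `ica_decomposition`: `sources` (`N x V`),
#'   `unmixing` (`N x n`), `group_mixing` (`n x N`), `n_components`,
#'   `converged`, `iterations`.
#' @export
fastica_decompose <- function(whitened, n_components = nrow(whitened),
                              seed = 1L, tol = 1e-4, max_iter = 200L) {
  assert_finite_matrix(whitened, "whitened")
  assert_count(n_components, "n_components")
  n <- nrow(whitened); V <- ncol(whitened)
  if (n_components > n)
    stop("`n_components` must not exceed nrow(whitened)", call. = FALSE)
  X <- whitened

  sym_decorrelate <- function(W) {
    s <- eigen(tcrossprod(W), symmetric = TRUE)
    s$vectors %*% (t(s$vectors) / sqrt(pmax(s$values, 1e-300))) %*% W
  }

  W <- with_seed(seed, matrix(stats::rnorm(n_components * n), n_components, n))
  W <- sym_decorrelate(W)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Y <- W %*% X
    G <- tanh(Y)
    Gp <- 1 - G^2                       # derivative of tanh
    W_new <- (G %*% t(X)) / V - rowMeans(Gp) * W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(1 - abs(rowSums(W_new * W))))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf(
      "fixed-point ICA did not converge in %d iterations (last delta %.3g); returning best iterate",
      max_iter, delta))

  Y <- W %*% X
  # sign convention: peak voxel of each component is positive
  flip <- vapply(seq_len(nrow(Y)),
                 function(i) sign(Y[i, which.max(abs(Y[i, ]))]),
                 numeric(1))
  flip[flip == 0] <- 1
  Y <- flip * Y
  W <- flip * W
  structure(list(sources = Y, unmixing = W, group_mixing = t(W),
                 n_components = n_components,
                 converged = converged, iterations = it),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> %d components x %d voxels (%s, %d iterations)\n",
              nrow(x$sources), ncol(x$sources),
              if (x$converged) "converged" else "not converged",
              x$iterations))
  invisible(x)
}

#' Stability-selected ICA across random restarts
#'
#' Runs the fixed-point decomposition `n_restarts` times from different
#' random starts, matches components across runs by absolute spatial
#' correlation (greedy assignment, sign-aligned), and returns the centroid
#' decomposition. A per-component stability index (mean absolute correlation
#' of cluster members to the centroid) is attached. With `n_restarts = 1`
#' this is exactly [fastica_decompose()].
#'
#' @inheritParams fastica_decompose
#' @param n_restarts Number of random restarts (>= 1).
#' @return An `ica_decomposition` with an extra `stability` vector.
#' @export
stability_select <- function(whitened, n_components = nrow(whitened),
                             n_restarts = 10L, seed = 1L,
                             tol = 1e-4, max_iter = 200L) {
  assert_count(n_restarts, "n_restarts")
  runs <- lapply(seq_len(n_restarts) - 1L, function(i)
    fastica_decompose(whitened, n_components, seed = seed + i,
                      tol = tol, max_iter = max_iter))
  if (n_restarts == 1L) {
    runs[[1]]$stability <- rep(1, n_components)
    return(runs[[1]])
  }
  V <- ncol(whitened)
  ref <- runs[[1]]$sources
  aligned <- lapply(runs, function(r) {
    C <- tcrossprod(ref, r$sources) / V          # unit-variance rows
    perm <- integer(n_components)
    sgn <- numeric(n_components)
    Cw <- abs(C)
    for (step in seq_len(n_components)) {
      idx <- arrayInd(which.max(Cw), dim(Cw))
      perm[idx[1]] <- idx[2]
      sgn[idx[1]] <- sign(C[idx[1], idx[2]])
      Cw[idx[1], ] <- -Inf; Cw[, idx[2]] <- -Inf
    }
    sgn[sgn == 0] <- 1
    sgn * r$sources[perm, , drop = FALSE]
  })
  centroid <- Reduce(`+`, aligned) / n_restarts
  W <- (centroid %*% t(whitened)) / V           # OLS onto whitened rows
  s <- eigen(tcrossprod(W), symmetric = TRUE)
  W <- s$vectors %*% (t(s$vectors) / sqrt(pmax(s$values, 1e-300))) %*% W
  Y <- W %*% whitened
  flip <- vapply(seq_len(nrow(Y)),
                 function(i) sign(Y[i, which.max(abs(Y[i, ]))]),
                 numeric(1))
  flip[flip == 0] <- 1
  Y <- flip * Y; W <- flip * W
  stability <- vapply(seq_len(n_components), function(i) {
    mean(vapply(aligned, function(a)
      abs(sum(a[i, ] * Y[i, ]) / V), numeric(1)))
  }, numeric(1))
  structure(list(sources = Y, unmixing = W, group_mixing = t(W),
                 n_components = n_components,
                 converged = all(vapply(runs, `[[`, logical(1), "converged")),
                 iterations = max(vapply(runs, `[[`, integer(1), "iterations")),
                 stability = stability),
            class = "ica_decomposition")
}

#' Back-reconstruct one subject's component time courses
#'
#' Solves the least-squares problem `min || X - A %*% Y ||^2` for the
#' `T x N` time-course matrix `A`, given the group spatial sources `Y`
#' (`N x V`). Falls back to the pseudo-inverse with a warning when
#' `Y %*% t(Y)` is singular.
#'
#' @param scan A `subject_scan` (its data share `V` with `Y`).
#' @param Y Group source matrix (`N x V`).
#' @return A `T x N` numeric matrix of time courses.
#' @export
subject_timecourses <- function(scan, Y) {
  stopifnot(inherits(scan, "subject_scan"))
  assert_finite_matrix(Y, "Y")
  if (ncol(scan$data) != ncol(Y))
    stop("scan and sources have different voxel counts", call. = FALSE)
  Gm <- tcrossprod(Y)
  X <- scan$data
  ok <- tryCatch({
    R <- chol(Gm)
    t(backsolve(R, backsolve(R, Y %*% t(X), transpose = TRUE)))
  }, error = function(e) NULL)
  if (is.null(ok)) {
    warning("source Gram matrix is rank deficient; using pseudo-inverse")
    ok <- X %*% t(Y) %*% pinv(Gm)
  }
  ok
}

#' Spatial-similarity regression against an RSN atlas
#'
#' Each component map `y_n` (row of `Y`) is regressed onto the `R` atlas maps
#' by ordinary least squares. The stacked coefficient rows form the
#' `N x R` spatial-similarity matrix `Q`; its transpose (`R x N`) is the
#' spatial feature block consumed by the convolutional fusion stage.
#'
#' @param Y Source matrix (`N x V`).
#' @param atlas An `rsn_atlas` with `V x R` maps.
#' @return A list of class `spatial_similarity` with `Q` (`N x R`),
#'   `spatial_features` (`R x N`), and `beta_basis` (the `V x R` atlas maps).
#' @export
rsn_regression <- function(Y, atlas) {
  assert_finite_matrix(Y, "Y")
  stopifnot(inherits(atlas, "rsn_atlas"))
  M <- atlas$maps
  if (ncol(Y) != nrow(M))
    stop("sources and atlas have different voxel counts", call. = FALSE)
  B <- tryCatch(solve(crossprod(M), crossprod(M, t(Y))),
                error = function(e) {
                  warning("atlas Gram matrix is singular; using pseudo-inverse")
                  pinv(crossprod(M)) %*% crossprod(M, t(Y))
                })
  structure(list(Q = t(B), spatial_features = unname(B), beta_basis = M),
            class = "spatial_similarity")
}

#' Extract per-subject spatio-temporal feature sets
#'
#' Full stage-1 pipeline: discard initial volumes, row-centre, concatenate
#' and whiten ([group_reduce()]), run stability-selected group ICA
#' ([stability_select()]), then dual regression per subject —
#' back-reconstruct time courses against the group maps, re-estimate
#' subject-specific spatial maps against those time courses — and finally
#' regress each subject's maps onto the atlas ([rsn_regression()]).
#'
#' @param scans List of `subject_scan`.
#' @param atlas An `rsn_atlas`.
#' @param n_components Number of independent components (default 17).
#' @param discard Leading volumes to drop (default 5).
#' @param n_restarts ICA restarts for stability selection (default 10).
#' @param seed Integer seed.
#' @param ... Passed to [fastica_decompose()] (`tol`, `max_iter`).
#' @return A list with `feature_sets` (per subject: `subject_id`,
#'   `timecourses` `T' x N`, `spatial_features` `R x N`, `label`),
#'   `decomposition`, and `similarity`.
#' @export
extract_feature_sets <- function(scans, atlas, n_components = 17L,
                                 discard = 5L, n_restarts = 10L,
                                 seed = 1L, ...) {
  scans2 <- lapply(scans, discard_initial_volumes, k = discard)
  scans2 <- lapply(scans2, function(s) {
    subject_scan(s$subject_id, s$data - rowMeans(s$data), s$label)
  })
  red <- group_reduce(scans2, n_components)
  dec <- stability_select(red$whitened, n_components,
                          n_restarts = n_restarts, seed = seed, ...)
  sim <- rsn_regression(dec$sources, atlas)
  fsets <- lapply(scans2, function(s) {
    A <- subject_timecourses(s, dec$sources)
    # subject-specific spatial maps: least squares of the scan onto A
    Ys <- tryCatch(solve(crossprod(A), crossprod(A, s$data)),
                   error = function(e) pinv(crossprod(A)) %*%
                     crossprod(A, s$data))
    structure(list(subject_id = s$subject_id,
                   timecourses = A,
                   spatial_features = rsn_regression(Ys, atlas)$spatial_features,
                   label = s$label),
              class = "subject_feature_set")
  })
  list(feature_sets = fsets, decomposition = dec, similarity = sim,
       reduction_info = red$info)
}
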