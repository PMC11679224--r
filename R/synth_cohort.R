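# Synthetic rs-fMRI cohort generator.
#
# Subject scans are linear mixtures X = A %*% S of spatially sparse
# (super-Gaussian) sources S with subject-specific time courses A, plus white
# Gaussian noise. A class effect is injected into a subset of sources for
# label-1 subjects, both as a time-course amplitude gain and as a band-limited
# spectral shift, so that temporal and frequency-domain classifiers have
# recoverable signal.

#' Build a synthetic resting-state network atlas
#'
#' Generates `n_networks` smooth, spatially localized maps over a 1-D voxel
#' line. Network centres are spread evenly (with seeded jitter) so the columns
#' are pairwise near-orthogonal, mimicking the low overlap of canonical RSN
#' templates used for spatial-similarity regression.
#'
#' @param n_voxels Number of voxels `V` (positive integer).
#' @param n_networks Number of networks `R` (positive integer, `<= n_voxels`).
#' @param seed Integer seed; the atlas is deterministic given the seed.
#' @return An object of class `rsn_atlas`: a list with `maps` (a `V x R`
#'   numeric matrix, unit-norm columns) and `names` (length-`R` character).
#' @examples
#' atlas <- make_rsn_atlas(500, 30, seed = 1)
#' dim(atlas$maps)
#' @export
make_rsn_atlas <- function(n_voxels, n_networks, seed = 1L) {
  assert_count(n_voxels, "n_voxels")
  assert_count(n_networks, "n_networks")
  if (n_networks > n_voxels)
    stop("`n_networks` must not exceed `n_voxels`", call. = FALSE)
  maps <- with_seed(seed, {
    spacing <- n_voxels / n_networks
    centres <- (seq_len(n_networks) - 0.5) * spacing +
      stats::runif(n_networks, -0.2, 0.2) * spacing
    width <- max(spacing / 3, 1)
    v <- seq_len(n_voxels)
    m <- vapply(centres, function(cc) exp(-((v - cc) / width)^2),
                numeric(n_voxels))
    # suppress the far tails so maps are genuinely sparse
    m[m < 1e-3] <- 0
    sweep(m, 2, sqrt(colSums(m^2)), "/")
  })
  structure(list(maps = maps,
                 names = sprintf("RSN%02d", seq_len(n_networks))),
            class = "rsn_atlas")
}

#' @export
print.rsn_atlas <- function(x, ...) {
  cat(sprintf("<rsn_atlas> %d voxels x %d networks\n",
              nrow(x$maps), ncol(x$maps)))
  invisible(x)
}

#' Construct a subject scan object
#'
#' @param subject_id Character id.
#' @param data Numeric `T x V` matrix (timepoints by voxels).
#' @param label Class label, 0 (control) or 1 (case).
#' @return An object of class `subject_scan`.
#' @export
subject_scan <- function(subject_id, data, label) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  assert_finite_matrix(data, "data")
  if (!label %in% c(0, 1)) stop("`label` must be 0 or 1", call. = FALSE)
  structure(list(subject_id = subject_id, data = data,
                 label = as.integer(label)),
            class = "subject_scan")
}

#' @export
print.subject_scan <- function(x, ...) {
  cat(sprintf("<subject_scan> %s: %d timepoints x %d voxels, label %d\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$label))
  invisible(x)
}

#' Simulate an imbalanced two-class rs-fMRI cohort
#'
#' Each subject's scan is `A_s %*% S + noise`: `S` holds `n_sources` sparse
#' super-Gaussian spatial sources aligned to the leading atlas columns, and
#' `A_s` holds smooth (AR(1)) per-subject time courses. For label-1 subjects
#' the time courses of the effect components are scaled by
#' `1 + 0.5 * effect_size` and receive an added band-limited oscillation with
#' amplitude proportional to `effect_size`. `effect_size = 0` makes the two
#' class-conditional distributions identical.
#'
#' All random draws happen before the effect is applied, so for a fixed seed
#' the between-class power difference is monotone in `effect_size`.
#'
#' @param n_pos,n_neg Number of label-1 (case) and label-0 (control) subjects.
#' @param T Timepoints per scan.
#' @param V Voxels per scan (must match the atlas).
#' @param n_sources Number of latent sources (`<= V` and `<=` atlas networks).
#' @param effect_size Non-negative scalar controlling class separation.
#' @param atlas An `rsn_atlas` whose maps provide the source geometry.
#' @param snr Signal-to-noise variance ratio; `Inf` disables noise.
#' @param seed Integer seed.
#' @return A list with `scans` (list of `subject_scan`, cases first) and
#'   `truth` (class `cohort_truth`: `sources` `n_sources x V`, `mixings`
#'   per-subject `T x n_sources` matrices, `effect_components`, `effect_size`).
#' @examples
#' atlas <- make_rsn_atlas(200, 12, seed = 1)
#' ch <- make_cohort(5, 3, T = 40, V = 200, n_sources = 4,
#'                   effect_size = 1, atlas = atlas, seed = 7)
#' length(ch$scans)
#' @export
make_cohort <- function(n_pos, n_neg, T, V, n_sources, effect_size,
                        atlas, snr = 10, seed = 1L) {
  assert_count(n_pos, "n_pos"); assert_count(n_neg, "n_neg")
  assert_count(T, "T"); assert_count(V, "V")
  assert_count(n_sources, "n_sources")
  if (effect_size < 0) stop("`effect_size` must be >= 0", call. = FALSE)
  if (n_sources > V) stop("`n_sources` must not exceed `V`", call. = FALSE)
  if (!inherits(atlas, "rsn_atlas")) stop("`atlas` must be an rsn_atlas",
                                          call. = FALSE)
  if (nrow(atlas$maps) != V)
    stop("atlas voxel count does not match `V`", call. = FALSE)
  if (n_sources > ncol(atlas$maps))
    stop("`n_sources` exceeds the number of atlas networks", call. = FALSE)

  n_sub <- n_pos + n_neg
  labels <- c(rep(1L, n_pos), rep(0L, n_neg))
  effect_components <- seq_len(max(1L, round(n_sources / 3)))

  out <- with_seed(seed, {
    # sparse super-Gaussian sources: atlas bumps, hard-thresholded
    S <- t(atlas$maps[, seq_len(n_sources), drop = FALSE])
    S[abs(S) < 0.05 * apply(abs(S), 1, max)] <- 0
    S <- S / sqrt(rowMeans(S^2))          # unit RMS rows

    # draw everything random first (identical across effect sizes)
    base <- lapply(seq_len(n_sub), function(i) {
      a <- vapply(seq_len(n_sources), function(j) {
        x <- stats::filter(stats::rnorm(T), 0.5, method = "recursive")
        as.numeric(x) / stats::sd(x)
      }, numeric(T))
      a
    })
    phases <- matrix(stats::runif(n_sub * length(effect_components),
                                  0, 2 * pi),
                     n_sub, length(effect_components))
    noise <- lapply(seq_len(n_sub), function(i)
      matrix(stats::rnorm(T * V), T, V))

    tt <- seq_len(T)
    osc_period <- 10                      # band-limited class oscillation
    mixings <- vector("list", n_sub)
    scans <- vector("list", n_sub)
    for (i in seq_len(n_sub)) {
      A <- base[[i]]
      if (labels[i] == 1L && effect_size > 0) {
        for (jj in seq_along(effect_components)) {
          j <- effect_components[jj]
          A[, j] <- A[, j] * (1 + 0.5 * effect_size) +
            0.4 * effect_size * sin(2 * pi * tt / osc_period + phases[i, jj])
        }
      }
      mixings[[i]] <- A
      X <- A %*% S
      if (is.finite(snr)) {
        sd_sig <- stats::sd(as.numeric(X))
        X <- X + noise[[i]] * (sd_sig / sqrt(snr))
      }
      id <- sprintf("sub-%03d", i)
      scans[[i]] <- subject_scan(id, X, labels[i])
    }
    list(scans = scans, mixings = mixings, S = S)
  })

  truth <- structure(list(sources = out$S,
                          mixings = out$mixings,
                          effect_components = effect_components,
                          effect_size = effect_size),
                     class = "cohort_truth")
  list(scans = out$scans, truth = truth)
}
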