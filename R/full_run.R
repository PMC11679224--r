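# End-to-end orchestration: simulate (or read) -> extract features ->
# fuse -> cross-validate -> report.

#' Run the full pipeline
#'
#' Either reads a cohort directory (NIfTI scans + `labels.csv`, as written
#' by [write_cohort()]) or simulates one, then runs group ICA feature
#' extraction, multi-scale convolutional fusion, and subject-level
#' cross-validation with training-fold oversampling.
#'
#' @param config A [stanet_config()].
#' @param input_dir Cohort directory; `NULL` simulates instead.
#' @param out_dir If non-`NULL`, intermediate artifacts (feature CSVs,
#'   fused CSV, JSON report) are written there.
#' @param simulate List of arguments for [make_cohort()] /
#'   [make_rsn_atlas()] used when `input_dir` is `NULL`; see Defaults.
#' @param seed Integer seed driving simulation, ICA, fusion and CV.
#' @param baseline Also evaluate the ridge-logistic baseline.
#' @param verbose Print stage progress.
#' @return The `stanet_cv_report`.
#'
#' @section Defaults: The simulated cohort mirrors the study conditions the
#'   pipeline targets: 51 cases vs 21 controls, 100 timepoints, 1000
#'   voxels, 17 latent sources, effect size 2, SNR 10, and a 90-network
#'   atlas.
#' @export
full_run <- function(config = stanet_config(), input_dir = NULL,
                     out_dir = NULL, simulate = list(), seed = 1L,
                     baseline = FALSE, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(input_dir)) {
    sim <- utils::modifyList(
      list(n_pos = 51L, n_neg = 21L, T = 100L, V = 1000L,
           n_sources = 17L, effect_size = 2, snr = 10, n_networks = 90L),
      simulate)
    say("simulating cohort: %d/%d subjects, T=%d, V=%d",
        sim$n_pos, sim$n_neg, sim$T, sim$V)
    atlas <- make_rsn_atlas(sim$V, sim$n_networks, seed = seed)
    cohort <- make_cohort(sim$n_pos, sim$n_neg, sim$T, sim$V,
                          sim$n_sources, sim$effect_size, atlas,
                          snr = sim$snr, seed = seed)
    scans <- cohort$scans
  } else {
    say("reading cohort from %s", input_dir)
    scans <- read_cohort(input_dir)
    atlas <- make_rsn_atlas(ncol(scans[[1]]$data), 90L, seed = seed)
  }
  say("extracting features: %d components, %d restarts",
      config$n_components, config$restarts)
  fx <- extract_feature_sets(scans, atlas,
                             n_components = config$n_components,
                             discard = config$discard,
                             n_restarts = config$restarts, seed = seed,
                             tol = config$ica_tol,
                             max_iter = config$ica_max_iter)
  bank <- conv_bank(config$kernel_sizes, config$n_filters,
                    config$pool_size, seed = seed)
  fused <- fuse_cohort(fx$feature_sets, bank)
  say("fused vectors: %d x %d", nrow(fused$vectors), ncol(fused$vectors))
  report <- cross_validate(fused, config, seed = seed, baseline = baseline)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_sets(fx$feature_sets, file.path(out_dir, "features"),
                       seed = seed)
    write_fused(fused, file.path(out_dir, "fused.csv"))
    write_report(report, file.path(out_dir, "report.json"))
    say("artifacts written to %s", out_dir)
  }
  report
}
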