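# Pipeline configuration with validated defaults.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default: 17 independent
#' components, 5 discarded volumes, kernel sizes 3/5/7/9/11 with 8 filters
#' per scale and 6x6 max pooling, hidden size 200, 3 stacked FGRU layers,
#' learning rate 0.01, 500 weight-update rounds, SMOTE balancing with
#' k = 5, and stratified 10-fold subject-level cross-validation. Unknown
#' keys are rejected.
#'
#' @param ... Named overrides of the defaults listed above.
#' @return A validated list of class `stanet_config`.
#' @examples
#' cfg <- stanet_config(hidden = 32, epochs = 50)
#' @export
stanet_config <- function(...) {
  defaults <- list(
    n_components = 17L, discard = 5L, restarts = 10L,
    kernel_sizes = c(3L, 5L, 7L, 9L, 11L), n_filters = 8L, pool_size = 6L,
    hidden = 200L, layers = 3L, lr = 0.01, epochs = 500L, ensemble = 1L,
    sampler = "smote", smote_k = 5L, folds = 10L, stratify = TRUE,
    ica_tol = 1e-4, ica_max_iter = 200L)
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("all config overrides must be named", call. = FALSE)
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    defaults[names(over)] <- over
  }
  cfg <- defaults
  for (key in c("n_components", "restarts", "n_filters", "pool_size",
                "hidden", "layers", "epochs", "ensemble", "smote_k", "folds",
                "ica_max_iter"))
    assert_count(cfg[[key]], key)
  if (cfg$discard < 0) stop("`discard` must be >= 0", call. = FALSE)
  if (!cfg$sampler %in% c("smote", "random", "none"))
    stop('`sampler` must be one of "smote", "random", "none"', call. = FALSE)
  if (cfg$lr <= 0) stop("`lr` must be positive", call. = FALSE)
  if (any(cfg$kernel_sizes %% 2 != 1) || any(cfg$kernel_sizes < 1))
    stop("`kernel_sizes` must be odd positive integers", call. = FALSE)
  structure(cfg, class = "stanet_config")
}

#' @export
print.stanet_config <- function(x, ...) {
  cat("<stanet_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-13s %s\n", nm, paste(x[[nm]], collapse = ",")))
  invisible(x)
}
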