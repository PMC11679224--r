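# Readers and writers: NIfTI scans, CSV feature/fused matrices, JSON
# manifests and reports. Every writer has a reader that round-trips.

#' Write a cohort to NIfTI files plus a labels table
#'
#' Each scan becomes one 4D NIfTI file (`<subject_id>.nii.gz`, voxels along
#' the first axis, time along the fourth, 1 mm isotropic grid), and
#' `labels.csv` records `subject_id,label`.
#'
#' @param scans List of `subject_scan`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(scans, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in scans) {
    arr <- array(t(s$data), dim = c(ncol(s$data), 1L, 1L, nrow(s$data)))
    RNifti::writeNifti(RNifti::asNifti(arr),
                       file.path(dir, paste0(s$subject_id, ".nii.gz")))
  }
  utils::write.csv(
    data.frame(subject_id = vapply(scans, `[[`, character(1), "subject_id"),
               label = vapply(scans, `[[`, integer(1), "label")),
    file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `<id>.nii.gz` files and `labels.csv`.
#' @return List of `subject_scan`.
#' @export
read_cohort <- function(dir) {
  lab <- utils::read.csv(file.path(dir, "labels.csv"),
                         colClasses = c("character", "integer"))
  lapply(seq_len(nrow(lab)), function(i) {
    arr <- RNifti::readNifti(file.path(dir, paste0(lab$subject_id[i],
                                                   ".nii.gz")))
    d <- dim(arr)
    subject_scan(lab$subject_id[i],
                 t(matrix(arr, prod(d[1:3]), d[4])),
                 lab$label[i])
  })
}

#' Write per-subject feature sets as CSV matrices plus a JSON manifest
#'
#' @param feature_sets List of `subject_feature_set`.
#' @param dir Output directory.
#' @param seed Seed recorded in the manifest.
#' @return Invisibly, the directory.
#' @export
write_feature_sets <- function(feature_sets, dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (fs in feature_sets) {
    utils::write.table(fs$timecourses,
                       file.path(dir, paste0(fs$subject_id, "_timecourses.csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    utils::write.table(fs$spatial_features,
                       file.path(dir, paste0(fs$subject_id, "_spatial.csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  manifest <- list(
    subject_ids = vapply(feature_sets, `[[`, character(1), "subject_id"),
    labels = vapply(feature_sets, `[[`, integer(1), "label"),
    n_components = ncol(feature_sets[[1]]$timecourses),
    n_networks = nrow(feature_sets[[1]]$spatial_features),
    timepoints = nrow(feature_sets[[1]]$timecourses),
    seed = seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read feature sets written by [write_feature_sets()]
#'
#' @param dir Directory with the CSV matrices and `manifest.json`.
#' @return List of `subject_feature_set`.
#' @export
read_feature_sets <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  lapply(seq_along(man$subject_ids), function(i) {
    id <- man$subject_ids[i]
    tc <- as.matrix(utils::read.csv(
      file.path(dir, paste0(id, "_timecourses.csv")), header = FALSE))
    sp <- as.matrix(utils::read.csv(
      file.path(dir, paste0(id, "_spatial.csv")), header = FALSE))
    dimnames(tc) <- NULL; dimnames(sp) <- NULL
    structure(list(subject_id = id, timecourses = tc,
                   spatial_features = sp, label = man$labels[i]),
              class = "subject_feature_set")
  })
}

#' Write fused feature vectors to CSV with a JSON layout sidecar
#'
#' @param fused Output of [fuse_cohort()].
#' @param file CSV path; the layout goes to `<file>.layout.json`.
#' @return Invisibly, `file`.
#' @export
write_fused <- function(fused, file) {
  df <- data.frame(subject_id = fused$subject_ids, label = fused$labels,
                   fused$vectors, check.names = FALSE)
  names(df) <- c("subject_id", "label",
                 sprintf("f%05d", seq_len(ncol(fused$vectors))))
  utils::write.csv(df, file, row.names = FALSE)
  jsonlite::write_json(fused$layout, paste0(file, ".layout.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read fused features written by [write_fused()]
#'
#' @param file CSV path written by [write_fused()].
#' @return A list like [fuse_cohort()] output.
#' @export
read_fused <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE,
                        colClasses = c(subject_id = "character"))
  layout <- jsonlite::read_json(paste0(file, ".layout.json"),
                                simplifyVector = TRUE)
  layout <- lapply(seq_len(nrow(layout)), function(i) {
    l <- as.list(layout[i, ])
    l$dim <- unlist(l$dim)
    l
  })
  vectors <- as.matrix(df[, -(1:2)])
  dimnames(vectors) <- NULL
  list(vectors = vectors, labels = as.integer(df$label),
       subject_ids = df$subject_id, layout = layout)
}

#' Write a cross-validation report as JSON
#'
#' @param report A `stanet_cv_report`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_report <- function(report, file) {
  out <- list(
    mean = report$mean,
    per_fold = lapply(report$per_fold, function(r)
      r[c("ACC", "SEN", "PPV", "F1", "Recall", "AUC")]),
    folds = as.list(report$folds),
    seed = report$seed,
    config = unclass(report$config))
  if (!is.null(report$baseline))
    out$baseline_mean <- report$baseline$mean
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
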