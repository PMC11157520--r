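# Volume and cohort I/O. Volumes are NIfTI-1 images used in stored index
# order (inputs are assumed already registered to a common space); cohorts
# are tab-separated manifests, one row per scan, and the unit of splitting
# is always the subject so longitudinal scans never leak across splits.

#' Construct a volume
#'
#' @param voxels rank-3 numeric array `(D, H, W)`.
#' @param subject_id,scan_id identifiers; all scans of a subject share its
#'   `subject_id`.
#' @param label 0 (NC) or 1 (MCI).
#' @param spacing voxel spacing in mm per axis.
#' @param lesion_mask optional logical array of the same shape (phantoms
#'   only).
#' @return An object of class `mci_volume`.
#' @export
new_volume <- function(voxels, subject_id, scan_id, label,
                       spacing = c(1, 1, 1), lesion_mask = NULL) {
  if (length(dim(voxels)) != 3L)
    abort_mcigate("voxels must be a rank-3 array", "mcigate_validation_error")
  if (!label %in% c(0, 1))
    abort_mcigate("label must be 0 (NC) or 1 (MCI)", "mcigate_validation_error")
  if (!is.null(lesion_mask) && !identical(dim(lesion_mask), dim(voxels)))
    abort_mcigate("lesion_mask shape differs from voxels",
                  "mcigate_validation_error")
  structure(list(voxels = voxels, spacing = spacing,
                 subject_id = as.character(subject_id),
                 scan_id = as.character(scan_id), label = as.integer(label),
                 lesion_mask = lesion_mask),
            class = "mci_volume")
}

#' @export
print.mci_volume <- function(x, ...) {
  cat(sprintf("<mci_volume> %s / %s label=%d grid=%s\n", x$subject_id,
              x$scan_id, x$label, paste(dim(x$voxels), collapse = "x")))
  invisible(x)
}

#' Write a volume as NIfTI-1
#'
#' @param v an `mci_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  img <- RNifti::asNifti(v$voxels, pixdim = v$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume described by a manifest row
#'
#' The voxel data are used in stored index order; no reorientation is
#' attempted. The array shape must match the grid declared by the cohort.
#'
#' @param path NIfTI file path.
#' @param manifest_row list or one-row data.frame with `subject_id`,
#'   `scan_id`, `label`.
#' @param grid_shape optional `(D, H, W)` to validate against.
#' @return An `mci_volume`.
#' @export
read_volume <- function(path, manifest_row, grid_shape = NULL) {
  if (!file.exists(path))
    abort_mcigate(paste0("volume file not found: ", path), "mcigate_io_error")
  img <- RNifti::readNifti(path)
  vox <- array(as.numeric(img), dim = dim(img))
  if (!is.null(grid_shape) && !all(dim(vox) == grid_shape))
    abort_mcigate(sprintf("volume %s has grid %s, manifest declares %s", path,
                          paste(dim(vox), collapse = "x"),
                          paste(grid_shape, collapse = "x")),
                  "mcigate_validation_error")
  pd <- RNifti::pixdim(img)
  new_volume(vox, manifest_row$subject_id, manifest_row$scan_id,
             as.integer(manifest_row$label), spacing = pd[seq_len(3)])
}

#' Construct a cohort from manifest records
#'
#' @param records data.frame with columns `subject_id`, `scan_id`, `label`,
#'   `path`.
#' @param grid_shape `(D, H, W)` voxel grid shared by all scans.
#' @return An object of class `mci_cohort`.
#' @export
new_cohort <- function(records, grid_shape) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("subject_id", "scan_id", "label", "path")
  if (!all(need %in% names(records)))
    abort_mcigate(paste0("manifest must have columns: ",
                         paste(need, collapse = ", ")),
                  "mcigate_validation_error")
  records$label <- as.integer(records$label)
  if (!all(records$label %in% c(0L, 1L)))
    abort_mcigate("labels must be 0 or 1", "mcigate_validation_error")
  if (anyDuplicated(records$path))
    abort_mcigate("duplicate paths in manifest", "mcigate_validation_error")
  lab_per_subj <- tapply(records$label, records$subject_id,
                         function(x) length(unique(x)))
  if (any(lab_per_subj > 1))
    abort_mcigate(paste0("conflicting labels for subject(s): ",
                         paste(names(lab_per_subj)[lab_per_subj > 1],
                               collapse = ", ")),
                  "mcigate_validation_error")
  structure(list(records = records, grid_shape = as.integer(grid_shape)),
            class = "mci_cohort")
}

#' @export
print.mci_cohort <- function(x, ...) {
  r <- x$records
  cat(sprintf("<mci_cohort> %d scans, %d subjects (%d NC / %d MCI), grid %s\n",
              nrow(r), length(unique(r$subject_id)),
              length(unique(r$subject_id[r$label == 0])),
              length(unique(r$subject_id[r$label == 1])),
              paste(x$grid_shape, collapse = "x")))
  invisible(x)
}

#' Read / write a cohort manifest (TSV)
#'
#' The manifest is tab-separated with header
#' `subject_id  scan_id  label  path`, one row per scan. Relative paths are
#' resolved against the manifest's directory.
#'
#' @param path manifest file path.
#' @param grid_shape optional grid; when `NULL` it is read from the first
#'   listed volume.
#' @return An `mci_cohort`.
#' @export
read_cohort <- function(path, grid_shape = NULL) {
  if (!file.exists(path))
    abort_mcigate(paste0("manifest not found: ", path), "mcigate_io_error")
  rec <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(subject_id = "character",
                                          scan_id = "character"))
  base <- dirname(path)
  abs_ <- file.path(base, rec$path)
  rec$path <- ifelse(file.exists(rec$path) | grepl("^/", rec$path),
                     rec$path, abs_)
  if (is.null(grid_shape)) {
    img <- RNifti::readNifti(rec$path[1])
    grid_shape <- dim(img)
  }
  new_cohort(rec, grid_shape)
}

#' @rdname read_cohort
#' @param cohort an `mci_cohort` to write. Volume paths under the
#'   manifest's directory are written relative to it, so a run directory
#'   is relocatable and reruns are byte-stable.
#' @export
write_cohort <- function(cohort, path) {
  rec <- cohort$records
  base <- paste0(normalizePath(dirname(path), mustWork = FALSE), "/")
  abs_ <- suppressWarnings(normalizePath(rec$path, mustWork = FALSE))
  under <- startsWith(abs_, base)
  rec$path[under] <- substring(abs_[under], nchar(base) + 1L)
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

cohort_subjects <- function(cohort) {
  r <- cohort$records
  idx <- !duplicated(r$subject_id)
  data.frame(subject_id = r$subject_id[idx], label = r$label[idx],
             stringsAsFactors = FALSE)
}

subset_cohort <- function(cohort, subject_ids) {
  new_cohort(cohort$records[cohort$records$subject_id %in% subject_ids, ,
                            drop = FALSE],
             cohort$grid_shape)
}

#' Leakage-free subject-level train/test split
#'
#' Splits by subject so that all scans of one subject land on one side.
#' The per-class number of test subjects is `round(test_fraction * n)` with
#' a minimum of one, preserving class balance; the draw is deterministic
#' given `seed`.
#'
#' @param cohort an `mci_cohort` with at least two subjects per class.
#' @param test_fraction fraction of subjects held out, in (0, 1).
#' @param seed integer seed.
#' @return List with `train` and `test` cohorts.
#' @export
subject_split <- function(cohort, test_fraction = 0.25, seed = 0L) {
  if (test_fraction <= 0 || test_fraction >= 1)
    abort_mcigate("test_fraction must be in (0, 1)", "mcigate_config_error")
  subj <- cohort_subjects(cohort)
  test_ids <- character(0)
  for (lab in c(0L, 1L)) {
    ids <- sort(subj$subject_id[subj$label == lab])
    if (length(ids) < 2)
      abort_mcigate(sprintf("need >= 2 subjects of class %d to split", lab),
                    "mcigate_config_error")
    n_test <- max(1L, round(test_fraction * length(ids)))
    if (n_test >= length(ids))
      abort_mcigate(sprintf("test allocation leaves no training subject for class %d",
                            lab), "mcigate_config_error")
    pick <- with_seed(derive_seed(seed, "split", lab),
                      sample(ids, n_test))
    test_ids <- c(test_ids, pick)
  }
  list(train = subset_cohort(cohort, setdiff(subj$subject_id, test_ids)),
       test = subset_cohort(cohort, test_ids))
}
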