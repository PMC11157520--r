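# Synthetic gray-matter phantoms. The phantom emulates the structure of a
# longitudinal MCI cohort: a smooth anatomical background shared by all
# subjects, a per-subject multiplicative gain held fixed across that
# subject's scans, localized ellipsoidal lesions in which class-1 (MCI-like)
# intensity is multiplied by an atrophy factor, and i.i.d. voxel noise.
# Every random draw comes from a substream derived from (seed, subject,
# scan), so cohorts are reproducible and extensible.

# Fixed background recipe: anisotropic Gaussian bumps at grid fractions
# (center per axis, sd per axis, amplitude). The superposition is rescaled
# to a 0.85 peak so that per-subject gains rarely reach the [0, 1] clamp.
PHANTOM_BUMPS <- list(
  list(c = c(0.50, 0.50, 0.50), s = c(0.30, 0.32, 0.30), a = 0.45),
  list(c = c(0.30, 0.40, 0.40), s = c(0.12, 0.14, 0.12), a = 0.25),
  list(c = c(0.70, 0.40, 0.40), s = c(0.12, 0.14, 0.12), a = 0.25),
  list(c = c(0.50, 0.65, 0.55), s = c(0.18, 0.15, 0.14), a = 0.20),
  list(c = c(0.35, 0.60, 0.50), s = c(0.10, 0.12, 0.10), a = 0.15),
  list(c = c(0.65, 0.60, 0.50), s = c(0.10, 0.12, 0.10), a = 0.15)
)

# Two mirrored lesion pairs at hippocampus-adjacent loci (fractions of each
# axis); radii default to 7% of each axis, at least 2 voxels.
PHANTOM_LESION_FRACS <- rbind(
  c(0.32, 0.40, 0.35), c(0.68, 0.40, 0.35),
  c(0.35, 0.55, 0.45), c(0.65, 0.55, 0.45)
)

phantom_background <- function(grid_shape) {
  ax <- lapply(1:3, function(i) seq_len(grid_shape[i]))
  bg <- array(0, dim = grid_shape)
  for (bump in PHANTOM_BUMPS) {
    gs <- lapply(1:3, function(i) {
      mu <- bump$c[i] * (grid_shape[i] - 1) + 1
      sd <- bump$s[i] * grid_shape[i]
      exp(-0.5 * ((ax[[i]] - mu) / sd)^2)
    })
    bg <- bg + bump$a * (gs[[1]] %o% gs[[2]] %o% gs[[3]])
  }
  bg * (0.85 / max(bg))
}

lesion_mask_from <- function(grid_shape, centers, radii) {
  mask <- array(FALSE, dim = grid_shape)
  ax <- lapply(1:3, function(i) seq_len(grid_shape[i]))
  for (j in seq_len(nrow(centers))) {
    d2 <- ((ax[[1]] - centers[j, 1]) / radii[j, 1])^2 %o%
      rep(1, grid_shape[2]) %o% rep(1, grid_shape[3]) +
      rep(1, grid_shape[1]) %o% ((ax[[2]] - centers[j, 2]) / radii[j, 2])^2 %o%
      rep(1, grid_shape[3]) +
      rep(1, grid_shape[1]) %o% rep(1, grid_shape[2]) %o%
      ((ax[[3]] - centers[j, 3]) / radii[j, 3])^2
    mask <- mask | (d2 <= 1)
  }
  mask
}

#' Phantom cohort specification
#'
#' Defines the study conditions of a synthetic cohort: grid, cohort size,
#' scans per subject, lesion geometry, class contrast, and noise levels.
#'
#' @param grid_shape `(D, H, W)` voxel grid; the full-scale default matches
#'   preprocessed gray-matter maps (84 x 102 x 84); `c(32, 40, 32)` is the
#'   scaled-down desk grid.
#' @param n_subjects_per_class subjects per class (NC and MCI-like).
#' @param scans_per_subject longitudinal scans per subject, `>= 1`.
#' @param lesion_centers n x 3 matrix of voxel coordinates; default places
#'   two mirrored pairs at hippocampus-adjacent loci.
#' @param lesion_radii n x 3 matrix (or length-3 vector) of per-axis radii
#'   in voxels; default 7% of each axis, at least 2 voxels.
#' @param atrophy_factor class-1 intensity multiplier inside lesions, in
#'   (0, 1]; 1 makes the classes indistinguishable.
#' @param noise_sd i.i.d. voxel noise standard deviation, `>= 0`.
#' @param subject_effect_sd standard deviation of the per-subject gain
#'   `1 + N(0, sd)`, shared across a subject's scans.
#' @param seed master seed; all per-subject and per-scan draws derive from
#'   it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(84L, 102L, 84L),
                         n_subjects_per_class = 40L,
                         scans_per_subject = 1L,
                         lesion_centers = NULL,
                         lesion_radii = NULL,
                         atrophy_factor = 0.6,
                         noise_sd = 0.05,
                         subject_effect_sd = 0.1,
                         seed = 0L) {
  grid_shape <- as.integer(grid_shape)
  if (is.null(lesion_centers))
    lesion_centers <- sweep(PHANTOM_LESION_FRACS, 2, grid_shape - 1, "*") + 1
  lesion_centers <- matrix(lesion_centers, ncol = 3)
  if (is.null(lesion_radii))
    lesion_radii <- pmax(2, 0.07 * grid_shape)
  if (is.null(dim(lesion_radii)))
    lesion_radii <- matrix(lesion_radii, nrow(lesion_centers), 3, byrow = TRUE)
  if (atrophy_factor <= 0 || atrophy_factor > 1)
    abort_mcigate("atrophy_factor must be in (0, 1]", "mcigate_validation_error")
  if (noise_sd < 0 || subject_effect_sd < 0)
    abort_mcigate("noise_sd and subject_effect_sd must be >= 0",
                  "mcigate_validation_error")
  if (scans_per_subject < 1)
    abort_mcigate("scans_per_subject must be >= 1", "mcigate_validation_error")
  lo <- lesion_centers - lesion_radii
  hi <- lesion_centers + lesion_radii
  if (any(lo < 1) || any(sweep(hi, 2, grid_shape, ">")))
    abort_mcigate("lesion ellipsoids must lie entirely within the grid",
                  "mcigate_validation_error")
  structure(list(grid_shape = grid_shape,
                 n_subjects_per_class = as.integer(n_subjects_per_class),
                 scans_per_subject = as.integer(scans_per_subject),
                 lesion_centers = lesion_centers, lesion_radii = lesion_radii,
                 atrophy_factor = atrophy_factor, noise_sd = noise_sd,
                 subject_effect_sd = subject_effect_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one phantom volume
#'
#' Deterministic given `(spec$seed, subject_id, scan_index)`: the smooth
#' background is multiplied by the subject's gain, intensities inside each
#' lesion ellipsoid are multiplied by `atrophy_factor` when `label = 1`,
#' voxel noise is added, and the result is clamped to `[0, 1]`.
#'
#' @param spec a [phantom_spec()].
#' @param subject_id subject identifier (drives the subject gain stream).
#' @param scan_index scan number within the subject (drives the noise
#'   stream).
#' @param label 0 (NC-like) or 1 (MCI-like).
#' @return An `mci_volume` with `lesion_mask` set.
#' @export
generate_phantom <- function(spec, subject_id, scan_index = 1L, label = 0L) {
  bg <- phantom_background(spec$grid_shape)
  mask <- lesion_mask_from(spec$grid_shape, spec$lesion_centers,
                           spec$lesion_radii)
  gain <- 1 + with_seed(derive_seed(spec$seed, "subject", subject_id),
                        stats::rnorm(1, 0, 1)) * spec$subject_effect_sd
  vox <- bg * gain
  if (label == 1) vox[mask] <- vox[mask] * spec$atrophy_factor
  if (spec$noise_sd > 0) {
    noise <- with_seed(derive_seed(spec$seed, "scan", subject_id, scan_index),
                       stats::rnorm(length(vox), 0, 1)) * spec$noise_sd
    vox <- vox + noise
  }
  vox <- clamp01(vox)
  dim(vox) <- spec$grid_shape
  new_volume(vox, subject_id,
             scan_id = sprintf("%s_t%02d", subject_id, scan_index),
             label = label, lesion_mask = mask)
}

#' Generate and write a phantom cohort
#'
#' Writes `n_subjects_per_class x 2 x scans_per_subject` NIfTI volumes plus
#' a TSV manifest (`manifest.tsv`) under `out_dir`. A subject's gain is
#' shared across its scans, so within-subject scans correlate more than
#' between-subject ones.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory (created if needed).
#' @return The generated `mci_cohort`.
#' @export
generate_cohort <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    abort_mcigate(paste0("cannot create output directory: ", out_dir),
                  "mcigate_io_error")
  rows <- list()
  for (label in c(0L, 1L)) {
    prefix <- c("nc", "mci")[label + 1L]
    for (i in seq_len(spec$n_subjects_per_class)) {
      sid <- sprintf("%s%03d", prefix, i)
      for (t in seq_len(spec$scans_per_subject)) {
        v <- generate_phantom(spec, sid, t, label)
        fname <- sprintf("%s.nii.gz", v$scan_id)
        write_volume(v, file.path(out_dir, fname))
        rows[[length(rows) + 1L]] <-
          data.frame(subject_id = sid, scan_id = v$scan_id, label = label,
                     path = fname, stringsAsFactors = FALSE)
      }
    }
  }
  rec <- do.call(rbind, rows)
  cohort <- new_cohort(
    transform(rec, path = file.path(out_dir, path)), spec$grid_shape)
  utils::write.table(rec, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cohort
}
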