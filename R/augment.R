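# Deterministic 25-fold augmentation: identity, single-axis flips,
# small-angle rotations with trilinear interpolation (zero padding outside
# the head, where gray-matter maps are zero anyway), and seeded additive
# Gaussian noise. Augmentation is meant for training data only, after
# splitting; it never changes label, subject, or grid shape.

#' Rotate a volume about one axis
#'
#' In-plane rotation of the two axes orthogonal to `axis`, about the volume
#' center, trilinear interpolation, zero padding outside the grid.
#'
#' @param vox rank-3 array.
#' @param axis axis index (1-3) kept fixed.
#' @param angle rotation angle in degrees (counterclockwise in the plane of
#'   the remaining two axes).
#' @return Rotated array, same shape.
#' @export
rotate_volume <- function(vox, axis, angle) {
  d <- dim(vox)
  plane <- setdiff(1:3, axis)
  n1 <- d[plane[1]]; n2 <- d[plane[2]]
  c1 <- (n1 + 1) / 2; c2 <- (n2 + 1) / 2
  th <- angle * pi / 180
  # inverse rotation: output coords -> source coords
  u <- rep(seq_len(n1) - c1, times = n2)
  v <- rep(seq_len(n2) - c2, each = n1)
  us <- cos(th) * u + sin(th) * v + c1
  vs <- -sin(th) * u + cos(th) * v + c2
  i0 <- floor(us); j0 <- floor(vs)
  fi <- us - i0; fj <- vs - j0
  # move the fixed axis first, plane axes in order
  perm <- c(axis, plane)
  xp <- aperm(vox, perm)
  m <- matrix(xp, d[axis], n1 * n2)
  out <- matrix(0, d[axis], n1 * n2)
  for (corner in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
    ii <- i0 + corner[1]; jj <- j0 + corner[2]
    w <- (if (corner[1] == 0) 1 - fi else fi) *
      (if (corner[2] == 0) 1 - fj else fj)
    ok <- ii >= 1 & ii <= n1 & jj >= 1 & jj <= n2 & w > 0
    if (!any(ok)) next
    cols <- ii[ok] + n1 * (jj[ok] - 1)
    out[, ok] <- out[, ok] + sweep(m[, cols, drop = FALSE], 2, w[ok], "*")
  }
  dim(out) <- c(d[axis], n1, n2)
  aperm(out, order(perm))
}

#' Build the augmentation catalogue
#'
#' The default catalogue has exactly 25 entries: the identity, three
#' single-axis flips, twelve rotations (plus/minus each angle about each of
#' the three axes) and nine additive-Gaussian-noise variants (each noise sd
#' drawn `noise_reps` times from seeded substreams). The catalogue is fixed
#' given its configuration; the only randomness is the seeded noise draws.
#'
#' @param rotation_angles rotation magnitudes in degrees.
#' @param noise_sds additive noise standard deviations.
#' @param noise_reps seeded draws per noise sd.
#' @param include_flips include the three single-axis flips.
#' @param seed integer seed for the noise streams.
#' @return An object of class `augment_catalogue`.
#' @export
augment_catalogue <- function(rotation_angles = c(5, 10),
                              noise_sds = c(0.01, 0.02, 0.03),
                              noise_reps = 3L, include_flips = TRUE,
                              seed = 0L) {
  rows <- list(data.frame(kind = "identity", axis = NA_integer_,
                          angle = NA_real_, sd = NA_real_, rep = NA_integer_))
  if (include_flips)
    for (ax in 1:3)
      rows[[length(rows) + 1L]] <- data.frame(kind = "flip", axis = ax,
                                              angle = NA, sd = NA, rep = NA)
  for (ax in 1:3)
    for (a in rotation_angles)
      for (sgn in c(1, -1))
        rows[[length(rows) + 1L]] <- data.frame(kind = "rotate", axis = ax,
                                                angle = sgn * a, sd = NA,
                                                rep = NA)
  for (s in noise_sds)
    for (r in seq_len(noise_reps))
      rows[[length(rows) + 1L]] <- data.frame(kind = "noise", axis = NA,
                                              angle = NA, sd = s, rep = r)
  structure(list(transforms = do.call(rbind, rows), seed = as.integer(seed)),
            class = "augment_catalogue")
}

#' Number of outputs per input volume
#' @param cat an `augment_catalogue`.
#' @return Integer expansion factor (25 for the default catalogue).
#' @export
expansion_factor <- function(cat) nrow(cat$transforms)

apply_transform <- function(vox, tr, cat, scan_id, entry) {
  switch(tr$kind,
    identity = vox,
    flip = {
      idx <- lapply(dim(vox), seq_len)
      idx[[tr$axis]] <- rev(idx[[tr$axis]])
      do.call(`[`, c(list(vox), idx))
    },
    rotate = rotate_volume(vox, tr$axis, tr$angle),
    noise = {
      eps <- with_seed(derive_seed(cat$seed, "augnoise", scan_id, entry),
                       stats::rnorm(length(vox)))
      vox + array(eps * tr$sd, dim = dim(vox))
    },
    abort_mcigate(paste0("unknown transform kind: ", tr$kind),
                  "mcigate_validation_error"))
}

#' Apply the full catalogue to one volume
#'
#' @param v an `mci_volume`.
#' @param cat an `augment_catalogue`.
#' @return List of `expansion_factor(cat)` volumes; entry 1 is `v` itself.
#'   All outputs keep `v`'s shape, `subject_id`, and label.
#' @export
augment_volume <- function(v, cat) {
  if (length(dim(v$voxels)) != 3L)
    abort_mcigate("volume must have a rank-3 voxel array",
                  "mcigate_validation_error")
  lapply(seq_len(nrow(cat$transforms)), function(i) {
    tr <- cat$transforms[i, ]
    vox <- apply_transform(v$voxels, tr, cat, v$scan_id, i)
    sid <- if (i == 1L) v$scan_id else sprintf("%s_aug%02d", v$scan_id, i)
    new_volume(vox, v$subject_id, sid, v$label, spacing = v$spacing)
  })
}

#' Augment a cohort on disk
#'
#' Applies the catalogue to every scan of `cohort`, writing the augmented
#' volumes and a manifest `manifest.tsv` to `out_dir`. Intended for the
#' training portion only (augmenting before the split would leak).
#'
#' @param cohort an `mci_cohort`.
#' @param cat an `augment_catalogue`.
#' @param out_dir output directory.
#' @return The augmented `mci_cohort`.
#' @export
augment_cohort <- function(cohort, cat, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (k in seq_len(nrow(cohort$records))) {
    row <- cohort$records[k, ]
    v <- read_volume(row$path, row, cohort$grid_shape)
    for (a in augment_volume(v, cat)) {
      fname <- sprintf("%s.nii.gz", a$scan_id)
      write_volume(a, file.path(out_dir, fname))
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = a$subject_id, scan_id = a$scan_id,
                   label = a$label, path = fname, stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, rows)
  utils::write.table(rec, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  new_cohort(transform(rec, path = file.path(out_dir, path)),
             cohort$grid_shape)
}
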