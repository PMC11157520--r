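# Volumetric Grad-CAM: channel weights are the spatial average of the
# gradient of a class score with respect to a convolutional stage's
# activations; the saliency map is the ReLU of the weighted activation
# sum, trilinearly upsampled to the input grid and normalized to [0, 1].
# The localization score quantifies whether high saliency coincides with
# the phantom's known lesion geometry.

cam_layers <- c("stage1", "stage2", "stage3", "stage4")

#' Grad-CAM saliency volume
#'
#' @param model an `mcigate_model`.
#' @param v an `mci_volume` (or rank-3 voxel array).
#' @param target_class class whose evidence is mapped, 0 or 1.
#' @param layer convolutional stage to attribute to (default the deepest,
#'   `"stage4"`).
#' @return List of class `cam_volume`: `weights` (non-negative rank-3
#'   array on the input grid, max 1 when nonzero), `layer_name`,
#'   `target_class`.
#' @export
grad_cam <- function(model, v, target_class = 1L, layer = "stage4") {
  if (!layer %in% cam_layers)
    abort_mcigate(paste0("unknown layer '", layer, "'; valid layers: ",
                         paste(cam_layers, collapse = ", ")),
                  "mcigate_validation_error")
  vox <- if (inherits(v, "mci_volume")) v$voxels else v
  x <- array(vox, dim = c(dim(vox), 1L, 1L))
  out <- model_forward(model, x, training = FALSE)
  act <- out[[layer]]
  score <- out$scores
  seed <- matrix(0, 1, model$config$n_classes)
  seed[1, target_class + 1L] <- 1
  ag_backward(score, seed)
  grad <- act$grad
  a <- act$val
  d <- dim(a)
  w <- apply(grad[, , , , 1, drop = FALSE], 4, mean)     # channel weights
  cam <- array(0, dim = d[1:3])
  for (c in seq_len(d[4])) cam <- cam + w[c] * a[, , , c, 1]
  cam <- pmax(cam, 0)
  dim(cam) <- c(d[1:3], 1L, 1L)
  cam <- cpp_resize3d_fwd(cam, as.integer(dim(vox)))
  cam <- array(cam, dim = dim(vox))
  if (max(cam) > 0) cam <- cam / max(cam)
  structure(list(weights = cam, layer_name = layer,
                 target_class = as.integer(target_class)),
            class = "cam_volume")
}

#' Lesion-localization score of a saliency map
#'
#' Mean saliency inside the lesion mask divided by mean saliency outside;
#' values above 1 mean the map concentrates on the lesioned region. The
#' score is invariant under positive rescaling of the map. A zero outside
#' mean with nonzero inside mean returns `Inf`.
#'
#' @param cam a `cam_volume` (or rank-3 non-negative array).
#' @param mask logical lesion mask of the same shape, neither empty nor
#'   full.
#' @return A single numeric score.
#' @export
localization_score <- function(cam, mask) {
  w <- if (inherits(cam, "cam_volume")) cam$weights else cam
  if (!identical(dim(w), dim(mask)))
    abort_mcigate("CAM and mask shapes differ", "mcigate_validation_error")
  n_in <- sum(mask)
  if (n_in == 0 || n_in == length(mask))
    abort_mcigate("mask must be nonempty and non-full",
                  "mcigate_validation_error")
  inside <- mean(w[mask])
  outside <- mean(w[!mask])
  if (outside == 0) {
    if (inside == 0) return(NaN)
    return(Inf)
  }
  inside / outside
}

#' Write a CAM volume as NIfTI aligned to its input
#'
#' @param cam a `cam_volume`.
#' @param path output `.nii` / `.nii.gz` path.
#' @param spacing voxel spacing in mm.
#' @export
write_cam <- function(cam, path, spacing = c(1, 1, 1)) {
  RNifti::writeNifti(RNifti::asNifti(cam$weights, pixdim = spacing), path)
  invisible(path)
}
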