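# --- synthetic 4-modality phantoms ----------------------------------------
#
# The phantom generator stands in for the multimodal brain-tumor MRI data so
# the whole pipeline is exercisable without any download. A phantom is a
# large centered "brain" ellipsoid of nonzero intensity (zero outside, as in
# skull-stripped data, so cropping is exercised), containing one or more
# randomly oriented "tumor" ellipsoids with modality-specific contrast, plus
# additive Gaussian noise inside the brain. The default contrasts emulate
# the qualitative appearance of the four modalities (tumor brightest on the
# FLAIR-like channel 1, strong enhancement on the T1gd-like channel 3) and
# deliberately overlap under noise so that no single-channel threshold
# solves the noisy task perfectly.

#' Phantom generator configuration
#'
#' @param volume_shape Spatial shape (desk-scale default 96^3; the reference
#'   data's 240 x 240 x 155 grid is supported).
#' @param n_volumes Number of phantoms in a generated dataset.
#' @param tumor_radius_range Range (voxels) of tumor ellipsoid semi-axes;
#'   minimum 2.
#' @param tumor_count_range Range of tumor ellipsoids per volume.
#' @param modality_contrasts 4 x 2 matrix: per-modality mean intensity of
#'   brain tissue (column 1) and tumor (column 2).
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Master seed; each phantom is fully determined by
#'   `(seed, index)`.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(volume_shape = c(96L, 96L, 96L),
                           n_volumes = 10L,
                           tumor_radius_range = c(5, 12),
                           tumor_count_range = c(1L, 3L),
                           modality_contrasts = cbind(
                             brain = c(1.0, 1.2, 1.1, 0.9),
                             tumor = c(1.8, 1.35, 1.6, 1.2)),
                           noise_sd = 0.3,
                           seed = 0L) {
  volume_shape <- as.integer(volume_shape)
  stopifnot(length(volume_shape) == 3L, all(volume_shape >= 16L))
  if (tumor_radius_range[1] < 2) stop("tumor radii must be >= 2 voxels")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (!is.matrix(modality_contrasts) || ncol(modality_contrasts) != 2L)
    stop("`modality_contrasts` must be a (modalities x 2) matrix")
  structure(list(volume_shape = volume_shape,
                 n_volumes = as.integer(n_volumes),
                 tumor_radius_range = as.numeric(tumor_radius_range),
                 tumor_count_range = as.integer(tumor_count_range),
                 modality_contrasts = modality_contrasts,
                 noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Voxels inside an arbitrarily oriented ellipsoid:
# || diag(1/semiaxes) R' (x - center) ||^2 <= 1
ellipsoid_mask <- function(dims, center, semiaxes, rotation = diag(3)) {
  gx <- seq_len(dims[1]) - center[1]
  gy <- seq_len(dims[2]) - center[2]
  gz <- seq_len(dims[3]) - center[3]
  n <- prod(dims)
  pts <- cbind(rep(gx, times = dims[2] * dims[3]),
               rep(rep(gy, each = dims[1]), times = dims[3]),
               rep(gz, each = dims[1] * dims[2]))
  u <- pts %*% rotation            # rows: R' (x - c) since (x-c)' R
  q <- (u[, 1] / semiaxes[1])^2 + (u[, 2] / semiaxes[2])^2 +
    (u[, 3] / semiaxes[3])^2
  array(q <= 1, dim = dims)
}

random_rotation <- function() {
  qr_res <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate one phantom volume
#'
#' Deterministic given `(config$seed, index)`.
#'
#' @param config A [phantom_config()].
#' @param index 1-based phantom index.
#' @return A [volume_sample()] with id `phantom<index>`; the generating
#'   geometry (brain and tumor ellipsoid parameters) is attached as
#'   attribute `geometry` for parameter-recovery tests.
#' @export
make_phantom <- function(config, index = 1L) {
  dims <- config$volume_shape
  with_seed(derive_seed(config$seed, 77000L + index), {
    brain_center <- dims / 2 + runif(3, -2, 2)
    brain_axes <- 0.38 * dims * runif(3, 0.9, 1.05)
    brain <- ellipsoid_mask(dims, brain_center, brain_axes)
    n_tumors <- sample(seq(config$tumor_count_range[1],
                           config$tumor_count_range[2]), 1L)
    tumors <- list()
    label <- array(FALSE, dim = dims)
    for (ti in seq_len(n_tumors)) {
      placed <- FALSE
      for (try in 1:100) {
        axes <- runif(3, config$tumor_radius_range[1], config$tumor_radius_range[2])
        rmax <- max(axes)
        inner <- brain_axes - rmax
        if (any(inner < 1)) next
        # uniform in the shrunken brain ellipsoid => tumor fits inside brain
        repeat {
          u <- runif(3, -1, 1)
          if (sum(u^2) <= 1) break
        }
        center <- brain_center + u * inner
        rot <- random_rotation()
        mask <- ellipsoid_mask(dims, center, axes, rot)
        label <- label | mask
        tumors[[ti]] <- list(center = center, semiaxes = axes,
                             rotation = as.vector(rot))
        placed <- TRUE
        break
      }
      if (!placed)
        stop("infeasible tumor geometry for phantom ", index,
             " after bounded retries (radii too large for the brain?)")
    }
    C <- nrow(config$modality_contrasts)
    img <- array(0, dim = c(dims, C))
    for (cc in seq_len(C)) {
      ch <- array(0, dim = dims)
      ch[brain] <- config$modality_contrasts[cc, 1]
      ch[label] <- config$modality_contrasts[cc, 2]
      if (config$noise_sd > 0) {
        nb <- sum(brain)
        ch[brain] <- ch[brain] + rnorm(nb, sd = config$noise_sd)
      }
      img[, , , cc] <- ch
    }
    out <- volume_sample(img, label * 1L, sprintf("phantom%04d", index))
    attr(out, "geometry") <- list(
      brain = list(center = brain_center, semiaxes = brain_axes),
      tumors = tumors)
    out
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_volumes` image/label NIfTI pairs plus a JSON manifest recording
#' the configuration, per-volume ids, generating seeds and ground-truth
#' geometry. Volumes are byte-identical when regenerated from the manifest's
#' seed.
#'
#' @param config A [phantom_config()].
#' @param dir Output directory.
#' @param gzip Compress volumes.
#' @return Invisibly, the manifest list.
#' @export
make_phantom_dataset <- function(config, dir, gzip = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  volumes <- vector("list", config$n_volumes)
  for (i in seq_len(config$n_volumes)) {
    s <- make_phantom(config, i)
    write_nifti(s$image, file.path(dir, paste0(s$id, "_img", ext)), datatype = "float32")
    write_nifti(s$label, file.path(dir, paste0(s$id, "_lab", ext)), datatype = "uint8")
    volumes[[i]] <- list(id = s$id, index = i,
                         seed = derive_seed(config$seed, 77000L + i),
                         geometry = attr(s, "geometry"))
  }
  manifest <- list(
    generator = "unet3d phantom",
    config = list(volume_shape = config$volume_shape,
                  n_volumes = config$n_volumes,
                  tumor_radius_range = config$tumor_radius_range,
                  tumor_count_range = config$tumor_count_range,
                  modality_contrasts = config$modality_contrasts,
                  noise_sd = config$noise_sd,
                  seed = config$seed),
    volumes = volumes)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Load a phantom dataset written by [make_phantom_dataset()]
#'
#' @param dir Dataset directory containing `manifest.json`.
#' @param ids Optional subset of volume ids to load.
#' @return List of [volume_sample()]s.
#' @export
read_phantom_dataset <- function(dir, ids = NULL) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  all_ids <- manifest$volumes$id
  if (is.null(ids)) ids <- all_ids
  lapply(ids, function(id) {
    find1 <- function(sufs) {
      for (s in sufs) {
        p <- file.path(dir, paste0(id, s))
        if (file.exists(p)) return(p)
      }
      stop("missing volume file for id '", id, "' in ", dir)
    }
    img <- read_nifti(find1(c("_img.nii.gz", "_img.nii")))
    lab <- read_nifti(find1(c("_lab.nii.gz", "_lab.nii")))
    attr(img, "spacing") <- NULL
    attr(lab, "spacing") <- NULL
    volume_sample(img, lab, id)
  })
}

#' Single-channel threshold baseline segmenter
#'
#' Labels voxels whose intensity on one channel exceeds a threshold. At zero
#' noise the default threshold (midway between brain and tumor mean on the
#' FLAIR-like channel) recovers the tumor exactly — establishing that the
#' phantom task is learnable and bounding achievable Dice from above; under
#' noise it is imperfect, which is what the network must beat by integrating
#' all four channels and spatial context.
#'
#' @param sample A raw (un-normalized) phantom [volume_sample()].
#' @param channel Channel index (default 1, FLAIR-like).
#' @param threshold Intensity cutoff.
#' @return Binary 3D mask.
#' @export
threshold_segment <- function(sample, channel = 1L, threshold = 1.4) {
  (sample$image[, , , channel] > threshold) * 1L
}
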