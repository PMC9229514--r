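# --- random patch extraction and augmentation -----------------------------

#' Random-patch datastore specification
#'
#' Training feeds on fixed-size sub-volumes ("patches") extracted at random
#' positions from the preprocessed volumes, so memory use is bounded
#' regardless of volume size. Reference settings: 64^3-voxel patches, 16
#' patches per image, mini-batches of 8.
#'
#' @param patch_size Spatial patch size, length-3 integer vector with all
#'   components divisible by 8 (a scalar is recycled).
#' @param patches_per_image Patches drawn from each volume per epoch.
#' @param batch_size Mini-batch size.
#' @return Object of class `patch_spec`.
#' @export
patch_spec <- function(patch_size = c(64L, 64L, 64L),
                       patches_per_image = 16L,
                       batch_size = 8L) {
  if (length(patch_size) == 1L) patch_size <- rep(patch_size, 3L)
  patch_size <- as.integer(patch_size)
  if (length(patch_size) != 3L || any(patch_size %% 8L != 0L) || any(patch_size < 8L))
    stop("`patch_size` components must be positive multiples of 8")
  patches_per_image <- as.integer(patches_per_image)
  batch_size <- as.integer(batch_size)
  if (patches_per_image < 1L) stop("`patches_per_image` must be >= 1")
  if (batch_size < 1L) stop("`batch_size` must be >= 1")
  structure(list(patch_size = patch_size,
                 patches_per_image = patches_per_image,
                 batch_size = batch_size),
            class = "patch_spec")
}

# Extract the aligned image/label patch starting at `origin` (1-based).
extract_patch <- function(sample, origin, size) {
  ix <- origin[1]:(origin[1] + size[1] - 1L)
  iy <- origin[2]:(origin[2] + size[2] - 1L)
  iz <- origin[3]:(origin[3] + size[3] - 1L)
  list(image = sample$image[ix, iy, iz, , drop = FALSE],
       label = if (!is.null(sample$label)) sample$label[ix, iy, iz, drop = FALSE],
       origin = origin, id = sample$id)
}

#' Sample aligned random patches from one volume
#'
#' Patch start positions are uniform over all positions at which the patch
#' lies fully inside the volume; image and label patches are cut at identical
#' coordinates. Deterministic given `seed`.
#'
#' @param sample A [volume_sample()] (cropped, spatial dims >= patch size).
#' @param spec A [patch_spec()].
#' @param seed Integer seed.
#' @return List of `spec$patches_per_image` patch pairs, each a list with
#'   `image`, `label`, `origin` (1-based start indices), `id`.
#' @export
sample_patches <- function(sample, spec, seed = 0L) {
  dims <- dim(sample$image)[1:3]
  ps <- spec$patch_size
  if (any(dims < ps))
    stop("volume '", sample$id, "' (", paste(dims, collapse = "x"),
         ") is smaller than the patch size (", paste(ps, collapse = "x"),
         "); pad the volume to at least the patch size or skip it")
  nvalid <- dims - ps + 1L
  origins <- with_seed(seed, {
    vapply(seq_len(spec$patches_per_image), function(i) {
      c(sample.int(nvalid[1], 1L), sample.int(nvalid[2], 1L), sample.int(nvalid[3], 1L))
    }, integer(3))
  })
  lapply(seq_len(spec$patches_per_image), function(i) {
    extract_patch(sample, origins[, i], ps)
  })
}

#' Draw a random grid-preserving augmentation transform
#'
#' The augmentation family is independent reflections along each spatial axis
#' (probability 1/2 each) composed with a rotation by a multiple of 90
#' degrees in the axial (H, W) plane. These transforms permute voxels without
#' interpolation, so intensity values and label counts are exactly preserved.
#'
#' @param seed Integer seed.
#' @return Object of class `patch_transform`: list with `flip`
#'   (logical 3-vector) and `k` (0-3 quarter-turns).
#' @export
random_transform <- function(seed = 0L) {
  with_seed(seed, {
    structure(list(flip = runif(3) < 0.5, k = sample(0:3, 1L)),
              class = "patch_transform")
  })
}

#' Identity transform
#' @return A `patch_transform` that leaves patches unchanged.
#' @export
identity_transform <- function() {
  structure(list(flip = c(FALSE, FALSE, FALSE), k = 0L),
            class = "patch_transform")
}

# Reverse one spatial axis of a 3D/4D array.
flip_axis <- function(x, ax) {
  idx <- rep(list(quote(expr = )), length(dim(x)))
  idx[[ax]] <- rev(seq_len(dim(x)[ax]))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# One counter-clockwise quarter turn in the (H, W) plane.
rot90_axial <- function(x) {
  perm <- seq_along(dim(x)); perm[1:2] <- c(2L, 1L)
  flip_axis(aperm(x, perm), 1L)
}

#' Apply (or invert) an augmentation transform
#'
#' Forward order is reflections first, then rotation; `inverse = TRUE`
#' applies the exact inverse so that
#' `apply_transform(apply_transform(x, tr), tr, inverse = TRUE)` returns `x`.
#' Rotation requires the first two spatial dims to be equal (cubic patches).
#'
#' @param x 3D `(H, W, D)` or 4D `(H, W, D, C)` array.
#' @param transform A `patch_transform`.
#' @param inverse Apply the inverse transform.
#' @return Transformed array of identical shape.
#' @export
apply_transform <- function(x, transform, inverse = FALSE) {
  stopifnot(inherits(transform, "patch_transform"))
  nd <- length(dim(x))
  if (!nd %in% c(3L, 4L)) stop("expected a 3D or 4D array")
  if (transform$k %% 4L != 0L && dim(x)[1] != dim(x)[2])
    stop("axial rotation requires equal (H, W) dimensions")
  do_flips <- function(x) {
    for (ax in which(transform$flip)) x <- flip_axis(x, ax)
    x
  }
  do_rot <- function(x, k) {
    k <- ((k %% 4L) + 4L) %% 4L
    for (i in seq_len(k)) x <- rot90_axial(x)
    x
  }
  if (!inverse) do_rot(do_flips(x), transform$k)
  else do_flips(do_rot(x, -transform$k))
}

#' Augment an aligned image/label patch pair
#'
#' Applies one random [random_transform()] identically to the image and the
#' label, so alignment, per-channel intensity multisets and the tumor voxel
#' count are preserved.
#'
#' @param pair Patch pair (list with `image`, `label`) as produced by
#'   [sample_patches()].
#' @param seed Integer seed.
#' @return The pair with transformed `image`/`label` and the applied
#'   `transform` attached.
#' @export
augment_patch <- function(pair, seed = 0L) {
  tr <- random_transform(seed)
  pair$image <- apply_transform(pair$image, tr)
  if (!is.null(pair$label)) pair$label <- apply_transform(pair$label, tr)
  pair$transform <- tr
  pair
}

#' Mini-batch updates per epoch
#'
#' One epoch visits every volume's patches once:
#' `ceiling(n_samples * patches_per_image / batch_size)` iterations. At the
#' reference scale (400 training volumes, 16 patches each, batches of 8) this
#' is exactly 800.
#'
#' @param n_samples Number of training volumes.
#' @param spec A [patch_spec()].
#' @return Integer iteration count.
#' @export
iterations_per_epoch <- function(n_samples, spec) {
  as.integer(ceiling(n_samples * spec$patches_per_image / spec$batch_size))
}

# Epoch plan: pooled, shuffled (sample, origin, augmentation-seed) triples
# split into mini-batches. Patch positions are resampled every epoch.
epoch_plan <- function(samples, spec, seed, augment = TRUE, shuffle = TRUE) {
  entries <- list()
  for (i in seq_along(samples)) {
    pats <- spec$patches_per_image
    dims <- dim(samples[[i]]$image)[1:3]
    ps <- spec$patch_size
    if (any(dims < ps))
      stop("volume '", samples[[i]]$id, "' is smaller than the patch size; ",
           "pad the volume or skip it")
    nvalid <- dims - ps + 1L
    org <- with_seed(derive_seed(seed, i), {
      matrix(c(sample.int(nvalid[1], pats, replace = TRUE),
               sample.int(nvalid[2], pats, replace = TRUE),
               sample.int(nvalid[3], pats, replace = TRUE)),
             nrow = 3L, byrow = TRUE)
    })
    for (p in seq_len(pats)) {
      entries[[length(entries) + 1L]] <-
        list(sample = i, origin = org[, p],
             aug_seed = if (augment) derive_seed(seed, i * 10000L + p) else NA)
    }
  }
  if (shuffle) {
    perm <- with_seed(derive_seed(seed, 999983L), sample(length(entries)))
    entries <- entries[perm]
  }
  split(entries, ceiling(seq_along(entries) / spec$batch_size))
}

# Turn one plan chunk into dense arrays: images (p1,p2,p3,C,B), labels
# (p1,p2,p3,B) binary, plus provenance.
materialize_batch <- function(samples, chunk, spec) {
  ps <- spec$patch_size
  B <- length(chunk)
  C <- dim(samples[[chunk[[1]]$sample]]$image)[4]
  images <- array(0, dim = c(ps, C, B))
  labels <- array(0L, dim = c(ps, B))
  origins <- vector("list", B)
  for (b in seq_len(B)) {
    e <- chunk[[b]]
    pair <- extract_patch(samples[[e$sample]], e$origin, ps)
    if (!is.na(e$aug_seed)) pair <- augment_patch(pair, e$aug_seed)
    images[, , , , b] <- pair$image
    labels[, , , b] <- pair$label
    origins[[b]] <- list(id = pair$id, origin = pair$origin)
  }
  list(images = images, labels = labels, origins = origins)
}

#' Materialized patch batches for one epoch
#'
#' Pools `patches_per_image` random patches from every volume, shuffles them,
#' and returns mini-batches of aligned image/label arrays with one-batch
#' provenance (`origins`). Labels are emitted as binary volumes; the trainer
#' one-hot encodes with class order (background, tumor). The final partial
#' batch is emitted, not dropped. Deterministic given `seed`; positions are
#' resampled each epoch by passing a different seed.
#'
#' @param samples Non-empty list of [volume_sample()]s.
#' @param spec A [patch_spec()].
#' @param seed Integer seed.
#' @param augment Apply random reflection/rotation augmentation.
#' @return List of batches; each has `images` `(p, p, p, C, B)`, `labels`
#'   `(p, p, p, B)` and `origins`.
#' @export
epoch_batches <- function(samples, spec, seed = 0L, augment = FALSE) {
  if (length(samples) == 0L) stop("`samples` must be a non-empty list")
  plan <- epoch_plan(samples, spec, seed, augment = augment)
  lapply(plan, function(chunk) materialize_batch(samples, chunk, spec))
}
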