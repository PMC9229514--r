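# --- preprocessing: crop, normalize, split --------------------------------

#' Bundle an image volume with its label volume
#'
#' @param image 4D array `(H, W, D, C)`: one channel per MRI modality
#'   (FLAIR, T1w, T1gd, T2w in the reference data).
#' @param label 3D array `(H, W, D)` of binary voxel labels
#'   (0 background, 1 tumor), or `NULL` for unlabeled volumes.
#' @param id Volume identifier string.
#' @param spacing Optional voxel size (mm) triple.
#' @return Object of class `volume_sample`.
#' @export
volume_sample <- function(image, label = NULL, id = "volume", spacing = c(1, 1, 1)) {
  if (length(dim(image)) != 4L)
    stop("`image` must be a 4D (H, W, D, C) array")
  if (!is.null(label)) {
    if (!all(dim(label) == dim(image)[1:3]))
      stop("image and label spatial shapes differ")
    if (!all(label %in% c(0, 1))) stop("label must be binary")
  }
  structure(list(image = image, label = label, id = as.character(id),
                 spacing = spacing),
            class = "volume_sample")
}

#' @export
print.volume_sample <- function(x, ...) {
  cat("volume_sample '", x$id, "': ", paste(dim(x$image), collapse = " x "),
      if (is.null(x$label)) " (unlabeled)" else
        sprintf(" (%d tumor voxels)", sum(x$label)), "\n", sep = "")
  invisible(x)
}

#' Crop region containing the brain
#'
#' The brain-extracted reference volumes are exactly zero outside the skull,
#' so the informative region is the tight axis-aligned bounding box of voxels
#' that are nonzero in any modality. The box is then expanded symmetrically
#' (clipped at the volume bounds) until each spatial extent is a multiple
#' of 8, the downsampling factor of the network's contracting path.
#'
#' @param image 4D array `(H, W, D, C)`.
#' @return Object of class `crop_region`: list with integer vectors `start`
#'   and `end` (1-based, inclusive) per spatial axis.
#' @export
compute_crop <- function(image) {
  if (length(dim(image)) != 4L) stop("`image` must be a 4D array")
  nz <- apply(image != 0, 1:3, any)
  if (!any(nz)) stop("cannot crop an all-zero volume")
  start <- integer(3); end <- integer(3)
  for (ax in 1:3) {
    present <- apply(nz, ax, any)
    idx <- which(present)
    start[ax] <- idx[1]; end[ax] <- idx[length(idx)]
  }
  dims <- dim(image)[1:3]
  for (ax in 1:3) {
    extent <- end[ax] - start[ax] + 1L
    target <- 8L * ceiling(extent / 8L)
    target <- min(target, 8L * (dims[ax] %/% 8L))  # cannot exceed volume
    grow <- target - extent
    if (grow > 0L) {
      lo <- grow %/% 2L
      start[ax] <- start[ax] - lo
      end[ax] <- end[ax] + (grow - lo)
      if (start[ax] < 1L) { end[ax] <- end[ax] + (1L - start[ax]); start[ax] <- 1L }
      if (end[ax] > dims[ax]) { start[ax] <- start[ax] - (end[ax] - dims[ax]); end[ax] <- dims[ax] }
    }
  }
  structure(list(start = start, end = end), class = "crop_region")
}

#' Apply a crop region to a sample
#'
#' @param sample A [volume_sample()].
#' @param crop A [compute_crop()] result.
#' @return Cropped `volume_sample` (image and label cut identically).
#' @export
apply_crop <- function(sample, crop) {
  s <- crop$start; e <- crop$end
  img <- sample$image[s[1]:e[1], s[2]:e[2], s[3]:e[3], , drop = FALSE]
  lab <- if (!is.null(sample$label))
    sample$label[s[1]:e[1], s[2]:e[2], s[3]:e[3], drop = FALSE]
  volume_sample(img, lab, sample$id, sample$spacing)
}

#' Per-modality z-score normalization
#'
#' Each modality is independently normalized by subtracting its mean and
#' dividing by its standard deviation, both computed over the (cropped)
#' volume. A zero-variance modality maps to all zeros. Labels are untouched.
#'
#' @param image Cropped 4D array.
#' @return Normalized 4D array with per-channel mean 0 and sd 1, plus
#'   attribute `norm` recording the means/sds used.
#' @export
normalize_volume <- function(image) {
  if (length(dim(image)) != 4L) stop("`image` must be a 4D array")
  C <- dim(image)[4]
  mu <- numeric(C); sdv <- numeric(C)
  for (cc in seq_len(C)) {
    v <- image[, , , cc]
    mu[cc] <- mean(v)
    # population sd: the normalization statistic of the cropped region
    sdv[cc] <- sqrt(mean((v - mu[cc])^2))
    image[, , , cc] <- if (sdv[cc] > 0) (v - mu[cc]) / sdv[cc] else 0
  }
  attr(image, "norm") <- list(mean = mu, sd = sdv)
  image
}

#' Crop and normalize a sample
#'
#' Convenience composition of [compute_crop()], [apply_crop()] and
#' [normalize_volume()].
#' @param sample A [volume_sample()].
#' @return Preprocessed `volume_sample` with attribute `crop` on the list.
#' @export
preprocess_sample <- function(sample) {
  crop <- compute_crop(sample$image)
  out <- apply_crop(sample, crop)
  norm_img <- normalize_volume(out$image)
  out$image <- norm_img
  out$crop <- crop
  out$norm <- attr(norm_img, "norm")
  out
}

#' Partition volume ids into training / validation / test sets
#'
#' With exactly 484 labeled volumes the split is 400 training, 29 validation
#' and 55 test, matching the reference protocol. Other counts are split
#' proportionally (82.6% / 6.0% / 11.4%) with largest-remainder rounding. The
#' split is by whole volumes (never by patches, preventing leakage), random,
#' and fully determined by `seed`.
#'
#' @param ids Character or integer vector of unique volume ids.
#' @param seed Integer seed.
#' @return List with elements `train`, `validation`, `test`: disjoint vectors
#'   whose union is `ids`.
#' @export
#' @examples
#' sp <- split_dataset(sprintf("vol%03d", 1:484), seed = 0)
#' lengths(sp)  # 400, 29, 55
split_dataset <- function(ids, seed = 0L) {
  if (anyDuplicated(ids)) stop("duplicate volume ids in `ids`")
  n <- length(ids)
  if (n < 3L) stop("need at least 3 ids to split")
  if (n == 484L) {
    sizes <- c(train = 400L, validation = 29L, test = 55L)
  } else {
    prop <- c(train = 400, validation = 29, test = 55) / 484
    raw <- n * prop
    sizes <- floor(raw)
    rem <- n - sum(sizes)
    if (rem > 0) {
      order_frac <- order(raw - sizes, decreasing = TRUE)
      sizes[order_frac[seq_len(rem)]] <- sizes[order_frac[seq_len(rem)]] + 1
    }
    sizes <- as.integer(sizes)
    names(sizes) <- c("train", "validation", "test")
    # every partition must be non-empty
    while (any(sizes == 0L)) {
      z <- which.min(sizes); b <- which.max(sizes)
      sizes[z] <- sizes[z] + 1L; sizes[b] <- sizes[b] - 1L
    }
  }
  perm <- with_seed(seed, sample(n))
  shuffled <- ids[perm]
  list(train = shuffled[seq_len(sizes[1])],
       validation = shuffled[sizes[1] + seq_len(sizes[2])],
       test = shuffled[sizes[1] + sizes[2] + seq_len(sizes[3])])
}

#' Write a preprocessed sample to disk
#'
#' Stores the image and label as NIfTI files plus a JSON sidecar holding the
#' crop region, normalization statistics and id, enabling mapping back to the
#' original grid.
#'
#' @param sample Preprocessed [volume_sample()] (from [preprocess_sample()]).
#' @param dir Output directory (created if missing).
#' @param gzip Compress volumes (default TRUE).
#' @return Invisible list of written paths.
#' @export
write_sample <- function(sample, dir, gzip = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  img_path <- file.path(dir, paste0(sample$id, "_img", ext))
  lab_path <- file.path(dir, paste0(sample$id, "_lab", ext))
  meta_path <- file.path(dir, paste0(sample$id, ".json"))
  write_nifti(sample$image, img_path, sample$spacing, "float32")
  if (!is.null(sample$label))
    write_nifti(sample$label, lab_path, sample$spacing, "uint8")
  meta <- list(id = sample$id, spacing = sample$spacing,
               crop = if (!is.null(sample$crop))
                 list(start = sample$crop$start, end = sample$crop$end),
               norm = sample$norm)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(list(image = img_path, label = lab_path, meta = meta_path))
}

#' Read a sample written by [write_sample()]
#'
#' @param dir Directory containing the files.
#' @param id Volume id.
#' @return A [volume_sample()] (with `crop`/`norm` metadata if present).
#' @export
read_sample <- function(dir, id) {
  find1 <- function(sufs) {
    for (s in sufs) {
      p <- file.path(dir, paste0(id, s))
      if (file.exists(p)) return(p)
    }
    NULL
  }
  img_path <- find1(c("_img.nii.gz", "_img.nii"))
  if (is.null(img_path)) stop("no image volume for id '", id, "' in ", dir)
  img <- read_nifti(img_path)
  lab_path <- find1(c("_lab.nii.gz", "_lab.nii"))
  lab <- if (!is.null(lab_path)) read_nifti(lab_path)
  spacing <- attr(img, "spacing")
  attr(img, "spacing") <- NULL
  if (!is.null(lab)) attr(lab, "spacing") <- NULL
  out <- volume_sample(img, lab, id, spacing)
  meta_path <- file.path(dir, paste0(id, ".json"))
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$crop))
      out$crop <- structure(list(start = meta$crop$start, end = meta$crop$end),
                            class = "crop_region")
    out$norm <- meta$norm
  }
  out
}
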