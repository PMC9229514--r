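# Random patch extraction, augmentation, batching.

make_test_sample <- function(side = 24L, seed = 1) {
  withr::with_seed(seed, {
    img <- array(rnorm(side^3 * 4), dim = c(side, side, side, 4))
    lab <- array(rbinom(side^3, 1, 0.2), dim = rep(side, 3))
    volume_sample(img, lab, sprintf("s%d", seed))
  })
}

test_that("patch spec validates its fields", {
  expect_error(patch_spec(patch_size = 20), "multiples of 8")
  expect_error(patch_spec(patches_per_image = 0), "patches_per_image")
  expect_equal(patch_spec(32)$patch_size, rep(32L, 3))
})

test_that("a volume equal to the patch yields the single valid origin", {
  s <- make_test_sample(16L)
  pats <- sample_patches(s, patch_spec(16L, patches_per_image = 5L), seed = 3)
  expect_length(pats, 5L)
  for (p in pats) {
    expect_equal(p$origin, c(1L, 1L, 1L))
    expect_identical(p$image, s$image)
  }
})

test_that("origins stay in bounds and re-extraction reproduces patches", {
  s <- make_test_sample(24L)
  ps <- patch_spec(16L, patches_per_image = 12L)
  pats <- sample_patches(s, ps, seed = 5)
  for (p in pats) {
    expect_true(all(p$origin >= 1L & p$origin <= 9L))  # 24 - 16 + 1
    again <- unet3d:::extract_patch(s, p$origin, ps$patch_size)
    expect_identical(again$image, p$image)
    expect_identical(again$label, p$label)
  }
  expect_identical(sample_patches(s, ps, seed = 5), pats)   # deterministic
  expect_false(identical(sample_patches(s, ps, seed = 6)[[1]]$origin,
                         pats[[1]]$origin) &&
               identical(sample_patches(s, ps, seed = 6)[[2]]$origin,
                         pats[[2]]$origin))
  expect_error(sample_patches(make_test_sample(8L), ps, seed = 1),
               "pad the volume")
})

test_that("origin distribution is uniform over the valid grid", {
  # 40^3 volume, 8^3 patches: 33 valid positions per axis
  s <- withr::with_seed(2, volume_sample(
    array(rnorm(40^3 * 4), dim = c(40, 40, 40, 4)),
    array(0L, dim = c(40, 40, 40)), "u"))
  ps <- patch_spec(8L, patches_per_image = 2000L)
  pats <- sample_patches(s, ps, seed = 11)
  org <- t(vapply(pats, `[[`, integer(3), "origin"))
  for (ax in 1:3) {
    counts <- tabulate(org[, ax], nbins = 33)
    expect_gt(stats::chisq.test(counts)$p.value, 0.01)
  }
})

test_that("augmentation transforms form a group action on aligned pairs", {
  s <- make_test_sample(16L)
  pair <- unet3d:::extract_patch(s, c(1L, 1L, 1L), rep(16L, 3))
  # identity transform leaves the pair unchanged
  idt <- identity_transform()
  expect_identical(apply_transform(pair$image, idt), pair$image)
  for (sd in 1:6) {
    tr <- random_transform(sd)
    img2 <- apply_transform(pair$image, tr)
    lab2 <- apply_transform(pair$label, tr)
    # label count and per-channel intensity multisets preserved
    expect_equal(sum(lab2), sum(pair$label))
    for (cc in 1:4)
      expect_equal(sort(as.vector(img2[, , , cc])),
                   sort(as.vector(pair$image[, , , cc])))
    # inverse transform restores the original exactly
    expect_identical(apply_transform(img2, tr, inverse = TRUE), pair$image)
    expect_identical(apply_transform(lab2, tr, inverse = TRUE), pair$label)
  }
  # single-axis reflection applied twice is the identity
  refl <- structure(list(flip = c(TRUE, FALSE, FALSE), k = 0L),
                    class = "patch_transform")
  expect_identical(apply_transform(apply_transform(pair$image, refl), refl),
                   pair$image)
})

test_that("augmented pairs remain aligned (joint transform)", {
  s <- make_test_sample(16L, seed = 4)
  pair <- unet3d:::extract_patch(s, c(1L, 1L, 1L), rep(16L, 3))
  aug <- augment_patch(pair, seed = 9)
  # a voxel's image/label pairing is preserved: tag tumor voxels on channel 1
  tagged <- pair
  tagged$image[, , , 1] <- pair$label * 100
  aug_t <- augment_patch(tagged, seed = 9)
  expect_identical(aug_t$image[, , , 1], aug_t$label * 100)
  expect_true(all(aug$label %in% c(0, 1)))
})

test_that("epoch batching covers all samples with the stated arithmetic", {
  expect_equal(iterations_per_epoch(400L, patch_spec()), 800L)  # 400*16/8
  expect_equal(iterations_per_epoch(1L, patch_spec(16L, 16L, 8L)), 2L)
  s1 <- make_test_sample(16L, 1); s2 <- make_test_sample(16L, 2)
  ps <- patch_spec(16L, patches_per_image = 3L, batch_size = 4L)
  batches <- epoch_batches(list(s1, s2), ps, seed = 7)
  expect_length(batches, 2L)                  # 6 patches -> 4 + 2 (partial kept)
  expect_equal(dim(batches[[1]]$images)[5], 4L)
  expect_equal(dim(batches[[2]]$images)[5], 2L)
  expect_equal(dim(batches[[1]]$labels), c(16L, 16L, 16L, 4L))
  # identical batch sequence under a fixed seed
  expect_identical(epoch_batches(list(s1, s2), ps, seed = 7), batches)
  # provenance: re-extracting at the recorded origin reproduces the patch
  samples <- list(s1 = s1, s2 = s2)
  b <- batches[[1]]
  for (i in seq_len(4)) {
    src <- if (b$origins[[i]]$id == "s1") s1 else s2
    again <- unet3d:::extract_patch(src, b$origins[[i]]$origin, ps$patch_size)
    expect_equal(b$images[, , , , i], again$image, ignore_attr = TRUE)
  }
  expect_error(epoch_batches(list(), ps, seed = 1), "non-empty")
})
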