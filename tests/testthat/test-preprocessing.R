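# Cropping, normalization, dataset splitting, NIfTI round trips.

test_that("compute_crop finds the nonzero bounding box (cube example)", {
  img <- array(0, dim = c(64, 64, 64, 4))
  img[11:50, 11:50, 11:50, ] <- 1  # 40^3 cube, 40 divisible by 8
  cr <- compute_crop(img)
  expect_equal(cr$start, rep(11L, 3))
  expect_equal(cr$end, rep(50L, 3))
  # fully nonzero volume crops to itself
  full <- array(1, dim = c(16, 16, 16, 4))
  cr2 <- compute_crop(full)
  expect_equal(cr2$start, rep(1L, 3))
  expect_equal(cr2$end, rep(16L, 3))
  expect_error(compute_crop(array(0, dim = c(8, 8, 8, 4))), "all-zero")
})

test_that("crop equals a brute-force index-scan oracle, then expands to /8", {
  for (s in 1:3) {
    img <- withr::with_seed(s, {
      a <- array(0, dim = c(32, 32, 32, 4))
      pts <- matrix(sample(5:28, 30, replace = TRUE), ncol = 3)
      for (r in seq_len(nrow(pts))) a[pts[r, 1], pts[r, 2], pts[r, 3], sample(4, 1)] <- 1
      a
    })
    # oracle: explicit min/max scan over nonzero voxels
    lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
    for (x in 1:32) for (y in 1:32) for (z in 1:32)
      if (any(img[x, y, z, ] != 0)) {
        lo <- pmin(lo, c(x, y, z)); hi <- pmax(hi, c(x, y, z))
      }
    cr <- compute_crop(img)
    expect_true(all(cr$start <= lo) && all(cr$end >= hi))
    ext <- cr$end - cr$start + 1L
    expect_true(all(ext %% 8L == 0L))
    expect_true(all(ext - (hi - lo + 1) < 8 + 1e-9))  # minimal expansion
    expect_true(all(cr$start >= 1L) && all(cr$end <= 32L))
  }
})

test_that("cropping never discards tumor voxels visible in any modality", {
  cfgp <- tiny_phantom_config(seed = 3)
  s <- make_phantom(cfgp, 1)
  cr <- compute_crop(s$image)
  cropped <- apply_crop(s, cr)
  expect_equal(sum(cropped$label), sum(s$label))
})

test_that("normalization gives per-modality zero mean, unit sd", {
  img <- withr::with_seed(5, array(rnorm(16^3 * 4, mean = 10, sd = 3),
                                   dim = c(16, 16, 16, 4)))
  img[, , , 2] <- 7        # constant modality -> all zeros
  img[, , , 3] <- rep(c(0, 2), length.out = 16^3)  # {0,2} -> {-1, +1}
  out <- normalize_volume(img)
  for (cc in c(1, 4)) {
    expect_lt(abs(mean(out[, , , cc])), 1e-6)
    expect_lt(abs(sqrt(mean(out[, , , cc]^2)) - 1), 1e-6)
  }
  expect_true(all(out[, , , 2] == 0))
  expect_setequal(unique(as.vector(out[, , , 3])), c(-1, 1))
})

test_that("preprocess_sample composes crop and normalize coherently", {
  s <- make_phantom(tiny_phantom_config(seed = 8), 1)
  p <- preprocess_sample(s)
  expect_true(all(dim(p$image)[1:3] %% 8 == 0))
  expect_equal(dim(p$image)[1:3], dim(p$label))
  expect_lt(max(abs(apply(p$image, 4, mean))), 1e-6)
  expect_equal(sum(p$label), sum(s$label))
})

test_that("split_dataset reproduces the 400/29/55 protocol at n = 484", {
  ids <- sprintf("vol%03d", 1:484)
  sp <- split_dataset(ids, seed = 0)
  expect_equal(lengths(sp), c(train = 400L, validation = 29L, test = 55L))
  expect_setequal(unlist(sp), ids)                # exhaustive
  expect_equal(anyDuplicated(unlist(sp)), 0L)     # disjoint
  sp2 <- split_dataset(ids, seed = 0)
  expect_identical(sp, sp2)                       # deterministic
  sp3 <- split_dataset(ids, seed = 1)
  expect_equal(lengths(sp3), lengths(sp))
  expect_false(identical(sp3$train, sp$train))    # different membership
  expect_error(split_dataset(c("a", "a", "b")), "duplicate")
})

test_that("other dataset sizes split proportionally and exhaustively", {
  for (n in c(12L, 55L, 100L)) {
    sp <- split_dataset(seq_len(n), seed = 2)
    expect_equal(sum(lengths(sp)), n)
    expect_true(all(lengths(sp) >= 1L))
    expect_setequal(unlist(sp), seq_len(n))
    # proportions near 400:29:55
    expect_equal(unname(lengths(sp)[1] / n), 400 / 484, tolerance = 0.1)
  }
})

test_that("NIfTI volumes round-trip, compressed and raw, both datatypes", {
  dir <- withr::local_tempdir()
  img <- withr::with_seed(9, array(rnorm(6 * 5 * 4 * 2), dim = c(6, 5, 4, 2)))
  lab <- withr::with_seed(9, array(rbinom(60, 1, .4), dim = c(5, 4, 3)))
  for (ext in c(".nii", ".nii.gz")) {
    p1 <- file.path(dir, paste0("img", ext))
    write_nifti(img, p1, spacing = c(1, 1.5, 2))
    back <- read_nifti(p1)
    expect_equal(dim(back), dim(img))
    expect_equal(attr(back, "spacing"), c(1, 1.5, 2), tolerance = 1e-6)
    attr(back, "spacing") <- NULL
    expect_equal(back, img, tolerance = 1e-6)  # float32 storage
    p2 <- file.path(dir, paste0("lab", ext))
    write_nifti(lab, p2, datatype = "uint8")
    back2 <- read_nifti(p2)
    attr(back2, "spacing") <- NULL
    expect_identical(back2, lab + 0)           # exact for uint8
  }
  expect_error(suppressWarnings(read_nifti(file.path(dir, "missing.nii"))))
})

test_that("written NIfTI is readable by an independent implementation", {
  # cross-check against Python nibabel (pre-installed in the test image)
  py <- Sys.which("python")
  if (py == "") succeed("python not on PATH; cross-check covered elsewhere")
  else {
    dir <- withr::local_tempdir()
    img <- withr::with_seed(10, array(rnorm(8 * 7 * 6), dim = c(8, 7, 6)))
    path <- file.path(dir, "x.nii.gz")
    write_nifti(img, path, spacing = c(1, 2, 3))
    out <- system2(py, c("-c", shQuote(paste0(
      "import nibabel, numpy; im = nibabel.load('", path, "'); ",
      "d = numpy.asanyarray(im.dataobj); ",
      "print(d.shape); print(round(float(d.sum()), 4)); ",
      "print([float(z) for z in im.header.get_zooms()])"))), stdout = TRUE)
    expect_equal(out[1], "(8, 7, 6)")
    expect_equal(as.numeric(out[2]), sum(img), tolerance = 1e-3)
    expect_equal(out[3], "[1.0, 2.0, 3.0]")
  }
})

test_that("preprocessed samples round-trip through the NIfTI cache", {
  dir <- withr::local_tempdir()
  s <- preprocess_sample(make_phantom(tiny_phantom_config(seed = 12), 2))
  write_sample(s, dir)
  back <- read_sample(dir, s$id)
  expect_equal(back$image, unname(s$image), tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(back$label, s$label + 0)
  expect_equal(back$crop$start, s$crop$start)
  expect_equal(unlist(back$norm), unlist(s$norm), tolerance = 1e-6)
})
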