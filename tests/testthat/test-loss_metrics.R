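# Generalized Dice loss, class weights and evaluation metrics.

test_that("class weights are inverse squared areas with absent-class cap", {
  T1 <- matrix(0, 104, 2)
  T1[1:100, 1] <- 1
  T1[101:104, 2] <- 1
  expect_equal(class_weights(T1), c(1 / 10000, 1 / 16))
  # equal areas -> equal weights
  T2 <- matrix(0, 10, 2); T2[1:5, 1] <- 1; T2[6:10, 2] <- 1
  expect_equal(class_weights(T2), rep(1 / 25, 2))
  # absent class -> capped at 1 (one voxel equivalent), no division by zero
  T3 <- matrix(0, 8, 2); T3[, 1] <- 1
  expect_equal(class_weights(T3), c(1 / 64, 1))
})

test_that("class weights on random patches match a loop oracle", {
  for (s in 1:3) {
    lab <- withr::with_seed(s, array(rbinom(6^3, 1, 0.3), dim = c(6, 6, 6)))
    T1 <- one_hot(lab)
    Tm <- matrix(T1, ncol = 2)
    oracle <- numeric(2)
    for (k in 1:2) {
      cnt <- 0
      for (m in seq_len(nrow(Tm))) cnt <- cnt + Tm[m, k]
      oracle[k] <- if (cnt > 0) 1 / cnt^2 else 1
    }
    expect_equal(class_weights(T1), oracle)
  }
})

test_that("generalized Dice loss hits its exact endpoints", {
  lab <- array(0L, dim = c(4, 4, 4)); lab[1:2, 1, 1] <- 1L
  T1 <- one_hot(lab)
  expect_equal(generalized_dice_loss(T1, T1), 0, tolerance = 1e-7)
  # disjoint crisp masks with both classes swapped: zero overlap in every class
  Y <- T1[, , , c(2, 1)]
  expect_equal(generalized_dice_loss(Y, T1), 1, tolerance = 1e-12)
})

test_that("soft predictions match the brute-force double-loop oracle", {
  for (s in 1:5) {
    dat <- withr::with_seed(s, {
      lab <- array(rbinom(4^3, 1, 0.4), dim = c(4, 4, 4))
      Y <- matrix(runif(4^3 * 2), ncol = 2)
      Y <- Y / rowSums(Y)
      list(lab = lab, Y = Y)
    })
    T1 <- matrix(one_hot(dat$lab), ncol = 2)
    expect_equal(generalized_dice_loss(dat$Y, T1), dice_loss_oracle(dat$Y, T1),
                 tolerance = 1e-10)
  }
})

test_that("loss is invariant under joint voxel permutation", {
  dat <- withr::with_seed(21, {
    lab <- rbinom(64, 1, 0.3)
    Y <- matrix(runif(128), ncol = 2); Y <- Y / rowSums(Y)
    list(lab = lab, Y = Y, perm = sample(64))
  })
  T1 <- cbind(1 - dat$lab, dat$lab)
  expect_equal(generalized_dice_loss(dat$Y, T1),
               generalized_dice_loss(dat$Y[dat$perm, ], T1[dat$perm, ]),
               tolerance = 1e-14)
})

test_that("moving a prediction toward its target never increases the loss", {
  dat <- withr::with_seed(22, {
    lab <- rbinom(27, 1, 0.4)
    Y <- matrix(runif(54), ncol = 2); Y <- Y / rowSums(Y)
    list(lab = lab, Y = Y)
  })
  T1 <- cbind(1 - dat$lab, dat$lab)
  L0 <- generalized_dice_loss(dat$Y, T1)
  for (m in c(1, 9, 20)) {
    Y2 <- dat$Y
    # move voxel m halfway toward its one-hot target
    Y2[m, ] <- Y2[m, ] + 0.5 * (T1[m, ] - Y2[m, ])
    expect_lte(generalized_dice_loss(Y2, T1), L0 + 1e-12)
  }
})

test_that("crisp equal-weight loss complements a set-based Dice oracle", {
  dat <- withr::with_seed(23, {
    truth <- array(rbinom(5^3, 1, 0.3), dim = c(5, 5, 5))
    pred <- array(rbinom(5^3, 1, 0.3), dim = c(5, 5, 5))
    list(truth = truth, pred = pred)
  })
  Y <- one_hot(dat$pred); T1 <- one_hot(dat$truth)
  L <- generalized_dice_loss(Y, T1, weights = c(1, 1), smooth = 0)
  # independent set-based multi-class soft Dice overlap
  inter <- sum(dat$pred & dat$truth) + sum(!dat$pred & !dat$truth)
  sizes <- length(dat$pred) + length(dat$truth)
  expect_equal(1 - L, 2 * inter / sizes, tolerance = 1e-12)
})

test_that("confusion counts are exact voxel counts", {
  truth <- array(0L, dim = c(4, 4, 4)); truth[1:5] <- 1L
  expect_identical(unclass(confusion_counts(truth, truth))[c("TP", "FP", "FN", "TN")],
                   list(TP = 5L, FP = 0L, FN = 0L, TN = 59L))
  allbg <- array(0L, dim = c(4, 4, 4))
  cc <- confusion_counts(allbg, truth)
  expect_equal(c(cc$FN, cc$TN), c(5L, 59L))
  # random pair against a per-voxel loop oracle
  dat <- withr::with_seed(31, list(p = array(rbinom(125, 1, .4), dim = c(5, 5, 5)),
                                   t = array(rbinom(125, 1, .4), dim = c(5, 5, 5))))
  cc <- confusion_counts(dat$p, dat$t)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(dat$p)) {
    if (dat$p[i] == 1 && dat$t[i] == 1) tp <- tp + 1
    else if (dat$p[i] == 1) fp <- fp + 1
    else if (dat$t[i] == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  expect_equal(c(cc$TP, cc$FP, cc$FN, cc$TN), c(tp, fp, fn, tn))
  expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, 125)
  expect_error(confusion_counts(dat$p * 2, dat$t), "binary")
})

test_that("DSC, SEN, SPEC follow their formulas and conventions", {
  cc <- structure(list(TP = 8, FP = 2, FN = 2, TN = 88), class = "confusion_counts")
  expect_equal(dsc(cc), 16 / 20)
  expect_equal(sen(cc), 8 / 10)
  expect_equal(spec(cc), 88 / 90)
  perfect <- structure(list(TP = 10, FP = 0, FN = 0, TN = 90),
                       class = "confusion_counts")
  expect_equal(c(dsc(perfect), sen(perfect), spec(perfect)), c(1, 1, 1))
  # no tumor in either mask: DSC defined as 1 (limit of vanishing masks)
  empty <- structure(list(TP = 0, FP = 0, FN = 0, TN = 100),
                     class = "confusion_counts")
  expect_equal(c(dsc(empty), sen(empty)), c(1, 1))
})

test_that("DSC complements the unweighted binary Dice loss on crisp masks", {
  dat <- withr::with_seed(32, list(p = array(rbinom(216, 1, .3), dim = c(6, 6, 6)),
                                   t = array(rbinom(216, 1, .3), dim = c(6, 6, 6))))
  cc <- confusion_counts(dat$p, dat$t)
  # tumor-channel-only soft Dice with unit weight, crisp inputs
  Yt <- as.vector(dat$p); Tt <- as.vector(dat$t)
  tumor_dice <- 2 * sum(Yt * Tt) / (sum(Yt^2) + sum(Tt^2))
  expect_equal(dsc(cc), tumor_dice, tolerance = 1e-12)
})
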