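# Architecture construction and the per-layer analysis table.

test_that("analyze_network propagates shapes and counts layers", {
  tab <- analyze_network(network_spec())
  expect_equal(nrow(tab), 44L)
  expect_equal(tab$activations[tab$name == "Input"], "64 x 64 x 64 x 4")
  expect_equal(tab$activations[tab$name == "softmax"], "64 x 64 x 64 x 2")
  # encoder stages halve spatial dims, decoder stages restore them
  expect_equal(tab$h[tab$name == "en1_maxpool"], 32L)
  expect_equal(tab$h[tab$name == "en3_maxpool"], 8L)
  expect_equal(tab$h[tab$name == "de4_transconv"], 16L)
  expect_equal(tab$h[tab$name == "de1_conv2"], 64L)
  # concat channel widths at default base: 768, 384, 192
  expect_equal(tab$c[tab$name == "concat3"], 768L)
  expect_equal(tab$c[tab$name == "concat2"], 384L)
  expect_equal(tab$c[tab$name == "concat1"], 192L)
  # encoder channel doublings 32 -> 64 -> 128 -> 256
  expect_equal(tab$c[tab$name == "en1_conv1"], 32L)
  expect_equal(tab$c[tab$name == "en1_conv2"], 64L)
  expect_equal(tab$c[tab$name == "en2_conv2"], 128L)
  expect_equal(tab$c[tab$name == "en3_conv2"], 256L)
})

test_that("closed-form learnable counts follow the layer-kind formulas", {
  for (base in c(2L, 8L)) {
    tab <- analyze_network(tiny_spec(base = base))
    conv <- tab[tab$kind == "conv3d" & tab$name != "convlast", ]
    expect_true(all(conv$learnable > 0))
    bn <- tab[tab$kind == "batchnorm", ]
    expect_equal(bn$learnable, 2L * bn$c)
    expect_equal(tab$learnable[tab$name == "convlast"],
                 1L * 2L * base * 2L + 2L)
    expect_true(all(tab$learnable[tab$kind %in%
      c("input", "relu", "maxpool3d", "concat", "softmax", "dice_output")] == 0L))
  }
})

test_that("instantiated parameter count equals the analysis-table sum", {
  # oracle equivalence between the declarative table and the concrete graph
  for (base in c(2L, 4L)) {
    spec <- tiny_spec(base = base)
    net <- build_network(spec, seed = 1)
    expect_identical(count_parameters(net), as.numeric(total_learnables(spec)))
  }
})

test_that("spec validation rejects bad input shapes", {
  expect_error(network_spec(c(50, 50, 50, 4)), "divisible by 8")
  expect_error(network_spec(c(64, 64, 64)), "H, W, D, C")
  expect_error(network_spec(c(64, 64, 64, 4), base_channels = 0), "base_channels")
})

test_that("weight initialization is seed-deterministic and fan-in scaled", {
  n1 <- build_network(tiny_spec(), seed = 5)
  n2 <- build_network(tiny_spec(), seed = 5)
  n3 <- build_network(tiny_spec(), seed = 6)
  expect_identical(n1$params, n2$params)
  expect_false(identical(n1$params$en1_conv1_W, n3$params$en1_conv1_W))
  # biases start at zero, batch-norm scales at one
  expect_true(all(n1$params$de1_conv1_b == 0))
  expect_true(all(n1$params$en2_bn1_scale == 1))
  # He scaling: sd ~ sqrt(2 / fan_in)
  W <- build_network(network_spec(base_channels = 32L), seed = 2)$params$en1_conv2_W
  expect_equal(sd(W), sqrt(2 / (27 * 32)), tolerance = 0.02)
})

test_that("forward produces per-voxel probability distributions", {
  spec <- tiny_spec()
  net <- build_network(spec, seed = 3)
  b <- tiny_batch(spec, B = 1L)
  p <- forward(net, b$images[, , , , 1])
  expect_equal(dim(p), c(16L, 16L, 16L, 2L))
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(max(abs(apply(p, 1:3, sum) - 1)), 1e-5)
})

test_that("forward is fully convolutional and validates inputs", {
  net <- build_network(tiny_spec(), seed = 3)
  for (side in c(16L, 24L)) {
    x <- array(0, dim = c(side, side, side, 4))
    p <- forward(net, x)
    expect_equal(dim(p), c(side, side, side, 2L))
    expect_true(all(is.finite(p)))  # all-zero input, fresh net: no NaN
  }
  expect_error(forward(net, array(0, dim = c(16, 16, 16, 3))), "channels")
  expect_error(forward(net, array(0, dim = c(12, 12, 12, 4))), "divisible by 8")
})

test_that("forward is bitwise deterministic for fixed seed and input", {
  spec <- tiny_spec()
  b <- tiny_batch(spec, B = 1L)
  p1 <- forward(build_network(spec, seed = 9), b$images)
  p2 <- forward(build_network(spec, seed = 9), b$images)
  expect_identical(p1, p2)
})

test_that("single and double precision forward agree closely", {
  spec <- tiny_spec()
  net <- build_network(spec, seed = 4)
  b <- tiny_batch(spec, B = 1L)
  pf <- forward(net, b$images, precision = "single")
  pd <- forward(net, b$images, precision = "double")
  expect_lt(max(abs(pf - pd)), 1e-4)
})

test_that("the C++ training loss equals the R reference loss formula", {
  spec <- tiny_spec(16L, 2L)
  net <- build_network(spec, seed = 8)
  b <- tiny_batch(spec, B = 3L, seed = 13)
  res <- unet3d:::unet_loss_and_gradients(net, b$images, b$labels,
                                          precision = "double")
  # train-mode forward (batch-normalization batch statistics), double precision
  probs <- unet3d:::cpp_unet_forward(net$params, net$bn_state,
                                     unet3d:::cpp_spec(spec),
                                     b$images, TRUE, TRUE)
  for (bi in 1:3) {
    T1 <- one_hot(b$labels[, , , bi])
    expect_equal(res$per_patch_loss[bi],
                 generalized_dice_loss(probs[, , , , bi], T1),
                 tolerance = 1e-9)
  }
})

test_that("backward gradients match central finite differences (double)", {
  spec <- network_spec(c(8, 8, 8, 4), base_channels = 2)
  net <- build_network(spec, seed = 1)
  b <- withr::with_seed(11, list(
    images = array(rnorm(8^3 * 4 * 2), dim = c(8, 8, 8, 4, 2)),
    labels = array(rbinom(8^3 * 2, 1, 0.3), dim = c(8, 8, 8, 2))))
  res <- unet3d:::unet_loss_and_gradients(net, b$images, b$labels,
                                          precision = "double")
  expect_true(is.finite(res$loss))
  expect_equal(res$loss, mean(res$per_patch_loss), tolerance = 1e-12)
  h <- 1e-6
  loss_at <- function(nm, i, delta) {
    np <- net
    np$params[[nm]][i] <- np$params[[nm]][i] + delta
    unet3d:::unet_loss_and_gradients(np, b$images, b$labels,
                                     precision = "double")$loss
  }
  check <- list(en1_conv1_W = c(5L, 100L), en1_bn1_scale = 1L,
                en1_bn1_offset = 2L, en2_conv2_W = 400L,
                de4_transconv_W = 10L, de3_conv1_W = 2000L,
                de1_conv2_b = 3L, convlast_W = 7L)
  for (nm in names(check)) {
    for (i in check[[nm]]) {
      fd <- (loss_at(nm, i, h) - loss_at(nm, i, -h)) / (2 * h)
      an <- res$grads[[nm]][i]
      expect_lt(abs(fd - an), 1e-7 + 1e-4 * abs(fd))
    }
  }
})
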