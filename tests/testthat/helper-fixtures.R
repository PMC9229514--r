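# Shared fixtures: all tiny objects are built in code at test time.

# Desk-size network spec: 16^3 patches, 2 base channels.
tiny_spec <- function(patch = 16L, base = 2L) {
  network_spec(c(patch, patch, patch, 4L), base_channels = base)
}

# A small random image/label batch for the given spec.
tiny_batch <- function(spec, B = 2L, seed = 7, tumor_frac = 0.2) {
  p <- spec$input_shape[1:3]
  withr::with_seed(seed, {
    list(images = array(rnorm(prod(p) * 4 * B), dim = c(p, 4L, B)),
         labels = array(rbinom(prod(p) * B, 1, tumor_frac), dim = c(p, B)))
  })
}

# A small phantom configuration used across tests.
tiny_phantom_config <- function(seed = 0L, n = 4L, shape = 40L) {
  phantom_config(volume_shape = rep(shape, 3L), n_volumes = n,
                 tumor_radius_range = c(4, 8), tumor_count_range = c(1L, 2L),
                 noise_sd = 0.3, seed = seed)
}

# Independent scalar-loop oracle for the generalized Dice loss (no vector
# arithmetic shared with the implementation).
dice_loss_oracle <- function(Y, T, smooth = 1e-8) {
  M <- nrow(Y); K <- ncol(Y)
  w <- numeric(K)
  for (k in seq_len(K)) {
    a <- 0
    for (m in seq_len(M)) a <- a + T[m, k]
    w[k] <- if (a > 0) 1 / a^2 else 1
  }
  num <- 0; den <- smooth
  for (k in seq_len(K)) {
    sk <- 0; qk <- 0
    for (m in seq_len(M)) {
      sk <- sk + Y[m, k] * T[m, k]
      qk <- qk + Y[m, k]^2 + T[m, k]^2
    }
    num <- num + 2 * w[k] * sk
    den <- den + w[k] * qk
  }
  1 - num / den
}

# Scalar-loop Adam reference: one parameter vector, plain loops.
adam_oracle_run <- function(w0, grad_fn, lr, steps, beta1 = 0.9,
                            beta2 = 0.999, eps = 1e-8) {
  w <- w0
  m <- numeric(length(w)); v <- numeric(length(w))
  path <- vector("list", steps)
  for (t in seq_len(steps)) {
    g <- grad_fn(w, t)
    for (i in seq_along(w)) {
      m[i] <- beta1 * m[i] + (1 - beta1) * g[i]
      v[i] <- beta2 * v[i] + (1 - beta2) * g[i]^2
      mhat <- m[i] / (1 - beta1^t)
      vhat <- v[i] / (1 - beta2^t)
      w[i] <- w[i] - lr * mhat / (sqrt(vhat) + eps)
    }
    path[[t]] <- w
  }
  list(w = w, path = path)
}
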