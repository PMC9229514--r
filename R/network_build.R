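# Parameter inventory: names, shapes and He-initialization fan-in for every
# trainable tensor, in a fixed order. Conv weights are stored as R arrays of
# dim (k, k, k, C_in, C_out); biases, offsets and scales as vectors.
unet_param_shapes <- function(spec) {
  ch <- unet_channel_plan(spec)
  out <- list()
  add <- function(name, dim, fan_in) out[[name]] <<- list(dim = dim, fan_in = fan_in)
  conv <- function(layer, k = 3L) {
    io <- ch[[layer]]
    add(paste0(layer, "_W"), c(k, k, k, io[1], io[2]), k^3 * io[1])
    add(paste0(layer, "_b"), io[2], NA)
  }
  bn <- function(layer, c) {
    add(paste0(layer, "_scale"), c, NA)
    add(paste0(layer, "_offset"), c, NA)
  }
  for (e in 1:3) {
    conv(paste0("en", e, "_conv1"))
    bn(paste0("en", e, "_bn1"), ch[[paste0("en", e, "_conv1")]][2])
    conv(paste0("en", e, "_conv2"))
  }
  for (d in c(4L, 3L, 2L, 1L)) {
    conv(paste0("de", d, "_conv1"))
    conv(paste0("de", d, "_conv2"))
    if (d > 1L) {
      io <- ch[[paste0("de", d, "_transconv")]]
      add(paste0("de", d, "_transconv_W"), c(2L, 2L, 2L, io[1], io[2]), 8L * io[1])
      add(paste0("de", d, "_transconv_b"), io[2], NA)
    }
  }
  conv("convlast", k = 1L)
  out
}

#' Instantiate a trainable 3D U-Net
#'
#' Allocates and initializes every trainable tensor of the architecture
#' described by `spec`. Weights use fan-in-scaled ("He") normal
#' initialization, `sd = sqrt(2 / (k^3 * C_in))`; biases and batch-norm
#' offsets start at 0, batch-norm scales at 1. Initialization is fully
#' determined by `seed`.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed controlling weight initialization.
#' @return An object of class `unet_network`: a list with elements `spec`,
#'   `params` (named list of arrays), `bn_state` (running means/variances used
#'   at inference), and `seed`.
#' @export
#' @examples
#' net <- build_network(network_spec(c(16, 16, 16, 4), base_channels = 2), seed = 1)
#' count_parameters(net)
build_network <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "unet_spec"))
  shapes <- unet_param_shapes(spec)
  params <- with_seed(derive_seed(seed, 1L), {
    lapply(shapes, function(s) {
      n <- prod(s$dim)
      if (is.na(s$fan_in)) {
        # bias / offset -> 0, scale -> 1
        array(0, dim = s$dim)
      } else {
        array(rnorm(n, sd = sqrt(2 / s$fan_in)), dim = s$dim)
      }
    })
  })
  for (nm in grep("_scale$", names(params), value = TRUE))
    params[[nm]][] <- 1
  bn_layers <- paste0("en", 1:3, "_bn1")
  ch <- unet_channel_plan(spec)
  bn_state <- list(
    mean = lapply(seq_along(bn_layers), function(i) {
      numeric(ch[[paste0("en", i, "_conv1")]][2])
    }),
    var = lapply(seq_along(bn_layers), function(i) {
      rep(1, ch[[paste0("en", i, "_conv1")]][2])
    })
  )
  names(bn_state$mean) <- names(bn_state$var) <- bn_layers
  structure(list(spec = spec, params = params, bn_state = bn_state,
                 seed = as.integer(seed)),
            class = "unet_network")
}

#' @export
print.unet_network <- function(x, ...) {
  cat("3D U-Net network (base", x$spec$base_channels, "channels,",
      format(count_parameters(x), big.mark = ","), "parameters)\n")
  invisible(x)
}

#' Count trainable scalars of an instantiated network
#'
#' Enumerates the network's trainable tensors and sums their element counts.
#' This is the concrete-graph side of the oracle equivalence with the
#' declarative [analyze_network()] table: the two totals must agree.
#'
#' @param network A [build_network()] result.
#' @return Numeric scalar (exact integer value).
#' @export
count_parameters <- function(network) {
  stopifnot(inherits(network, "unet_network"))
  sum(vapply(network$params, function(p) as.numeric(length(p)), numeric(1)))
}

# Internal spec list handed to the C++ core.
cpp_spec <- function(spec) {
  list(base = spec$base_channels,
       cin = spec$input_shape[4],
       K = spec$num_classes,
       leaky = spec$leaky_slope)
}

check_patch_dims <- function(spec, x) {
  d <- dim(x)
  if (length(d) == 4L) {
    x <- array(x, dim = c(d, 1L))
    d <- dim(x)
  }
  if (length(d) != 5L)
    stop("input patch must be a 4D (H, W, D, C) or 5D (H, W, D, C, B) array")
  if (d[4] != spec$input_shape[4])
    stop("patch has ", d[4], " channels; the network expects ", spec$input_shape[4])
  if (any(d[1:3] %% 8L != 0L))
    stop("patch spatial dimensions (", paste(d[1:3], collapse = ", "),
         ") must be divisible by 8")
  x
}

#' Forward pass: per-voxel class probabilities
#'
#' Runs a patch (or batch of patches) through the network. The output of the
#' final softmax is a per-voxel probability distribution over the classes:
#' values lie in `[0, 1]` and sum to 1 across the class dimension.
#'
#' @param network A [build_network()] result.
#' @param patch Array `(H, W, D, C)` or `(H, W, D, C, B)`; spatial dimensions
#'   divisible by 8 and `C` matching the spec.
#' @param precision `"single"` (default; the training precision) or
#'   `"double"` (used by numerical tests).
#' @return Array `(H, W, D, K)` (or `(H, W, D, K, B)` for batched input) of
#'   class probabilities.
#' @export
forward <- function(network, patch, precision = c("single", "double")) {
  stopifnot(inherits(network, "unet_network"))
  precision <- match.arg(precision)
  x <- check_patch_dims(network$spec, patch)
  out <- cpp_unet_forward(network$params, network$bn_state, cpp_spec(network$spec),
                          x, FALSE, precision == "double")
  if (length(dim(patch)) == 4L) {
    dm <- dim(out)
    out <- array(out, dim = dm[1:4])
  }
  out
}

# Loss + gradients for one mini-batch; used by the trainer. Returns the batch
# mean generalized Dice loss, per-parameter gradients, per-patch losses, and
# updated batch-norm running statistics.
unet_loss_and_gradients <- function(network, images, labels,
                                    bn_momentum = 0.1,
                                    precision = c("single", "double")) {
  precision <- match.arg(precision)
  x <- check_patch_dims(network$spec, images)
  if (length(dim(labels)) == 3L) labels <- array(labels, dim = c(dim(labels), 1L))
  stopifnot(all(dim(labels) == dim(x)[c(1:3, 5)]))
  cpp_unet_fwd_bwd(network$params, network$bn_state, cpp_spec(network$spec),
                   x, array(as.integer(labels), dim = dim(labels)),
                   bn_momentum, precision == "double")
}
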