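#' Describe a 3D U-Net architecture
#'
#' Declarative description of the three-encoder / four-decoder 3D U-Net used
#' for binary brain-tumor segmentation. The contracting path holds three
#' encoder modules (two 3x3x3 convolutions each, the first followed by batch
#' normalization, each module ending in 2x2x2 max pooling); the expanding path
#' holds four decoder modules (two 3x3x3 convolutions each, the first three
#' ending in a 2x2x2 stride-2 transposed convolution). Skip connections
#' concatenate the second ReLU output of each encoder with the equal-size
#' transposed-convolution output. A final 1x1x1 convolution maps features to
#' the two classes (background, tumor), followed by a voxel-wise softmax.
#'
#' All convolutions use stride 1 and 'same' zero padding, so the network is
#' fully convolutional: any input whose spatial dimensions are divisible by
#' 2^3 = 8 yields an output of identical spatial size.
#'
#' @param input_shape Integer vector `(H, W, D, C)`. Spatial dimensions must be
#'   divisible by 8; `C` is the number of imaging modalities (default 4:
#'   FLAIR, T1w, T1gd, T2w).
#' @param base_channels Feature maps produced by the first convolution
#'   (default 32, as in the reference architecture). Encoder channel widths
#'   double per stage: 32, 64, 128, 256 at default width.
#' @param num_classes Number of output classes (default 2, binary
#'   segmentation).
#' @param leaky_slope Negative-axis slope of the activation. The reference
#'   per-layer record uses plain ReLU; the default 0 reproduces it. A small
#'   positive value gives leaky ReLU.
#' @return An object of class `unet_spec`.
#' @seealso [analyze_network()], [build_network()]
#' @export
#' @examples
#' spec <- network_spec()
#' spec
#' nrow(analyze_network(spec))  # 44 layers
network_spec <- function(input_shape = c(64L, 64L, 64L, 4L),
                         base_channels = 32L,
                         num_classes = 2L,
                         leaky_slope = 0) {
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 4L || any(input_shape < 1L))
    stop("`input_shape` must be (H, W, D, C) with all components >= 1")
  if (any(input_shape[1:3] %% 8L != 0L))
    stop("spatial input dimensions (", paste(input_shape[1:3], collapse = ", "),
         ") must be divisible by 8 (three 2x halvings along the contracting path)")
  base_channels <- as.integer(base_channels)
  if (base_channels < 1L) stop("`base_channels` must be >= 1")
  num_classes <- as.integer(num_classes)
  if (num_classes < 2L) stop("`num_classes` must be >= 2")
  if (leaky_slope < 0 || leaky_slope >= 1) stop("`leaky_slope` must be in [0, 1)")
  structure(
    list(input_shape = input_shape,
         base_channels = base_channels,
         num_encoders = 3L,
         num_decoders = 4L,
         num_classes = num_classes,
         leaky_slope = as.numeric(leaky_slope)),
    class = "unet_spec")
}

#' @export
print.unet_spec <- function(x, ...) {
  cat("3D U-Net specification\n")
  cat("  input shape   :", paste(x$input_shape, collapse = " x "), "\n")
  cat("  base channels :", x$base_channels, "\n")
  cat("  encoders      :", x$num_encoders, " decoders:", x$num_decoders, "\n")
  cat("  classes       :", x$num_classes, "\n")
  tab <- analyze_network(x)
  cat("  layers        :", nrow(tab), " total learnables:",
      format(sum(tab$learnable), big.mark = ","), "\n")
  invisible(x)
}

# Channel widths of every convolutional block, derived from base_channels.
# Returned as a list of (in, out) pairs keyed by layer name.
unet_channel_plan <- function(spec) {
  c0 <- spec$base_channels
  cin <- spec$input_shape[4]
  K <- spec$num_classes
  list(
    en1_conv1 = c(cin, c0),        en1_conv2 = c(c0, 2 * c0),
    en2_conv1 = c(2 * c0, 2 * c0), en2_conv2 = c(2 * c0, 4 * c0),
    en3_conv1 = c(4 * c0, 4 * c0), en3_conv2 = c(4 * c0, 8 * c0),
    de4_conv1 = c(8 * c0, 8 * c0), de4_conv2 = c(8 * c0, 16 * c0),
    de4_transconv = c(16 * c0, 16 * c0),
    de3_conv1 = c(24 * c0, 8 * c0), de3_conv2 = c(8 * c0, 8 * c0),
    de3_transconv = c(8 * c0, 8 * c0),
    de2_conv1 = c(12 * c0, 4 * c0), de2_conv2 = c(4 * c0, 4 * c0),
    de2_transconv = c(4 * c0, 4 * c0),
    de1_conv1 = c(6 * c0, 2 * c0), de1_conv2 = c(2 * c0, 2 * c0),
    convlast = c(2 * c0, K))
}

#' Per-layer analysis of a 3D U-Net
#'
#' Propagates activation shapes layer by layer and computes the learnable
#' parameter count of every layer in closed form: a `k^3` convolution with
#' `C_in` input and `C_out` output channels has `k^3 * C_in * C_out + C_out`
#' learnables (weights plus bias), batch normalization has `2 * C` (offset and
#' scale), a 2x2x2 transposed convolution has `8 * C_in * C_out + C_out`, and
#' all other layers have none. The sum of the `learnable` column equals the
#' number of trainable scalars of the instantiated network
#' (see [count_parameters()]).
#'
#' @param spec A [network_spec()].
#' @return A `data.frame` with one row per layer (44 rows for the default
#'   architecture): `index`, `name`, `kind`, `type`, `h`, `w`, `d`, `c`
#'   (activation shape), `activations` (formatted string), `kernel`,
#'   `learnable`.
#' @export
analyze_network <- function(spec) {
  stopifnot(inherits(spec, "unet_spec"))
  ch <- unet_channel_plan(spec)
  s <- list(spec$input_shape[1:3])  # spatial size per resolution level
  for (i in 1:3) s[[i + 1]] <- s[[i]] %/% 2L

  rows <- list()
  add <- function(name, kind, type, sp, c, learnable = 0L, kernel = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, kind = kind, type = type,
      h = sp[1], w = sp[2], d = sp[3], c = c,
      activations = paste(c(sp, c), collapse = " x "),
      kernel = kernel, learnable = learnable,
      stringsAsFactors = FALSE)
  }
  conv_learn <- function(name, k = 3L) {
    io <- ch[[name]]
    k^3 * io[1] * io[2] + io[2]
  }

  add("Input", "input", "3-D Image Input", s[[1]], spec$input_shape[4])
  for (e in 1:3) {
    pre <- paste0("en", e)
    lv <- s[[e]]
    c1 <- ch[[paste0(pre, "_conv1")]][2]; c2 <- ch[[paste0(pre, "_conv2")]][2]
    add(paste0(pre, "_conv1"), "conv3d", "Convolution", lv, c1,
        conv_learn(paste0(pre, "_conv1")), "3x3x3")
    add(paste0(pre, "_bn1"), "batchnorm", "Batch Normalization", lv, c1, 2L * c1)
    add(paste0(pre, "_relu1"), "relu", "ReLU", lv, c1)
    add(paste0(pre, "_conv2"), "conv3d", "Convolution", lv, c2,
        conv_learn(paste0(pre, "_conv2")), "3x3x3")
    add(paste0(pre, "_relu2"), "relu", "ReLU", lv, c2)
    add(paste0(pre, "_maxpool"), "maxpool3d", "3-D Max Pooling", s[[e + 1]], c2, 0L, "2x2x2")
  }
  for (d in c(4L, 3L, 2L, 1L)) {
    pre <- paste0("de", d)
    lv <- s[[d]]
    c1 <- ch[[paste0(pre, "_conv1")]][2]; c2 <- ch[[paste0(pre, "_conv2")]][2]
    add(paste0(pre, "_conv1"), "conv3d", "Convolution", lv, c1,
        conv_learn(paste0(pre, "_conv1")), "3x3x3")
    add(paste0(pre, "_relu1"), "relu", "ReLU", lv, c1)
    add(paste0(pre, "_conv2"), "conv3d", "Convolution", lv, c2,
        conv_learn(paste0(pre, "_conv2")), "3x3x3")
    add(paste0(pre, "_relu2"), "relu", "ReLU", lv, c2)
    if (d > 1L) {
      tc <- ch[[paste0(pre, "_transconv")]]
      up <- s[[d - 1]]
      add(paste0(pre, "_transconv"), "transposed_conv3d", "Transposed Convolution 3D",
          up, tc[2], 8L * tc[1] * tc[2] + tc[2], "2x2x2")
      skip_c <- ch[[paste0("en", d - 1, "_conv2")]][2]
      add(paste0("concat", d - 1), "concat", "Concatenation", up, tc[2] + skip_c)
    }
  }
  add("convlast", "conv3d", "Convolution", s[[1]], spec$num_classes,
      conv_learn("convlast", k = 1L), "1x1x1")
  add("softmax", "softmax", "Softmax", s[[1]], spec$num_classes)
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(
    name = "Output", kind = "dice_output", type = "Classification Output",
    h = NA_integer_, w = NA_integer_, d = NA_integer_, c = NA_integer_,
    activations = "", kernel = "", learnable = 0L, stringsAsFactors = FALSE))
  out$index <- seq_len(nrow(out))
  out[, c("index", "name", "kind", "type", "h", "w", "d", "c",
          "activations", "kernel", "learnable")]
}

#' Total learnable parameters implied by the analysis table
#'
#' @param spec A [network_spec()].
#' @return Integer scalar: sum of the `learnable` column of
#'   [analyze_network()].
#' @export
total_learnables <- function(spec) sum(analyze_network(spec)$learnable)
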