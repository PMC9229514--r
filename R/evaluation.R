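# --- whole-volume inference and test-set evaluation -----------------------

#' Segment a whole volume by patch tiling
#'
#' The network operates on fixed-size patches, so a whole volume is
#' zero-padded (at the high end of each axis) to spatial multiples of the
#' tile size, cut into non-overlapping tiles, passed through the network,
#' argmax-labeled, stitched back together, and un-padded. With
#' 'same'-padding convolutions every tile's output covers the full tile, so
#' stitching is exact and deterministic.
#'
#' @param network A trained [build_network()] result.
#' @param sample A preprocessed (cropped + normalized) [volume_sample()].
#' @param tile_size Spatial tile edge (multiple of 8; default 64, the
#'   training patch size).
#' @return 3D integer array of predicted labels (0 background, 1 tumor) of
#'   the sample's spatial shape.
#' @export
segment_volume <- function(network, sample, tile_size = 64L) {
  img <- sample$image
  dims <- dim(img)
  if (length(dims) != 4L) stop("sample image must be 4D")
  if (tile_size %% 8L != 0L) stop("`tile_size` must be a multiple of 8")
  if (abs(mean(img)) > 0.1)
    warning("volume '", sample$id, "' does not look preprocessed ",
            "(mean intensity ", signif(mean(img), 3), " far from 0)")
  pad <- (tile_size - dims[1:3] %% tile_size) %% tile_size
  pdims <- dims[1:3] + pad
  padded <- array(0, dim = c(pdims, dims[4]))
  padded[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]), ] <- img
  out <- array(0L, dim = pdims)
  for (z0 in seq(1L, pdims[3], by = tile_size))
    for (y0 in seq(1L, pdims[2], by = tile_size))
      for (x0 in seq(1L, pdims[1], by = tile_size)) {
        ix <- x0:(x0 + tile_size - 1L)
        iy <- y0:(y0 + tile_size - 1L)
        iz <- z0:(z0 + tile_size - 1L)
        probs <- forward(network, padded[ix, iy, iz, , drop = FALSE])
        out[ix, iy, iz] <- (probs[, , , 2] >= probs[, , , 1]) * 1L
      }
  out[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]), drop = FALSE]
}

# Box-and-whisker summary (1.5 IQR rule: whiskers reach the most extreme
# points not considered outliers) of a numeric vector.
box_summary <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_lim <- q[1] - 1.5 * iqr
  hi_lim <- q[3] + 1.5 * iqr
  inliers <- x[x >= lo_lim & x <= hi_lim]
  list(mean = mean(x), median = q[2], q25 = q[1], q75 = q[3],
       whisker_low = min(inliers), whisker_high = max(inliers),
       outliers = sort(x[x < lo_lim | x > hi_lim]))
}

#' Evaluate a network on a test set
#'
#' Segments every test volume with [segment_volume()] and reports per-volume
#' confusion counts, DSC, sensitivity and specificity for the tumor class,
#' plus per-class (background / tumor) Dice and their mean — the summary is
#' emitted for both classes since either may be the one a published average
#' refers to. Distribution summaries use the box-plot convention: median,
#' quartiles, 1.5 IQR whiskers, outliers.
#'
#' @param network A trained network.
#' @param samples Non-empty list of preprocessed labeled test samples.
#' @param tile_size Tiling size for [segment_volume()].
#' @return Object of class `eval_report`: list with `rows` (data.frame:
#'   id, TP, FP, FN, TN, DSC, SEN, SPEC, dice_background, dice_tumor,
#'   mean_class_dice) and `summary` (per-class box summaries plus mean DSC).
#' @export
evaluate_testset <- function(network, samples, tile_size = 64L) {
  if (length(samples) == 0L) stop("empty test set")
  rows <- lapply(samples, function(s) {
    if (is.null(s$label)) stop("test sample '", s$id, "' has no label")
    pred <- segment_volume(network, s, tile_size)
    cc <- confusion_counts(pred, s$label)
    pc <- per_class_dice(pred, s$label)
    data.frame(id = s$id, TP = cc$TP, FP = cc$FP, FN = cc$FN, TN = cc$TN,
               DSC = dsc(cc), SEN = sen(cc), SPEC = spec(cc),
               dice_background = pc[["background"]],
               dice_tumor = pc[["tumor"]],
               mean_class_dice = mean(pc),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  structure(list(
    rows = rows,
    summary = list(mean_dsc = mean(rows$DSC),
                   tumor = box_summary(rows$dice_tumor),
                   background = box_summary(rows$dice_background))),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Test-set evaluation over", nrow(x$rows), "volumes\n")
  cat(sprintf("  mean tumor DSC : %.5f\n", x$summary$mean_dsc))
  for (cls in c("tumor", "background")) {
    s <- x$summary[[cls]]
    cat(sprintf("  %-10s median %.4f IQR [%.4f, %.4f] whiskers [%.4f, %.4f] outliers %d\n",
                cls, s$median, s$q25, s$q75, s$whisker_low, s$whisker_high,
                length(s$outliers)))
  }
  invisible(x)
}

#' Write the per-volume metric table as CSV
#'
#' @param report An [evaluate_testset()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  write.csv(report$rows, path, row.names = FALSE)
  invisible(path)
}

#' Box plot of per-class Dice scores
#'
#' Draws the per-class Dice distributions of an evaluation report in the
#' usual box-and-whisker style (median line, quartile box, 1.5 IQR
#' whiskers).
#'
#' @param report An [evaluate_testset()] result.
#' @param path Optional PNG path; when given the plot is written there.
#' @return Invisibly, the boxplot statistics from [graphics::boxplot()].
#' @export
plot_dice_distribution <- function(report, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 600, height = 480)
    on.exit(grDevices::dev.off())
  }
  b <- graphics::boxplot(
    list(background = report$rows$dice_background,
         tumor = report$rows$dice_tumor),
    ylab = "Dice similarity coefficient", col = "lightsteelblue",
    medcol = "red", range = 1.5)
  invisible(b)
}
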