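# --- generalized Dice loss and evaluation metrics -------------------------
#
# The training objective is a class-weighted soft Dice loss between a
# predicted per-class probability map Y and a one-hot ground truth T:
#
#   L = 1 - 2 * sum_k w_k sum_m Y_km T_km /
#           ( sum_k w_k sum_m (Y_km^2 + T_km^2) + s )
#
# with per-class weights w_k = 1 / (sum_m T_km)^2, the inverse squared area
# of the expected region. Inverse-area weighting reduces the influence of
# large regions (background) so small tumor regions drive the loss. The
# smoothing constant s = 1e-8 and the absent-class convention below keep the
# loss finite on patches that contain no tumor.

#' Flatten a per-class map to an M x K matrix
#'
#' Accepts either an `(..., K)` array whose last dimension indexes classes, or
#' an `M x K` matrix (returned unchanged). All spatial voxels are flattened.
#' @param x Per-class array or matrix.
#' @return `M x K` numeric matrix.
#' @keywords internal
flatten_classes <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (is.null(d) || length(d) < 2L)
    stop("expected an array with a trailing class dimension")
  matrix(x, ncol = d[length(d)])
}

#' One-hot encode a binary label volume
#'
#' @param labels Integer/logical array with values 0 (background) and
#'   1 (tumor).
#' @param num_classes Number of classes (default 2).
#' @return Array of dim `c(dim(labels), num_classes)` with class order
#'   (background, tumor).
#' @export
one_hot <- function(labels, num_classes = 2L) {
  v <- as.integer(labels)
  if (any(v < 0L | v >= num_classes))
    stop("labels must lie in 0 .. num_classes - 1")
  out <- array(0, dim = c(dim(labels) %||% length(labels), num_classes))
  m <- prod(dim(labels) %||% length(labels))
  flat <- matrix(out, ncol = num_classes)
  flat[cbind(seq_len(m), v + 1L)] <- 1
  array(flat, dim = dim(out))
}

#' Inverse-squared-area class weights
#'
#' Computes `w_k = 1 / (sum_m T_km)^2`, the inverse squared expected area of
#' class `k`. A class absent from `T` would give `1/0`; it receives the
#' substituted cap `w_k = 1` (one voxel equivalent, `1 / 1^2`), so patches
#' without tumor remain trainable and never produce NaN.
#'
#' @param T One-hot ground truth, `(..., K)` array or `M x K` matrix.
#' @return Numeric vector of `K` positive weights.
#' @export
#' @examples
#' T <- matrix(0, 104, 2); T[1:100, 1] <- 1; T[101:104, 2] <- 1
#' class_weights(T)  # 1/10000, 1/16
class_weights <- function(T) {
  Tm <- flatten_classes(T)
  area <- colSums(Tm)
  ifelse(area > 0, 1 / area^2, 1)
}

#' Class-weighted generalized Dice loss
#'
#' @param Y Predicted per-class probabilities in `[0, 1]`, same shape as `T`.
#' @param T One-hot ground truth.
#' @param weights Per-class weights; defaults to [class_weights()] of `T`.
#' @param smooth Denominator smoothing constant (default `1e-8`).
#' @return Scalar loss in `[0, 1]`: 0 for a perfect crisp prediction, 1 for
#'   completely disjoint crisp masks.
#' @export
generalized_dice_loss <- function(Y, T, weights = class_weights(T),
                                  smooth = 1e-8) {
  Ym <- flatten_classes(Y); Tm <- flatten_classes(T)
  if (!all(dim(Ym) == dim(Tm)))
    stop("Y and T must have identical shape")
  if (length(weights) != ncol(Tm))
    stop("need one weight per class")
  num <- 2 * sum(weights * colSums(Ym * Tm))
  den <- sum(weights * colSums(Ym^2 + Tm^2)) + smooth
  1 - num / den
}

#' Voxel-wise confusion counts for the tumor class
#'
#' @param pred Binary predicted mask (tumor = 1).
#' @param truth Binary ground-truth mask, same shape.
#' @return Object of class `confusion_counts`: list with `TP`, `FP`, `FN`,
#'   `TN` (their sum equals the voxel count).
#' @export
confusion_counts <- function(pred, truth) {
  p <- as.vector(pred); t <- as.vector(truth)
  if (length(p) != length(t)) stop("masks must have the same shape")
  if (!all(p %in% c(0, 1)) || !all(t %in% c(0, 1)))
    stop("masks must be binary (0 = background, 1 = tumor)")
  structure(list(TP = sum(p == 1 & t == 1), FP = sum(p == 1 & t == 0),
                 FN = sum(p == 0 & t == 1), TN = sum(p == 0 & t == 0)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d FP=%d FN=%d TN=%d\n",
              x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

# Degenerate-denominator convention: when a ratio metric's denominator is 0,
# return 1 if the corresponding target set is empty in both masks (nothing to
# find, nothing found), else 0. This is the limit of the Dice formula as both
# masks vanish, and the standard convention for empty-mask volumes.
safe_ratio <- function(num, den) if (den > 0) num / den else 1

#' Dice similarity coefficient
#'
#' `DSC = 2 TP / (2 TP + FP + FN)`. With no tumor in either mask the
#' denominator vanishes; the value is then 1 by convention.
#' @param counts A [confusion_counts()] object.
#' @return Scalar in `[0, 1]`.
#' @export
dsc <- function(counts) safe_ratio(2 * counts$TP, 2 * counts$TP + counts$FP + counts$FN)

#' Sensitivity (true positive rate)
#'
#' `SEN = TP / (TP + FN)`; 1 by convention when the truth has no tumor.
#' @inheritParams dsc
#' @return Scalar in `[0, 1]`.
#' @export
sen <- function(counts) safe_ratio(counts$TP, counts$TP + counts$FN)

#' Specificity (true negative rate)
#'
#' `SPEC = TN / (TN + FP)`; 1 by convention when the truth has no background.
#' @inheritParams dsc
#' @return Scalar in `[0, 1]`.
#' @export
spec <- function(counts) safe_ratio(counts$TN, counts$TN + counts$FP)

# Per-class crisp Dice overlap (background and tumor), from binary masks.
per_class_dice <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  c(background = safe_ratio(2 * cc$TN, 2 * cc$TN + cc$FN + cc$FP),
    tumor = dsc(cc))
}
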