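# Evaluation metrics: per-class IoU and Dice from pixel confusion counts, and
# the symmetric Hausdorff distance between mask boundaries (pure maximum, no
# percentile variant), reported per class and as the mean over the three
# vessels, mirroring the usual results-table layout.

#' Pixel confusion counts for one class
#'
#' One-vs-rest binarization of `class_id` in both masks, then pixelwise
#' counting.
#'
#' @param pred_mask,gt_mask equal-size integer label matrices.
#' @param class_id the foreground class (1 PA, 2 Ao, 3 SVC).
#' @return a `confusion_counts` list with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(pred_mask, gt_mask, class_id) {
  if (!identical(dim(pred_mask), dim(gt_mask)))
    stop_v3("mask sizes differ", "vessel3_shape_error")
  p <- pred_mask == class_id
  g <- gt_mask == class_id
  structure(list(TP = sum(p & g), FP = sum(p & !g),
                 FN = sum(!p & g), TN = sum(!p & !g)),
            class = "confusion_counts")
}

#' Intersection-over-union, percent
#'
#' `100 * TP / (TP + FN + FP)`. Undefined (NA) when the union is empty.
#'
#' @param counts a `confusion_counts` object.
#' @return percentage in \[0, 100\], or NA.
#' @export
iou <- function(counts) {
  u <- counts$TP + counts$FN + counts$FP
  if (u == 0) return(NA_real_)
  100 * counts$TP / u
}

#' Dice coefficient, percent
#'
#' `100 * 2*TP / (2*TP + FN + FP)`. Undefined (NA) when both masks are empty.
#'
#' @inheritParams iou
#' @return percentage in \[0, 100\], or NA.
#' @export
dice_score <- function(counts) {
  d <- 2 * counts$TP + counts$FN + counts$FP
  if (d == 0) return(NA_real_)
  100 * 2 * counts$TP / d
}

#' Boundary pixels of a binary mask
#'
#' Foreground pixels with at least one background 4-neighbor; pixels on the
#' image border count the outside as background.
#'
#' @param binary_mask logical or 0/1 matrix.
#' @return a k x 2 matrix of 0-based (x, y) = (column, row) coordinates, or
#'   NULL for an empty mask.
#' @export
extract_boundary <- function(binary_mask) {
  m <- binary_mask > 0
  if (!any(m)) return(NULL)
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  inner <- pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)] &
    pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)]
  b <- which(m & !inner, arr.ind = TRUE)
  cbind(x = b[, 2] - 1L, y = b[, 1] - 1L)
}

#' Symmetric Hausdorff distance between two point sets
#'
#' `max( max_a min_b d(a,b), max_b min_a d(b,a) )` with Euclidean `d`, in
#' pixels.
#'
#' @param A,B k x 2 coordinate matrices (as from [extract_boundary()]), or
#'   binary masks whose boundaries are extracted first.
#' @return distance in pixels, or NA when either set is empty.
#' @export
hausdorff <- function(A, B) {
  if (is.logical(A) || (is.matrix(A) && ncol(A) != 2)) A <- extract_boundary(A)
  if (is.logical(B) || (is.matrix(B) && ncol(B) != 2)) B <- extract_boundary(B)
  if (is.null(A) || is.null(B) || nrow(A) == 0 || nrow(B) == 0) return(NA_real_)
  .hausdorff_cpp(matrix(as.numeric(A), ncol = 2), matrix(as.numeric(B), ncol = 2))
}

# Per-image, per-class metric triple; NA where undefined.
metrics_one <- function(pred, gt, class_id) {
  cc <- confusion(pred, gt, class_id)
  hd <- if (any(pred == class_id) && any(gt == class_id))
    hausdorff(pred == class_id, gt == class_id) else NA_real_
  c(dice = dice_score(cc), iou = iou(cc), hd = hd)
}

#' Evaluate predicted masks against ground truth
#'
#' Computes per-image per-class Dice, IoU and Hausdorff distance, averages
#' each over images (macro average, NA entries excluded and counted), then
#' adds the mean over the three vessel classes.
#'
#' @param pred_masks,gt_masks aligned lists of equal-size label masks.
#' @return a `metrics_report` data frame with rows PA, Ao, SVC, Mean and
#'   columns Dice, IoU, HD (Dice/IoU percent, HD pixels). Attribute
#'   `n_undefined` counts skipped per-image entries per metric and class.
#' @export
evaluate_batch <- function(pred_masks, gt_masks) {
  if (is.matrix(pred_masks)) pred_masks <- list(pred_masks)
  if (is.matrix(gt_masks)) gt_masks <- list(gt_masks)
  n <- length(pred_masks)
  if (n == 0 || n != length(gt_masks))
    stop_v3("need equal-length, non-empty mask lists", "vessel3_input_error")
  vals <- array(NA_real_, c(n, 3, 3),
                dimnames = list(NULL, vessel_classes(), c("dice", "iou", "hd")))
  for (i in seq_len(n))
    for (k in 1:3) vals[i, k, ] <- metrics_one(pred_masks[[i]], gt_masks[[i]], k)
  per_class <- apply(vals, c(2, 3), mean, na.rm = TRUE)
  per_class[is.nan(per_class)] <- NA_real_
  n_undef <- apply(vals, c(2, 3), function(v) sum(is.na(v)))
  rep_df <- data.frame(structure = c(vessel_classes(), "Mean"),
                       Dice = c(per_class[, "dice"], mean(per_class[, "dice"])),
                       IoU = c(per_class[, "iou"], mean(per_class[, "iou"])),
                       HD = c(per_class[, "hd"], mean(per_class[, "hd"])),
                       row.names = NULL)
  structure(rep_df, class = c("metrics_report", "data.frame"),
            n_undefined = n_undef, n_images = n)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("segmentation metrics over %d image(s):\n", attr(x, "n_images")))
  df <- as.data.frame(x)
  df$Dice <- round(df$Dice, 2); df$IoU <- round(df$IoU, 2); df$HD <- round(df$HD, 2)
  print(df, row.names = FALSE)
  nu <- attr(x, "n_undefined")
  if (!is.null(nu) && any(nu > 0))
    cat(sprintf("(%d undefined per-image entries excluded from means)\n", sum(nu)))
  invisible(x)
}
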