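# Stage-1 ROI localization: pick the best detection per vessel class, merge
# the survivors into the minimum enclosing rectangle, pad by a margin, crop
# and resize for the stage-2 network, and map predicted masks back to the
# original frame. Coordinates are 0-based half-open [min, max) throughout;
# x indexes columns, y indexes rows. The detector itself is pluggable: any
# function(image) returning a box table works, and an oracle detector that
# jitters ground-truth boxes stands in for tests.

empty_boxes <- function() {
  data.frame(class_id = integer(), x_min = numeric(), y_min = numeric(),
             x_max = numeric(), y_max = numeric(), confidence = numeric())
}

check_boxes <- function(boxes) {
  need <- c("class_id", "x_min", "y_min", "x_max", "y_max", "confidence")
  if (!all(need %in% names(boxes)))
    stop_v3("box table must have columns %s", "vessel3_input_error",
            paste(need, collapse = ", "))
  if (nrow(boxes) && any(boxes$x_min >= boxes$x_max | boxes$y_min >= boxes$y_max))
    stop_v3("degenerate box (min >= max)", "vessel3_input_error")
  invisible(boxes)
}

#' Best detection per class
#'
#' Keeps, for each vessel class, the highest-confidence box; ties are broken
#' by larger area, then by first occurrence. Classes with no detection are
#' listed in attribute `missing_classes`.
#'
#' @param detections box data frame (columns `class_id, x_min, y_min, x_max,
#'   y_max, confidence`).
#' @return box data frame with at most one row per class, ordered by class.
#' @export
select_best_per_class <- function(detections) {
  check_boxes(detections)
  out <- empty_boxes()
  for (k in 1:3) {
    d <- detections[detections$class_id == k, , drop = FALSE]
    if (nrow(d) == 0) next
    area <- (d$x_max - d$x_min) * (d$y_max - d$y_min)
    ord <- order(-d$confidence, -area, seq_len(nrow(d)))
    out <- rbind(out, d[ord[1], , drop = FALSE])
  }
  rownames(out) <- NULL
  structure(out, missing_classes = setdiff(1:3, out$class_id))
}

#' Merge boxes into a padded ROI rectangle
#'
#' The minimum axis-aligned rectangle enclosing every box, expanded by
#' `margin` pixels on all sides and clamped to the image bounds.
#'
#' @param boxes non-empty box data frame.
#' @param margin expansion in pixels (default 5).
#' @param image_size c(H, W).
#' @return a `roi_rect` list (`x_min, y_min, x_max, y_max, source`).
#' @examples
#' b <- data.frame(class_id = 1:3, x_min = c(10, 30, 12), y_min = c(10, 15, 40),
#'                 x_max = c(20, 40, 18), y_max = c(20, 25, 50), confidence = 1)
#' merge_to_roi(b, margin = 5, image_size = c(256, 256))
#' @export
merge_to_roi <- function(boxes, margin = 5, image_size) {
  check_boxes(boxes)
  if (nrow(boxes) == 0)
    stop_v3("no detections: stage-1 found no vessels", "vessel3_no_detections")
  if (margin < 0) stop_v3("margin must be >= 0", "vessel3_input_error")
  H <- image_size[1]; W <- image_size[2]
  structure(list(x_min = max(0, min(boxes$x_min) - margin),
                 y_min = max(0, min(boxes$y_min) - margin),
                 x_max = min(W, max(boxes$x_max) + margin),
                 y_max = min(H, max(boxes$y_max) + margin),
                 source = "detector"),
            class = "roi_rect")
}

#' ROI from a coarse binary vessel mask
#'
#' The first-stage alternative to box detection: the tight bounding rectangle
#' of all foreground pixels, expanded by `margin` and clamped.
#'
#' @param binary_mask logical or 0/1 matrix (all vessels labeled 1).
#' @param margin expansion in pixels.
#' @return a `roi_rect` with `source = "binary_mask"`.
#' @export
roi_from_binary_mask <- function(binary_mask, margin = 5) {
  fg <- which(binary_mask > 0, arr.ind = TRUE)
  if (nrow(fg) == 0)
    stop_v3("no foreground in binary mask", "vessel3_no_detections")
  H <- nrow(binary_mask); W <- ncol(binary_mask)
  structure(list(x_min = max(0, min(fg[, 2]) - 1 - margin),
                 y_min = max(0, min(fg[, 1]) - 1 - margin),
                 x_max = min(W, max(fg[, 2]) + margin),
                 y_max = min(H, max(fg[, 1]) + margin),
                 source = "binary_mask"),
            class = "roi_rect")
}

roi_width <- function(roi) roi$x_max - roi$x_min
roi_height <- function(roi) roi$y_max - roi$y_min

#' Crop an ROI and resize it for the stage-2 network
#'
#' Bilinear resize of the crop to `out_size`; the returned transform records
#' everything needed to map stage-2 masks back to the original frame.
#'
#' @param image grayscale matrix.
#' @param roi a `roi_rect` within the image bounds.
#' @param out_size c(H, W) after resize (default 256x256).
#' @return list(image = resized crop, transform = `crop_transform`).
#' @export
crop_resize <- function(image, roi, out_size = c(256L, 256L)) {
  ch <- roi_height(roi); cw <- roi_width(roi)
  if (ch <= 1 || cw <= 1)
    stop_v3("degenerate ROI (%dx%d)", "vessel3_input_error", ch, cw)
  if (roi$x_min < 0 || roi$y_min < 0 || roi$x_max > ncol(image) || roi$y_max > nrow(image))
    stop_v3("ROI exceeds image bounds", "vessel3_input_error")
  crop <- image[(roi$y_min + 1):roi$y_max, (roi$x_min + 1):roi$x_max, drop = FALSE]
  x4 <- crop; dim(x4) <- c(ch, cw, 1L, 1L)
  res <- .resize_bilinear_fwd(x4, as.integer(out_size[1]), as.integer(out_size[2]))
  out <- matrix(res, out_size[1], out_size[2])
  tr <- structure(list(roi = roi, crop_size = c(ch, cw),
                       out_size = as.integer(out_size),
                       scale = c(out_size[1] / ch, out_size[2] / cw)),
                  class = "crop_transform")
  list(image = out, transform = tr)
}

#' Map a stage-2 mask back to the original image frame
#'
#' Nearest-neighbor resize of the ROI-space mask back to the crop size, then
#' pasted at the ROI position on a background canvas.
#'
#' @param mask_in_roi integer mask at `transform$out_size`.
#' @param transform the `crop_transform` from [crop_resize()].
#' @param original_size c(H, W) of the original image.
#' @return full-size integer mask.
#' @export
uncrop_mask <- function(mask_in_roi, transform, original_size) {
  if (!identical(dim(mask_in_roi), as.integer(transform$out_size)))
    stop_v3("mask size %s does not match transform out_size %s", "vessel3_shape_error",
            paste(dim(mask_in_roi), collapse = "x"),
            paste(transform$out_size, collapse = "x"))
  roi <- transform$roi
  back <- .resize_nearest(matrix(as.numeric(mask_in_roi), nrow(mask_in_roi)),
                          as.integer(transform$crop_size[1]),
                          as.integer(transform$crop_size[2]))
  full <- matrix(0L, original_size[1], original_size[2])
  full[(roi$y_min + 1):roi$y_max, (roi$x_min + 1):roi$x_max] <-
    as.integer(round(back))
  full
}

#' Oracle detector: jittered ground-truth boxes
#'
#' A test stand-in for a trained object detector. Each ground-truth box is
#' independently dropped with probability `drop_prob`; survivors have every
#' corner perturbed uniformly within ±`jitter_px` (clamped to the image, kept
#' non-degenerate) and a confidence drawn uniformly in \[0.5, 1\].
#'
#' @param gt_boxes ground-truth box data frame.
#' @param jitter_px maximum corner perturbation, pixels.
#' @param drop_prob per-box drop probability.
#' @param seed RNG seed.
#' @param image_size c(H, W) for clamping.
#' @return box data frame.
#' @export
oracle_detector <- function(gt_boxes, jitter_px = 0, drop_prob = 0, seed = 0L,
                            image_size = c(256L, 256L)) {
  check_boxes(gt_boxes)
  with_seed(seed, {
    out <- empty_boxes()
    H <- image_size[1]; W <- image_size[2]
    for (i in seq_len(nrow(gt_boxes))) {
      if (runif(1) < drop_prob) next
      b <- gt_boxes[i, , drop = FALSE]
      if (jitter_px > 0) {
        j <- round(runif(4, -jitter_px, jitter_px))
        b$x_min <- clamp(b$x_min + j[1], 0, W - 1)
        b$y_min <- clamp(b$y_min + j[2], 0, H - 1)
        b$x_max <- clamp(b$x_max + j[3], b$x_min + 1, W)
        b$y_max <- clamp(b$y_max + j[4], b$y_min + 1, H)
      }
      b$confidence <- runif(1, 0.5, 1)
      out <- rbind(out, b)
    }
    rownames(out) <- NULL
    out
  })
}

#' Build a detector function from the oracle
#'
#' Returns a `function(image)` closure suitable for [run_two_stage()]; the
#' ground truth is looked up per call via `gt_lookup(image)`.
#'
#' @param gt_lookup function mapping an image to its ground-truth boxes.
#' @param jitter_px,drop_prob,seed as in [oracle_detector()].
#' @return a detector function.
#' @export
make_oracle_detector <- function(gt_lookup, jitter_px = 0, drop_prob = 0, seed = 0L) {
  count <- 0L
  function(image) {
    count <<- count + 1L
    oracle_detector(gt_lookup(image), jitter_px, drop_prob,
                    seed = derive_seed(seed, count),
                    image_size = dim(image))
  }
}

#' @export
print.roi_rect <- function(x, ...) {
  cat(sprintf("<roi_rect> x:[%g,%g) y:[%g,%g) source=%s\n",
              x$x_min, x$x_max, x$y_min, x$y_max, x$source))
  invisible(x)
}
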