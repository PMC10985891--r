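# Compound training loss: equally weighted class-weighted cross-entropy and
# soft Dice, L = 0.5 * L_dice + 0.5 * L_ce. Predictions p(k,i) are per-channel
# sigmoid probabilities; ground truth g(k,i) is the one-hot encoding of the
# labeled mask (no background channel). Only positive pixels contribute to the
# cross-entropy term; the Dice term penalizes false positives.

# Split (..., M) tensors into an M-column matrix of per-channel pixel vectors.
loss_as_mat <- function(x) {
  d <- dim(x)
  if (is.null(d)) return(matrix(x, ncol = 1))
  M <- d[length(d)]
  matrix(x, ncol = M)
}

check_loss_shapes <- function(pred, gt) {
  dp <- dim(pred) %||% length(pred)
  dg <- dim(gt) %||% length(gt)
  if (!identical(dp, dg))
    stop_v3("prediction and ground truth shapes differ (%s vs %s)",
            "vessel3_shape_error", paste(dp, collapse = "x"), paste(dg, collapse = "x"))
}

#' One-hot encoding of a labeled mask
#'
#' @param mask integer matrix with labels in 0..n_classes.
#' @param n_classes number of foreground classes (channels).
#' @return array (H, W, n_classes) of 0/1 indicators; background has no channel.
#' @export
mask_to_onehot <- function(mask, n_classes = 3L) {
  d <- dim(mask)
  out <- array(0, c(d, n_classes))
  for (k in seq_len(n_classes)) out[, , k] <- as.numeric(mask == k)
  out
}

#' Inverse-frequency class weights over a training split
#'
#' For every foreground class k the weight is `W_k = N_total / N_k`, where
#' `N_k` counts class-k pixels over all supplied masks and `N_total` is the
#' total pixel count of the split. Rare classes (the SVC in 3VV images)
#' therefore get proportionally larger cross-entropy weight.
#'
#' @param masks a list of labeled masks (or a single mask matrix).
#' @param n_classes number of foreground classes.
#' @return a `class_weights` object: named weight vector plus the counts.
#' @examples
#' m <- matrix(0L, 10, 10); m[1:5, 1:5] <- 1L; m[6:9, 6:9] <- 2L; m[1, 10] <- 3L
#' compute_class_weights(m)$W
#' @export
compute_class_weights <- function(masks, n_classes = 3L) {
  if (is.matrix(masks)) masks <- list(masks)
  if (length(masks) < 1) stop_v3("need at least one mask", "vessel3_input_error")
  nk <- numeric(n_classes)
  ntot <- 0
  for (m in masks) {
    ntot <- ntot + length(m)
    for (k in seq_len(n_classes)) nk[k] <- nk[k] + sum(m == k)
  }
  absent <- which(nk == 0)
  if (length(absent))
    stop_v3("class weighting undefined: class %s absent from every mask",
            "vessel3_missing_class_error",
            paste(vessel_classes()[absent], collapse = ", "))
  W <- ntot / nk
  names(W) <- vessel_classes()[seq_len(n_classes)]
  structure(list(W = W, N_k = nk, N_total = ntot), class = "class_weights")
}

#' Class-weighted cross-entropy over positive pixels
#'
#' `-(1/(M*N)) * sum_k sum_i W_k * g(k,i) * log p(k,i)`, with probabilities
#' clamped to `[eps, 1]`. Only pixels with `g(k,i) = 1` contribute.
#'
#' @param pred probabilities, any array whose last dimension indexes the M
#'   channels (a matrix or vector is treated as one channel).
#' @param gt binary ground truth, same shape.
#' @param weights a `class_weights` object, a numeric vector of per-channel
#'   weights, or a scalar (recycled).
#' @param eps probability clamp.
#' @return scalar loss.
#' @examples
#' ce_loss(matrix(c(0.5, 0.9), 1), matrix(c(1, 0), 1), weights = 2)  # log(2)/2 * 2 / 2
#' @export
ce_loss <- function(pred, gt, weights = 1, eps = 1e-7) {
  check_loss_shapes(pred, gt)
  p <- loss_as_mat(pred)
  g <- loss_as_mat(gt)
  M <- ncol(p)
  N <- nrow(p)
  W <- if (inherits(weights, "class_weights")) weights$W else weights
  W <- rep_len(as.numeric(W), M)
  pc <- clamp(p, eps, 1)
  -sum(sweep(g * log(pc), 2, W, "*")) / (M * N)
}

#' Soft Dice loss
#'
#' Mean over channels of `1 - (2 * sum(g*p) + eps) / (sum(g) + sum(p) + eps)`.
#'
#' @inheritParams ce_loss
#' @param eps smoothing constant added to numerator and denominator.
#' @return scalar in \[0, 1\].
#' @export
dice_loss <- function(pred, gt, eps = 1e-6) {
  check_loss_shapes(pred, gt)
  p <- loss_as_mat(pred)
  g <- loss_as_mat(gt)
  num <- 2 * colSums(g * p) + eps
  den <- colSums(g) + colSums(p) + eps
  mean(1 - num / den)
}

#' Compound segmentation loss
#'
#' `L = 0.5 * L_dice + 0.5 * L_ce`.
#'
#' @inheritParams ce_loss
#' @param eps_prob probability clamp for the cross-entropy term.
#' @param eps_dice smoothing constant for the Dice term.
#' @return a `loss_value` list with fields `L`, `L_ce`, `L_dice`, `M`, `N`.
#' @export
total_loss <- function(pred, gt, weights = 1, eps_prob = 1e-7, eps_dice = 1e-6) {
  lce <- ce_loss(pred, gt, weights, eps = eps_prob)
  ldc <- dice_loss(pred, gt, eps = eps_dice)
  p <- loss_as_mat(pred)
  structure(list(L = 0.5 * ldc + 0.5 * lce, L_ce = lce, L_dice = ldc,
                 M = ncol(p), N = nrow(p)),
            class = "loss_value")
}

#' Gradient of the compound loss with respect to the predictions
#'
#' Analytic `dL/dp(k,i)` for [total_loss()]; used by the training loop (chained
#' through the output sigmoid) and verifiable against finite differences.
#'
#' @inheritParams total_loss
#' @return array with the shape of `pred`.
#' @export
total_loss_grad <- function(pred, gt, weights = 1, eps_prob = 1e-7, eps_dice = 1e-6) {
  check_loss_shapes(pred, gt)
  p <- loss_as_mat(pred)
  g <- loss_as_mat(gt)
  M <- ncol(p)
  N <- nrow(p)
  W <- if (inherits(weights, "class_weights")) weights$W else weights
  W <- rep_len(as.numeric(W), M)
  pc <- clamp(p, eps_prob, 1)
  gce <- -sweep(g, 2, W, "*") / (M * N * pc)
  gce[p < eps_prob] <- 0  # clamped region: CE is locally flat in p
  num <- 2 * colSums(g * p) + eps_dice
  den <- colSums(g) + colSums(p) + eps_dice
  gdc <- sweep(-2 * g, 2, den, "/") + matrix(rep(num / den^2, each = N), N, M)
  gdc <- gdc / M
  out <- 0.5 * gce + 0.5 * gdc
  if (!is.null(dim(pred))) dim(out) <- dim(pred)
  out
}

#' @export
print.loss_value <- function(x, ...) {
  cat(sprintf("loss: L=%.6f (ce=%.6f, dice=%.6f) over M=%d channels, N=%d pixels\n",
              x$L, x$L_ce, x$L_dice, x$M, x$N))
  invisible(x)
}

#' @export
print.class_weights <- function(x, ...) {
  cat("class weights W_k = N_total / N_k:\n")
  print(round(x$W, 3))
  invisible(x)
}
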