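# Independent brute-force references, written as literal double loops so they
# share nothing with the package's vectorized/C++ paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

hausdorff_ref <- function(A, B) {
  dmin <- function(P, Q) {
    out <- numeric(nrow(P))
    for (i in seq_len(nrow(P))) {
      best <- Inf
      for (j in seq_len(nrow(Q))) {
        d <- sqrt(sum((P[i, ] - Q[j, ])^2))
        if (d < best) best <- d
      }
      out[i] <- best
    }
    max(out)
  }
  max(dmin(A, B), dmin(B, A))
}

iou_ref <- function(pred, gt, k) {
  tp <- fp <- fn <- 0
  for (i in seq_along(pred)) {
    p <- pred[i] == k; g <- gt[i] == k
    if (p && g) tp <- tp + 1
    else if (p) fp <- fp + 1
    else if (g) fn <- fn + 1
  }
  if (tp + fp + fn == 0) NA_real_ else 100 * tp / (tp + fp + fn)
}

dice_ref_counts <- function(pred, gt, k) {
  tp <- fp <- fn <- 0
  for (i in seq_along(pred)) {
    p <- pred[i] == k; g <- gt[i] == k
    if (p && g) tp <- tp + 1
    else if (p) fp <- fp + 1
    else if (g) fn <- fn + 1
  }
  if (2 * tp + fp + fn == 0) NA_real_ else 100 * 2 * tp / (2 * tp + fp + fn)
}

ce_ref <- function(p, g, W, eps = 1e-7) {
  pm <- matrix(p, ncol = dim(p)[length(dim(p))] %||% 1)
  gm <- matrix(g, ncol = ncol(pm))
  W <- rep_len(W, ncol(pm))
  acc <- 0
  for (k in seq_len(ncol(pm)))
    for (i in seq_len(nrow(pm)))
      acc <- acc + W[k] * gm[i, k] * log(max(min(pm[i, k], 1), eps))
  -acc / (ncol(pm) * nrow(pm))
}

dice_loss_ref <- function(p, g, eps = 1e-6) {
  pm <- matrix(p, ncol = dim(p)[length(dim(p))] %||% 1)
  gm <- matrix(g, ncol = ncol(pm))
  tot <- 0
  for (k in seq_len(ncol(pm))) {
    num <- den <- 0
    for (i in seq_len(nrow(pm))) {
      num <- num + gm[i, k] * pm[i, k]
      den <- den + gm[i, k] + pm[i, k]
    }
    tot <- tot + 1 - (2 * num + eps) / (den + eps)
  }
  tot / ncol(pm)
}
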