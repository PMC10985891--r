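# Training pipeline for the stage-2 network, plus the two-stage inference
# orchestration and the AMFF-vs-ASPP ablation harness. The two stages are
# trained independently; stage-2 training crops are built from ground-truth
# boxes (teacher forcing), optionally jittered through the oracle detector.

#' Training configuration
#'
#' Defaults follow the study schedule: 35 epochs of Adam, learning rate 0.001
#' stepped down to 0.0001 for the final 10 epochs. The printed "decay rate of
#' 1e-8" is exposed as the optimizer's numerical-stability epsilon (see the
#' methods vignette for the reading of this ambiguous constant).
#'
#' @param epochs total training epochs.
#' @param lr_initial,lr_final learning rates before/within the final phase.
#' @param final_phase number of trailing epochs run at `lr_final`.
#' @param adam_eps Adam stability constant.
#' @param batch_size minibatch size.
#' @param seed master seed (weights, shuffling, augmentation).
#' @param augment logical: apply random flip/rotation/scaling per sample.
#' @param augment_settings see [augment_pair()].
#' @param loss_eps_prob,loss_eps_dice loss epsilons (see [total_loss()]).
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 35L, lr_initial = 1e-3, lr_final = 1e-4,
                         final_phase = 10L, adam_eps = 1e-8, batch_size = 8L,
                         seed = 0L, augment = TRUE,
                         augment_settings = list(p_flip = 0.5, max_rotate = 15,
                                                 scale_range = c(0.9, 1.1)),
                         loss_eps_prob = 1e-7, loss_eps_dice = 1e-6) {
  if (epochs < 1) stop_v3("epochs must be >= 1", "vessel3_config_error")
  if (lr_initial <= 0 || lr_final <= 0) stop_v3("learning rates must be > 0", "vessel3_config_error")
  structure(list(epochs = as.integer(epochs), lr_initial = lr_initial,
                 lr_final = lr_final, final_phase = as.integer(final_phase),
                 adam_eps = adam_eps, batch_size = as.integer(batch_size),
                 seed = as.integer(seed), augment = augment,
                 augment_settings = augment_settings,
                 loss_eps_prob = loss_eps_prob, loss_eps_dice = loss_eps_dice),
            class = "train_config")
}

#' Split sample ids into train/validation/test
#'
#' Shuffles by seed, then partitions by the ratios with largest-remainder
#' rounding (so 100 ids at 7:1:2 give exactly 70/10/20).
#'
#' @param sample_ids character or integer vector of ids.
#' @param ratios length-3 positive weights for train:val:test (default 7:1:2).
#' @param seed shuffle seed.
#' @return list(train, val, test) of disjoint, exhaustive id vectors.
#' @export
split_dataset <- function(sample_ids, ratios = c(7, 1, 2), seed = 0L) {
  n <- length(sample_ids)
  if (n < 10) stop_v3("need at least 10 samples to split", "vessel3_input_error")
  if (length(ratios) != 3 || any(ratios <= 0))
    stop_v3("ratios must be three positive numbers", "vessel3_config_error")
  frac <- ratios / sum(ratios)
  base <- floor(n * frac)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(-(n * frac - base), seq_along(frac))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  if (any(base == 0))
    stop_v3("too few samples for a non-empty split at these ratios", "vessel3_input_error")
  ids <- with_seed(seed, sample(sample_ids))
  list(train = ids[seq_len(base[1])],
       val = ids[base[1] + seq_len(base[2])],
       test = ids[base[1] + base[2] + seq_len(base[3])])
}

#' Jointly augment an image/mask pair
#'
#' One geometric transform — optional horizontal flip, rotation, isotropic
#' scaling about the centre — applied identically to both. The image is
#' resampled bilinearly, the mask nearest-neighbor, so no new labels can
#' appear. Drawn parameters are deterministic per seed; an identity draw
#' returns the pair untouched.
#'
#' @param image grayscale matrix.
#' @param mask integer label matrix, same size.
#' @param settings list with `p_flip`, `max_rotate` (degrees), `scale_range`.
#'   Set `force = list(flip=, angle=, scale=)` inside `settings` to bypass the
#'   random draw.
#' @param seed RNG seed.
#' @return list(image, mask).
#' @export
augment_pair <- function(image, mask,
                         settings = list(p_flip = 0.5, max_rotate = 15,
                                         scale_range = c(0.9, 1.1)),
                         seed = 0L) {
  if (!identical(dim(image), dim(mask)))
    stop_v3("image and mask sizes differ", "vessel3_shape_error")
  par <- if (!is.null(settings$force)) settings$force else with_seed(seed, {
    list(flip = runif(1) < (settings$p_flip %||% 0.5),
         angle = runif(1, -1, 1) * (settings$max_rotate %||% 15),
         scale = runif(1, settings$scale_range[1] %||% 1, settings$scale_range[2] %||% 1))
  })
  flip <- isTRUE(par$flip); angle <- par$angle %||% 0; scale <- par$scale %||% 1
  if (flip) {
    image <- image[, ncol(image):1, drop = FALSE]
    mask <- mask[, ncol(mask):1, drop = FALSE]
  }
  if (abs(angle) < 1e-12 && abs(scale - 1) < 1e-12)
    return(list(image = image, mask = mask))
  # inverse map: rotate by -angle and scale by 1/scale about the centre
  th <- angle * pi / 180
  m <- c(cos(th), -sin(th), sin(th), cos(th)) / scale  # (a,b,c,d) acting on (dy,dx)
  mv <- c(m, 0, 0)
  img2 <- .warp_affine(image, mv, TRUE, mean(image))
  msk2 <- .warp_affine(matrix(as.numeric(mask), nrow(mask)), mv, FALSE, 0)
  list(image = clamp(img2, 0, 1), mask = matrix(as.integer(round(msk2)), nrow(mask)))
}

#' Learning rate at an epoch
#'
#' Step schedule: `lr_initial` until the final phase, `lr_final` for the last
#' `final_phase` epochs. Epochs are 0-based.
#'
#' @param epoch 0-based epoch index.
#' @param config a [train_config()].
#' @return learning rate.
#' @export
lr_at_epoch <- function(epoch, config = train_config()) {
  if (epoch < 0 || epoch >= config$epochs)
    stop_v3("epoch %d outside [0, %d)", "vessel3_input_error", epoch, config$epochs)
  if (epoch < config$epochs - config$final_phase) config$lr_initial else config$lr_final
}

# --- Adam ---------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    pn <- layer_param_names(l)
    st <- lapply(pn, function(p) list(m = array(0, dim(l[[p]]) %||% length(l[[p]])),
                                      v = array(0, dim(l[[p]]) %||% length(l[[p]]))))
    names(st) <- pn
    st
  })
}

adam_step <- function(layers, state, lr, t, eps, beta1 = 0.9, beta2 = 0.999) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(layers)) {
    l <- layers[[nm]]
    pn <- layer_param_names(l)
    gn <- layer_grad_names(l)
    for (j in seq_along(pn)) {
      g <- l[[gn[j]]]
      st <- state[[nm]][[pn[j]]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      l[[pn[j]]] <- l[[pn[j]]] - lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      state[[nm]][[pn[j]]] <- st
    }
    layer_zero_grad(l)
  }
  state
}

# --- Stage-2 training ----------------------------------------------------

# Stack a list of (image, mask) pairs into network input and one-hot target.
stack_batch <- function(samples) {
  if (any(vapply(samples, function(s) is.null(s$image) || is.null(s$mask), logical(1))))
    stop_v3("sample without image/mask (check your indexing)", "vessel3_input_error")
  H <- nrow(samples[[1]]$image); W <- ncol(samples[[1]]$image)
  n <- length(samples)
  x <- array(0, c(H, W, 1L, n))
  g <- array(0, c(H, W, 3L, n))
  for (i in seq_len(n)) {
    x[, , 1, i] <- samples[[i]]$image
    g[, , , i] <- mask_to_onehot(samples[[i]]$mask)
  }
  list(x = x, g = g)
}

batch_val_dice <- function(model, samples, threshold = 0.5) {
  preds <- lapply(samples, function(s) predict(model, s$image, type = "mask",
                                               threshold = threshold))
  rep <- evaluate_batch(preds, lapply(samples, `[[`, "mask"))
  rep$Dice[rep$structure == "Mean"] / 100
}

#' Train the stage-2 segmentation network
#'
#' Minimizes the compound loss with Adam under the configured step schedule.
#' Class weights are computed once over the training masks. Logs train loss,
#' validation loss and validation mean Dice per epoch and keeps the weights
#' of the best-validation-Dice epoch. Fully deterministic per seed on CPU.
#'
#' @param train_samples,val_samples lists with `$image` (matrix, network
#'   input size) and `$mask` (integer labels 0-3).
#' @param config a [train_config()].
#' @param net_cfg a [net_config()]; choose `head = "amff"` or `"aspp"` here.
#' @param verbose print per-epoch progress.
#' @return a `stage2_fit`: `model`, `log` (data frame), `best_epoch`,
#'   `class_weights`.
#' @export
train_stage2 <- function(train_samples, val_samples = list(),
                         config = train_config(), net_cfg = net_config(),
                         verbose = FALSE) {
  model <- vessel_net(net_cfg, seed = config$seed)
  layers <- net_layers(model)
  cw <- compute_class_weights(lapply(train_samples, `[[`, "mask"))
  state <- adam_init(layers)
  n <- length(train_samples)
  log <- data.frame()
  best <- list(dice = -Inf, state = NULL, epoch = NA_integer_)
  t_step <- 0L
  for (epoch in seq_len(config$epochs) - 1L) {
    ord <- with_seed(derive_seed(config$seed, 7000L + epoch), sample(n))
    lr <- lr_at_epoch(epoch, config)
    ep_loss <- 0; nb <- 0
    for (b0 in seq(1, n, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1, n)]
      batch <- lapply(train_samples[idx], function(s) {
        if (config$augment) {
          a <- augment_pair(s$image, s$mask, config$augment_settings,
                            seed = derive_seed(config$seed, 100000L + t_step * 131L + s$aug_id %||% 0L))
          list(image = a$image, mask = a$mask)
        } else list(image = s$image, mask = s$mask)
      })
      bt <- stack_batch(batch)
      out <- net_forward_tape(model, bt$x, training = TRUE)
      p <- out$prob$value
      lv <- total_loss(p, bt$g, cw, config$loss_eps_prob, config$loss_eps_dice)
      if (!is.finite(lv$L))
        stop_v3("non-finite loss at epoch %d (batch starting %d)",
                "vessel3_nan_loss", epoch, b0)
      gp <- total_loss_grad(p, bt$g, cw, config$loss_eps_prob, config$loss_eps_dice)
      dim(gp) <- dim(p)
      # backprop from the probability node (sigmoid is on the tape)
      tape_backward(out$tape, out$prob, gp)
      t_step <- t_step + 1L
      state <- adam_step(layers, state, lr, t_step, config$adam_eps)
      ep_loss <- ep_loss + lv$L; nb <- nb + 1
    }
    val_loss <- NA_real_; val_dice <- NA_real_
    if (length(val_samples)) {
      vb <- stack_batch(val_samples)
      vout <- net_forward_tape(model, vb$x, training = FALSE)
      vl <- total_loss(vout$prob$value, vb$g, cw, config$loss_eps_prob, config$loss_eps_dice)
      val_loss <- vl$L
      val_dice <- batch_val_dice(model, val_samples)
      if (is.finite(val_dice) && val_dice > best$dice) {
        best <- list(dice = val_dice, state = net_state(model), epoch = epoch)
      }
    }
    log <- rbind(log, data.frame(epoch = epoch, lr = lr, train_loss = ep_loss / nb,
                                 val_loss = val_loss, val_dice = val_dice))
    if (verbose)
      cat(sprintf("epoch %2d lr %.4g train %.4f val %.4f dice %.3f\n",
                  epoch, lr, ep_loss / nb, val_loss, val_dice))
  }
  if (!is.null(best$state)) net_load_state(model, best$state)
  structure(list(model = model, log = log, best_epoch = best$epoch,
                 class_weights = cw, config = config),
            class = "stage2_fit")
}

#' @export
print.stage2_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat(sprintf("<stage2_fit> %d epochs, final train loss %.4f, best val dice %.3f (epoch %s)\n",
              nrow(x$log), last$train_loss,
              suppressWarnings(max(x$log$val_dice, na.rm = TRUE)),
              x$best_epoch))
  invisible(x)
}

#' Loss/Dice curves of a fit
#' @param x a `stage2_fit`.
#' @param ... unused.
#' @export
plot.stage2_fit <- function(x, ...) {
  graphics::matplot(x$log$epoch, cbind(x$log$train_loss, x$log$val_loss),
                    type = "l", lty = 1:2, col = c("black", "red"),
                    xlab = "epoch", ylab = "loss")
  graphics::legend("topright", c("train", "val"), lty = 1:2, col = c("black", "red"))
  invisible(x)
}

#' Two-stage inference on one image
#'
#' Detector boxes -> best per class -> merged padded ROI -> bilinear crop to
#' the network input size -> stage-2 forward -> thresholded labeling ->
#' mapped back to the original frame. If the detector returns nothing, the
#' whole image is used as the ROI (full-size fallback).
#'
#' @param image grayscale matrix in \[0,1\].
#' @param detector `function(image) -> box data frame`.
#' @param model a trained `vessel_net` (or `stage2_fit`).
#' @param margin ROI padding, pixels.
#' @param out_size network input size c(H, W); defaults to the image size
#'   rounded to a multiple of 8... the size the model was trained at should
#'   be passed for best results.
#' @param threshold per-channel probability threshold.
#' @return full-size integer mask (0-3).
#' @export
run_two_stage <- function(image, detector, model, margin = 5,
                          out_size = NULL, threshold = 0.5) {
  if (inherits(model, "stage2_fit")) model <- model$model
  if (is.null(out_size)) out_size <- dim(image)
  roi <- tryCatch({
    det <- detector(image)
    best <- select_best_per_class(det)
    merge_to_roi(best, margin = margin, image_size = dim(image))
  }, vessel3_no_detections = function(e) {
    structure(list(x_min = 0, y_min = 0, x_max = ncol(image), y_max = nrow(image),
                   source = "fallback_full_size"), class = "roi_rect")
  })
  cr <- crop_resize(image, roi, out_size = out_size)
  mask_roi <- predict(model, cr$image, type = "mask", threshold = threshold)
  uncrop_mask(mask_roi, cr$transform, dim(image))
}

#' Build stage-2 training crops from labeled samples
#'
#' Teacher-forced crop construction: each sample's ground-truth boxes
#' (optionally jittered through [oracle_detector()]) are merged into a padded
#' ROI, the image is cropped and bilinearly resized to the network input
#' size, and the mask follows the identical geometry with nearest-neighbor
#' resampling.
#'
#' @param samples list of samples with `$image`, `$mask`, `$boxes`.
#' @param margin ROI padding, pixels.
#' @param out_size crop output size c(H, W).
#' @param jitter_px box corner jitter (0 = exact ground truth).
#' @param seed seed for the jitter.
#' @return list of crop-space samples (`image`, `mask`, `transform`, `id`).
#' @export
make_crop_samples <- function(samples, margin = 5, out_size = c(64L, 64L),
                              jitter_px = 0, seed = 0L) {
  lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    boxes <- s$boxes
    if (jitter_px > 0)
      boxes <- oracle_detector(boxes, jitter_px = jitter_px, drop_prob = 0,
                               seed = derive_seed(seed, i), image_size = dim(s$image))
    roi <- merge_to_roi(boxes, margin = margin, image_size = dim(s$image))
    cr <- crop_resize(s$image, roi, out_size = out_size)
    # nearest-resize the mask through the same ROI geometry
    mroi <- s$mask[(roi$y_min + 1):roi$y_max, (roi$x_min + 1):roi$x_max, drop = FALSE]
    mk <- .resize_nearest(matrix(as.numeric(mroi), nrow(mroi)),
                          as.integer(out_size[1]), as.integer(out_size[2]))
    list(image = cr$image, mask = matrix(as.integer(mk), out_size[1], out_size[2]),
         transform = cr$transform, id = s$id %||% i, aug_id = i)
  })
}

#' AMFF vs ASPP ablation harness
#'
#' Trains an AMFF-head and an ASPP-head network on identical data, splits and
#' seeds, evaluates both on the same held-out samples, and repeats over
#' several seeds. The report carries per-seed side-by-side metrics and the
#' mean and spread of the per-class Dice deltas (AMFF minus ASPP); the sign
#' of the delta is an experimental outcome, not an assertion.
#'
#' @param train_samples,test_samples crop-space sample lists (see
#'   [train_stage2()]).
#' @param config a [train_config()]; its seed is replaced by each element of
#'   `seeds`.
#' @param net_cfg a [net_config()] (head field is overridden per arm).
#' @param seeds integer vector of seeds (>= 3 for a spread estimate).
#' @return an `ablation_report` list: `per_seed` (data frame of per-class
#'   Dice/IoU/HD for both heads), `delta_summary` (mean and sd of per-class
#'   Dice deltas), `test_ids`.
#' @export
ablation_run <- function(train_samples, test_samples, config = train_config(),
                         net_cfg = net_config(), seeds = c(1L, 2L, 3L)) {
  per_seed <- data.frame()
  test_ids <- vapply(test_samples, function(s) as.character(s$id %||% NA), character(1))
  gt <- lapply(test_samples, `[[`, "mask")
  for (sd in seeds) {
    cfg <- config; cfg$seed <- as.integer(sd)
    for (head in c("amff", "aspp")) {
      ncfg <- net_cfg; ncfg$head <- head
      fit <- train_stage2(train_samples, val_samples = test_samples,
                          config = cfg, net_cfg = ncfg)
      preds <- lapply(test_samples, function(s) predict(fit$model, s$image, type = "mask"))
      rep <- evaluate_batch(preds, gt)
      df <- as.data.frame(rep)
      df$head <- head; df$seed <- sd
      per_seed <- rbind(per_seed, df)
    }
  }
  deltas <- do.call(rbind, lapply(seeds, function(sd) {
    a <- per_seed[per_seed$seed == sd & per_seed$head == "amff", ]
    b <- per_seed[per_seed$seed == sd & per_seed$head == "aspp", ]
    data.frame(seed = sd, structure = a$structure, dice_delta = a$Dice - b$Dice)
  }))
  delta_summary <- do.call(rbind, lapply(split(deltas, deltas$structure), function(d) {
    data.frame(structure = d$structure[1], mean_dice_delta = mean(d$dice_delta),
               sd_dice_delta = stats::sd(d$dice_delta))
  }))
  rownames(delta_summary) <- NULL
  structure(list(per_seed = per_seed, delta_summary = delta_summary,
                 test_ids = test_ids, seeds = seeds),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat(sprintf("<ablation_report> %d seed(s), %d test image(s)\n",
              length(x$seeds), length(x$test_ids)))
  cat("per-class Dice delta (AMFF - ASPP):\n")
  print(transform(x$delta_summary,
                  mean_dice_delta = round(mean_dice_delta, 2),
                  sd_dice_delta = round(sd_dice_delta, 2)), row.names = FALSE)
  invisible(x)
}
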