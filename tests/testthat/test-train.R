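test_that("dataset splitting is exact, seeded and exhaustive", {
  sp <- split_dataset(1:100, c(7, 1, 2), seed = 3)
  expect_length(sp$train, 70); expect_length(sp$val, 10); expect_length(sp$test, 20)
  expect_identical(sp, split_dataset(1:100, c(7, 1, 2), seed = 3))
  expect_false(identical(sp, split_dataset(1:100, c(7, 1, 2), seed = 4)))

  withr::with_seed(1, {
    for (n in c(10, 13, 57, 101)) {
      s <- split_dataset(seq_len(n), seed = n)
      all_ids <- c(s$train, s$val, s$test)
      expect_setequal(all_ids, seq_len(n))
      expect_equal(length(all_ids), n)
      expect_equal(anyDuplicated(all_ids), 0)
    }
  })
  expect_error(split_dataset(1:5), class = "vessel3_input_error")
})

test_that("augmentation transforms image and mask jointly and safely", {
  ph <- generate_phantom(desk_spec(), seed = 2)

  flip_s <- list(force = list(flip = TRUE, angle = 0, scale = 1))
  once <- augment_pair(ph$image, ph$mask, flip_s)
  twice <- augment_pair(once$image, once$mask, flip_s)
  expect_identical(twice$image, ph$image)
  expect_identical(twice$mask, ph$mask)

  ident <- augment_pair(ph$image, ph$mask,
                        list(force = list(flip = FALSE, angle = 0, scale = 1)))
  expect_identical(ident$image, ph$image)
  expect_identical(ident$mask, ph$mask)

  # labels never leave {0..3}; geometry stays aligned (class pixels keep the
  # same intensity statistics as the source lumen)
  for (s in 1:200) {
    a <- augment_pair(ph$image, ph$mask, seed = s)
    expect_true(all(a$mask %in% 0:3))
    expect_identical(dim(a$image), dim(a$mask))
  }
  # alignment: augmenting the mask itself as an image keeps label regions
  a2 <- augment_pair(ph$mask / 3, ph$mask, seed = 77)
  inside <- a2$mask > 0
  expect_gt(stats::cor(as.vector(a2$image[inside]), as.vector(a2$mask[inside] / 3)), 0.9)
})

test_that("the learning-rate schedule steps down for the final phase", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(0, cfg), 0.001)
  expect_equal(lr_at_epoch(24, cfg), 0.001)
  expect_equal(lr_at_epoch(25, cfg), 0.0001)
  expect_equal(lr_at_epoch(34, cfg), 0.0001)
  expect_error(lr_at_epoch(35, cfg), class = "vessel3_input_error")
  expect_error(lr_at_epoch(-1, cfg), class = "vessel3_input_error")
})

test_that("stage-2 training is reproducible and logs the schedule", {
  ds <- make_dataset(desk_spec(), n = 6, seed = 5)
  crops <- make_crop_samples(ds, margin = 5, out_size = c(32, 32))
  tcfg <- train_config(epochs = 3, final_phase = 1, batch_size = 3, seed = 9,
                       augment = TRUE)
  ncfg <- tiny_net()
  f1 <- train_stage2(crops[1:4], crops[5:6], tcfg, ncfg)
  f2 <- train_stage2(crops[1:4], crops[5:6], tcfg, ncfg)
  expect_identical(f1$log$train_loss, f2$log$train_loss)
  expect_identical(net_state(f1$model), net_state(f2$model))
  expect_equal(f1$log$lr, c(0.001, 0.001, 0.0001))
  expect_equal(nrow(f1$log), 3)
  expect_true(all(is.finite(f1$log$train_loss)))
  expect_s3_class(f1$class_weights, "class_weights")
})

test_that("training surfaces a missing-class error from the loss module", {
  ds <- make_dataset(desk_spec(), n = 4, seed = 6)
  crops <- make_crop_samples(ds, out_size = c(32, 32))
  for (i in seq_along(crops)) crops[[i]]$mask[crops[[i]]$mask == 3L] <- 0L
  expect_error(train_stage2(crops, list(), train_config(epochs = 1), tiny_net()),
               class = "vessel3_missing_class_error")
})

test_that("two-stage inference falls back to full-size when detection fails", {
  ds <- make_dataset(desk_spec(), n = 1, seed = 8)
  s <- ds[[1]]
  net <- vessel_net(tiny_net(), seed = 2)

  drop_all <- function(image) vessel3:::empty_boxes()
  m_fallback <- run_two_stage(s$image, drop_all, net, margin = 5, out_size = c(64, 64))
  full_roi <- structure(list(x_min = 0, y_min = 0, x_max = 64, y_max = 64,
                             source = "detector"), class = "roi_rect")
  direct <- predict(net, crop_resize(s$image, full_roi, c(64, 64))$image, type = "mask")
  expect_identical(m_fallback, direct)
  expect_identical(dim(m_fallback), dim(s$image))

  det <- make_oracle_detector(function(img) s$boxes, jitter_px = 0, seed = 1)
  m2 <- run_two_stage(s$image, det, net, margin = 5, out_size = c(64, 64))
  expect_identical(dim(m2), dim(s$image))
})

test_that("the ablation harness trains both heads on identical data and reports deltas", {
  ds <- make_dataset(desk_spec(), n = 8, seed = 12)
  crops <- make_crop_samples(ds, out_size = c(32, 32))
  tcfg <- train_config(epochs = 2, final_phase = 1, batch_size = 4, augment = FALSE)
  rep <- ablation_run(crops[1:6], crops[7:8], tcfg, tiny_net(), seeds = c(1L, 2L))
  expect_s3_class(rep, "ablation_report")
  expect_setequal(unique(rep$per_seed$head), c("amff", "aspp"))
  # two heads x (3 classes + mean) per seed
  expect_equal(nrow(rep$per_seed), 2 * 4 * 2)
  expect_equal(nrow(rep$delta_summary), 4)
  expect_true(all(c("mean_dice_delta", "sd_dice_delta") %in% names(rep$delta_summary)))
  expect_length(rep$test_ids, 2)
})
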