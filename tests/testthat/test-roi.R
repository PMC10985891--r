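test_that("best-per-class selection maximizes confidence with deterministic ties", {
  b <- data.frame(class_id = c(1, 1), x_min = c(0, 5), y_min = c(0, 5),
                  x_max = c(10, 15), y_max = c(10, 15), confidence = c(0.9, 0.6))
  out <- select_best_per_class(b)
  expect_equal(nrow(out), 1)
  expect_equal(out$confidence, 0.9)

  expect_equal(nrow(select_best_per_class(b[0, ])), 0)
  expect_equal(attr(select_best_per_class(b), "missing_classes"), c(2, 3))

  # ties: larger area wins, then first occurrence
  t1 <- data.frame(class_id = 2, x_min = c(0, 0, 0), y_min = 0,
                   x_max = c(4, 8, 8), y_max = c(4, 8, 8), confidence = 0.7)
  t1$y_min <- c(0, 1, 2)
  sel <- select_best_per_class(t1)
  expect_equal(sel$y_min, 1)  # larger area, earliest of the equal pair

  # brute-force argmax oracle
  withr::with_seed(5, {
    for (rep in 1:20) {
      boxes <- random_boxes(7)
      sel <- select_best_per_class(boxes)
      for (k in unique(boxes$class_id)) {
        d <- boxes[boxes$class_id == k, ]
        best_conf <- max(d$confidence)
        expect_equal(sel$confidence[sel$class_id == k], best_conf)
      }
    }
  })
})

test_that("merge_to_roi reproduces the worked example and clamps at borders", {
  b <- data.frame(class_id = 1:3,
                  x_min = c(10, 30, 12), y_min = c(10, 15, 40),
                  x_max = c(20, 40, 18), y_max = c(20, 25, 50),
                  confidence = 1)
  roi <- merge_to_roi(b, margin = 5, image_size = c(256, 256))
  expect_equal(c(roi$x_min, roi$y_min, roi$x_max, roi$y_max), c(5, 5, 45, 55))

  one <- data.frame(class_id = 1, x_min = 0, y_min = 0, x_max = 10, y_max = 10,
                    confidence = 1)
  roi1 <- merge_to_roi(one, margin = 5, image_size = c(256, 256))
  expect_equal(c(roi1$x_min, roi1$y_min, roi1$x_max, roi1$y_max), c(0, 0, 15, 15))

  expect_error(merge_to_roi(one[0, ], margin = 5, image_size = c(256, 256)),
               class = "vessel3_no_detections")
})

test_that("merged ROI contains every box and is permutation-invariant", {
  withr::with_seed(11, {
    for (rep in 1:50) {
      boxes <- random_boxes(sample(1:6, 1))
      roi <- merge_to_roi(boxes, margin = 5, image_size = c(256, 256))
      expect_true(all(boxes$x_min >= roi$x_min & boxes$x_max <= roi$x_max))
      expect_true(all(boxes$y_min >= roi$y_min & boxes$y_max <= roi$y_max))
      perm <- boxes[sample(nrow(boxes)), ]
      expect_equal(merge_to_roi(perm, 5, c(256, 256)), roi)
      # removing the margin gives the tight rectangle
      tight <- merge_to_roi(boxes, 0, c(256, 256))
      expect_equal(tight$x_min, min(boxes$x_min))
      expect_equal(tight$y_max, max(boxes$y_max))
    }
  })
})

test_that("binary-mask ROI matches box-merging on the same foreground", {
  m <- matrix(0L, 256, 256)
  m[101, 101] <- 1L  # pixel (100,100) 0-based
  roi <- roi_from_binary_mask(m, margin = 5)
  expect_equal(c(roi$x_min, roi$y_min, roi$x_max, roi$y_max), c(95, 95, 106, 106))

  full <- matrix(1L, 64, 64)
  rf <- roi_from_binary_mask(full, margin = 5)
  expect_equal(c(rf$x_min, rf$y_min, rf$x_max, rf$y_max), c(0, 0, 64, 64))

  expect_error(roi_from_binary_mask(matrix(0L, 8, 8)), class = "vessel3_no_detections")

  # equivalence with merge_to_roi on the mask's single-class boxes
  for (s in 1:5) {
    ph <- generate_phantom(desk_spec(), seed = 200 + s)
    bin <- (ph$mask > 0) * 1L
    r1 <- roi_from_binary_mask(bin, margin = 5)
    r2 <- merge_to_roi(mask_to_instance_boxes(bin), margin = 5, image_size = dim(bin))
    expect_equal(r1[c("x_min", "y_min", "x_max", "y_max")],
                 r2[c("x_min", "y_min", "x_max", "y_max")])
  }
})

test_that("crop_resize is identity on a full-frame ROI and records scale", {
  img <- matrix(runif(64 * 64), 64, 64)
  roi <- structure(list(x_min = 0, y_min = 0, x_max = 64, y_max = 64,
                        source = "detector"), class = "roi_rect")
  cr <- crop_resize(img, roi, out_size = c(64, 64))
  expect_equal(cr$image, img, tolerance = 1e-12)
  expect_equal(cr$transform$scale, c(1, 1))

  roi2 <- structure(list(x_min = 0, y_min = 0, x_max = 32, y_max = 32,
                         source = "detector"), class = "roi_rect")
  cr2 <- crop_resize(img, roi2, out_size = c(64, 64))
  expect_equal(cr2$transform$scale, c(2, 2))

  bad <- structure(list(x_min = 10, y_min = 10, x_max = 11, y_max = 40,
                        source = "detector"), class = "roi_rect")
  expect_error(crop_resize(img, bad), class = "vessel3_input_error")
})

test_that("down-then-up resize round trip has bounded interpolation error", {
  withr::with_seed(3, {
    cb <- outer(1:64, 1:64, function(r, c) (r %/% 32 + c %/% 32) %% 2)
    x4 <- cb; dim(x4) <- c(64, 64, 1, 1)
    down <- vessel3:::.resize_bilinear_fwd(x4, 32L, 32L)
    up <- vessel3:::.resize_bilinear_fwd(down, 64L, 64L)
    expect_lt(mean(abs(up - x4)), 0.1)
  })
})

test_that("bilinear resize agrees with an independent implementation", {
  suppressPackageStartupMessages(requireNamespace("EBImage"))
  img <- outer(1:40, 1:40, function(r, c) 0.5 + 0.4 * sin(r / 6) * cos(c / 5))
  x4 <- img; dim(x4) <- c(40, 40, 1, 1)
  ours <- matrix(vessel3:::.resize_bilinear_fwd(x4, 20L, 20L), 20, 20)
  ref <- EBImage::imageData(EBImage::resize(EBImage::Image(img), w = 20, h = 20))
  expect_lt(mean(abs(ours - ref)), 0.05)
})

test_that("uncrop maps ROI masks back to the original frame", {
  # identity transform
  m <- matrix(sample(0:3, 64 * 64, replace = TRUE), 64, 64)
  roi <- structure(list(x_min = 0, y_min = 0, x_max = 64, y_max = 64,
                        source = "detector"), class = "roi_rect")
  tr <- crop_resize(matrix(0, 64, 64), roi, out_size = c(64, 64))$transform
  expect_identical(uncrop_mask(m, tr, c(64, 64)), matrix(as.integer(m), 64, 64))

  empty <- matrix(0L, 64, 64)
  expect_identical(uncrop_mask(empty, tr, c(64, 64)), empty)

  # integer 2x scale round trip keeps per-class Dice high
  ph <- generate_phantom(desk_spec(), seed = 5)
  roi2 <- merge_to_roi(ph$boxes, margin = 4, image_size = dim(ph$mask))
  # force even side lengths for an exact integer scale
  roi2$x_max <- roi2$x_min + 2 * ((roi2$x_max - roi2$x_min) %/% 2)
  roi2$y_max <- roi2$y_min + 2 * ((roi2$y_max - roi2$y_min) %/% 2)
  out_size <- 2 * c(roi2$y_max - roi2$y_min, roi2$x_max - roi2$x_min)
  crm <- ph$mask[(roi2$y_min + 1):roi2$y_max, (roi2$x_min + 1):roi2$x_max]
  up <- matrix(as.integer(vessel3:::.resize_nearest(
    matrix(as.numeric(crm), nrow(crm)), out_size[1], out_size[2])), out_size[1])
  tr2 <- structure(list(roi = roi2, crop_size = dim(crm), out_size = out_size,
                        scale = c(2, 2)), class = "crop_transform")
  back <- uncrop_mask(up, tr2, dim(ph$mask))
  rep <- evaluate_batch(list(back), list(ph$mask))
  expect_gte(min(rep$Dice[1:3]), 90)

  expect_error(uncrop_mask(matrix(0L, 10, 10), tr2, dim(ph$mask)),
               class = "vessel3_shape_error")
})

test_that("the oracle detector respects jitter and drop contracts", {
  gt <- data.frame(class_id = 1:3,
                   x_min = c(10, 30, 50), y_min = c(10, 30, 50),
                   x_max = c(20, 44, 56), y_max = c(22, 40, 55),
                   confidence = 1)
  same <- oracle_detector(gt, jitter_px = 0, drop_prob = 0, seed = 1)
  expect_equal(same[, 1:5], gt[, 1:5])
  expect_true(all(same$confidence >= 0.5 & same$confidence <= 1))

  expect_equal(nrow(oracle_detector(gt, 0, drop_prob = 1, seed = 1)), 0)

  for (s in 1:300) {
    jit <- oracle_detector(gt, jitter_px = 3, drop_prob = 0, seed = s)
    for (col in c("x_min", "y_min", "x_max", "y_max"))
      expect_true(all(abs(jit[[col]] - gt[[col]]) <= 3))
    expect_true(all(jit$x_min < jit$x_max & jit$y_min < jit$y_max))
  }
})
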