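test_that("phantom generation is deterministic and labels are well-formed", {
  spec <- desk_spec()
  a <- generate_phantom(spec, seed = 42)
  b <- generate_phantom(spec, seed = 42)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(a$boxes, b$boxes)
  d <- generate_phantom(spec, seed = 43)
  expect_false(identical(a$image, d$image))
  expect_identical(dim(a$image), dim(a$mask))
  expect_true(all(a$mask %in% 0:3))
  for (k in 1:3) expect_gt(sum(a$mask == k), 0)
})

test_that("the SVC analog is much smaller than the PA analog", {
  spec <- phantom_spec(pa_radius = c(14, 20), ao_radius = c(10, 14),
                       svc_radius = c(3, 5))
  for (s in 1:5) {
    ph <- generate_phantom(spec, seed = s)
    expect_lt(sum(ph$mask == 3) / sum(ph$mask == 1), 0.25)
  }
})

test_that("noise-free, clutter-free phantoms contain exactly the configured intensities", {
  spec <- desk_spec(clutter_count = 0L, speckle_shape = NULL)
  ph <- generate_phantom(spec, seed = 7)
  expect_setequal(unique(as.vector(ph$image)),
                  c(spec$background_intensity, spec$wall_intensity, spec$lumen_intensity))
})

test_that("expected vessel areas are ordered PA >= Ao > SVC", {
  spec <- desk_spec()
  areas <- sapply(1:100, function(s) {
    m <- generate_phantom(spec, seed = s)$mask
    c(sum(m == 1), sum(m == 2), sum(m == 3))
  })
  mu <- rowMeans(areas)
  expect_gte(mu[1], mu[2])
  expect_gt(mu[2], mu[3])
})

test_that("speckle is multiplicative, unit-mean and seed-sensitive", {
  z <- matrix(0, 32, 32)
  expect_identical(apply_speckle(z, shape = 4, seed = 1), z)
  cimg <- matrix(0.5, 256, 256)
  out <- apply_speckle(cimg, shape = 4, seed = 9)
  expect_lt(abs(mean(out) - 0.5), 0.02)
  expect_false(identical(apply_speckle(cimg, 4, seed = 1), apply_speckle(cimg, 4, seed = 2)))
  expect_true(all(out >= 0 & out <= 1))
  expect_error(apply_speckle(cimg, shape = 0), class = "vessel3_spec_error")
  expect_error(apply_speckle(cimg, shape = -2), class = "vessel3_spec_error")
})

test_that("instance boxes are exact tight bounding rectangles", {
  m <- matrix(0L, 10, 10)
  m[3:5, 4:7] <- 1L  # pixels rows 2..4, cols 3..6 in 0-based coords
  b <- mask_to_instance_boxes(m)
  expect_equal(b$y_min, 2); expect_equal(b$y_max, 5)
  expect_equal(b$x_min, 3); expect_equal(b$x_max, 7)
  expect_equal(b$confidence, 1.0)

  expect_equal(nrow(mask_to_instance_boxes(matrix(0L, 5, 5))), 0)
  expect_error(mask_to_instance_boxes(matrix(7L, 2, 2)), class = "vessel3_label_error")

  # tightness on random phantoms: every class pixel inside its box and every
  # box side touched by at least one pixel
  for (s in 1:5) {
    ph <- generate_phantom(desk_spec(), seed = 100 + s)
    bx <- ph$boxes
    for (i in seq_len(nrow(bx))) {
      k <- bx$class_id[i]
      w <- which(ph$mask == k, arr.ind = TRUE)
      x <- w[, 2] - 1; y <- w[, 1] - 1
      expect_true(all(x >= bx$x_min[i] & x < bx$x_max[i]))
      expect_true(all(y >= bx$y_min[i] & y < bx$y_max[i]))
      expect_true(any(x == bx$x_min[i]) && any(x == bx$x_max[i] - 1))
      expect_true(any(y == bx$y_min[i]) && any(y == bx$y_max[i] - 1))
    }
  }
})

test_that("datasets are reproducible on disk and class-imbalanced as designed", {
  spec <- desk_spec()
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  make_dataset(spec, n = 10, seed = 7, dir = d1)
  make_dataset(spec, n = 10, seed = 7, dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_length(grep("^images/", f1), 10)
  expect_length(grep("^masks/", f1), 10)
  sums1 <- tools::md5sum(file.path(d1, f1[f1 != "manifest.json"]))
  sums2 <- tools::md5sum(file.path(d2, f1[f1 != "manifest.json"]))
  expect_identical(unname(sums1), unname(sums2))

  ds <- make_dataset(spec, n = 200, seed = 11)
  cw <- compute_class_weights(lapply(ds, `[[`, "mask"))
  expect_gt(cw$W["SVC"], cw$W["PA"])
  expect_gt(cw$W["SVC"], cw$W["Ao"])
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("infeasible specifications fail loudly", {
  expect_error(phantom_spec(image_size = c(40, 40)), class = "vessel3_infeasible_spec")
  expect_error(phantom_spec(svc_radius = c(3, 10)), class = "vessel3_spec_error")
  expect_error(phantom_spec(lumen_intensity = 1.4), class = "vessel3_spec_error")
  # feasible radii but an arrangement that cannot fit: generation fails
  tight <- desk_spec(size = 64L)
  tight$gap_range <- c(30, 35)
  expect_error(generate_phantom(tight, seed = 1), class = "vessel3_infeasible_spec")
})
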