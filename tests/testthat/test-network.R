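test_that("encoder halves resolution three times and is zero-preserving", {
  net <- vessel_net(tiny_net(), seed = 1)
  f <- net_encode(net, matrix(runif(64 * 64), 64, 64))
  expect_equal(dim(f)[1:3], c(8, 8, 16))  # 64/8, channels = 8*base
  f2 <- net_encode(net, matrix(runif(128 * 128), 128, 128))
  expect_equal(dim(f2)[1:2], c(16, 16))
  expect_error(net_encode(net, matrix(0, 60, 60)), class = "vessel3_shape_error")

  # zero weights + zero input stay zero through conv/bn/relu stacks
  zstate <- net_state(net)
  for (nm in names(zstate))
    if (!grepl("running_var", nm)) zstate[[nm]][] <- 0
  for (nm in grep("running_var", names(zstate), value = TRUE)) zstate[[nm]][] <- 1
  znet <- vessel_net(tiny_net(), seed = 2)
  net_load_state(znet, zstate)
  expect_true(all(net_encode(znet, matrix(0, 64, 64)) == 0))
})

test_that("spatial attention is bounded, shape-preserving and zero-preserving", {
  withr::with_seed(2, {
    for (rep in 1:5) {
      f <- array(rnorm(8 * 8 * 16), c(8, 8, 16))
      out <- spatial_attention(f, seed = rep)
      expect_equal(dim(out), dim(f))
      expect_true(all(abs(out) <= abs(f) + 1e-12))
      amap <- attr(out, "attention_map")
      expect_true(all(amap > 0 & amap < 1))
    }
  })
  z <- array(0, c(4, 4, 8))
  expect_true(all(spatial_attention(z) == 0))
})

test_that("fusion head concatenation arithmetic follows branch_count x branch_channels", {
  net2 <- vessel_net(tiny_net(), seed = 3)  # 2 branches x 16 channels
  f <- array(runif(8 * 8 * 16), c(8, 8, 16))
  fused <- net_head(net2, f)
  expect_equal(dim(fused)[1:3], c(8, 8, 32))
  expect_error(net_head(net2, array(0, c(8, 8, 7))), class = "vessel3_shape_error")
  expect_error(net_config(base_channels = 2, branch_count = 2, dilations = c(1, 2, 3)),
               class = "vessel3_config_error")
  expect_error(net_config(dilations = c(6, 1, 12, 18)), class = "vessel3_config_error")
})

test_that("gradient footprint grows with dilation rate", {
  footprint <- function(dil) {
    layer <- vessel3:::with_seed(1, vessel3:::layer_conv(3, 3, 1, 1, dil = dil, pad = dil))
    layer$w[] <- 1
    tape <- vessel3:::new_tape()
    x <- vessel3:::op_input(tape, array(0.5, c(31, 31, 1, 1)))
    y <- vessel3:::op_conv(tape, x, layer)
    g <- array(0, dim(y$value)); g[16, 16, 1, 1] <- 1
    vessel3:::tape_backward(tape, y, g)
    nz <- which(x$grad[, , 1, 1] != 0, arr.ind = TRUE)
    max(diff(range(nz[, 1])), diff(range(nz[, 2]))) + 1  # spatial extent
  }
  f1 <- footprint(1); f4 <- footprint(4); f9 <- footprint(9)
  expect_gt(f4, f1)
  expect_gt(f9, f4)
})

test_that("decoder produces in-range probabilities and is constant on constant input", {
  net <- vessel_net(tiny_net(), seed = 4)
  fused <- array(0.7, c(8, 8, 32, 1))
  prob <- net_decode(net, fused)
  expect_equal(dim(prob)[1:3], c(64, 64, 3))
  expect_true(all(prob >= 0 & prob <= 1))
  # interior of the low-res map is constant before upsampling; check the
  # upsampled interior away from border effects
  interior <- prob[24:40, 24:40, 1, 1]
  expect_lt(diff(range(interior)), 1e-10)

  withr::with_seed(5, {
    p2 <- net_decode(net, array(rnorm(8 * 8 * 32), c(8, 8, 32)))
    expect_true(all(p2 >= 0 & p2 <= 1))
  })
  expect_error(net_decode(net, array(0, c(8, 8, 31))), class = "vessel3_shape_error")
})

test_that("full forward pass composes, is deterministic, and heads are drop-in", {
  net <- vessel_net(tiny_net(), seed = 6)
  img <- generate_phantom(desk_spec(), seed = 1)$image
  p1 <- predict(net, img)
  p2 <- predict(net, img)
  expect_equal(dim(p1)[1:3], c(64, 64, 3))
  expect_identical(as.vector(p1), as.vector(p2))
  expect_false(is.null(attr(p1, "logits")))

  aspp <- swap_head(net, "aspp", seed = 7)
  pa <- predict(aspp, img)
  expect_equal(dim(pa), dim(p1))
  # encoder and decoder parameters are shared objects; heads are namespaced
  expect_identical(net_state(net)[grep("^encoder", names(net_state(net)))],
                   net_state(aspp)[grep("^encoder", names(net_state(aspp)))])
  expect_true(all(grepl("^(encoder|head|decoder)\\.", names(net_state(net)))))
})

test_that("ASPP baseline has fewer parameters than AMFF at matched width", {
  amff <- vessel_net(tiny_net("amff"), seed = 1)
  aspp <- vessel_net(tiny_net("aspp"), seed = 1)
  expect_lt(count_params(aspp), count_params(amff))
  # the difference is exactly the attention convolutions
  n_att <- 2 * (7 * 7 * 2 * 1 + 1)
  expect_equal(count_params(amff) - count_params(aspp), n_att)
})

test_that("mask conversion assigns argmax above threshold with low-class ties", {
  prob <- array(0, c(2, 2, 3))
  prob[1, 1, ] <- c(0.9, 0.8, 0.1)   # PA wins
  prob[1, 2, ] <- c(0.6, 0.6, 0.2)   # tie -> lower class
  prob[2, 1, ] <- c(0.2, 0.3, 0.45)  # below threshold -> background
  prob[2, 2, ] <- c(0.1, 0.2, 0.95)  # SVC
  m <- prob_to_mask(prob, threshold = 0.5)
  expect_identical(m, matrix(as.integer(c(1, 0, 1, 3)), 2, 2))
})

test_that("checkpoints round-trip through disk", {
  net <- vessel_net(tiny_net(), seed = 8)
  img <- matrix(runif(64 * 64), 64, 64)
  p1 <- predict(net, img)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(net, f)
  net2 <- load_checkpoint(f)
  expect_identical(as.vector(predict(net2, img)), as.vector(p1))
  unlink(f)
})
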