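# Shared fixtures. Desk-scale phantoms are 64x64 with radii chosen so the
# three vessels and their walls fit the small frame while keeping the size
# ordering PA > Ao > SVC and the SVC much smaller than the great arteries.

desk_spec <- function(size = 64L, clutter_count = 3L, speckle_shape = 6) {
  phantom_spec(image_size = c(size, size),
               pa_radius = c(6, 8), ao_radius = c(4.2, 5.5), svc_radius = c(2, 2.8),
               wall_thickness = 1.5, gap_range = c(1.5, 4),
               clutter_count = clutter_count, speckle_shape = speckle_shape)
}

# Smallest network that still exercises every architectural element.
tiny_net <- function(head = "amff") {
  net_config(base_channels = 2L, branch_count = 2L, dilations = c(1L, 2L),
             decode_channels = 4L, head = head)
}

random_box <- function(W = 256, H = 256) {
  x0 <- sample(0:(W - 10), 1); y0 <- sample(0:(H - 10), 1)
  data.frame(class_id = sample(1:3, 1),
             x_min = x0, y_min = y0,
             x_max = x0 + sample(2:9, 1), y_max = y0 + sample(2:9, 1),
             confidence = round(runif(1), 3))
}

random_boxes <- function(n, W = 256, H = 256) {
  do.call(rbind, lapply(seq_len(n), function(i) random_box(W, H)))
}

random_mask <- function(H, W, p = 0.3, classes = 0:1) {
  matrix(sample(classes, H * W, replace = TRUE, prob = c(1 - p, rep(p / (length(classes) - 1), length(classes) - 1))),
         H, W)
}
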