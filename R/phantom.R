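# Synthetic 3VV-like ultrasound phantoms: three near-circular dark-lumen
# vessels with bright walls on a speckled mid-gray background, arranged
# roughly collinearly (PA, Ao, SVC left to right, as in the three-vessel
# view) with a large size disparity — the SVC analog is much smaller than the
# great arteries. Ground-truth labels: 0 background, 1 PA, 2 Ao, 3 SVC.

#' Phantom specification
#'
#' @param image_size c(H, W) in pixels.
#' @param pa_radius,ao_radius,svc_radius min/max lumen radius per vessel, in
#'   pixels; must satisfy PA >= Ao > SVC with the SVC range at most 40% of
#'   the PA range.
#' @param collinearity_tol maximum deviation (degrees) of the vessel-center
#'   line from horizontal.
#' @param lumen_intensity,wall_intensity,background_intensity grayscale means
#'   in \[0,1\].
#' @param wall_thickness bright wall ring thickness, pixels.
#' @param speckle_shape shape parameter of the multiplicative gamma speckle;
#'   `NULL` disables speckle.
#' @param clutter_count number of distractor arcs/ellipse outlines drawn in
#'   the background.
#' @param gap_range min/max clear spacing (pixels) between adjacent vessel
#'   walls along the arrangement line.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(image_size = c(256L, 256L),
                         pa_radius = c(14, 20), ao_radius = c(10, 14),
                         svc_radius = c(3, 6),
                         collinearity_tol = 15,
                         lumen_intensity = 0.08, wall_intensity = 0.85,
                         background_intensity = 0.45,
                         wall_thickness = 2.5,
                         speckle_shape = 4, clutter_count = 6L,
                         gap_range = c(3, 9)) {
  spec <- list(image_size = as.integer(image_size),
               radii = list(PA = as.numeric(pa_radius), Ao = as.numeric(ao_radius),
                            SVC = as.numeric(svc_radius)),
               collinearity_tol = collinearity_tol,
               lumen_intensity = lumen_intensity, wall_intensity = wall_intensity,
               background_intensity = background_intensity,
               wall_thickness = wall_thickness,
               speckle_shape = speckle_shape, clutter_count = as.integer(clutter_count),
               gap_range = as.numeric(gap_range))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  r <- spec$radii
  if (any(unlist(r) <= 0)) stop_v3("radii must be positive", "vessel3_spec_error")
  if (any(vapply(r, function(x) x[1] > x[2], logical(1))))
    stop_v3("radius ranges must be min <= max", "vessel3_spec_error")
  if (r$PA[2] < r$Ao[2] || r$Ao[1] < r$SVC[1] || r$Ao[2] <= r$SVC[2])
    stop_v3("radius ranges must be ordered PA >= Ao > SVC", "vessel3_spec_error")
  if (r$SVC[2] > 0.4 * r$PA[2])
    stop_v3("SVC radius range must be at most 40%% of the PA range", "vessel3_spec_error")
  ints <- c(spec$lumen_intensity, spec$wall_intensity, spec$background_intensity)
  if (any(ints < 0 | ints > 1)) stop_v3("intensities must lie in [0,1]", "vessel3_spec_error")
  if (!is.null(spec$speckle_shape) && spec$speckle_shape <= 0)
    stop_v3("speckle shape must be positive", "vessel3_spec_error")
  # largest vessel (with wall) must fit with a 2-pixel margin
  rmax <- max(unlist(r)) * 1.3 + spec$wall_thickness
  if (2 * rmax + 4 > min(spec$image_size))
    stop_v3("radii too large for the image (infeasible spec)", "vessel3_infeasible_spec")
  invisible(spec)
}

# Membership grid of a rotated filled ellipse. Binary (no anti-aliasing) so
# the noise-free phantom contains exactly the configured intensities.
ellipse_mask <- function(H, W, cy, cx, ry, rx, theta) {
  yy <- matrix(seq_len(H) - cy, H, W)
  xx <- matrix(rep(seq_len(W) - cx, each = H), H, W)
  u <- cos(theta) * xx + sin(theta) * yy
  v <- -sin(theta) * xx + cos(theta) * yy
  (u / rx)^2 + (v / ry)^2 <= 1
}

#' Multiplicative gamma speckle
#'
#' Multiplies the image by unit-mean gamma noise (shape `shape`, scale
#' `1/shape`) and clips to \[0,1\]; the standard desk surrogate for
#' ultrasound speckle.
#'
#' @param image matrix with values in \[0,1\].
#' @param shape positive gamma shape; larger values give milder speckle.
#' @param seed RNG seed.
#' @return speckled matrix, same size.
#' @export
apply_speckle <- function(image, shape, seed = 0L) {
  if (is.null(shape) || !is.finite(shape) || shape <= 0)
    stop_v3("speckle shape must be a positive number", "vessel3_spec_error")
  if (any(image < 0 | image > 1)) stop_v3("image values must lie in [0,1]", "vessel3_input_error")
  noise <- with_seed(seed, matrix(rgamma(length(image), shape = shape, scale = 1 / shape),
                                  nrow(image), ncol(image)))
  clamp(image * noise, 0, 1)
}

#' Tight bounding boxes of every class in a mask
#'
#' One box per present class: the exact axis-aligned bounding rectangle of
#' that class's pixels, in 0-based half-open (x = column, y = row)
#' coordinates, confidence 1.
#'
#' @param mask integer label matrix (labels 0-3).
#' @return data frame with columns `class_id, x_min, y_min, x_max, y_max,
#'   confidence`; zero rows if no foreground.
#' @export
mask_to_instance_boxes <- function(mask) {
  if (!all(mask %in% 0:3))
    stop_v3("mask contains labels outside 0..3", "vessel3_label_error")
  rows <- list()
  for (k in 1:3) {
    w <- which(mask == k, arr.ind = TRUE)
    if (nrow(w) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      class_id = k,
      x_min = min(w[, 2]) - 1L, y_min = min(w[, 1]) - 1L,
      x_max = max(w[, 2]), y_max = max(w[, 1]),
      confidence = 1.0)
  }
  if (!length(rows))
    return(data.frame(class_id = integer(), x_min = integer(), y_min = integer(),
                      x_max = integer(), y_max = integer(), confidence = numeric()))
  do.call(rbind, rows)
}

#' Generate one synthetic 3VV phantom
#'
#' Deterministic for a fixed (spec, seed). The three vessels are drawn as
#' filled ellipses (eccentricity at most 1.3) in left-to-right order PA, Ao,
#' SVC along a roughly horizontal line, each as a dark lumen inside a bright
#' wall ring; distractor clutter is drawn first and labeled background;
#' multiplicative speckle is applied last.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @return a `phantom_sample` list: `image` (matrix in \[0,1\]), `mask`
#'   (integer labels 0-3), `boxes` (tight per-class boxes), `seed_used`.
#' @examples
#' s <- generate_phantom(phantom_spec(image_size = c(64, 64),
#'   pa_radius = c(7, 9), ao_radius = c(5, 7), svc_radius = c(2, 3)), seed = 1)
#' table(s$mask)
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = 0L) {
  validate_phantom_spec(spec)
  with_seed(seed, {
    H <- spec$image_size[1]; W <- spec$image_size[2]
    img <- matrix(spec$background_intensity, H, W)
    mask <- matrix(0L, H, W)

    # clutter first: bright arcs / ellipse outlines, background label
    if (spec$clutter_count > 0) {
      for (j in seq_len(spec$clutter_count)) {
        cy <- runif(1, 0.1 * H, 0.9 * H); cx <- runif(1, 0.1 * W, 0.9 * W)
        r1 <- runif(1, 0.03, 0.12) * min(H, W)
        th <- runif(1, 0, pi)
        outer_m <- ellipse_mask(H, W, cy, cx, r1 + runif(1, 1, 2.5),
                                r1 * runif(1, 1, 1.6) + 2, th)
        inner_m <- ellipse_mask(H, W, cy, cx, r1, r1 * runif(1, 1, 1.6), th)
        ring <- outer_m & !inner_m
        if (runif(1) < 0.5) ring <- ring & ellipse_mask(H, W, cy, cx + r1, 1.6 * r1, 1.6 * r1, 0)
        img[ring] <- runif(1, 0.55, 0.95)
      }
    }

    placed <- FALSE
    for (attempt in 1:60) {
      rads <- c(runif(1, spec$radii$PA[1], spec$radii$PA[2]),
                runif(1, spec$radii$Ao[1], spec$radii$Ao[2]),
                runif(1, spec$radii$SVC[1], spec$radii$SVC[2]))
      eccs <- runif(3, 1, 1.3)
      thetas <- runif(3, 0, pi)
      ang <- runif(1, -spec$collinearity_tol, spec$collinearity_tol) * pi / 180
      gap <- spec$wall_thickness * 2 + runif(2, spec$gap_range[1], spec$gap_range[2])
      # centre-to-centre spacing along the line
      sp12 <- rads[1] * eccs[1] + rads[2] * eccs[2] + gap[1]
      sp23 <- rads[2] * eccs[2] + rads[3] * eccs[3] + gap[2]
      mid <- c(H / 2 + runif(1, -0.08 * H, 0.08 * H),
               W / 2 + runif(1, -0.08 * W, 0.08 * W))
      dirv <- c(sin(ang), cos(ang))  # (dy, dx), left-to-right
      c1 <- mid - dirv * (sp12 + sp23 / 2) / 2
      c2 <- c1 + dirv * sp12
      c3 <- c2 + dirv * sp23
      centers <- rbind(c1, c2, c3)
      margin <- rads * 1.3 + spec$wall_thickness + 2
      ok <- all(centers[, 1] - margin >= 1) && all(centers[, 1] + margin <= H) &&
        all(centers[, 2] - margin >= 1) && all(centers[, 2] + margin <= W)
      if (!ok) next
      lum <- wall <- vector("list", 3)
      for (k in 1:3) {
        lum[[k]] <- ellipse_mask(H, W, centers[k, 1], centers[k, 2],
                                 rads[k], rads[k] * eccs[k], thetas[k])
        wall[[k]] <- ellipse_mask(H, W, centers[k, 1], centers[k, 2],
                                  rads[k] + spec$wall_thickness,
                                  rads[k] * eccs[k] + spec$wall_thickness, thetas[k])
      }
      disjoint <- !any(wall[[1]] & wall[[2]]) && !any(wall[[2]] & wall[[3]]) &&
        !any(wall[[1]] & wall[[3]])
      if (!disjoint) next
      for (k in 1:3) {
        img[wall[[k]]] <- spec$wall_intensity
        img[lum[[k]]] <- spec$lumen_intensity
        mask[lum[[k]]] <- k
      }
      placed <- TRUE
      break
    }
    if (!placed)
      stop_v3("could not place three disjoint vessels (infeasible spec)",
              "vessel3_infeasible_spec")
    if (!is.null(spec$speckle_shape))
      img <- apply_speckle(img, spec$speckle_shape, seed = derive_seed(seed, 104729L))
    structure(list(image = img, mask = mask,
                   boxes = mask_to_instance_boxes(mask),
                   seed_used = as.integer(seed)),
              class = "phantom_sample")
  })
}

#' Generate a phantom dataset
#'
#' `n` samples with per-sample seeds derived deterministically from the
#' master seed. When `dir` is given, images and masks are written as 8-bit
#' PNG, all boxes to one `boxes.json`, and a `manifest.json` is created (see
#' [read_sample()]).
#'
#' @param spec a [phantom_spec()].
#' @param n number of samples.
#' @param seed master seed.
#' @param dir optional output directory.
#' @return invisibly, the list of `phantom_sample`s (with `$id`); if `dir` is
#'   given, the manifest is attached as attribute `"manifest"`.
#' @export
make_dataset <- function(spec = phantom_spec(), n, seed = 0L, dir = NULL) {
  if (n < 1) stop_v3("n must be >= 1", "vessel3_input_error")
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    s <- generate_phantom(spec, seed = derive_seed(seed, i))
    s$id <- sprintf("phantom_%04d", i)
    samples[[i]] <- s
  }
  if (!is.null(dir)) {
    manifest <- write_dataset(samples, dir)
    attr(samples, "manifest") <- manifest
  }
  invisible(samples)
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %dx%d, class pixels: PA=%d Ao=%d SVC=%d\n",
              nrow(x$image), ncol(x$image),
              sum(x$mask == 1), sum(x$mask == 2), sum(x$mask == 3)))
  invisible(x)
}

#' Display a phantom (image and mask side by side)
#' @param x a `phantom_sample`.
#' @param ... passed to `graphics::image`.
#' @export
plot.phantom_sample <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  flip <- function(m) t(m[nrow(m):1, ])
  graphics::image(flip(x$image), col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, main = "image", ...)
  graphics::image(flip(x$mask), col = c("black", "#e41a1c", "#377eb8", "#4daf4a"),
                  zlim = c(0, 3), axes = FALSE, main = "mask (PA/Ao/SVC)")
  invisible(x)
}
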