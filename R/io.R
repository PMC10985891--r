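# File formats: 8-bit grayscale PNG for images; 8-bit PNG holding raw label
# values 0-3 for masks (bit-exact round trip); one JSON file per dataset for
# boxes; a JSON manifest tying ids to files and split assignments; metric
# reports as CSV + JSON; configuration as YAML.

#' Write a phantom dataset to disk
#'
#' @param samples list of `phantom_sample`s (with `$id`).
#' @param dir output directory (created if needed).
#' @return the manifest list, invisibly (also written to `manifest.json`).
#' @export
write_dataset <- function(samples, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  boxes <- list()
  records <- list()
  for (s in samples) {
    id <- s$id %||% stop_v3("sample has no id", "vessel3_input_error")
    img_path <- file.path("images", paste0(id, ".png"))
    mask_path <- file.path("masks", paste0(id, ".png"))
    png::writePNG(s$image, file.path(dir, img_path))
    png::writePNG(s$mask / 255, file.path(dir, mask_path))
    if (nrow(s$boxes)) {
      b <- s$boxes
      b$sample_id <- id
      b$class <- vessel_classes()[b$class_id]
      boxes[[length(boxes) + 1]] <- b[, c("sample_id", "class", "x_min", "y_min",
                                          "x_max", "y_max", "confidence")]
    }
    records[[length(records) + 1]] <- list(id = id, image = img_path,
                                           mask = mask_path, split = "unassigned")
  }
  jsonlite::write_json(do.call(rbind, boxes), file.path(dir, "boxes.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  manifest <- list(format_version = 1L, dir = normalizePath(dir), samples = records)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a dataset manifest
#' @param dir dataset directory containing `manifest.json`.
#' @return manifest list; sample ids must be unique.
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop_v3("no manifest.json in %s", "vessel3_io_error", dir)
  m <- jsonlite::read_json(path)
  m$dir <- dir
  ids <- vapply(m$samples, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop_v3("duplicate sample ids in manifest", "vessel3_io_error")
  m
}

#' Read one sample (image, mask, boxes) from a dataset directory
#'
#' The image is normalized to \[0,1\] (16-bit PNGs are scaled by their bit
#' depth); mask labels are validated to lie in 0-3.
#'
#' @param manifest a manifest from [read_manifest()] (or [make_dataset()]).
#' @param id sample id.
#' @return list(image, mask, boxes).
#' @export
read_sample <- function(manifest, id) {
  ids <- vapply(manifest$samples, `[[`, character(1), "id")
  i <- match(id, ids)
  if (is.na(i)) stop_v3("id '%s' not in manifest", "vessel3_io_error", id)
  rec <- manifest$samples[[i]]
  img_path <- file.path(manifest$dir, rec$image)
  mask_path <- file.path(manifest$dir, rec$mask)
  for (p in c(img_path, mask_path))
    if (!file.exists(p)) stop_v3("missing file: %s", "vessel3_io_error", p)
  img <- png::readPNG(img_path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  # readPNG already maps any bit depth to [0,1]
  mask_raw <- png::readPNG(mask_path)
  if (length(dim(mask_raw)) == 3) mask_raw <- mask_raw[, , 1]
  mask <- matrix(as.integer(round(mask_raw * 255)), nrow(mask_raw))
  if (!all(mask %in% 0:3))
    stop_v3("illegal label(s) %s in mask for id '%s'", "vessel3_label_error",
            paste(setdiff(unique(as.vector(mask)), 0:3), collapse = ","), id)
  boxes <- empty_boxes()
  bpath <- file.path(manifest$dir, "boxes.json")
  if (file.exists(bpath)) {
    all_b <- jsonlite::read_json(bpath, simplifyVector = TRUE)
    if (length(all_b) && nrow(all_b)) {
      b <- all_b[all_b$sample_id == id, , drop = FALSE]
      if (nrow(b)) {
        boxes <- data.frame(class_id = match(b$class, vessel_classes()),
                            x_min = b$x_min, y_min = b$y_min,
                            x_max = b$x_max, y_max = b$y_max,
                            confidence = b$confidence)
      }
    }
  }
  list(image = img, mask = mask, boxes = boxes)
}

#' Write a metrics report as CSV and JSON
#'
#' The CSV shows 2-decimal values for reading; the JSON keeps full precision
#' and reproduces the report exactly on re-read.
#'
#' @param report a `metrics_report` from [evaluate_batch()].
#' @param path base path; `.csv` and `.json` are appended.
#' @return invisibly, the two file paths.
#' @export
write_report <- function(report, path) {
  df <- as.data.frame(report)
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  out <- df
  out$Dice <- sprintf("%.2f", out$Dice)
  out$IoU <- sprintf("%.2f", out$IoU)
  out$HD <- sprintf("%.2f", out$HD)
  write.csv(out, csv, row.names = FALSE)
  jsonlite::write_json(list(rows = df, n_images = attr(report, "n_images"),
                            n_undefined = as.data.frame(attr(report, "n_undefined"))),
                       js, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = js))
}

#' Re-read a JSON metrics report
#' @param path base path used in [write_report()] (without extension).
#' @return a `metrics_report`.
#' @export
read_report <- function(path) {
  j <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- as.data.frame(j$rows)
  structure(df, class = c("metrics_report", "data.frame"), n_images = j$n_images,
            n_undefined = j$n_undefined)
}

default_config <- function() {
  list(image = list(out_size = c(256L, 256L)),
       roi = list(margin = 5),
       split = list(ratios = c(7, 1, 2), seed = 0L),
       phantom = list(),     # overrides for phantom_spec()
       net = list(),         # overrides for net_config()
       train = list())       # overrides for train_config()
}

#' Load and validate a YAML configuration
#'
#' Missing keys are filled from the defaults (256x256 input, ROI margin 5,
#' 7:1:2 split, 35-epoch schedule); unknown top-level or nested keys are
#' rejected with their key path.
#'
#' @param path YAML file; `NULL` or an empty file yields the full defaults.
#' @return configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  user <- if (is.null(path)) list() else yaml::read_yaml(path) %||% list()
  known_sub <- list(image = c("out_size"), roi = c("margin"),
                    split = c("ratios", "seed"),
                    phantom = names(formals(phantom_spec)),
                    net = names(formals(net_config)),
                    train = names(formals(train_config)))
  for (key in names(user)) {
    if (!key %in% names(cfg))
      stop_v3("unknown configuration key '%s'", "vessel3_config_error", key)
    for (sub in names(user[[key]]))
      if (!sub %in% known_sub[[key]])
        stop_v3("unknown configuration key '%s.%s'", "vessel3_config_error", key, sub)
    cfg[[key]] <- modifyList(cfg[[key]], user[[key]])
  }
  if (!is.null(cfg$roi$margin) && cfg$roi$margin < 0)
    stop_v3("roi.margin must be >= 0", "vessel3_config_error")
  if (length(cfg$split$ratios) != 3 || any(cfg$split$ratios <= 0))
    stop_v3("split.ratios must be three positive numbers", "vessel3_config_error")
  # materialize the typed sub-configs so downstream validation runs now
  cfg$train_config <- do.call(train_config, cfg$train)
  cfg$net_config <- do.call(net_config, cfg$net)
  cfg$phantom_spec <- do.call(phantom_spec, cfg$phantom)
  cfg
}

#' Save / load network checkpoints
#'
#' Checkpoints are the flat parameter state plus the architecture config,
#' serialized with `saveRDS`.
#'
#' @param model a `vessel_net` or `stage2_fit`.
#' @param path file path.
#' @return `load_checkpoint` returns a `vessel_net`.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "stage2_fit")) model <- model$model
  saveRDS(list(config = model$config, state = net_state(model),
               format_version = 1L), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- vessel_net(ck$config, seed = 0L)
  net_load_state(model, ck$state)
  model
}
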