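#' End-to-end orchestration: generate -> preprocess -> detect -> measure -> report
#'
#' A run is fully described by a config (YAML file or R list) plus a seed.
#' Ground-truth-box mode (the default) feeds the annotated boxes straight to
#' the measurement stage, so the size-calculation pipeline is testable without
#' trained detector weights.
#'
#' @name pipeline
NULL

#' Default run configuration
#'
#' @return nested list with sections \code{scene} (generator), \code{preprocess},
#'   \code{augment}, \code{model}, \code{metrics} and \code{lwc}.
#' @export
default_config <- function() {
  list(
    seed = 1,
    scene = list(n_per_class = list(Y = 1, G = 1, P = 1, Z = 1),
                 overlap_fraction = 0, with_block = TRUE, shadow_strength = 0.6,
                 canvas = c(768, 768), ppmm = 10, block_mm = c(3, 9),
                 n_scenes = 1),
    preprocess = list(enabled = TRUE, dilate_kernel = 41, offset = 12, gain = 1),
    augment = list(hsv_h = 0.015, hsv_s = 0.7, hsv_v = 0.4, translate = 0.2,
                   scale = 0.5, fliplr = 0.5, mosaic = 1, mixup = 0.05,
                   paste_in = 0.05),
    model = list(block_counts = c(1, 2, 2, 1),
                 stage_channels = c(64, 128, 256, 512), n_classes = 4),
    metrics = list(conf_min = 0.25),
    lwc = list(n_strips = 50, block_mm = 9)
  )
}

#' Read a YAML run configuration, filling unset fields with defaults
#'
#' @param path YAML file; NULL returns \code{\link{default_config}}.
#' @return config list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_cfg <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(upd[[nm]]) && is.list(base[[nm]]))
        merge_cfg(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  merge_cfg(cfg, user)
}

#' Run the full pipeline on synthetic scenes
#'
#' Generates \code{config$scene$n_scenes} scenes, optionally applies
#' background-shadow elimination, takes detection boxes (ground-truth mode),
#' calibrates from the rendered block, measures every object with the LWC
#' algorithm and assembles per-object and aggregate tables.
#'
#' @param config list from \code{\link{read_config}}/\code{\link{default_config}}.
#' @param out_dir optional directory; when given, scenes, per-object CSV and
#'   aggregate CSV are written there deterministically.
#' @return a \code{run_report}: list(objects, aggregates, scenes, config).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  sc_cfg <- config$scene
  assert_that(!is.null(sc_cfg$block_mm) || !is.null(config$lwc$block_px),
              "config must provide a calibration block size (scene$block_mm) or lwc$block_px")
  seeds <- config$seed + seq_len(sc_cfg$n_scenes) - 1
  scenes <- lapply(seeds, function(s)
    generate_scene(n_per_class = unlist(sc_cfg$n_per_class),
                   overlap_fraction = sc_cfg$overlap_fraction,
                   with_block = isTRUE(sc_cfg$with_block),
                   shadow_strength = sc_cfg$shadow_strength,
                   seed = s, canvas = sc_cfg$canvas, ppmm = sc_cfg$ppmm,
                   block_mm = sc_cfg$block_mm))
  reports <- list()
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    img <- sc$image
    fg <- NULL
    if (isTRUE(config$preprocess$enabled)) {
      pp <- eliminate_shadow(img, dilate_kernel = config$preprocess$dilate_kernel,
                             offset = config$preprocess$offset,
                             gain = config$preprocess$gain)
      img <- pp$image
      fg <- pp$mask          # measurement reuses the segmentation
    }
    cal <- if (!is.null(sc$block_px_length)) {
      calibrate(sc$block_px_length, sc$block_mm[2])
    } else {
      calibrate(config$lwc$block_px, config$lwc$block_mm)
    }
    rep_i <- measure_scene(img, sc$boxes, cal, n = config$lwc$n_strips,
                           truths = sc$truths, fg_mask = fg)
    rep_i$scene <- i
    reports[[i]] <- rep_i
  }
  objects <- do.call(rbind, reports)
  aggregates <- aggregate_report(objects)
  out <- structure(list(objects = objects, aggregates = aggregates,
                        scenes = scenes, config = config),
                   class = "run_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(scenes)) write_scene(scenes[[i]], out_dir,
                                             sprintf("scene_%03d", i))
    utils::write.csv(format(objects, digits = 8), file.path(out_dir, "objects.csv"),
                     row.names = FALSE)
    utils::write.csv(format(aggregates, digits = 8),
                     file.path(out_dir, "aggregates.csv"), row.names = FALSE)
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("pipeline run: %d scene(s), %d object(s) measured\n",
              length(x$scenes), sum(!is.na(x$objects$length_mm))))
  print.data.frame(x$aggregates, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Split a manifest into train/test listings
#'
#' Thin wrapper over \code{\link{build_manifest}} for pre-existing manifests:
#' re-splits the given records per label at \code{ratio}.
#'
#' @param manifest data.frame with columns record_id and label.
#' @param ratio length-2 (train, test).
#' @param seed integer seed.
#' @return list(train, test) data.frames.
#' @export
split_dataset <- function(manifest, ratio = c(7, 3), seed = 1) {
  counts <- table(manifest$label)
  m <- build_manifest(as.list(counts), ratio = ratio, seed = seed)
  # carry the caller's record ids, per label in input order
  m$record_id <- unlist(lapply(names(counts), function(lb)
    manifest$record_id[manifest$label == lb]))
  list(train = m[m$split == "train", c("record_id", "label")],
       test = m[m$split == "test", c("record_id", "label")])
}
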