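#' Read and write YOLO-format annotations
#'
#' The YOLO annotation dialect: one line per object, whitespace-separated
#' `class cx cy w h [confidence]`, all box fields normalized to the image
#' dimensions with 6-decimal precision.  Reading validates field count and
#' the [0, 1] range and reports the file and line number of the first
#' malformed line.
#'
#' @param path annotation file path.
#' @return `read_yolo_annotations`: data frame with `class_id, cx, cy, w, h`
#'   and `confidence` (NA when absent).
#' @export
read_yolo_annotations <- function(path) {
  if (!file.exists(path)) stop("read_yolo_annotations: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
                    w = numeric(), h = numeric(), confidence = numeric())
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (!length(f) %in% c(5L, 6L))
      stop("read_yolo_annotations: ", path, " line ", i,
           ": expected 5 or 6 fields, found ", length(f))
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v))
      stop("read_yolo_annotations: ", path, " line ", i, ": non-numeric field")
    if (any(v[2:5] < 0 | v[2:5] > 1))
      stop("read_yolo_annotations: ", path, " line ", i,
           ": normalized coordinate outside [0, 1]")
    out <- rbind(out, data.frame(class_id = as.integer(v[1]), cx = v[2],
                                 cy = v[3], w = v[4], h = v[5],
                                 confidence = if (length(v) == 6L) v[6]
                                              else NA_real_))
  }
  out
}

#' @rdname read_yolo_annotations
#' @param ann data frame with columns `class_id, cx, cy, w, h` and optional
#'   `confidence`.
#' @param with_confidence append the confidence column when present.
#' @export
write_yolo_annotations <- function(ann, path, with_confidence = FALSE) {
  fmt <- function(x) formatC(x, format = "f", digits = 6)
  lines <- paste(ann$class_id, fmt(ann$cx), fmt(ann$cy), fmt(ann$w),
                 fmt(ann$h))
  if (with_confidence && !is.null(ann$confidence) && !anyNA(ann$confidence))
    lines <- paste(lines, fmt(ann$confidence))
  writeLines(lines, path)
  invisible(path)
}

#' Convert between pixel boxes and normalized YOLO records
#'
#' @param boxes data frame with half-open pixel columns
#'   `x_min, y_min, x_max, y_max` and `class_id`.
#' @param ann data frame of YOLO records (`class_id, cx, cy, w, h`).
#' @param image_w,image_h image dimensions in pixels.
#' @return The converted data frame.
#' @export
boxes_to_yolo <- function(boxes, image_w, image_h) {
  data.frame(class_id = boxes$class_id,
             cx = (boxes$x_min + boxes$x_max) / 2 / image_w,
             cy = (boxes$y_min + boxes$y_max) / 2 / image_h,
             w = (boxes$x_max - boxes$x_min) / image_w,
             h = (boxes$y_max - boxes$y_min) / image_h)
}

#' @rdname boxes_to_yolo
#' @export
yolo_to_boxes <- function(ann, image_w, image_h) {
  out <- data.frame(x_min = (ann$cx - ann$w / 2) * image_w,
                    y_min = (ann$cy - ann$h / 2) * image_h,
                    x_max = (ann$cx + ann$w / 2) * image_w,
                    y_max = (ann$cy + ann$h / 2) * image_h,
                    class_id = ann$class_id)
  if (!is.null(ann$confidence)) out$confidence <- ann$confidence
  out
}

#' Read and write raw detection grids as CSV
#'
#' Columns `cx, cy, w, h, objectness, p0, p1, ...`; lossless round-trip
#' within numeric precision.
#'
#' @param path CSV file path.
#' @param grid a [raw_grid()].
#' @export
read_raw_grid <- function(path) {
  g <- utils::read.csv(path)
  need <- c("cx", "cy", "w", "h", "objectness")
  if (!all(need %in% names(g)))
    stop("read_raw_grid: ", path, " lacks columns ",
         paste(setdiff(need, names(g)), collapse = ", "))
  pcols <- grep("^p[0-9]+$", names(g), value = TRUE)
  if (length(pcols) == 0L) stop("read_raw_grid: no class-probability columns")
  raw_grid(g$cx, g$cy, g$w, g$h, g$objectness,
           as.matrix(g[, pcols, drop = FALSE]))
}

#' @rdname read_raw_grid
#' @export
write_raw_grid <- function(grid, path) {
  utils::write.csv(as.data.frame(unclass(grid)), path, row.names = FALSE)
  invisible(path)
}

#' Write a counting report
#'
#' JSON report per image (count, per-seed features, resolved configuration,
#' library version, and the coordinate convention) plus an optional flat CSV
#' with one row per seed.
#'
#' @param result a `seed_count` from [count_seeds()].
#' @param path output `.json` path; a `.csv` beside it when `csv = TRUE`.
#' @param csv also write the per-seed CSV.
#' @export
write_count_report <- function(result, path, csv = TRUE) {
  rep <- list(
    coordinate_convention = paste(
      "0-based, origin top-left, x = column, y = row,",
      "half-open boxes [x_min, x_max) x [y_min, y_max)"),
    seedcount_version = as.character(utils::packageVersion("seedcount")),
    config = result$config[!vapply(result$config, is.null, logical(1))],
    threshold = result$threshold,
    foreground_polarity = attr(result$mask, "polarity"),
    regions_filtered = result$n_filtered,
    count = result$count,
    seeds = result$features)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (csv)
    utils::write.csv(result$features, sub("\\.json$", ".csv", path),
                     row.names = FALSE)
  invisible(path)
}

#' Write a synthetic sample to disk
#'
#' Emits the image PNG, the true mask PNG, YOLO-format annotations, and a
#' manifest JSON carrying the generator configuration.
#'
#' @param sample a `sim_sample` from [simulate_seed_image()].
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @export
write_sim_sample <- function(sample, dir, stem = "sample") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image_png(sample$image, file.path(dir, paste0(stem, ".png")))
  write_image_png(unclass(sample$true_mask) * 255,
                  file.path(dir, paste0(stem, "_mask.png")))
  ann <- boxes_to_yolo(sample$truth$boxes, sample$config$image_w,
                       sample$config$image_h)
  write_yolo_annotations(ann, file.path(dir, paste0(stem, ".txt")))
  jsonlite::write_json(sample$config[setdiff(names(sample$config), "bg_rgb")],
                       file.path(dir, paste0(stem, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Evaluate prediction files against ground-truth files
#'
#' Pairs prediction and truth YOLO-format annotation files by file-name stem
#' (the annotation-ecosystem convention) and computes the full metrics
#' report.  Unmatched stems on either side are an error, listed explicitly.
#'
#' @param pred_paths prediction files (`class cx cy w h confidence`).
#' @param truth_paths ground-truth files (`class cx cy w h`).
#' @param image_w,image_h pixel dimensions shared by all images.
#' @param ... passed to [evaluate_detections()].
#' @return A `metrics_report`.
#' @export
evaluate_files <- function(pred_paths, truth_paths, image_w, image_h, ...) {
  stem <- function(p) sub("\\.[^.]*$", "", basename(p))
  ps <- stem(pred_paths); ts <- stem(truth_paths)
  unmatched <- c(setdiff(ps, ts), setdiff(ts, ps))
  if (length(unmatched))
    stop("evaluate_files: unmatched stems: ", paste(unmatched, collapse = ", "))
  truth_paths <- truth_paths[match(ps, ts)]
  preds <- lapply(pred_paths, function(p) {
    a <- read_yolo_annotations(p)
    b <- yolo_to_boxes(a, image_w, image_h)
    b$confidence[is.na(b$confidence)] <- 1
    detections(b$x_min, b$y_min, b$x_max, b$y_max, b$confidence,
               b$class_id, paste0("class", b$class_id))
  })
  gts <- lapply(truth_paths, function(p) {
    a <- read_yolo_annotations(p)
    ground_truth(yolo_to_boxes(a, image_w, image_h)[
      , c("x_min", "y_min", "x_max", "y_max", "class_id")])
  })
  evaluate_detections(preds, gts, ...)
}

#' Load a run configuration from YAML with overrides
#'
#' Reads a flat-key YAML file holding any of the [count_config()],
#' [sim_config()] and post-processing parameters, fills unset fields from
#' the package defaults, and applies explicit overrides last (CLI
#' precedence).  Unknown keys are an error.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list applied after the file.
#' @return List with elements `count` ([count_config()]), `sim`
#'   ([sim_config()]), `tau`, and `nms_iou`.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  known_count <- names(formals(count_config))
  known_count <- setdiff(known_count, "polarity")
  known_sim <- names(formals(sim_config))
  extra <- setdiff(names(vals),
                   c(known_count, known_sim, "polarity", "tau", "nms_iou"))
  if (length(extra))
    stop("load_run_config: unknown keys: ", paste(extra, collapse = ", "))
  cc <- do.call(count_config,
                vals[intersect(names(vals), c(known_count, "polarity"))])
  sc <- do.call(sim_config, vals[intersect(names(vals), known_sim)])
  list(count = cc, sim = sc,
       tau = vals$tau %||% 0.25, nms_iou = vals$nms_iou %||% 0.45)
}
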