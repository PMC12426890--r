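#' Counting-pipeline configuration
#'
#' All tunables of the image-processing counting pipeline with their
#' defaults.  `min_area_px` is specified at the native capture resolution
#' (3024 x 4032) and is rescaled by the processed image's relative area, so
#' speck rejection behaves consistently across downsampled images.
#'
#' @param kernel_px odd Gaussian kernel size in pixels.
#' @param sigma Gaussian standard deviation in pixels.
#' @param threshold fixed 8-bit threshold level, or `NULL` for automatic
#'   Otsu selection.
#' @param polarity foreground polarity: `"auto"`, `"bright"` or `"dark"`.
#' @param connectivity component connectivity, 4 or 8.
#' @param min_area_px minimum region area (px) at native resolution.
#' @param max_area_px maximum region area (px), `Inf` for unbounded.
#' @param mm_per_px millimetres per pixel; 1 reports dimensions in pixel
#'   units.  See [calibration_from_reference()].
#' @param oversize_factor a region whose area exceeds this multiple of the
#'   median region area is flagged as a suspected merged cluster.
#' @return Named list of class `count_config`.
#' @export
count_config <- function(kernel_px = 5L, sigma = 1.0, threshold = NULL,
                         polarity = c("auto", "bright", "dark"),
                         connectivity = 8L, min_area_px = 10,
                         max_area_px = Inf, mm_per_px = 1.0,
                         oversize_factor = 3.0) {
  polarity <- match.arg(polarity)
  structure(list(kernel_px = as.integer(kernel_px), sigma = sigma,
                 threshold = threshold, polarity = polarity,
                 connectivity = as.integer(connectivity),
                 min_area_px = min_area_px, max_area_px = max_area_px,
                 mm_per_px = mm_per_px, oversize_factor = oversize_factor),
            class = "count_config")
}

#' Millimetre calibration from a reference object
#'
#' Converts a measured pixel length of a reference object of known physical
#' length into an mm-per-pixel scale.
#'
#' @param reference_px measured length of the reference in pixels.
#' @param reference_mm its known physical length in millimetres.
#' @return mm-per-pixel scale factor.
#' @export
calibration_from_reference <- function(reference_px, reference_mm) {
  if (reference_px <= 0 || reference_mm <= 0)
    stop("calibration_from_reference: lengths must be positive")
  reference_mm / reference_px
}

#' Measure a segmented region
#'
#' Computes the bounding box, length (longer box side, mm), width (shorter
#' side, mm), aspect ratio L/W, pixel area, and centroid of a region, using
#' a linear mm-per-pixel calibration.
#'
#' @param region a [pixel_region()].
#' @param mm_per_px millimetres per pixel (> 0).
#' @param seed_id 1-based ordinal assigned after spatial sorting.
#' @return One-row data frame of the region's descriptors.
#' @export
extract_features <- function(region, mm_per_px = 1.0, seed_id = 1L) {
  if (mm_per_px <= 0) stop("extract_features: mm_per_px must be > 0")
  b <- region$bbox
  side_x <- b[["x_max"]] - b[["x_min"]]
  side_y <- b[["y_max"]] - b[["y_min"]]
  len <- max(side_x, side_y) * mm_per_px
  wid <- min(side_x, side_y) * mm_per_px
  data.frame(seed_id = as.integer(seed_id),
             x_min = b[["x_min"]], y_min = b[["y_min"]],
             x_max = b[["x_max"]], y_max = b[["y_max"]],
             length_mm = len, width_mm = wid, aspect_ratio = len / wid,
             area_px = region$pixel_count,
             centroid_x = mean(region$pixels[, 1]),
             centroid_y = mean(region$pixels[, 2]))
}

#' Count seeds in an image
#'
#' Runs the full image-processing pipeline: grayscale conversion, Gaussian
#' smoothing, (Otsu or fixed) thresholding, connected-component
#' segmentation, area filtering, top-to-bottom sorting, and millimetre-
#' calibrated feature extraction.  The seed count is the number of surviving
#' regions; each gets a 1-based identifier in sorted order.
#'
#' Touching or overlapping seeds merge into a single component and are
#' counted once; such regions are flagged (`cluster_suspect`) when their
#' area exceeds `oversize_factor` times the median region area.  Regions
#' touching the image border are counted but flagged (`on_border`).
#'
#' @param img a `raster_image`, `gray_image`, or a path to a PNG file.
#' @param config a [count_config()].
#' @return Object of class `seed_count`: list with `count`, `features`
#'   (data frame, one row per seed), `mask` (the binary mask used),
#'   `threshold`, `n_filtered`, and `config`.
#' @examples
#' sim <- simulate_seed_image(sim_config(n_seeds = 5, rng_seed = 1))
#' res <- count_seeds(sim$image)
#' res$count
#' @export
count_seeds <- function(img, config = count_config()) {
  if (is.character(img)) img <- read_image_png(img)
  gray <- if (is.matrix(img)) gray_image(unclass(img)) else to_grayscale(img)
  blurred <- gaussian_blur(gray, config$kernel_px, config$sigma)
  if (is.null(config$threshold) && length(unique(as.vector(blurred))) < 2L) {
    # single-intensity image: nothing to separate, hence nothing to count
    message("count_seeds: constant image, no foreground; count 0")
    mask <- binary_mask(matrix(0, nrow(blurred), ncol(blurred)), "dark")
    level <- NA_integer_
  } else {
    level <- tryCatch(
      if (is.null(config$threshold)) otsu_threshold(blurred)
      else config$threshold,
      error = function(e) stop("count_seeds: threshold selection failed: ",
                               conditionMessage(e)))
    mask <- binarize(blurred, level, config$polarity)
  }

  regions <- label_components(mask, config$connectivity)
  # speck threshold scales with image area relative to native capture size
  scale_area <- nrow(gray) * ncol(gray) / (3024 * 4032)
  min_area <- config$min_area_px * scale_area
  regions <- filter_regions(regions, min_area, config$max_area_px)
  n_removed <- attr(regions, "n_removed")
  regions <- sort_regions(regions)
  regions <- lapply(regions, trace_external_contour)

  feats <- if (length(regions) == 0L) {
    extract_features(pixel_region(1L, cbind(0L, 0L)), 1, 1L)[0, ]
  } else {
    do.call(rbind, lapply(seq_along(regions), function(i)
      extract_features(regions[[i]], config$mm_per_px, i)))
  }
  if (nrow(feats) > 0L) {
    H <- nrow(gray); W <- ncol(gray)
    feats$on_border <- feats$x_min == 0 | feats$y_min == 0 |
                       feats$x_max == W | feats$y_max == H
    med <- stats::median(feats$area_px)
    feats$cluster_suspect <- feats$area_px > config$oversize_factor * med
  }
  structure(list(count = length(regions), features = feats,
                 regions = regions, mask = mask, threshold = level,
                 n_filtered = n_removed, config = config),
            class = "seed_count")
}

#' @export
print.seed_count <- function(x, ...) {
  cat("Seed count:", x$count, "\n")
  cat("  threshold level:", x$threshold,
      "| foreground polarity:", attr(x$mask, "polarity"),
      "| regions filtered out:", x$n_filtered, "\n")
  if (any(x$features$cluster_suspect %||% FALSE))
    cat("  note:", sum(x$features$cluster_suspect),
        "oversized region(s) may be merged seed clusters\n")
  if (any(x$features$on_border %||% FALSE))
    cat("  note:", sum(x$features$on_border),
        "region(s) touch the image border\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.seed_count <- function(object, ...) {
  f <- object$features
  cat("Seed count:", object$count, "\n")
  if (nrow(f) > 0) {
    cat(sprintf("  length (mm): mean %.2f  range [%.2f, %.2f]\n",
                mean(f$length_mm), min(f$length_mm), max(f$length_mm)))
    cat(sprintf("  width  (mm): mean %.2f  range [%.2f, %.2f]\n",
                mean(f$width_mm), min(f$width_mm), max(f$width_mm)))
    cat(sprintf("  aspect L/W : mean %.2f\n", mean(f$aspect_ratio)))
    cat(sprintf("  area  (px) : median %.0f\n", stats::median(f$area_px)))
  }
  invisible(object)
}

#' @export
as.data.frame.seed_count <- function(x, ...) x$features

#' Overlay the detected seeds on an image
#'
#' Draws the source image with each counted region's bounding box and its
#' seed identifier at the centroid.
#'
#' @param x a `seed_count` result.
#' @param img the image that was counted (optional; the binary mask is shown
#'   when omitted).
#' @param ... passed to [graphics::plot()].
#' @export
plot.seed_count <- function(x, img = NULL, ...) {
  f <- x$features
  if (is.null(img)) {
    a <- unclass(x$mask)
  } else {
    a <- unclass(img) / 255
  }
  H <- if (is.matrix(a)) nrow(a) else dim(a)[1]
  W <- if (is.matrix(a)) ncol(a) else dim(a)[2]
  graphics::plot(NA, xlim = c(0, W), ylim = c(H, 0), asp = 1,
                 xlab = "x (px)", ylab = "y (px)", ...)
  graphics::rasterImage(if (is.matrix(a)) 1 - a else a, 0, H, W, 0,
                        interpolate = FALSE)
  if (nrow(f) > 0) {
    graphics::rect(f$x_min, f$y_min, f$x_max, f$y_max, border = "red")
    graphics::text(f$centroid_x, f$centroid_y, f$seed_id,
                   col = "blue", cex = 0.7)
  }
  invisible(x)
}
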