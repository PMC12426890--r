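# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.backgrounds <- list(
  white_a4     = c(245, 245, 242),
  orange_table = c(214, 132, 48),
  black_table  = c(26, 26, 30)
)

#' Synthetic seed-image configuration
#'
#' Defines one imaging condition for the generator: canvas size, background
#' surface, number of seeds, the seed shape/colour profile, placement
#' constraints, and degradation (sensor noise, illumination gradient).  The
#' default canvas is 1008 x 1344, the native 3024 x 4032 portrait capture
#' downscaled 3x with aspect ratio preserved; seed sizes default to the
#' desk-scale equivalent of millimetre-sized seeds (a 2-4 mm seed spans
#' roughly 10-20 px at this scale), rendered as rotated filled ellipses in
#' dark brown tones.  Noise and gradient default to 0 so baseline scenes
#' segment exactly.
#'
#' @param image_w,image_h canvas size in pixels.
#' @param background `"white_a4"`, `"orange_table"`, `"black_table"`, or a
#'   length-3 RGB vector (0-255).
#' @param n_seeds number of seeds to place (>= 0).
#' @param major_axis_px range of the seed major axis, px.
#' @param aspect_ratio range of major/minor axis ratio (>= 1).
#' @param fill_rgb_min,fill_rgb_max per-channel bounds of the seed fill
#'   colour (0-255).
#' @param min_separation_px minimum centre-to-centre distance when touching
#'   is disallowed; the default `NULL` resolves to
#'   `max(major_axis_px) + 12` (the largest seed plus two 5-px blur
#'   kernels), which guarantees blurred seeds stay disjoint.
#' @param allow_touching if `TRUE` the separation constraint is dropped and
#'   seeds may overlap into clusters.
#' @param noise_sigma additive Gaussian pixel noise sd, 8-bit units.
#' @param illumination_gradient maximum relative intensity change across the
#'   image width (multiplicative, left to right).
#' @param rng_seed integer seed; identical configs produce bit-identical
#'   samples.
#' @return A `sim_config` list.
#' @export
sim_config <- function(image_w = 1008L, image_h = 1344L,
                       background = "white_a4", n_seeds = 30L,
                       major_axis_px = c(18, 30), aspect_ratio = c(1.2, 2.2),
                       fill_rgb_min = c(70, 45, 25),
                       fill_rgb_max = c(130, 95, 60),
                       min_separation_px = NULL, allow_touching = FALSE,
                       noise_sigma = 0, illumination_gradient = 0,
                       rng_seed = 1L) {
  if (is.character(background)) {
    if (!background %in% names(.backgrounds))
      stop("sim_config: unknown background '", background, "'")
    bg <- .backgrounds[[background]]
  } else bg <- background
  if (is.null(min_separation_px))
    min_separation_px <- max(major_axis_px) + 12
  if (diff(range(major_axis_px)) < 0 || min(major_axis_px) < 2)
    stop("sim_config: major_axis_px range must be >= 2 px")
  if (min(aspect_ratio) < 1)
    stop("sim_config: aspect_ratio must be >= 1")
  structure(list(image_w = as.integer(image_w), image_h = as.integer(image_h),
                 background = background, bg_rgb = bg,
                 n_seeds = as.integer(n_seeds),
                 major_axis_px = major_axis_px, aspect_ratio = aspect_ratio,
                 fill_rgb_min = fill_rgb_min, fill_rgb_max = fill_rgb_max,
                 min_separation_px = min_separation_px,
                 allow_touching = isTRUE(allow_touching),
                 noise_sigma = noise_sigma,
                 illumination_gradient = illumination_gradient,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Generate a synthetic seed image with ground truth
#'
#' Places `n_seeds` rotated filled ellipses on the configured background by
#' rejection sampling (10,000 placement attempts, then an explicit capacity
#' error naming `min_separation_px`), composites them with per-seed size,
#' rotation and colour jitter, then applies additive Gaussian noise and the
#' multiplicative illumination gradient.  Ground-truth boxes are tight to
#' each ellipse's pixel set before degradation; the true mask is the union
#' of seed pixels.
#'
#' @param config a [sim_config()].
#' @return A `sim_sample`: list with `image` (`raster_image`), `truth`
#'   ([ground_truth()] with half-open pixel boxes and `class_id` 0),
#'   `true_mask` (`binary_mask`), and `config`.
#' @export
simulate_seed_image <- function(config = sim_config()) {
  .with_seed(config$rng_seed, {
    W <- config$image_w; H <- config$image_h
    margin <- max(config$major_axis_px) / 2 + 2
    if (2 * margin >= min(W, H))
      stop("simulate_seed_image: canvas too small for the seed size profile")
    # placement
    cx <- cy <- numeric(0)
    attempts <- 0L
    while (length(cx) < config$n_seeds) {
      if (attempts >= 10000L)
        stop("simulate_seed_image: placement infeasible after 10000 attempts; ",
             "reduce n_seeds (", config$n_seeds, ") or min_separation_px (",
             config$min_separation_px, ")")
      attempts <- attempts + 1L
      px <- stats::runif(1, margin, W - margin)
      py <- stats::runif(1, margin, H - margin)
      ok <- config$allow_touching || length(cx) == 0L ||
        min((cx - px)^2 + (cy - py)^2) >= config$min_separation_px^2
      if (ok) { cx <- c(cx, px); cy <- c(cy, py) }
    }
    # per-seed shape and colour
    n <- config$n_seeds
    major <- stats::runif(n, config$major_axis_px[1], config$major_axis_px[2])
    aspect <- stats::runif(n, config$aspect_ratio[1], config$aspect_ratio[2])
    theta <- stats::runif(n, 0, pi)
    cols <- vapply(1:3, function(ch)
      stats::runif(n, config$fill_rgb_min[ch], config$fill_rgb_max[ch]),
      numeric(n))
    cols <- matrix(cols, nrow = n, ncol = 3)

    img <- array(0, c(H, W, 3))
    for (ch in 1:3) img[, , ch] <- config$bg_rgb[ch]
    mask <- matrix(0L, H, W)
    boxes <- data.frame(x_min = numeric(), y_min = numeric(),
                        x_max = numeric(), y_max = numeric(),
                        class_id = integer())
    for (i in seq_len(n)) {
      a <- major[i] / 2; b <- a / aspect[i]
      xr <- max(0L, floor(cx[i] - a)):min(W - 1L, ceiling(cx[i] + a))
      yr <- max(0L, floor(cy[i] - a)):min(H - 1L, ceiling(cy[i] + a))
      dxm <- outer(rep(1, length(yr)), xr + 0.5 - cx[i])
      dym <- outer(yr + 0.5 - cy[i], rep(1, length(xr)))
      u <- (dxm * cos(theta[i]) + dym * sin(theta[i])) / a
      v <- (-dxm * sin(theta[i]) + dym * cos(theta[i])) / b
      inside <- u^2 + v^2 <= 1
      hit <- which(inside, arr.ind = TRUE)
      if (nrow(hit) == 0L) next
      rows <- yr[hit[, 1]] + 1L; colsx <- xr[hit[, 2]] + 1L
      for (ch in 1:3) img[cbind(rows, colsx, ch)] <- cols[i, ch]
      mask[cbind(rows, colsx)] <- 1L
      boxes <- rbind(boxes, data.frame(
        x_min = min(colsx) - 1L, y_min = min(rows) - 1L,
        x_max = max(colsx), y_max = max(rows), class_id = 0L))
    }
    if (config$noise_sigma > 0)
      img <- img + array(stats::rnorm(H * W * 3, 0, config$noise_sigma),
                         c(H, W, 3))
    if (config$illumination_gradient != 0) {
      g <- config$illumination_gradient
      fac <- 1 + g * ((seq_len(W) - 1) / max(W - 1, 1) - 0.5)
      for (ch in 1:3) img[, , ch] <- sweep(img[, , ch], 2, fac, `*`)
    }
    img <- array(as.integer(floor(pmin(pmax(img, 0), 255) + 0.5)), c(H, W, 3))
    structure(list(image = raster_image(img),
                   truth = ground_truth(boxes, nrow(boxes)),
                   true_mask = binary_mask(mask, "dark"),
                   config = config),
              class = "sim_sample")
  })
}

#' Build a raw detection grid from ground truth
#'
#' Fixture generator for the post-processing chain: converts true boxes to
#' normalized centre/size records with sampled objectness, optionally
#' perturbed with box jitter, near-duplicate records, and spurious
#' low-confidence records, so decoding, confidence filtering and NMS can be
#' exercised without a trained detector.  With zero perturbation,
#' [decode_raw()] inverts the grid back to the true boxes within 1 px.
#'
#' @param truth a [ground_truth()].
#' @param image_w,image_h image dimensions in pixels.
#' @param jitter_px sd of Gaussian jitter added to box corners (px).
#' @param duplicate_rate probability each true box also emits a duplicate
#'   record (slightly jittered, slightly lower confidence).
#' @param spurious_rate expected number of spurious records per true box;
#'   spurious records get confidences from `spurious_conf`.
#' @param conf_range objectness range for true-box records.
#' @param spurious_conf objectness range for spurious records (default below
#'   the usual 0.25 confidence threshold).
#' @param rng_seed integer seed; `NULL` uses the current RNG stream.
#' @return A [raw_grid()] with a single class column `p0 = 1`.
#' @export
raw_grid_from_truth <- function(truth, image_w, image_h, jitter_px = 0,
                                duplicate_rate = 0, spurious_rate = 0,
                                conf_range = c(0.85, 0.99),
                                spurious_conf = c(0.02, 0.2),
                                rng_seed = NULL) {
  build <- function() {
    b <- truth$boxes
    n <- nrow(b)
    corners <- as.matrix(b[, c("x_min", "y_min", "x_max", "y_max"),
                         drop = FALSE])
    rows <- list()
    emit <- function(corners, conf) {
      if (jitter_px > 0)
        corners <- corners + matrix(stats::rnorm(length(corners), 0, jitter_px),
                                    ncol = 4)
      x0 <- pmin(corners[, 1], corners[, 3]); x1 <- pmax(corners[, 1], corners[, 3])
      y0 <- pmin(corners[, 2], corners[, 4]); y1 <- pmax(corners[, 2], corners[, 4])
      data.frame(cx = pmin(pmax((x0 + x1) / 2 / image_w, 0), 1),
                 cy = pmin(pmax((y0 + y1) / 2 / image_h, 0), 1),
                 w = pmin(pmax((x1 - x0) / image_w, 1 / image_w), 1),
                 h = pmin(pmax((y1 - y0) / image_h, 1 / image_h), 1),
                 objectness = conf)
    }
    if (n > 0) {
      rows[[1]] <- emit(corners, stats::runif(n, conf_range[1], conf_range[2]))
      dup <- stats::runif(n) < duplicate_rate
      if (any(dup))
        rows[[length(rows) + 1L]] <- emit(
          corners[dup, , drop = FALSE] +
            matrix(stats::rnorm(4 * sum(dup), 0, 0.5), ncol = 4),
          stats::runif(sum(dup), conf_range[1] * 0.9, conf_range[2] * 0.95))
    }
    n_sp <- stats::rpois(1, spurious_rate * max(n, 1))
    if (spurious_rate > 0 && n_sp > 0) {
      sw <- stats::runif(n_sp, 5, 30); sh <- stats::runif(n_sp, 5, 30)
      sx <- stats::runif(n_sp, 0, image_w - sw)
      sy <- stats::runif(n_sp, 0, image_h - sh)
      rows[[length(rows) + 1L]] <- emit(
        cbind(sx, sy, sx + sw, sy + sh),
        stats::runif(n_sp, spurious_conf[1], spurious_conf[2]))
    }
    g <- do.call(rbind, rows)
    if (is.null(g))
      return(raw_grid(numeric(), numeric(), numeric(), numeric(),
                      numeric(), matrix(numeric(), 0, 1)))
    raw_grid(g$cx, g$cy, g$w, g$h, g$objectness,
             matrix(1, nrow(g), 1))
  }
  if (is.null(rng_seed)) build() else .with_seed(rng_seed, build())
}

#' Counter functions for the experiment harness
#'
#' `counter_ip()` wraps the image-processing pipeline ([count_seeds()]);
#' `counter_truth` reads the sample's ground truth (an oracle, for harness
#' validation); `counter_detector()` routes the sample's truth through a
#' raw grid and the detection post-processing chain.
#'
#' @param config a [count_config()] for the IP counter.
#' @param sample a `sim_sample`.
#' @param ... perturbation arguments passed to [raw_grid_from_truth()].
#' @return A function `sample -> integer count`.
#' @export
counter_ip <- function(config = count_config()) {
  function(sample) count_seeds(sample$image, config)$count
}

#' @rdname counter_ip
#' @export
counter_truth <- function(sample) sample$truth$true_count

#' @rdname counter_ip
#' @export
counter_detector <- function(...) {
  function(sample) {
    g <- raw_grid_from_truth(sample$truth, sample$config$image_w,
                             sample$config$image_h, ...)
    postprocess_detections(g, sample$config$image_w,
                           sample$config$image_h)$count
  }
}

#' Replicated counting-accuracy experiment
#'
#' For each target quantity, generates `replicates` synthetic images (each
#' with its own derived RNG seed), runs the supplied counter on each, and
#' summarizes the counts as mean +/- SE per quantity.  The per-image seed is
#' `master_seed + 1000 * (quantity_index - 1) + (replicate - 1)`, so the
#' whole experiment — and every individual image — is reproducible from the
#' master seed.
#'
#' @param quantities integer vector of true seed counts to test.
#' @param replicates images per quantity (>= 2).
#' @param config a [sim_config()] template; `n_seeds` and `rng_seed` are
#'   overridden per image.
#' @param counter a function `sim_sample -> count`; see [counter_ip()].
#' @param master_seed integer master seed.
#' @return A `count_experiment`: list with `records` (data frame: quantity,
#'   replicate, rng_seed, truth, count) and `summaries` (one
#'   [count_summary()] per quantity).
#' @export
run_count_experiment <- function(quantities = c(10, 70, 100), replicates = 6,
                                 config = sim_config(),
                                 counter = counter_ip(),
                                 master_seed = 1L) {
  if (replicates < 2) stop("run_count_experiment: need >= 2 replicates")
  recs <- list()
  for (qi in seq_along(quantities)) {
    for (r in seq_len(replicates)) {
      seed_i <- master_seed + 1000L * (qi - 1L) + (r - 1L)
      cfg <- config
      cfg$n_seeds <- as.integer(quantities[qi])
      cfg$rng_seed <- as.integer(seed_i)
      sample <- simulate_seed_image(cfg)
      cnt <- tryCatch(counter(sample), error = function(e)
        stop("run_count_experiment: counter failed on quantity ",
             quantities[qi], ", replicate ", r, " (seed ", seed_i, "): ",
             conditionMessage(e)))
      recs[[length(recs) + 1L]] <- data.frame(
        quantity = quantities[qi], replicate = r, rng_seed = seed_i,
        truth = sample$truth$true_count, count = cnt)
    }
  }
  records <- do.call(rbind, recs)
  summaries <- lapply(quantities, function(q) {
    count_summary(records$count[records$quantity == q], true_count = q)
  })
  names(summaries) <- as.character(quantities)
  structure(list(records = records, summaries = summaries,
                 master_seed = master_seed),
            class = "count_experiment")
}

#' @export
print.count_experiment <- function(x, ...) {
  cat("Counting-accuracy experiment (master seed", x$master_seed, ")\n")
  for (q in names(x$summaries)) {
    s <- x$summaries[[q]]
    cat(sprintf("  truth %3s seeds: %.2f ± %.2f over %d replicates\n",
                q, s$mean, s$se, s$n_replicates))
  }
  invisible(x)
}
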