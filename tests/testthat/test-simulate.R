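test_that("the generator is deterministic and ground-truth consistent", {
  cfg <- sim_config(n_seeds = 12, rng_seed = 99)
  a <- simulate_seed_image(cfg)
  b <- simulate_seed_image(cfg)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(unclass(a$true_mask), unclass(b$true_mask))
  expect_identical(a$truth$boxes, b$truth$boxes)
  # different seed, different scene
  c_ <- simulate_seed_image(sim_config(n_seeds = 12, rng_seed = 100))
  expect_false(identical(unclass(a$image), unclass(c_$image)))

  expect_equal(a$truth$true_count, 12L)
  expect_equal(nrow(a$truth$boxes), 12L)
  # non-touching: the true mask has exactly n components
  expect_length(label_components(a$true_mask), 12L)
  # every seed pixel lies inside some ground-truth box
  fg <- which(unclass(a$true_mask) == 1L, arr.ind = TRUE)
  x <- fg[, 2] - 1L; y <- fg[, 1] - 1L
  covered <- rep(FALSE, length(x))
  for (i in seq_len(nrow(a$truth$boxes))) {
    bx <- a$truth$boxes[i, ]
    covered <- covered | (x >= bx$x_min & x < bx$x_max &
                          y >= bx$y_min & y < bx$y_max)
  }
  expect_true(all(covered))
})

test_that("an empty scene is background only", {
  s <- simulate_seed_image(sim_config(n_seeds = 0, rng_seed = 1))
  expect_equal(s$truth$true_count, 0L)
  expect_equal(sum(s$true_mask), 0)
  expect_true(all(as.vector(unclass(s$image)) %in% c(245, 242)))  # bg RGB only
})

test_that("background intensities order black < orange < white", {
  means <- vapply(c("black_table", "orange_table", "white_a4"), function(bg) {
    s <- simulate_seed_image(sim_config(n_seeds = 0, background = bg,
                                        image_w = 50, image_h = 50))
    mean(to_grayscale(s$image))
  }, numeric(1))
  expect_true(means[1] < means[2] && means[2] < means[3])
})

test_that("infeasible placement fails with a capacity error", {
  cfg <- sim_config(image_w = 200, image_h = 200, n_seeds = 50,
                    min_separation_px = 80, rng_seed = 1)
  expect_error(simulate_seed_image(cfg), "min_separation_px")
  expect_error(sim_config(aspect_ratio = c(0.5, 2)), "aspect_ratio")
  expect_error(sim_config(background = "green_table"), "unknown background")
})

test_that("noise and illumination degrade pixels but not the truth", {
  clean <- simulate_seed_image(sim_config(n_seeds = 20, rng_seed = 5))
  noisy <- simulate_seed_image(sim_config(n_seeds = 20, rng_seed = 5,
                                          noise_sigma = 6,
                                          illumination_gradient = 0.05))
  expect_identical(clean$truth$boxes, noisy$truth$boxes)
  expect_false(identical(unclass(clean$image), unclass(noisy$image)))
  # moderate noise does not break the counter on well-separated seeds
  expect_equal(count_seeds(noisy$image)$count, 20)
})

test_that("perturbed raw grids behave as configured", {
  s <- simulate_seed_image(sim_config(n_seeds = 10, rng_seed = 8))
  W <- s$config$image_w; H <- s$config$image_h

  # duplicates have near-unit IoU with originals, and NMS removes them
  g_dup <- raw_grid_from_truth(s$truth, W, H, duplicate_rate = 1,
                               rng_seed = 2)
  expect_equal(nrow(g_dup), 20L)
  pp <- postprocess_detections(g_dup, W, H)
  expect_equal(pp$count, 10L)

  # spurious records carry sub-threshold confidence and are filtered out
  g_sp <- raw_grid_from_truth(ground_truth(s$truth$boxes[0, ], 0), W, H,
                              spurious_rate = 5, rng_seed = 3)
  expect_gt(nrow(g_sp), 0L)
  expect_equal(postprocess_detections(g_sp, W, H, tau = 0.25)$count, 0L)

  # jitter moves boxes but keeps them matchable at IoU 0.5
  g_j <- raw_grid_from_truth(s$truth, W, H, jitter_px = 1.5, rng_seed = 4)
  d <- nms(filter_confidence(decode_raw(g_j, W, H), 0.25), 0.45)
  m <- match_detections(d, s$truth, 0.5)
  expect_equal(m$fn, 0)
})

test_that("the experiment harness is reproducible and summarized per quantity", {
  ex <- run_count_experiment(quantities = c(3, 6), replicates = 3,
                             config = sim_config(image_w = 400,
                                                 image_h = 500),
                             counter = counter_truth, master_seed = 7)
  expect_equal(nrow(ex$records), 6L)
  # oracle counter: mean equals the quantity with zero spread
  expect_equal(ex$summaries[["3"]]$mean, 3)
  expect_equal(ex$summaries[["6"]]$mean, 6)
  expect_equal(ex$summaries[["3"]]$se, 0)
  # per-image seeds follow the documented derivation
  expect_equal(ex$records$rng_seed,
               c(7, 8, 9, 1007, 1008, 1009))
  # identical master seed reproduces the records exactly
  ex2 <- run_count_experiment(quantities = c(3, 6), replicates = 3,
                              config = sim_config(image_w = 400,
                                                  image_h = 500),
                              counter = counter_truth, master_seed = 7)
  expect_identical(ex$records, ex2$records)
  expect_output(print(ex), "master seed 7")

  # degenerate counter: mean 0, deviation equals the quantity
  ex0 <- run_count_experiment(quantities = 4, replicates = 2,
                              config = sim_config(image_w = 400,
                                                  image_h = 500),
                              counter = function(s) 0, master_seed = 1)
  expect_equal(ex0$summaries[["4"]]$mean, 0)
  expect_equal(ex0$summaries[["4"]]$mean_abs_dev, 4)
  expect_error(run_count_experiment(replicates = 1), "replicates")
})

test_that("detector-route counter matches truth on clean grids", {
  ex <- run_count_experiment(quantities = 5, replicates = 2,
                             config = sim_config(image_w = 400,
                                                 image_h = 500),
                             counter = counter_detector(rng_seed = 11),
                             master_seed = 2)
  expect_equal(ex$summaries[["5"]]$mean, 5)
  expect_equal(ex$summaries[["5"]]$se, 0)
})
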