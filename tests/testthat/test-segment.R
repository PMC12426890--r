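test_that("component labeling agrees with a flood-fill oracle", {
  set.seed(31)
  for (rep in 1:50) {
    mask <- matrix(rbinom(144, 1, runif(1, 0.2, 0.7)), 12, 12)
    for (conn in c(4L, 8L)) {
      regions <- label_components(mask, conn)
      ol <- oracle_label(mask, conn)
      expect_equal(length(regions), max(ol))
      expect_true(same_partition(regions_to_label(regions, 12, 12), ol))
    }
  }
})

test_that("labeling handles trivial masks and conserves foreground area", {
  expect_identical(label_components(matrix(0, 5, 5)), list())
  full <- label_components(matrix(1, 4, 4))
  expect_length(full, 1L)
  expect_equal(full[[1]]$pixel_count, 16L)
  set.seed(32)
  mask <- matrix(rbinom(400, 1, 0.4), 20, 20)
  regions <- label_components(mask, 8L)
  expect_equal(sum(vapply(regions, function(r) r$pixel_count, numeric(1))),
               sum(mask))
  expect_error(label_components(mask, 6L), "connectivity")
})

test_that("diagonal pixels merge under 8- but not 4-connectivity", {
  mask <- matrix(0, 4, 4); mask[1, 1] <- 1; mask[2, 2] <- 1
  expect_length(label_components(mask, 8L), 1L)
  expect_length(label_components(mask, 4L), 2L)
})

test_that("external contour tracing visits the outer border only", {
  # single pixel: degenerate one-vertex contour
  r1 <- trace_external_contour(pixel_region(1L, cbind(x = 3L, y = 4L)))
  expect_equal(nrow(r1$contour), 1L)
  expect_equal(as.integer(r1$contour[1, ]), c(3L, 4L))

  # solid 3x3 square: the 8 border pixels, each exactly once
  px <- as.matrix(expand.grid(x = 0:2, y = 0:2))
  r <- trace_external_contour(pixel_region(1L, px))
  expect_equal(nrow(r$contour), 8L)
  expect_setequal(paste(r$contour[, 1], r$contour[, 2]),
                  paste(px[, 1], px[, 2])[!(px[, 1] == 1 & px[, 2] == 1)])

  # interior holes are ignored: 5x5 with a punched centre traces like solid
  solid <- as.matrix(expand.grid(x = 0:4, y = 0:4))
  holed <- solid[!(solid[, 1] == 2 & solid[, 2] == 2), ]
  cs <- trace_external_contour(pixel_region(1L, solid))$contour
  ch <- trace_external_contour(pixel_region(1L, holed))$contour
  expect_equal(ch, cs)

  # orientation: non-negative shoelace sum in image coordinates
  i2 <- c(2:nrow(cs), 1L)
  expect_gte(sum(cs[, 1] * cs[i2, 2] - cs[i2, 1] * cs[, 2]), 0)
})

test_that("contours of random blobs cover exactly the boundary pixels", {
  set.seed(33)
  for (rep in 1:20) {
    mask <- draw_disc(matrix(0, 15, 15), runif(1, 5, 10), runif(1, 5, 10),
                      runif(1, 2, 4))
    regions <- label_components(mask, 8L)
    for (reg in regions) {
      ct <- trace_external_contour(reg)$contour
      # boundary pixels: members with at least one 4-neighbour outside
      pxs <- reg$pixels
      member <- matrix(FALSE, 17, 17)
      member[cbind(pxs[, 2] + 2L, pxs[, 1] + 2L)] <- TRUE
      boundary <- apply(pxs, 1, function(p) {
        x <- p[1] + 2L; y <- p[2] + 2L
        !(member[y - 1, x] && member[y + 1, x] &&
          member[y, x - 1] && member[y, x + 1])
      })
      expect_setequal(paste(ct[, 1], ct[, 2]),
                      paste(pxs[boundary, 1], pxs[boundary, 2]))
    }
  }
})

test_that("chain simplification keeps only straight-segment endpoints", {
  rect <- cbind(x = c(0:4, rep(4, 2), 4:0, rep(0, 2)),
                y = c(rep(0, 5), 1:2, rep(3, 5), 2:1))
  out <- simplify_chain(rect)
  expect_equal(nrow(out), 4L)
  expect_setequal(paste(out[, 1], out[, 2]), c("0 0", "4 0", "4 3", "0 3"))

  tri <- cbind(c(0, 4, 0), c(0, 0, 3))
  expect_equal(simplify_chain(tri), tri)

  set.seed(34)
  for (rep in 1:30) {
    mask <- draw_disc(matrix(0, 12, 12), runif(1, 4, 8), runif(1, 4, 8),
                      runif(1, 2, 4))
    reg <- label_components(mask, 8L)[[1]]
    poly <- trace_external_contour(reg)$contour
    expect_equal(simplify_chain(poly), oracle_simplify(poly))
  }
})

test_that("area filtering keeps the configured window and logs removals", {
  regions <- list(
    pixel_region(1L, cbind(x = 0:1, y = c(0L, 0L))),                  # area 2
    pixel_region(2L, as.matrix(expand.grid(x = 0:9, y = 0:4))),      # area 50
    pixel_region(3L, as.matrix(expand.grid(x = 0:39, y = 0:19))))    # area 800
  expect_length(filter_regions(regions), 3L)
  kept <- filter_regions(regions, 10, 500)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$pixel_count, 50L)
  expect_equal(attr(kept, "n_removed"), 2L)
  expect_error(filter_regions(regions, 10, 5), "min_area")
})

test_that("region sorting is lexicographic on (y_min, x_min, label)", {
  mk <- function(label, x, y) pixel_region(label, cbind(x = x, y = y))
  a <- mk(1L, 4L, 5L); b <- mk(2L, 9L, 2L); c <- mk(3L, 3L, 2L)
  got <- sort_regions(list(a, b, c))
  expect_equal(vapply(got, function(r) r$label, integer(1)), c(3L, 2L, 1L))

  set.seed(35)
  for (rep in 1:20) {
    regs <- lapply(1:8, function(i)
      mk(i, sample(0:5, 1), sample(0:5, 1)))
    perm <- sample(regs)
    got <- sort_regions(perm)
    key <- vapply(perm, function(r)
      sprintf("%03d-%03d-%03d", r$bbox[["y_min"]], r$bbox[["x_min"]],
              r$label), character(1))
    expect_equal(vapply(got, function(r) r$label, integer(1)),
                 vapply(perm[order(key)], function(r) r$label, integer(1)))
  }
})

test_that("feature extraction converts to millimetres correctly", {
  reg <- pixel_region(1L, as.matrix(expand.grid(x = 10:59, y = 20:49)))
  f <- extract_features(reg, mm_per_px = 0.1, seed_id = 7L)
  expect_equal(f$length_mm, 5.0)
  expect_equal(f$width_mm, 3.0)
  expect_equal(f$aspect_ratio, 5 / 3)
  expect_equal(f$area_px, 1500L)
  expect_equal(f$seed_id, 7L)
  # square region has aspect exactly 1
  sq <- pixel_region(1L, as.matrix(expand.grid(x = 0:9, y = 0:9)))
  expect_equal(extract_features(sq, 0.3)$aspect_ratio, 1.0)
  # doubling the scale doubles lengths, aspect unchanged
  f2 <- extract_features(reg, mm_per_px = 0.2)
  expect_equal(f2$length_mm, 2 * f$length_mm)
  expect_equal(f2$width_mm, 2 * f$width_mm)
  expect_equal(f2$aspect_ratio, f$aspect_ratio)
  expect_error(extract_features(reg, mm_per_px = 0), "mm_per_px")
})

test_that("4-connected labeling agrees with an established imaging library", {
  set.seed(36)
  for (rep in 1:10) {
    mask <- matrix(rbinom(400, 1, 0.45), 20, 20)
    expect_equal(length(label_components(mask, 4L)),
                 max(EBImage::bwlabel(mask)))
  }
})
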