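#' Image containers
#'
#' Images are plain base-R arrays addressed row-major in concept but stored as
#' standard R matrices/arrays: a colour image is an H x W x 3 integer array of
#' 8-bit values (0-255), a grayscale image an H x W matrix of 8-bit values,
#' and a binary mask an H x W matrix of 0/1.  Coordinates throughout the
#' package are 0-based with origin at the top-left: x is the column index,
#' y is the row index, and bounding boxes are half-open
#' `[x_min, x_max) x [y_min, y_max)`.
#'
#' @param pixels numeric array; H x W x 3 for colour, H x W for gray.
#' @return An object of class `raster_image` (H x W x 3) or `gray_image`
#'   (H x W matrix).
#' @name image-containers
NULL

#' @rdname image-containers
#' @export
raster_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("raster_image: 'pixels' must be an H x W x 3 array")
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L)
    stop("raster_image: image must have at least one pixel")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("raster_image: channel values must lie in [0, 255]")
  structure(pixels, class = "raster_image")
}

#' @rdname image-containers
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels))
    stop("gray_image: 'pixels' must be an H x W matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("gray_image: image must have at least one pixel")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("gray_image: values must lie in [0, 255]")
  structure(pixels, class = "gray_image")
}

#' Binary foreground mask
#'
#' @param pixels H x W matrix of 0/1.
#' @param polarity which side of the threshold became foreground:
#'   `"bright"` (pixels above threshold) or `"dark"` (pixels at or below).
#' @return A `binary_mask`: 0/1 matrix with a `polarity` attribute.
#' @export
binary_mask <- function(pixels, polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  if (!is.matrix(pixels) || !all(pixels %in% c(0, 1)))
    stop("binary_mask: 'pixels' must be a 0/1 matrix")
  structure(pixels, polarity = polarity, class = "binary_mask")
}

#' Convert a colour image to 8-bit grayscale
#'
#' Luminance is the ITU-R BT.601 combination 0.299 R + 0.587 G + 0.114 B,
#' rounded half-up to the nearest integer.
#'
#' @param img a `raster_image` or H x W x 3 array of 8-bit values.
#' @return A `gray_image` of the same height and width.
#' @examples
#' g <- to_grayscale(raster_image(array(255, c(2, 2, 3))))
#' stopifnot(all(g == 255))
#' @export
to_grayscale <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L)
    stop("to_grayscale: expected an H x W x 3 image")
  if (prod(dim(img)) == 0L)
    stop("to_grayscale: empty image")
  y <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  # round half-up (base round() is half-to-even)
  gray_image(matrix(floor(y + 0.5), nrow = dim(img)[1]))
}

# reflect-padded index vector: mirrors without repeating the edge sample
.reflect_idx <- function(n, r) {
  idx <- seq_len(n + 2L * r) - r
  idx <- ifelse(idx < 1L, 2L - idx, idx)
  idx <- ifelse(idx > n, 2L * n - idx, idx)
  idx
}

#' One-dimensional Gaussian kernel weights
#'
#' @param kernel_px odd window size in pixels.
#' @param sigma standard deviation in pixels.
#' @return Numeric vector of length `kernel_px` summing to 1.
#' @export
gaussian_kernel <- function(kernel_px, sigma) {
  if (kernel_px < 1L || kernel_px %% 2L == 0L)
    stop("gaussian_kernel: 'kernel_px' must be a positive odd integer")
  if (sigma <= 0) stop("gaussian_kernel: 'sigma' must be > 0")
  x <- seq.int(-(kernel_px %/% 2L), kernel_px %/% 2L)
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

#' Gaussian smoothing of a grayscale image
#'
#' Separable Gaussian convolution with reflect border padding; kernel weights
#' are normalized to sum 1, so a constant image is returned unchanged.  The
#' result is rounded back to 8-bit.
#'
#' @param img a `gray_image` or numeric matrix.
#' @param kernel_px odd kernel size (default 5).
#' @param sigma Gaussian standard deviation in pixels (default 1).
#' @return A `gray_image` of identical dimensions.
#' @export
gaussian_blur <- function(img, kernel_px = 5L, sigma = 1.0) {
  if (!is.matrix(img)) stop("gaussian_blur: expected a grayscale matrix")
  w <- gaussian_kernel(kernel_px, sigma)
  r <- kernel_px %/% 2L
  out <- unclass(img) * 1.0
  if (r > 0L) {
    # vertical pass: weighted sum of row-shifted copies of the padded image
    pad <- out[.reflect_idx(nrow(out), r), , drop = FALSE]
    acc <- matrix(0, nrow(out), ncol(out))
    for (k in seq_len(kernel_px))
      acc <- acc + w[k] * pad[(k - 1L) + seq_len(nrow(out)), , drop = FALSE]
    # horizontal pass
    pad <- acc[, .reflect_idx(ncol(out), r), drop = FALSE]
    acc2 <- matrix(0, nrow(out), ncol(out))
    for (k in seq_len(kernel_px))
      acc2 <- acc2 + w[k] * pad[, (k - 1L) + seq_len(ncol(out)), drop = FALSE]
    out <- acc2
  }
  gray_image(matrix(floor(pmin(pmax(out, 0), 255) + 0.5), nrow = nrow(img)))
}

#' Otsu's automatic threshold
#'
#' Scans all 256 candidate levels of the 8-bit histogram and returns the level
#' maximizing the between-class variance; ties are broken by the smallest
#' level.  Pixels with value <= level fall in the lower class.
#'
#' @param img a `gray_image` or numeric matrix of 8-bit values.
#' @return Integer threshold level in 0..255.
#' @export
otsu_threshold <- function(img) {
  v <- as.integer(unclass(img))
  if (length(unique(v)) < 2L)
    stop("otsu_threshold: degenerate histogram (constant image)")
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)                 # P(class0) for t = 0..255
  mu <- cumsum(p * (0:255))          # partial means
  mu_t <- mu[256]
  # between-class variance for thresholds t = 0..254 (t = 255 puts all in one class)
  t <- 1:255
  denom <- omega[t] * (1 - omega[t])
  sigma_b <- ifelse(denom > 0, (mu_t * omega[t] - mu[t])^2 / denom, -Inf)
  as.integer(which.max(sigma_b) - 1L)
}

#' Binarize a grayscale image
#'
#' `bright` marks pixels strictly above `level` as foreground; `dark` marks
#' pixels at or below `level`.  `auto` picks whichever polarity yields the
#' minority foreground (< 0.5 of the pixels), since seeds occupy a small
#' fraction of a counting image on any of the supported backgrounds.
#'
#' @param img a `gray_image` or numeric matrix.
#' @param level threshold level in [0, 255].
#' @param polarity `"bright"`, `"dark"`, or `"auto"`.
#' @return A `binary_mask` recording the polarity used.
#' @export
binarize <- function(img, level, polarity = c("auto", "bright", "dark")) {
  polarity <- match.arg(polarity)
  if (level < 0 || level > 255) stop("binarize: 'level' must be in [0, 255]")
  m <- unclass(img)
  bright <- (m > level) * 1
  if (polarity == "auto") {
    polarity <- if (mean(bright) < 0.5) "bright" else "dark"
  }
  px <- if (polarity == "bright") bright else 1 - bright
  binary_mask(px, polarity)
}

#' Read / write PNG images as 8-bit arrays
#'
#' Thin wrappers around the \pkg{png} package mapping to the package's
#' integer 0-255 containers.  Grayscale PNGs are promoted to 3 channels on
#' read; alpha channels are dropped.
#'
#' @param path file path.
#' @param img image to write (`raster_image`, `gray_image`, or matrix/array).
#' @return `read_image_png` returns a `raster_image`.
#' @export
read_image_png <- function(path) {
  if (!file.exists(path)) stop("read_image_png: cannot read '", path, "'")
  a <- png::readPNG(path)
  if (is.matrix(a)) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  raster_image(array(as.integer(floor(a * 255 + 0.5)), dim = dim(a)))
}

#' @rdname read_image_png
#' @export
write_image_png <- function(img, path) {
  a <- unclass(img)
  if (is.matrix(a)) a <- array(rep(a, 3L), c(dim(a), 3L))
  png::writePNG(a / 255, path)
  invisible(path)
}
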