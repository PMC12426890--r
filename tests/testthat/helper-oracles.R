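# Brute-force reference implementations, independent of the package code
# paths they check.

# reflect-padded index (re-derived here, not shared with the implementation)
oracle_reflect <- function(n, r) {
  idx <- seq_len(n + 2L * r) - r
  idx <- ifelse(idx < 1L, 2L - idx, idx)
  ifelse(idx > n, 2L * n - idx, idx)
}

# dense (non-separable) 2-D Gaussian convolution with reflect padding
oracle_blur <- function(img, kernel_px, sigma) {
  r <- kernel_px %/% 2L
  x <- seq.int(-r, r)
  w1 <- exp(-x^2 / (2 * sigma^2)); w1 <- w1 / sum(w1)
  K <- outer(w1, w1)
  H <- nrow(img); W <- ncol(img)
  pad <- img[oracle_reflect(H, r), oracle_reflect(W, r), drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W))
    out[i, j] <- sum(K * pad[i:(i + kernel_px - 1L), j:(j + kernel_px - 1L)])
  matrix(floor(pmin(pmax(out, 0), 255) + 0.5), H, W)
}

# exhaustive Otsu: try all 256 levels, recompute class variances directly
oracle_otsu <- function(img) {
  v <- as.integer(img)
  best <- -Inf; best_t <- NA_integer_
  for (t in 0:255) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    sb <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-12) { best <- sb; best_t <- t }
  }
  best_t
}

# stack-based flood fill labeling
oracle_label <- function(mask, connectivity) {
  H <- nrow(mask); W <- ncol(mask)
  nb <- if (connectivity == 4L) rbind(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))
        else as.matrix(expand.grid(dr = -1:1, dc = -1:1))[-5, ]
  lab <- matrix(0L, H, W); cur <- 0L
  for (r0 in seq_len(H)) for (c0 in seq_len(W)) {
    if (mask[r0, c0] != 1 || lab[r0, c0] != 0L) next
    cur <- cur + 1L
    stack <- list(c(r0, c0)); lab[r0, c0] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        rr <- p[1] + nb[k, 1]; cc <- p[2] + nb[k, 2]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            mask[rr, cc] == 1 && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# do two labelings induce the same partition of the foreground pixels?
same_partition <- function(lab_a, lab_b) {
  fg <- lab_a > 0 | lab_b > 0
  if (!all((lab_a > 0) == (lab_b > 0))) return(FALSE)
  pairs <- paste(lab_a[fg], lab_b[fg])
  length(unique(pairs)) == length(unique(lab_a[fg])) &&
    length(unique(pairs)) == length(unique(lab_b[fg]))
}

# regions list -> label matrix, for comparison against oracle_label
regions_to_label <- function(regions, H, W) {
  lab <- matrix(0L, H, W)
  for (r in regions)
    lab[cbind(r$pixels[, 2] + 1L, r$pixels[, 1] + 1L)] <- r$label
  lab
}

# IoU by counting unit cells of a discrete grid (integer boxes only)
oracle_iou_pixels <- function(a, b, grid = 40L) {
  in_box <- function(bx) {
    m <- matrix(FALSE, grid, grid)
    xs <- seq.int(bx[1], bx[3] - 1L); ys <- seq.int(bx[2], bx[4] - 1L)
    m[ys + 1L, xs + 1L] <- TRUE
    m
  }
  A <- in_box(a); B <- in_box(b)
  if (!any(A & B)) return(0)
  sum(A & B) / sum(A | B)
}

# all-point-interpolated AP recomputed rank by rank
oracle_ap <- function(is_tp, n_gt) {
  if (n_gt == 0) return(if (length(is_tp)) 0 else 1)
  if (!length(is_tp)) return(0)
  tp <- cumsum(is_tp); fp <- cumsum(!is_tp)
  prec <- tp / (tp + fp); rec <- tp / n_gt
  ap <- 0; prev_r <- 0
  for (k in which(is_tp)) {
    r <- rec[k]
    ap <- ap + (r - prev_r) * max(prec[rec >= r])
    prev_r <- r
  }
  ap
}

# collinearity scan: keep vertex when the triangle with its closed-polygon
# neighbours has nonzero area
oracle_simplify <- function(poly) {
  n <- nrow(poly)
  if (n <= 2L) return(poly)
  keep <- vapply(seq_len(n), function(i) {
    p <- poly[if (i == 1L) n else i - 1L, ]
    q <- poly[i, ]
    s <- poly[if (i == n) 1L else i + 1L, ]
    area2 <- abs(p[1] * (q[2] - s[2]) + q[1] * (s[2] - p[2]) +
                 s[1] * (p[2] - q[2]))
    area2 > 0
  }, logical(1))
  if (!any(keep)) return(poly[1L, , drop = FALSE])
  poly[keep, , drop = FALSE]
}

# draw a filled circle into a 0/1 matrix (for hand-built scenes)
draw_disc <- function(mask, cx, cy, radius) {
  H <- nrow(mask); W <- ncol(mask)
  for (y in seq_len(H)) for (x in seq_len(W))
    if ((x - cx)^2 + (y - cy)^2 <= radius^2) mask[y, x] <- 1
  mask
}

# hand-built colour image: dark discs on a light background
disc_image <- function(H, W, centers, radius, bg = 245, fg = 80) {
  m <- matrix(0, H, W)
  for (ct in centers) m <- draw_disc(m, ct[1], ct[2], radius)
  array(rep(bg * (1 - m) + fg * m, 3L), c(H, W, 3L))
}
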