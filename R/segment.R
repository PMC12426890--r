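#' A segmented connected pixel region
#'
#' @param label positive integer label.
#' @param pixels integer matrix with columns `x`, `y` (0-based pixel
#'   coordinates) listing the member pixels.
#' @return A `pixel_region`: list with `label`, `pixel_count`, `pixels`,
#'   `bbox` (half-open `c(x_min, y_min, x_max, y_max)`), and `contour`
#'   (filled by [trace_external_contour()], `NULL` until then).
#' @export
pixel_region <- function(label, pixels) {
  if (!is.matrix(pixels) || ncol(pixels) != 2L || nrow(pixels) < 1L)
    stop("pixel_region: 'pixels' must be a non-empty 2-column (x, y) matrix")
  bbox <- c(x_min = min(pixels[, 1]), y_min = min(pixels[, 2]),
            x_max = max(pixels[, 1]) + 1L, y_max = max(pixels[, 2]) + 1L)
  structure(list(label = as.integer(label), pixel_count = nrow(pixels),
                 pixels = pixels, bbox = bbox, contour = NULL),
            class = "pixel_region")
}

#' Label connected foreground components
#'
#' Partitions the foreground pixels of a binary mask into maximal connected
#' regions under 4- or 8-neighbour adjacency.  Internally the mask is
#' decomposed into horizontal runs which are merged across adjacent rows with
#' a union-find, so cost scales with the number of runs rather than the
#' number of pixels.
#'
#' @param mask a `binary_mask` or 0/1 matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return List of [pixel_region()] objects; empty list for an all-zero mask.
#'   Label order follows the raster-scan order of each region's first run and
#'   carries no meaning before [sort_regions()].
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L))
    stop("label_components: connectivity must be 4 or 8")
  m <- unclass(mask)
  storage.mode(m) <- "integer"
  H <- nrow(m); W <- ncol(m)
  if (sum(m) == 0L) return(list())
  # horizontal runs: work on the transpose so image rows are columns
  mt <- t(m)
  up <- rbind(0L, mt[-W, , drop = FALSE])
  dn <- rbind(mt[-1, , drop = FALSE], 0L)
  si <- which(mt == 1L & up == 0L, arr.ind = TRUE)   # run starts: (x, row)
  ei <- which(mt == 1L & dn == 0L, arr.ind = TRUE)   # run ends, same order
  n_run <- nrow(si)
  run_row <- si[, 2]; run_x0 <- si[, 1]; run_x1 <- ei[, 1]

  # union-find with path halving over runs
  parent <- seq_len(n_run)
  uf_find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  slack <- if (connectivity == 8L) 1L else 0L
  by_row <- split(seq_len(n_run), run_row)
  rows <- as.integer(names(by_row))
  for (ri in seq_along(rows)[-1]) {
    if (rows[ri] - rows[ri - 1] != 1L) next
    cur <- by_row[[ri]]; prv <- by_row[[ri - 1]]
    for (a in cur) for (b in prv) {
      if (run_x0[a] <= run_x1[b] + slack && run_x1[a] >= run_x0[b] - slack) {
        ra <- uf_find(a); rb <- uf_find(b)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  root <- vapply(seq_len(n_run), uf_find, integer(1))
  lab <- match(root, unique(root))
  regions <- vector("list", max(lab))
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k)
    xs <- unlist(lapply(idx, function(i) run_x0[i]:run_x1[i]), use.names = FALSE)
    ys <- rep.int(run_row[idx], run_x1[idx] - run_x0[idx] + 1L)
    regions[[k]] <- pixel_region(k, cbind(x = xs - 1L, y = ys - 1L))
  }
  regions
}

#' Trace the external contour of a region
#'
#' Moore-neighbour border following on the region's own pixel set: returns the
#' ordered closed outer boundary, ignoring any interior holes.  Orientation is
#' normalized so the shoelace sum over (x, y) image coordinates is
#' non-negative (counter-clockwise under the image axes).  A single-pixel
#' region yields a degenerate one-vertex contour.
#'
#' @param region a [pixel_region()].
#' @return The region with its `contour` field set to an n x 2 (x, y) matrix
#'   of boundary pixel coordinates.
#' @export
trace_external_contour <- function(region) {
  px <- region$pixels
  x0 <- min(px[, 1]); y0 <- min(px[, 2])
  w <- max(px[, 1]) - x0 + 1L; h <- max(px[, 2]) - y0 + 1L
  # local mask with 1-pixel background border
  m <- matrix(0L, h + 2L, w + 2L)
  m[cbind(px[, 2] - y0 + 2L, px[, 1] - x0 + 2L)] <- 1L
  if (nrow(px) == 1L) {
    region$contour <- px[1, , drop = FALSE]
    return(region)
  }
  # start: topmost then leftmost foreground pixel (raster order)
  start <- which(t(m) == 1L, arr.ind = TRUE)[1, ]     # (x, y) in local coords
  sx <- start[1]; sy <- start[2]
  # clockwise Moore neighbourhood starting at west
  dx <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dy <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  cx <- sx; cy <- sy
  back <- 1L                                          # came from the west
  contour <- matrix(0L, 0L, 2L)
  first_dir <- NA_integer_
  repeat {
    contour <- rbind(contour, c(cx, cy))
    found <- FALSE
    d <- back
    for (step in 1:8) {
      d <- d %% 8L + 1L
      nx <- cx + dx[d]; ny <- cy + dy[d]
      if (m[ny, nx] == 1L) { found <- TRUE; break }
    }
    if (!found) break                                 # isolated pixel
    if (is.na(first_dir)) first_dir <- d
    # Jacob's stopping criterion: back at start, leaving in the same direction
    if (nx == sx && ny == sy && nrow(contour) > 1L) {
      d2 <- d
      # peek the direction the next step would take out of the start pixel
      bk2 <- (d2 + 3L) %% 8L + 1L
      dd <- bk2
      for (step in 1:8) {
        dd <- dd %% 8L + 1L
        if (m[sy + dy[dd], sx + dx[dd]] == 1L) break
      }
      if (dd == first_dir) break
    }
    cx <- nx; cy <- ny
    back <- (d + 3L) %% 8L + 1L                       # reverse of d
    if (nrow(contour) > 4L * nrow(px)) break          # safety bound
  }
  contour <- unique(contour)
  ct <- cbind(contour[, 1] + x0 - 2L, contour[, 2] + y0 - 2L)
  colnames(ct) <- c("x", "y")
  # normalize orientation: shoelace sum >= 0 in image coordinates
  if (nrow(ct) >= 3L) {
    i2 <- c(2:nrow(ct), 1L)
    s <- sum(ct[, 1] * ct[i2, 2] - ct[i2, 1] * ct[, 2])
    if (s < 0) ct <- ct[nrow(ct):1, , drop = FALSE]
  }
  region$contour <- ct
  region
}

#' Compress a contour to straight-segment endpoints
#'
#' Removes every vertex collinear with its two neighbours (closed-polygon
#' wraparound), so only endpoints of straight runs remain; the polygon shape
#' is preserved exactly.  An axis-aligned rectangle boundary reduces to its
#' 4 corners.
#'
#' @param polygon n x 2 matrix of vertices of a closed polygon.
#' @return Matrix of the surviving vertices, in the original order.
#' @export
simplify_chain <- function(polygon) {
  n <- nrow(polygon)
  if (is.null(n) || n <= 2L) return(polygon)
  prv <- polygon[c(n, 1:(n - 1L)), , drop = FALSE]
  nxt <- polygon[c(2:n, 1L), , drop = FALSE]
  cross <- (polygon[, 1] - prv[, 1]) * (nxt[, 2] - polygon[, 2]) -
           (polygon[, 2] - prv[, 2]) * (nxt[, 1] - polygon[, 1])
  keep <- cross != 0
  if (!any(keep)) return(polygon[1L, , drop = FALSE])
  polygon[keep, , drop = FALSE]
}

#' Reject regions outside an area window
#'
#' Speck-noise / oversize rejection: keeps regions whose pixel area lies in
#' `[min_area_px, max_area_px]`.  The number of removals is attached as the
#' `n_removed` attribute.
#'
#' @param regions list of [pixel_region()].
#' @param min_area_px,max_area_px inclusive area bounds in pixels.
#' @return Filtered list with attribute `n_removed`.
#' @export
filter_regions <- function(regions, min_area_px = 0, max_area_px = Inf) {
  if (min_area_px < 0 || min_area_px > max_area_px)
    stop("filter_regions: need 0 <= min_area_px <= max_area_px")
  areas <- vapply(regions, function(r) r$pixel_count, numeric(1))
  keep <- areas >= min_area_px & areas <= max_area_px
  structure(regions[keep], n_removed = sum(!keep))
}

#' Order regions top-to-bottom
#'
#' Sorts ascending by bounding-box `y_min`, ties broken by `x_min`, then by
#' label, giving the spatial top-to-bottom, left-to-right numbering used for
#' seed identifiers.
#'
#' @param regions list of [pixel_region()].
#' @return The same regions, reordered.
#' @export
sort_regions <- function(regions) {
  if (length(regions) == 0L) return(regions)
  ys <- vapply(regions, function(r) r$bbox[["y_min"]], numeric(1))
  xs <- vapply(regions, function(r) r$bbox[["x_min"]], numeric(1))
  ls <- vapply(regions, function(r) r$label, integer(1))
  regions[order(ys, xs, ls)]
}
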