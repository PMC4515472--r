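# Core image containers and per-plane operations shared by all image-based
# assays. All pixel coordinates are (row, col), 0-based, pixel-centre
# semantics; physical areas are reported in um^2 via pixel_size_um^2.

CHANNEL_NAMES <- c("DAPI", "GFP", "RFP", "PH3", "R", "G", "B")

#' Single-channel image plane
#'
#' A 2-D non-negative intensity grid with an isotropic physical pixel size and
#' a channel label. The plane is stored as a plain numeric matrix (rows x cols)
#' carrying `pixel_size_um` and `channel` attributes, so all base matrix
#' operations apply.
#'
#' @param pixels numeric matrix of intensities, all `>= 0`.
#' @param pixel_size_um micrometres per pixel (isotropic), `> 0`.
#' @param channel channel label, one of `"DAPI"`, `"GFP"`, `"RFP"`, `"PH3"`,
#'   `"R"`, `"G"`, `"B"`.
#' @return An object of class `image_plane`.
#' @export
image_plane <- function(pixels, pixel_size_um = 1, channel = "DAPI") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stopf("image plane must have >= 1 row and column")
  if (any(!is.finite(pixels)) || any(pixels < 0)) stopf("intensities must be finite and >= 0")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0)
    stopf("pixel_size_um must be a single value > 0")
  channel <- match.arg(channel, CHANNEL_NAMES)
  structure(pixels, pixel_size_um = pixel_size_um, channel = channel,
            class = c("image_plane", class(pixels)))
}

#' Physical pixel size of an image plane
#'
#' @param img an [image_plane] (or any object carrying a `pixel_size_um`
#'   attribute).
#' @return Micrometres per pixel; 1 when the attribute is absent.
#' @export
pixel_size <- function(img) {
  ps <- attr(img, "pixel_size_um")
  if (is.null(ps)) 1 else ps
}

# Rebuild an image_plane from raw pixels, inheriting metadata from `template`.
plane_like <- function(pixels, template, clip_zero = FALSE) {
  if (clip_zero) pixels[pixels < 0] <- 0
  image_plane(pixels, pixel_size_um = pixel_size(template),
              channel = attr(template, "channel") %||% "DAPI")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane> %s, %d x %d px, %.4g um/px, range [%.4g, %.4g]\n",
              attr(x, "channel"), nrow(x), ncol(x), pixel_size(x), min(x), max(x)))
  invisible(x)
}

#' Multi-channel z-stack
#'
#' Named collection of channels, each an ordered list of [image_plane]
#' z-planes of identical shape. This is the raw input of the quantification
#' pipeline: a confocal-style acquisition with one or more of DAPI/GFP/RFP/PH3.
#'
#' @param channels named list; each element either a list of matrices /
#'   `image_plane`s (z-planes) or a rows x cols x z array.
#' @param pixel_size_um micrometres per pixel, shared by all channels.
#' @param metadata free-form provenance list (kept verbatim).
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(channels, pixel_size_um = 1, metadata = list()) {
  if (length(channels) < 1L || is.null(names(channels)) || any(names(channels) == ""))
    stopf("channels must be a non-empty named list")
  nms <- names(channels)
  channels <- lapply(seq_along(channels), function(i) {
    ch <- channels[[i]]
    if (is.array(ch) && length(dim(ch)) == 3L)
      ch <- lapply(seq_len(dim(ch)[3]), function(z) ch[, , z])
    if (is.matrix(ch)) ch <- list(ch)
    lapply(ch, function(p) image_plane(unclass(as.matrix(p)), pixel_size_um, nms[i]))
  })
  names(channels) <- nms
  shapes <- unique(lapply(channels, function(ch) c(dim(ch[[1]]), length(ch))))
  if (length(shapes) != 1L) stopf("all channels must share plane shape and plane count")
  structure(list(channels = channels, pixel_size_um = pixel_size_um, metadata = metadata),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]][[1]])
  cat(sprintf("<channel_stack> %s | %d x %d px x %d z | %.4g um/px\n",
              paste(names(x$channels), collapse = ", "),
              d[1], d[2], length(x$channels[[1]]), x$pixel_size_um))
  invisible(x)
}

#' Maximum-intensity projection of one channel
#'
#' Collapses the z-planes of `channel` to a single plane by the per-pixel
#' maximum over z, the standard reconstruction for confocal stacks acquired
#' at ~1 um z-spacing.
#'
#' @param stack a [channel_stack].
#' @param channel channel name present in the stack.
#' @return An [image_plane]; `pixel_size_um` is preserved.
#' @export
max_project <- function(stack, channel) {
  if (!inherits(stack, "channel_stack")) stopf("stack must be a channel_stack")
  if (!channel %in% names(stack$channels))
    stopf("channel '%s' not in stack (has: %s)", channel,
          paste(names(stack$channels), collapse = ", "))
  planes <- stack$channels[[channel]]
  out <- Reduce(pmax, lapply(planes, unclass))
  image_plane(out, stack$pixel_size_um, channel)
}

#' Percentile-based levels adjustment
#'
#' Linearly rescales intensities so that the `low_pct` percentile maps to 0
#' and the `high_pct` percentile to `full_scale`, clipping to
#' `[0, full_scale]`. A constant input cannot be stretched and comes back as
#' an all-zero plane with a warning.
#'
#' @param img an [image_plane] or numeric matrix.
#' @param low_pct,high_pct percentiles in `[0, 100]` with `low_pct < high_pct`.
#'   Defaults (1, 99) are robust to hot pixels.
#' @param full_scale output full-scale value (default 1).
#' @return The rescaled [image_plane].
#' @export
adjust_levels <- function(img, low_pct = 1, high_pct = 99, full_scale = 1) {
  if (!(low_pct >= 0 && low_pct < high_pct && high_pct <= 100))
    stopf("need 0 <= low_pct < high_pct <= 100")
  x <- unclass(as.matrix(img))
  q <- quantile(x, c(low_pct, high_pct) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    warnf("constant image within the chosen percentiles; returning all zeros")
    return(plane_like(x * 0, img))
  }
  y <- (x - q[1]) / (q[2] - q[1]) * full_scale
  y[y < 0] <- 0
  y[y > full_scale] <- full_scale
  plane_like(y, img)
}

#' Median-filter denoising
#'
#' Replaces each pixel by the median over a square window of side
#' `2 * radius_px + 1`; at the image border the window is truncated to the
#' pixels that exist. Radius 0 is the identity. A median filter removes the
#' impulse noise typical of photon-counting detectors while preserving
#' nucleus edges.
#'
#' @param img an [image_plane] or numeric matrix.
#' @param radius_px non-negative integer window radius (default 1).
#' @return The filtered [image_plane].
#' @export
denoise <- function(img, radius_px = 1L) {
  radius_px <- as.integer(radius_px)
  if (radius_px < 0L) stopf("radius_px must be >= 0")
  x <- unclass(as.matrix(img))
  if (radius_px == 0L) return(plane_like(x, img))
  nr <- nrow(x); nc <- ncol(x)
  offs <- expand.grid(dr = -radius_px:radius_px, dc = -radius_px:radius_px)
  stack <- matrix(NA_real_, nr * nc, nrow(offs))
  pad <- matrix(NA_real_, nr + 2L * radius_px, nc + 2L * radius_px)
  pad[radius_px + seq_len(nr), radius_px + seq_len(nc)] <- x
  for (k in seq_len(nrow(offs))) {
    stack[, k] <- pad[radius_px + offs$dr[k] + seq_len(nr),
                      radius_px + offs$dc[k] + seq_len(nc)]
  }
  med <- apply(stack, 1L, median, na.rm = TRUE)
  plane_like(matrix(med, nr, nc), img)
}

#' Polygonal region of interest
#'
#' Ordered polygon vertices in (row, col), 0-based pixel-centre coordinates,
#' mirroring the hand-drawn gut outlines of the original workflow. The
#' polygon must be simple (non-self-intersecting) and have at least three
#' vertices.
#'
#' @param vertices n x 2 numeric matrix (or coercible) of (row, col) vertices.
#' @param closed logical; the polygon is treated as closed regardless, the
#'   flag is kept for provenance.
#' @return An object of class `roi`.
#' @export
roi_polygon <- function(vertices, closed = TRUE) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || nrow(v) < 3L) stopf("roi needs >= 3 (row, col) vertices")
  storage.mode(v) <- "double"
  if (polygon_self_intersects(v)) stopf("roi polygon must be simple (non-self-intersecting)")
  structure(list(vertices = v, closed = isTRUE(closed)), class = "roi")
}

#' Read a polygon ROI from JSON
#'
#' @param path JSON file holding a list of `[row, col]` vertex pairs.
#' @return An [roi_polygon].
#' @export
read_roi_json <- function(path) {
  v <- jsonlite::fromJSON(path)
  roi_polygon(as.matrix(v))
}

# Shoelace signed area of an n x 2 (row, col) vertex matrix.
shoelace_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

# Proper-crossing test for non-adjacent polygon edges (O(n^2), n is small).
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1L), ])
  cross <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through closure
      d1 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Rasterise an ROI to a binary mask
#'
#' Marks the pixels of a `rows x cols` frame whose 0-based centres fall
#' inside the polygon under the even-odd rule; pixels exactly on the boundary
#' are included.
#'
#' @param roi an [roi_polygon].
#' @param shape integer vector `c(rows, cols)`.
#' @return Logical matrix of dimension `shape`.
#' @export
roi_mask <- function(roi, shape) {
  if (!inherits(roi, "roi")) roi <- roi_polygon(roi)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L)) stopf("shape must be positive (rows, cols)")
  v <- roi$vertices
  if (shoelace_area(v) == 0) stopf("degenerate (zero-area) roi polygon")
  pr <- rep(seq_len(shape[1]) - 1, times = shape[2])
  pc <- rep(seq_len(shape[2]) - 1, each = shape[1])
  inside <- points_in_polygon(pr, pc, v)
  matrix(inside, shape[1], shape[2])
}

# Even-odd rule with boundary inclusion, vectorised over points.
points_in_polygon <- function(pr, pc, v, eps = 1e-9) {
  n <- nrow(v)
  inside <- logical(length(pr))
  onedge <- logical(length(pr))
  j <- n
  for (i in seq_len(n)) {
    yi <- v[i, 1]; xi <- v[i, 2]; yj <- v[j, 1]; xj <- v[j, 2]
    # boundary: point collinear with edge and within its bounding box
    d <- (xj - xi) * (pr - yi) - (yj - yi) * (pc - xi)
    len2 <- (xj - xi)^2 + (yj - yi)^2
    on <- abs(d) <= eps * max(1, sqrt(len2)) &
      pr >= pmin(yi, yj) - eps & pr <= pmax(yi, yj) + eps &
      pc >= pmin(xi, xj) - eps & pc <= pmax(xi, xj) + eps
    onedge <- onedge | on
    # even-odd crossing of the horizontal ray towards +col
    crosses <- ((yi > pr) != (yj > pr)) &
      (pc < (xj - xi) * (pr - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onedge
}

#' Rank images by mean ROI intensity
#'
#' Automates the intensity ranking of reporter images: each image's mean
#' intensity inside its ROI is computed and the images are ordered ascending.
#' Ties (identical means) keep input order and are flagged; the resulting
#' ranks feed the Mann-Whitney test via [mann_whitney()].
#'
#' @param planes list of [image_plane]s, all of the same channel.
#' @param rois list of [roi_polygon]s, one per plane.
#' @return A data.frame with columns `index` (input position, in ascending
#'   intensity order), `mean_intensity`, `rank` (mid-ranks under ties) and
#'   `tied`.
#' @export
rank_by_intensity <- function(planes, rois) {
  if (length(planes) < 2L) stopf("need at least 2 images to rank")
  if (length(rois) != length(planes)) stopf("one roi per image required")
  chans <- vapply(planes, function(p) attr(p, "channel") %||% NA_character_, "")
  if (length(unique(chans)) != 1L) stopf("all images must be the same channel")
  means <- mapply(function(p, r) {
    m <- roi_mask(r, dim(p))
    if (!any(m)) stopf("empty ROI (no pixel centres inside polygon)")
    mean(unclass(as.matrix(p))[m])
  }, planes, rois)
  ord <- order(means)  # stable: ties keep input order
  rk <- rank(means, ties.method = "average")
  data.frame(index = ord, mean_intensity = means[ord], rank = rk[ord],
             tied = (duplicated(means) | duplicated(means, fromLast = TRUE))[ord])
}
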