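# Neutral-lipid quantification: Oil Red O channel-subtraction scoring of
# bright-field gut images, and TLC band densitometry of scanned plates.

#' Co-registered RGB image
#'
#' Three equal-shape channel planes from a bright-field colour acquisition.
#'
#' @param r,g,b numeric matrices (or [image_plane]s) of identical shape.
#' @param pixel_size_um physical pixel size (default 1).
#' @return An object of class `rgb_image` with elements `r`, `g`, `b`.
#' @export
rgb_image <- function(r, g, b, pixel_size_um = 1) {
  r <- unclass(as.matrix(r)); g <- unclass(as.matrix(g)); b <- unclass(as.matrix(b))
  if (!all(dim(r) == dim(g)) || !all(dim(r) == dim(b)))
    stopf("r, g, b must have identical shapes")
  if (min(r, g, b) < 0) stopf("intensities must be >= 0")
  structure(list(r = image_plane(r, pixel_size_um, "R"),
                 g = image_plane(g, pixel_size_um, "G"),
                 b = image_plane(b, pixel_size_um, "B")),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image> %d x %d px, %.4g um/px\n", nrow(x$r), ncol(x$r),
              pixel_size(x$r)))
  invisible(x)
}

#' Oil Red O lipid score by R-G channel subtraction
#'
#' The red Oil Red O droplet signal is isolated by subtracting the green
#' channel from the red (grey background cancels since R = G = B there),
#' clipping negatives to zero so that blue/green artefacts cannot produce
#' negative lipid signal, and averaging over the ROI. An optional minimum
#' particle-area filter can restrict the signal to connected droplets of at
#' least `min_area_px` pixels before averaging (off by default).
#'
#' @param img an [rgb_image].
#' @param roi an [roi_polygon] outlining the gut.
#' @param min_area_px optional particle-size filter in pixels (0 = off).
#' @return Mean of `max(R - G, 0)` over the ROI (unitless intensity).
#' @export
oro_score <- function(img, roi, min_area_px = 0L) {
  s <- pmax(unclass(img$r) - unclass(img$g), 0)
  m <- roi_mask(roi, dim(s))
  if (!any(m)) stopf("empty ROI")
  if (min_area_px > 0L) {
    lab <- EBImage::bwlabel(s > 0)
    a <- tabulate(as.integer(lab))
    keep <- as.matrix(lab) %in% which(a >= min_area_px)
    s[!matrix(keep, nrow(s), ncol(s))] <- 0
  }
  mean(s[m])
}

#' TLC lane densitometry
#'
#' For each lane (a column window of the inverted bright-field plate scan)
#' the per-row summed intensity profile is computed; each declared band row
#' window is integrated above a linear baseline interpolated between the
#' medians of the profile at the window edges (3-row neighbourhoods).
#' Negative integrals are clipped to 0. Raw integrals are returned; loading
#' normalisation across lanes is left to the caller.
#'
#' @param img inverted bright-field [image_plane] (high = more stain).
#' @param lanes list of `c(col_start, col_end)` 0-based inclusive column
#'   bounds; lanes must not overlap.
#' @param band_windows list of `c(row_start, row_end)` 0-based inclusive row
#'   windows, shared by all lanes.
#' @return A list of per-lane objects of class `tlc_lane_profile`, each with
#'   `lane_bounds`, `profile` and a `bands` data.frame
#'   (`row_start`, `row_end`, `integrated_intensity`, `background`).
#' @export
tlc_quantify <- function(img, lanes, band_windows) {
  x <- unclass(as.matrix(img))
  lanes <- lapply(lanes, as.integer)
  for (l in lanes)
    if (length(l) != 2L || l[1] > l[2] || l[1] < 0L || l[2] >= ncol(x))
      stopf("lane bounds must be 0-based (col_start <= col_end) within the image")
  if (length(lanes) > 1L) {
    b <- do.call(rbind, lanes)
    o <- order(b[, 1])
    if (any(b[o, 1][-1] <= b[o, 2][-nrow(b)])) stopf("lanes must be disjoint")
  }
  band_windows <- lapply(band_windows, as.integer)
  for (w in band_windows)
    if (length(w) != 2L || w[1] > w[2] || w[1] < 0L || w[2] >= nrow(x))
      stopf("band windows must be 0-based row ranges within the image")
  lapply(lanes, function(l) {
    prof <- rowSums(x[, (l[1] + 1):(l[2] + 1), drop = FALSE])
    bands <- do.call(rbind, lapply(band_windows, function(w) {
      i0 <- w[1] + 1L; i1 <- w[2] + 1L
      edge <- function(i) median(prof[max(1, i - 1):min(length(prof), i + 1)])
      b0 <- edge(i0); b1 <- edge(i1)
      base <- b0 + (b1 - b0) * (seq(i0, i1) - i0) / max(1L, i1 - i0)
      data.frame(row_start = w[1], row_end = w[2],
                 integrated_intensity = max(0, sum(prof[i0:i1] - base)),
                 background = mean(base))
    }))
    structure(list(lane_bounds = l, profile = prof, bands = bands),
              class = "tlc_lane_profile")
  })
}

#' @export
print.tlc_lane_profile <- function(x, ...) {
  cat(sprintf("<tlc_lane_profile> cols %d-%d, %d band(s)\n",
              x$lane_bounds[1], x$lane_bounds[2], nrow(x$bands)))
  print(x$bands)
  invisible(x)
}
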