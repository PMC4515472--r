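# Multi-page TIFF dialect: one page per (channel, z), channel-major order,
# with a JSON sidecar declaring channel names, z-counts and pixel size.
# Vendor TIFF metadata is unreliable, so the sidecar is authoritative.

#' Write a channel stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are written channel-major (all z of channel 1, then channel 2, ...)
#' as 32-bit float TIFF; `<path>.json` records the channel order, planes per
#' channel, pixel size and metadata needed to reload the stack.
#'
#' @param stack a [channel_stack].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  if (!inherits(stack, "channel_stack")) stopf("stack must be a channel_stack")
  pages <- unlist(lapply(stack$channels, function(ch) lapply(ch, function(p) unclass(p))),
                  recursive = FALSE)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- list(channels = names(stack$channels),
                  planes_per_channel = vapply(stack$channels, length, 1L),
                  pixel_size_um = stack$pixel_size_um,
                  metadata = stack$metadata)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a channel stack from multi-page TIFF
#'
#' The channel layout is taken from the JSON sidecar written by
#' [write_stack_tiff()], or from an explicit `channels`/`planes_per_channel`
#' declaration when no sidecar exists.
#'
#' @param path TIFF path.
#' @param channels,planes_per_channel optional explicit layout overriding the
#'   sidecar; `planes_per_channel` recycles to `length(channels)`.
#' @param pixel_size_um pixel size override (default from sidecar, else 1).
#' @return A [channel_stack].
#' @export
read_stack_tiff <- function(path, channels = NULL, planes_per_channel = NULL,
                            pixel_size_um = NULL) {
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::fromJSON(side_path) else NULL
  channels <- channels %||% side$channels
  if (is.null(channels)) stopf("no sidecar found for '%s'; pass channels= explicitly", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  planes_per_channel <- rep(planes_per_channel %||% side$planes_per_channel %||%
                              (length(pages) / length(channels)),
                            length.out = length(channels))
  if (sum(planes_per_channel) != length(pages))
    stopf("TIFF has %d pages but layout declares %d", length(pages), sum(planes_per_channel))
  pixel_size_um <- pixel_size_um %||% side$pixel_size_um %||% 1
  idx <- cumsum(c(0, planes_per_channel))
  chs <- lapply(seq_along(channels), function(i) pages[(idx[i] + 1):idx[i + 1]])
  names(chs) <- channels
  channel_stack(chs, pixel_size_um,
                metadata = if (is.null(side$metadata)) list() else as.list(side$metadata))
}

#' Read an RGB image from PNG or TIFF
#'
#' @param path image path ending in `.png`, `.tif` or `.tiff`.
#' @param pixel_size_um physical pixel size (default 1).
#' @return An [rgb_image].
#' @export
read_rgb_image <- function(path, pixel_size_um = 1) {
  a <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
       else tiff::readTIFF(path)
  if (length(dim(a)) != 3L || dim(a)[3] < 3L) stopf("'%s' is not an RGB image", path)
  rgb_image(a[, , 1], a[, , 2], a[, , 3], pixel_size_um = pixel_size_um)
}
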