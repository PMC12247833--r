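# Multi-channel TIFF input/output.
#
# Channel stacks are stored as multi-page 16-bit TIFFs (one page per
# channel, grey levels scaled to the 16-bit range) with a JSON sidecar
# (<path>.json) carrying channel names and the physical pixel size, since
# baseline TIFF has no standard slot for either.

#' Write / read a ChannelStack as multi-page TIFF
#'
#' @param stack A [ChannelStack-class].
#' @param path TIFF path; a `<path>.json` sidecar records channel names
#'   and pixel size.
#' @param max_grey Full-scale grey level mapped to 16-bit max
#'   (default 65535).
#' @return `writeChannelStack` returns `path` invisibly;
#'   `readChannelStack` returns a [ChannelStack-class].
#' @export
writeChannelStack <- function(stack, path, max_grey = 65535) {
  stopifnot(is(stack, "ChannelStack"))
  pages <- lapply(stack@channels, function(m) pmin(pmax(m / max_grey, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  jsonlite::write_json(list(channels = channelNames(stack),
                            pixel_size_um = pixelSize(stack),
                            max_grey = max_grey),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeChannelStack
#' @param channel_names,pixel_size_um Overrides used when no sidecar
#'   exists.
#' @export
readChannelStack <- function(path, channel_names = NULL,
                             pixel_size_um = NULL, max_grey = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    if (is.null(channel_names)) channel_names <- unlist(meta$channels)
    if (is.null(pixel_size_um)) pixel_size_um <- meta$pixel_size_um
    if (!is.null(meta$max_grey)) max_grey <- meta$max_grey
  }
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_along(pages))
  if (is.null(pixel_size_um))
    stop("pixel_size_um unknown: no sidecar and no override given")
  channels <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]   # tolerate RGB pages
    round(p * max_grey, 6)
  })
  names(channels) <- channel_names
  channelStack(channels, pixel_size_um)
}
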