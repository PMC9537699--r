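#' Multi-channel image stacks with physical voxel sizes
#'
#' An `image_stack` is a named list of voxel arrays (all the same shape,
#' indexed `[y, x, z]`) plus a physical voxel size `(z, y, x)` in
#' micrometres. The conventional channel names used throughout the package
#' are `dapi` (nuclear stain), `cell` (cytoplasm / microtubule stain) and
#' `reporter` (the tagged protein being quantified).
#'
#' @param channels named list of numeric arrays, identical dimensions.
#' @param voxel_size numeric `(z, y, x)` in micrometres, all > 0.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size) {
  if (!is.list(channels) || length(channels) == 0 || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("channels must be a non-empty named list of arrays", call. = FALSE)
  dims <- lapply(channels, function(ch) dim(.as_stack3d(ch)))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all channels must share the same dimensions", call. = FALSE)
  channels <- lapply(channels, .as_stack3d)
  structure(list(channels = channels,
                 voxel_size = .check_voxel_size(voxel_size)),
            class = "image_stack")
}

.check_voxel_size <- function(voxel_size) {
  if (length(voxel_size) == 2L) voxel_size <- c(1, voxel_size) # 2D: unit z
  if (length(voxel_size) != 3L || !is.numeric(voxel_size) ||
      any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be 3 strictly positive numbers (z, y, x)",
         call. = FALSE)
  if (is.null(names(voxel_size)) || !setequal(names(voxel_size), c("z", "y", "x")))
    names(voxel_size) <- c("z", "y", "x")
  voxel_size[c("z", "y", "x")]
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("image_stack: %d channel(s) [%s], %d x %d x %d voxels (y,x,z), voxel %.3g x %.3g x %.3g um (z,y,x)\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3],
              x$voxel_size["z"], x$voxel_size["y"], x$voxel_size["x"]))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1]])

#' Write an image stack as per-channel multi-page TIFF plus a JSON sidecar
#'
#' Each channel is written as one multi-page 16-bit TIFF (`<prefix>_<channel>.tif`,
#' one page per z plane). Intensities are stored scaled to the stack-wide
#' maximum; the scale factor, channel names and voxel size go to
#' `<prefix>_meta.json` so [read_image_stack()] can restore physical values.
#'
#' @param stack an [image_stack()].
#' @param prefix path prefix (directory must exist).
#' @return invisibly, the sidecar path.
#' @export
write_image_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "image_stack"))
  offset <- min(vapply(stack$channels, min, 0))
  scale <- max(1e-12, max(vapply(stack$channels, max, 0)) - offset)
  files <- character(0)
  for (nm in names(stack$channels)) {
    arr <- (stack$channels[[nm]] - offset) / scale
    pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
    f <- paste0(prefix, "_", nm, ".tif")
    tiff::writeTIFF(pages, f, bits.per.sample = 16L)
    files <- c(files, basename(f))
  }
  meta <- list(channels = names(stack$channels), files = files,
               voxel_size_um = as.list(stack$voxel_size),
               intensity_scale = scale, intensity_offset = offset,
               shape_yxz = dim(stack$channels[[1]]))
  sidecar <- paste0(prefix, "_meta.json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param prefix the same path prefix passed to [write_image_stack()].
#' @return an [image_stack()] with intensities restored to their original scale
#'   (up to 16-bit quantisation).
#' @export
read_image_stack <- function(prefix) {
  sidecar <- paste0(prefix, "_meta.json")
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  chans <- list()
  for (i in seq_along(meta$channels)) {
    pages <- tiff::readTIFF(file.path(dirname(prefix), meta$files[i]), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, dim = meta$shape_yxz)
    for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
    off <- if (is.null(meta$intensity_offset)) 0 else meta$intensity_offset
    chans[[meta$channels[i]]] <- arr * meta$intensity_scale + off
  }
  vs <- unlist(meta$voxel_size_um)
  image_stack(chans, c(z = vs[["z"]], y = vs[["y"]], x = vs[["x"]]))
}
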