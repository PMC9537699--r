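#' Global auto-thresholding
#'
#' Histogram-based automatic threshold selection over the whole stack
#' (2D or 3D). `"otsu"` maximises between-class variance on a 256-bin
#' histogram; `"isodata"` iterates the intermeans rule (threshold = midpoint
#' of the two class means) to a fixed point. Both return a threshold on the
#' intensity scale of the input; voxels strictly above it are foreground.
#'
#' @param x numeric array of intensities.
#' @param method `"otsu"` or `"isodata"`.
#' @param n_bins histogram resolution.
#' @return numeric threshold, with attribute `method`.
#' @export
auto_threshold <- function(x, method = c("otsu", "isodata"), n_bins = 256L) {
  method <- match.arg(method)
  v <- as.numeric(x)
  rng <- range(v)
  if (!all(is.finite(rng)) || rng[1] == rng[2])
    stop("cannot threshold a constant (or non-finite) image", call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(n_bins, pmax(1L, findInterval(v, breaks,
                                                  rightmost.closed = TRUE))),
                nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  thr <- switch(method, otsu = .otsu_threshold(h, mids, breaks),
                isodata = .isodata_threshold(h, mids))
  structure(thr, method = method)
}

.otsu_threshold <- function(h, mids, breaks) {
  w <- h / sum(h)
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- -Inf
  k <- which.max(sb2)  # split after bin k; threshold at the bin boundary
  breaks[k + 1L]
}

.isodata_threshold <- function(h, mids) {
  thr <- sum(h * mids) / sum(h)
  for (i in 1:200) {
    lo <- mids <= thr
    if (!any(lo) || all(lo)) break
    m0 <- sum(h[lo] * mids[lo]) / sum(h[lo])
    m1 <- sum(h[!lo] * mids[!lo]) / sum(h[!lo])
    new <- (m0 + m1) / 2
    if (abs(new - thr) < 1e-9 * diff(range(mids))) { thr <- new; break }
    thr <- new
  }
  thr
}

.segment_channel <- function(channel, voxel_size, method, closing_um) {
  thr <- auto_threshold(channel, method = method)
  fg <- channel > as.numeric(thr)
  if (!any(fg)) stop("auto-threshold produced an empty foreground",
                     call. = FALSE)
  if (closing_um > 0) fg <- close_mask(fg, closing_um, voxel_size)
  fg <- largest_component(fg)
  fg <- fill_holes(fg)
  list(mask = fg,
       provenance = list(method = attr(thr, "method"),
                         threshold = as.numeric(thr),
                         closing_um = closing_um,
                         n_voxels = sum(fg)))
}

#' Segment the nucleus from the DAPI channel
#'
#' Global auto-threshold, then largest connected component and hole filling.
#'
#' @param dapi numeric array (2D or 3D), the nuclear-stain channel.
#' @param voxel_size `(z, y, x)` um.
#' @param method auto-threshold method, see [auto_threshold()].
#' @return list with `mask` (logical array) and `provenance` (method,
#'   threshold value, voxel count).
#' @export
segment_nucleus <- function(dapi, voxel_size, method = "otsu") {
  .segment_channel(dapi, voxel_size, method, closing_um = 0)
}

#' Segment the whole cell from the cytoplasm/microtubule channel
#'
#' As [segment_nucleus()], with a 0.3 um morphological closing applied
#' before component selection because cytoskeletal texture is patchy.
#'
#' @inheritParams segment_nucleus
#' @param cell_channel numeric array, cytoplasm or microtubule stain.
#' @param closing_um closing ball radius in um.
#' @export
segment_cell <- function(cell_channel, voxel_size, method = "otsu",
                         closing_um = 0.3) {
  .segment_channel(cell_channel, voxel_size, method, closing_um = closing_um)
}

#' Reconcile nucleus and cell masks
#'
#' Enforces the containment `nucleus` within `cell`. If less than
#' `min_containment` of the nucleus lies inside the cell mask the pairing is
#' flagged as inconsistent (e.g. the wrong channel was segmented); otherwise
#' the nucleus is clipped to the cell.
#'
#' @param nucleus,cell segmentation results (or bare logical masks).
#' @param min_containment fraction of nucleus voxels that must fall inside
#'   the cell mask.
#' @return list `nucleus_mask`, `cell_mask`, `consistent` (logical),
#'   `containment` (fraction), `provenance`.
#' @export
reconcile_masks <- function(nucleus, cell, min_containment = 0.8) {
  nm <- if (is.list(nucleus)) nucleus$mask else nucleus
  cm <- if (is.list(cell)) cell$mask else cell
  if (!identical(dim(nm), dim(cm)))
    stop("nucleus and cell masks differ in shape", call. = FALSE)
  if (!any(nm) || !any(cm))
    stop("cannot reconcile empty masks", call. = FALSE)
  containment <- sum(nm & cm) / sum(nm)
  consistent <- containment >= min_containment
  if (!consistent)
    warning(sprintf("nucleus mask only %.0f%% inside cell mask; channels may be misassigned",
                    100 * containment), call. = FALSE)
  list(nucleus_mask = nm & cm, cell_mask = cm,
       consistent = consistent, containment = containment,
       provenance = list(
         nucleus = if (is.list(nucleus)) nucleus$provenance else NULL,
         cell = if (is.list(cell)) cell$provenance else NULL))
}
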