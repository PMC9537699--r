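#' Physical-distance transform and voxel morphology
#'
#' Low-level mask operations shared by the segmentation and band modules.
#' All distances are Euclidean in physical units (micrometres), computed by
#' an exact separable distance transform that honours anisotropic voxel
#' spacing. Arrays are indexed `[y, x, z]`; a 2D matrix is treated as a
#' single-plane stack.
#'
#' @name morphology
NULL

# spacing per array dimension (y, x, z) from a (z, y, x) voxel-size vector
.dim_spacing <- function(voxel_size) {
  vs <- .check_voxel_size(voxel_size)
  c(vs[["y"]], vs[["x"]], vs[["z"]])
}

.as_stack3d <- function(mask) {
  if (is.matrix(mask)) dim(mask) <- c(dim(mask), 1L)
  if (length(dim(mask)) != 3L)
    stop("mask must be a 2D matrix or 3D array", call. = FALSE)
  mask
}

#' Squared/plain Euclidean distance to a mask, in micrometres
#'
#' For every voxel, the distance from its centre to the nearest centre of a
#' `TRUE` voxel of `mask`, measured in physical units so that anisotropic
#' voxels (e.g. coarser z sampling) are handled correctly. Voxels inside the
#' mask have distance 0; if the mask is empty all distances are `Inf`.
#'
#' @param mask logical matrix (2D) or 3D array, indexed `[y, x, z]`.
#' @param voxel_size numeric length-3 vector `(z, y, x)` in micrometres, or a
#'   named vector with names `z`, `y`, `x`.
#' @param squared return squared distances (exact; avoids the final sqrt).
#' @return numeric array of the same shape as `mask`.
#' @export
distance_to_mask <- function(mask, voxel_size, squared = FALSE) {
  m3 <- .as_stack3d(mask)
  sp <- .dim_spacing(voxel_size)
  d2 <- .edt_squared_cpp(as.logical(m3), as.integer(dim(m3)), as.numeric(sp))
  dim(d2) <- dim(m3)
  if (!squared) d2 <- sqrt(d2)
  if (is.matrix(mask)) dim(d2) <- dim(mask)
  d2
}

#' Label connected components (6-connectivity in 3D, 4 in 2D)
#'
#' @inheritParams distance_to_mask
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(mask) {
  m3 <- .as_stack3d(mask)
  lab <- .label_components_cpp(as.logical(m3), as.integer(dim(m3)))
  dim(lab) <- dim(m3)
  if (is.matrix(mask)) dim(lab) <- dim(mask)
  lab
}

#' Keep only the largest connected component of a mask
#' @inheritParams distance_to_mask
#' @return logical array.
#' @export
largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  counts <- tabulate(lab[lab > 0L])
  out <- lab == which.max(counts)
  dim(out) <- dim(mask)
  out
}

#' Fill interior holes of a mask
#'
#' A hole is a background component with no voxel on the array border.
#' Works natively in 3D; a cavity open only through z still counts as
#' connected to the border.
#'
#' @inheritParams distance_to_mask
#' @return logical array.
#' @export
fill_holes <- function(mask) {
  m3 <- .as_stack3d(mask)
  bg <- !m3
  lab <- label_components(bg)
  dm <- dim(m3)
  border <- array(FALSE, dm)
  border[c(1L, dm[1L]), , ] <- TRUE
  border[, c(1L, dm[2L]), ] <- TRUE
  if (dm[3L] > 1L) border[, , c(1L, dm[3L])] <- TRUE
  touching <- unique(lab[border & bg])
  hole <- bg & !(lab %in% touching)
  out <- m3 | hole
  if (is.matrix(mask)) dim(out) <- dim(mask) else dim(out) <- dm
  out
}

#' Morphological closing with a physical-radius ball
#'
#' Dilation then erosion with a Euclidean ball of radius `radius_um`,
#' realised through two distance transforms so the structuring element is
#' spherical in physical (not voxel) space.
#'
#' @inheritParams distance_to_mask
#' @param radius_um ball radius in micrometres; 0 returns the mask unchanged.
#' @export
close_mask <- function(mask, radius_um, voxel_size) {
  if (radius_um < 0) stop("radius_um must be >= 0", call. = FALSE)
  if (radius_um == 0) return(mask)
  r2 <- radius_um^2 + 1e-9
  dil <- distance_to_mask(mask, voxel_size, squared = TRUE) <= r2
  ero <- !(distance_to_mask(!dil, voxel_size, squared = TRUE) <= r2)
  dim(ero) <- dim(mask)
  ero
}
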