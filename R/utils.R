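# run code with a temporary RNG state so generators are pure in (spec, seed)
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

.is_point3 <- function(p) is.numeric(p) && length(p) == 3L && all(is.finite(p))

#' Physical centroid of a mask
#'
#' Mean voxel-centre coordinate of the `TRUE` voxels of a `[y, x, z]` mask,
#' in micrometres relative to the array corner.
#' @param mask logical 2D/3D array.
#' @param voxel_size `(z, y, x)` um.
#' @return named numeric `(x, y, z)`.
#' @export
mask_centroid <- function(mask, voxel_size) {
  vs <- .check_voxel_size(voxel_size)
  m3 <- .as_stack3d(mask)
  idx <- which(m3, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no centroid", call. = FALSE)
  c(x = mean((idx[, 2] - 0.5) * vs[["x"]]),
    y = mean((idx[, 1] - 0.5) * vs[["y"]]),
    z = mean((idx[, 3] - 0.5) * vs[["z"]]))
}

#' Sorensen-Dice overlap of two masks
#' @param a,b logical arrays of identical shape.
#' @return numeric in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}
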