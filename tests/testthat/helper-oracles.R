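# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# brute-force physical distance from every voxel centre to the nearest TRUE
# voxel centre of `mask` (all-pairs; only for small stacks)
edt_bruteforce <- function(mask, voxel_size) {
  vs <- voxel_size[c("z", "y", "x")]
  m3 <- if (is.matrix(mask)) array(mask, c(dim(mask), 1)) else mask
  idx <- which(m3, arr.ind = TRUE)
  pts <- cbind(idx[, 1] * vs[["y"]], idx[, 2] * vs[["x"]], idx[, 3] * vs[["z"]])
  qi <- which(array(TRUE, dim(m3)), arr.ind = TRUE)
  qp <- cbind(qi[, 1] * vs[["y"]], qi[, 2] * vs[["x"]], qi[, 3] * vs[["z"]])
  d <- apply(qp, 1, function(p) sqrt(min(colSums((t(pts) - p)^2))))
  array(d, dim(m3))
}

# dense-polyline arc length of a quadratic curve C(t) = a0 + a1 t + a2 t^2
polyline_arc <- function(a0, a1, a2, t_max = 1, n = 1e5) {
  t <- seq(0, t_max, length.out = n)
  pts <- cbind(a0[1] + a1[1] * t + a2[1] * t^2,
               a0[2] + a1[2] * t + a2[2] * t^2,
               a0[3] + a1[3] * t + a2[3] * t^2)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# literal step-by-step two-stage step-up procedure (independent of
# bky_step_up's vectorised internals)
bky_literal <- function(p, q = 0.05) {
  m <- length(p)
  q1 <- q / (1 + q)
  bh <- function(pv, a) {
    o <- order(pv)
    k <- 0L
    for (i in m:1) if (pv[o][i] <= i * a / m) { k <- i; break }
    rej <- rep(FALSE, m)
    if (k > 0L) rej[o[seq_len(k)]] <- TRUE
    rej
  }
  r1 <- sum(bh(p, q1))
  if (r1 == 0L) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  bh(p, q1 * m / (m - r1))
}

# a small, quick synthetic cell (coarser lateral sampling than the default)
# for unit tests that only need the geometry, not confocal-grade sampling
fast_cell_spec <- function(...) {
  cell_spec(..., voxel_size = c(z = 0.5, y = 0.25, x = 0.25))
}
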