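#' Specification of one synthetic hair cell
#'
#' Parameters of the generative model for a single elongated, optionally
#' curved cell: a tube of radius `cell_radius` around a smooth midline of
#' arc length `cell_length`, with a spherical nucleus centred on the midline
#' at arc-length fraction `true_relative_position` from the apical end, and
#' an optional nuclear-envelope reporter rim of enrichment `ne_enrichment_factor`
#' over cytoplasm.
#'
#' The midline bend amplitude is `axis_curvature * cell_length / 2`
#' perpendicular to the apical-basal chord; `axis_curvature = 0` gives a
#' straight cell. The default `midline = "sine"` family is deliberately not
#' the quadratic family used by [fit_cell_axis()], so axis recovery is tested
#' against a genuinely different curve.
#'
#' @param cell_length midline arc length, um (> 0). Default 30 (outer hair
#'   cells run roughly 25-40 um).
#' @param axis_curvature dimensionless bend parameter, 0 = straight.
#' @param true_relative_position nucleus arc position in `[0, 1]`
#'   (0 = apical); controls span roughly 0.7-0.8.
#' @param nucleus_radius um; must fit inside the cell radially and along the
#'   axis.
#' @param cell_radius tube radius, um.
#' @param ne_enrichment_factor k >= 0: reporter intensity at the nuclear rim
#'   relative to cytoplasm (1 = no enrichment).
#' @param ne_shell_um rim shell thickness, um.
#' @param cytoplasm_intensity,background_intensity arbitrary units.
#' @param noise_model list with `photon_scaling` (expected photon count at
#'   cytoplasm intensity; Poisson component) and `gaussian_sd` (additive
#'   read noise sd, same units as intensities). Set both to `0`/`Inf` via
#'   `noise_model = NULL` for noiseless output.
#' @param voxel_size `(z, y, x)` um.
#' @param midline `"sine"`, `"quadratic"` or `"straight"`.
#' @return object of class `synthetic_cell_spec`.
#' @export
cell_spec <- function(cell_length = 30, axis_curvature = 0,
                      true_relative_position = 0.75,
                      nucleus_radius = 2.2, cell_radius = 3.2,
                      ne_enrichment_factor = 1, ne_shell_um = 0.3,
                      cytoplasm_intensity = 100, background_intensity = 10,
                      noise_model = list(photon_scaling = 50, gaussian_sd = 2),
                      voxel_size = c(z = 0.5, y = 0.1, x = 0.1),
                      midline = c("sine", "quadratic", "straight")) {
  midline <- match.arg(midline)
  if (!is.numeric(cell_length) || cell_length <= 0)
    stop("cell_length must be > 0", call. = FALSE)
  if (true_relative_position < 0 || true_relative_position > 1)
    stop("true_relative_position must lie in [0, 1]", call. = FALSE)
  if (nucleus_radius <= 0 || cell_radius <= 0)
    stop("radii must be > 0", call. = FALSE)
  if (ne_enrichment_factor < 0)
    stop("ne_enrichment_factor must be >= 0", call. = FALSE)
  if (is.null(noise_model))
    noise_model <- list(photon_scaling = 0, gaussian_sd = 0)
  stopifnot(is.list(noise_model),
            all(c("photon_scaling", "gaussian_sd") %in% names(noise_model)))
  vs <- .check_voxel_size(voxel_size)
  # the nucleus must fit inside the cell body
  if (nucleus_radius > cell_radius)
    stop("nucleus (radius ", nucleus_radius,
         " um) does not fit inside the cell radius (", cell_radius, " um)",
         call. = FALSE)
  arc <- true_relative_position * cell_length
  if (arc < nucleus_radius || cell_length - arc < nucleus_radius)
    stop("nucleus does not fit inside the cell: arc position ", signif(arc, 4),
         " um leaves less than one nucleus radius (", nucleus_radius,
         " um) of clearance to a cell pole", call. = FALSE)
  structure(list(cell_length = cell_length, axis_curvature = axis_curvature,
                 true_relative_position = true_relative_position,
                 nucleus_radius = nucleus_radius, cell_radius = cell_radius,
                 ne_enrichment_factor = ne_enrichment_factor,
                 ne_shell_um = ne_shell_um,
                 cytoplasm_intensity = cytoplasm_intensity,
                 background_intensity = background_intensity,
                 noise_model = noise_model, voxel_size = vs,
                 midline = midline),
            class = "synthetic_cell_spec")
}

# midline point set as a function of u in [0,1]:
#   lateral offset A * bend(u), axial progress D * u
.bend_fun <- function(midline) {
  switch(midline,
         sine      = function(u) sin(pi * u),
         quadratic = function(u) 4 * u * (1 - u),
         straight  = function(u) rep(0, length(u)))
}

.polyline_length <- function(pts) sum(sqrt(rowSums(diff(pts)^2)))

# solve the chord span D so the midline arc length equals cell_length,
# then return the midline as a closure plus a dense arc-length table
.solve_midline <- function(spec, n_dense = 20001L) {
  L <- spec$cell_length
  A <- if (spec$midline == "straight") 0 else spec$axis_curvature * L / 2
  bend <- .bend_fun(if (A == 0) "straight" else spec$midline)
  u <- seq(0, 1, length.out = 2001L)
  arc_of <- function(D) .polyline_length(cbind(A * bend(u), D * u))
  D <- if (A == 0) L else uniroot(function(D) arc_of(D) - L,
                                  lower = L / 4, upper = L,
                                  tol = 1e-10)$root
  f <- function(uu) cbind(lat = A * bend(uu), ax = D * uu)
  ud <- seq(0, 1, length.out = n_dense)
  pd <- f(ud)
  s <- c(0, cumsum(sqrt(rowSums(diff(pd)^2))))
  list(f = f, D = D, A = A, u_dense = ud, s_dense = s,
       total_length = s[length(s)])
}

#' Generate a ground-truthed synthetic cell image
#'
#' Renders a 3-channel confocal-like stack (`dapi`: bright inside the
#' nucleus; `cell`: bright over the whole cell body; `reporter`: cytoplasm
#' intensity over the cell, times `k` in a thin nuclear-rim shell) with
#' Poisson photon noise plus Gaussian read noise, and records the noiseless
#' masks, landmarks and generative parameters as ground truth.
#'
#' Ground-truth lengths are computed on the continuous midline by dense
#' polyline integration, so they do not depend on the voxel grid.
#'
#' @param spec a [cell_spec()].
#' @param seed integer; the generator is a pure function of `(spec, seed)`.
#' @return list with elements `stack` (an [image_stack()]) and `truth`
#'   (class `cell_ground_truth`: landmarks, `true_relative_position`,
#'   `true_total_length`, `nucleus_mask`, `cell_mask`, `ne_mask`,
#'   `noiseless` channel list, `nucleus_center`, `origin`, `spec`).
#' @export
generate_cell_image <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_cell_spec"))
  vs <- spec$voxel_size
  ml <- .solve_midline(spec)

  pad <- spec$cell_radius + 1.6  # room for the perinuclear band + margin
  lat <- ml$f(seq(0, 1, length.out = 512L))[, "lat"]
  x0 <- min(lat) - pad; x1 <- max(lat) + pad
  y0 <- -pad; y1 <- ml$D + pad
  z0 <- -pad; z1 <- pad
  nx <- ceiling((x1 - x0) / vs[["x"]])
  ny <- ceiling((y1 - y0) / vs[["y"]])
  nz <- ceiling((z1 - z0) / vs[["z"]])
  origin <- c(x = x0, y = y0, z = z0)
  # voxel-centre physical coordinates
  xs <- x0 + (seq_len(nx) - 0.5) * vs[["x"]]
  ys <- y0 + (seq_len(ny) - 0.5) * vs[["y"]]
  zs <- z0 + (seq_len(nz) - 0.5) * vs[["z"]]

  # rasterise the midline and take a physical distance transform to get the tube
  step <- min(vs) / 2
  nu <- max(64L, ceiling(spec$cell_length / step))
  mu <- seq(0, 1, length.out = nu)
  mp <- ml$f(mu)  # lat -> x, ax -> y; midline plane z = 0
  ix <- pmin(nx, pmax(1L, ceiling((mp[, "lat"] - x0) / vs[["x"]])))
  iy <- pmin(ny, pmax(1L, ceiling((mp[, "ax"] - y0) / vs[["y"]])))
  iz <- pmin(nz, pmax(1L, rep(ceiling((0 - z0) / vs[["z"]]), nu)))
  mid_mask <- array(FALSE, c(ny, nx, nz))
  mid_mask[cbind(iy, ix, iz)] <- TRUE
  d_mid <- distance_to_mask(mid_mask, vs)
  cell_mask <- d_mid <= spec$cell_radius

  # nucleus: sphere centred on the midline at the requested arc fraction
  s_target <- spec$true_relative_position * ml$total_length
  u_star <- approx(ml$s_dense, ml$u_dense, xout = s_target, rule = 2)$y
  ctr2 <- ml$f(u_star)
  center <- c(x = unname(ctr2[1, "lat"]), y = unname(ctr2[1, "ax"]), z = 0)
  d2n <- outer(outer((ys - center[["y"]])^2, (xs - center[["x"]])^2, "+"),
               (zs - center[["z"]])^2, "+")
  nucleus_mask <- d2n <= spec$nucleus_radius^2
  if (!any(nucleus_mask))
    stop("nucleus smaller than one voxel at this voxel size", call. = FALSE)
  cell_mask <- cell_mask | nucleus_mask
  ne_mask <- (distance_to_mask(nucleus_mask, vs, squared = TRUE) <=
                spec$ne_shell_um^2 + 1e-9) & !nucleus_mask

  bg <- spec$background_intensity
  cy <- spec$cytoplasm_intensity
  k <- spec$ne_enrichment_factor
  dapi0 <- array(bg, dim(cell_mask)); dapi0[nucleus_mask] <- cy
  cell0 <- array(bg, dim(cell_mask)); cell0[cell_mask] <- cy
  rep0 <- array(bg, dim(cell_mask)); rep0[cell_mask] <- cy
  rep0[ne_mask & cell_mask] <- k * cy

  noisy <- .with_seed(seed, lapply(list(dapi = dapi0, cell = cell0,
                                        reporter = rep0),
                                   .apply_noise, nm = spec$noise_model,
                                   ref = cy))
  stack <- image_stack(noisy, vs)

  apical2 <- ml$f(0); basal2 <- ml$f(1)
  landmarks <- cell_landmarks(
    apical = c(unname(apical2[1, "lat"]), unname(apical2[1, "ax"]), 0),
    nucleus_centroid = unname(center[c("x", "y", "z")]),
    basal = c(unname(basal2[1, "lat"]), unname(basal2[1, "ax"]), 0),
    cell_id = "synthetic")
  truth <- structure(list(
    landmarks = landmarks,
    true_relative_position = s_target / ml$total_length,
    true_total_length = ml$total_length,
    nucleus_mask = nucleus_mask, cell_mask = cell_mask, ne_mask = ne_mask,
    noiseless = list(dapi = dapi0, cell = cell0, reporter = rep0),
    nucleus_center = center, origin = origin, spec = spec),
    class = "cell_ground_truth")
  list(stack = stack, truth = truth)
}

.apply_noise <- function(arr, nm, ref) {
  out <- arr
  if (nm$photon_scaling > 0) {
    gain <- ref / nm$photon_scaling
    out <- array(rpois(length(arr), pmax(arr, 0) / gain) * gain, dim(arr))
  }
  if (nm$gaussian_sd > 0)
    out <- out + array(rnorm(length(arr), 0, nm$gaussian_sd), dim(arr))
  out
}

#' Landmarks for a synthetic cell, optionally using the segmented nucleus
#'
#' Builds the three-point landmark set (apical, nucleus centroid, basal) the
#' axis fit consumes. Apical and basal come from the generative midline;
#' the nucleus centroid comes either from ground truth or, to exercise the
#' full measurement path, from the centroid of the nucleus segmented out of
#' the noisy DAPI channel.
#'
#' @param truth `cell_ground_truth` from [generate_cell_image()].
#' @param stack matching [image_stack()]; required for
#'   `nucleus_from = "segmented"`.
#' @param nucleus_from `"true"` or `"segmented"`.
#' @param method auto-threshold method for segmentation.
#' @return a [cell_landmarks()] object.
#' @export
landmarks_from_truth <- function(truth, stack = NULL,
                                 nucleus_from = c("true", "segmented"),
                                 method = "otsu") {
  nucleus_from <- match.arg(nucleus_from)
  lm <- truth$landmarks
  if (nucleus_from == "segmented") {
    if (is.null(stack)) stop("stack required for segmented landmarks",
                             call. = FALSE)
    seg <- segment_nucleus(stack$channels$dapi, stack$voxel_size,
                           method = method)
    ctr <- mask_centroid(seg$mask, stack$voxel_size)
    # masks live on the grid; landmarks in midline coordinates
    ctr <- ctr + truth$origin[c("x", "y", "z")]
    lm <- cell_landmarks(lm$apical, unname(ctr), lm$basal, lm$cell_id)
  }
  lm
}
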