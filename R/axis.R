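#' Three anatomical landmarks of one hair cell
#'
#' The apical surface point, nucleus centroid and basal end of the cell, in
#' physical micrometres. These are the reference points from which the cell
#' axis is fitted; 2D inputs are accepted by embedding at z = 0.
#'
#' @param apical,nucleus_centroid,basal numeric length-2 or length-3 points (um).
#' @param cell_id label carried through outputs.
#' @return object of class `cell_landmarks`.
#' @export
cell_landmarks <- function(apical, nucleus_centroid, basal, cell_id = "cell") {
  embed <- function(p, what) {
    if (length(p) == 2L) p <- c(p, 0)
    if (!.is_point3(p)) stop(what, " must be a finite 2D or 3D point",
                             call. = FALSE)
    unname(as.numeric(p))
  }
  structure(list(apical = embed(apical, "apical"),
                 nucleus_centroid = embed(nucleus_centroid, "nucleus_centroid"),
                 basal = embed(basal, "basal"),
                 cell_id = as.character(cell_id)),
            class = "cell_landmarks")
}

#' Fit a smooth axis curve through the three landmarks
#'
#' Fits the unique quadratic parametric curve \eqn{C(t)}, \eqn{t \in [0,1]},
#' with \eqn{C(0)} at the apical point, \eqn{C(1)} at the basal point and
#' passing through the nucleus centroid at the chord-length parameter
#' \eqn{t_N = d_1 / (d_1 + d_2)} (\eqn{d_1, d_2}: apical-nucleus and
#' nucleus-basal chords). For collinear landmarks the quadratic term
#' vanishes and the curve is the straight segment, so arc length equals
#' chord length exactly (computed in closed form). Otherwise arc lengths
#' are obtained by adaptive quadrature of \eqn{\lVert C'(t)\rVert} at
#' relative tolerance 1e-6.
#'
#' @param landmarks a [cell_landmarks()] object.
#' @param off_axis_warn perpendicular nucleus offset, as a multiple of the
#'   apical-basal chord, beyond which a warning (not an error) is raised.
#' @return object of class `cell_axis_curve` with fields `total_length`
#'   (um), `nucleus_arc` (um), `t_nucleus`, polynomial coefficients and the
#'   input landmarks.
#' @export
fit_cell_axis <- function(landmarks, off_axis_warn = 1.0) {
  stopifnot(inherits(landmarks, "cell_landmarks"))
  p0 <- landmarks$apical; pn <- landmarks$nucleus_centroid
  p1 <- landmarks$basal
  chord <- sqrt(sum((p1 - p0)^2))
  scale <- max(chord, sqrt(sum((pn - p0)^2)), sqrt(sum((p1 - pn)^2)))
  if (chord <= 1e-12 * max(scale, 1))
    stop("degenerate axis: apical and basal landmarks coincide",
         call. = FALSE)
  d1 <- sqrt(sum((pn - p0)^2))
  d2 <- sqrt(sum((p1 - pn)^2))
  tN <- d1 / (d1 + d2)

  # perpendicular offset of the nucleus from the apical-basal chord
  uhat <- (p1 - p0) / chord
  perp <- sqrt(max(0, sum((pn - p0)^2) - sum((pn - p0) * uhat)^2))
  if (perp > off_axis_warn * chord)
    warning(sprintf("cell %s: nucleus centroid lies %.2f um off-axis (> %g x chord)",
                    landmarks$cell_id, perp, off_axis_warn), call. = FALSE)

  # C(t) = a0 + a1 t + a2 t^2 interpolating (0,p0), (tN,pn), (1,p1)
  a0 <- p0
  if (tN <= 1e-12 || tN >= 1 - 1e-12) {
    # nucleus coincides with an end landmark: straight chord
    a2 <- c(0, 0, 0)
    a1 <- p1 - p0
  } else {
    a2 <- ((pn - p0) - tN * (p1 - p0)) / (tN^2 - tN)
    a1 <- (p1 - p0) - a2
  }

  lin <- sqrt(sum(a2^2)) <= 1e-9 * max(scale, 1)
  if (lin) {
    total <- sqrt(sum(a1^2))
    s_n <- tN * total
  } else {
    speed <- function(t) sqrt((a1[1] + 2 * a2[1] * t)^2 +
                              (a1[2] + 2 * a2[2] * t)^2 +
                              (a1[3] + 2 * a2[3] * t)^2)
    total <- integrate(speed, 0, 1, rel.tol = 1e-6)$value
    s_n <- if (tN == 0) 0 else integrate(speed, 0, tN, rel.tol = 1e-6)$value
  }
  structure(list(landmarks = landmarks, a0 = a0, a1 = a1, a2 = a2,
                 t_nucleus = tN, total_length = total, nucleus_arc = s_n,
                 linear = lin),
            class = "cell_axis_curve")
}

#' Evaluate a fitted axis curve
#' @param curve a `cell_axis_curve`.
#' @param t numeric vector of parameters in `[0, 1]`.
#' @return matrix of points, one row per `t`, columns x/y/z.
#' @export
axis_curve_points <- function(curve, t) {
  stopifnot(inherits(curve, "cell_axis_curve"))
  cbind(curve$a0[1] + curve$a1[1] * t + curve$a2[1] * t^2,
        curve$a0[2] + curve$a1[2] * t + curve$a2[2] * t^2,
        curve$a0[3] + curve$a1[3] * t + curve$a2[3] * t^2)
}

#' @export
print.cell_axis_curve <- function(x, ...) {
  cat(sprintf("cell_axis_curve [%s]: L = %.3f um, nucleus arc = %.3f um (p = %.4f)%s\n",
              x$landmarks$cell_id, x$total_length, x$nucleus_arc,
              x$nucleus_arc / x$total_length,
              if (x$linear) ", straight" else ""))
  invisible(x)
}

#' Relative nuclear position along the fitted axis
#'
#' The arc length from the apical landmark to the nucleus centroid divided
#' by the total curve length: 0 at the apical surface, 1 at the basal end.
#' Control outer hair cells sit around 0.7-0.8; apical displacement of the
#' nucleus lowers the value.
#'
#' @param curve a `cell_axis_curve` from [fit_cell_axis()].
#' @return numeric scalar in `[0, 1]`.
#' @export
relative_nuclear_position <- function(curve) {
  stopifnot(inherits(curve, "cell_axis_curve"))
  if (curve$total_length <= 0)
    stop("degenerate axis: zero total length", call. = FALSE)
  min(1, max(0, curve$nucleus_arc / curve$total_length))
}

#' Per-cell relative nuclear positions for a landmark table
#'
#' Applies [fit_cell_axis()] and [relative_nuclear_position()] to every row
#' of a landmark table (see [read_landmarks()] for the schema). Rows that
#' fail validation are reported with `NA` measurements and the failure
#' reason; they never abort the batch. Row order is preserved.
#'
#' @param landmarks data frame with columns `cell_id`, `ax, ay, az`,
#'   `nx, ny, nz`, `bx, by, bz` (physical um) and optional `group`, `age`.
#' @return data frame: `cell_id`, `group`, `age`, `total_length_um`,
#'   `nucleus_arc_um`, `relative_position`, `status`.
#' @export
batch_positions <- function(landmarks) {
  cols <- c("cell_id", "ax", "ay", "az", "nx", "ny", "nz", "bx", "by", "bz")
  out <- data.frame(cell_id = character(0), group = character(0),
                    age = character(0), total_length_um = numeric(0),
                    nucleus_arc_um = numeric(0), relative_position = numeric(0),
                    status = character(0), stringsAsFactors = FALSE)
  if (nrow(landmarks) == 0L) return(out)
  missing_cols <- setdiff(cols, names(landmarks))
  if (length(missing_cols))
    stop("landmark table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  res <- vector("list", nrow(landmarks))
  for (i in seq_len(nrow(landmarks))) {
    row <- landmarks[i, ]
    rec <- list(cell_id = as.character(row$cell_id),
                group = if ("group" %in% names(landmarks)) as.character(row$group) else NA_character_,
                age = if ("age" %in% names(landmarks)) as.character(row$age) else NA_character_,
                total_length_um = NA_real_, nucleus_arc_um = NA_real_,
                relative_position = NA_real_, status = "ok")
    fit <- tryCatch({
      lm <- cell_landmarks(c(row$ax, row$ay, row$az),
                           c(row$nx, row$ny, row$nz),
                           c(row$bx, row$by, row$bz), row$cell_id)
      fit_cell_axis(lm)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      rec$status <- paste0("error: ", conditionMessage(fit))
    } else {
      rec$total_length_um <- fit$total_length
      rec$nucleus_arc_um <- fit$nucleus_arc
      rec$relative_position <- relative_nuclear_position(fit)
    }
    res[[i]] <- as.data.frame(rec, stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Read a landmark CSV
#'
#' Expected columns: `cell_id, group, age, ax, ay, az, nx, ny, nz, bx, by,
#' bz, units, voxel_z, voxel_y, voxel_x`. `units` is `"um"` or `"voxel"`;
#' voxel-unit rows are converted to physical micrometres at parse time using
#' the per-row voxel size. `group`/`age` and the voxel columns are optional
#' when `units` is `"um"` throughout.
#'
#' @param path CSV file path.
#' @return data frame in physical um, suitable for [batch_positions()].
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "ax", "ay", "az", "nx", "ny", "nz", "bx", "by", "bz")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("landmark CSV lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!"units" %in% names(df)) df$units <- "um"
  vox <- df$units == "voxel"
  if (any(vox)) {
    for (v in c("voxel_z", "voxel_y", "voxel_x"))
      if (!v %in% names(df))
        stop("voxel-unit rows need voxel_z/voxel_y/voxel_x columns",
             call. = FALSE)
    for (axis in c("x", "y", "z")) {
      vcol <- df[[paste0("voxel_", axis)]]
      for (pref in c("a", "n", "b")) {
        col <- paste0(pref, axis)
        df[[col]][vox] <- df[[col]][vox] * vcol[vox]
      }
    }
    df$units <- "um"
  }
  df
}
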