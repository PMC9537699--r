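#' Ordered cisternae segments along a membrane contour
#'
#' Submembrane cisternae annotated as intervals `[start, end]` (um) along
#' the lateral-membrane contour of one outer hair cell. Intervals must be
#' sorted, non-overlapping and lie within `[0, contour_length]`.
#'
#' @param segments two-column matrix or data frame (`start`, `end`) in um.
#' @param contour_length total contour length in um.
#' @param cell_id,group labels carried to outputs.
#' @return object of class `cisternae_profile`.
#' @export
cisternae_profile <- function(segments, contour_length, cell_id = "cell",
                              group = NA_character_) {
  seg <- as.matrix(segments)
  if (ncol(seg) != 2L) stop("segments must have two columns (start, end)",
                            call. = FALSE)
  colnames(seg) <- c("start", "end")
  if (nrow(seg) == 0L) stop("profile needs at least one segment", call. = FALSE)
  if (any(!is.finite(seg))) stop("segment coordinates must be finite",
                                 call. = FALSE)
  if (any(seg[, "end"] <= seg[, "start"])) {
    i <- which(seg[, "end"] <= seg[, "start"])[1]
    stop(sprintf("segment %d has end (%.3f) <= start (%.3f)",
                 i, seg[i, "end"], seg[i, "start"]), call. = FALSE)
  }
  if (nrow(seg) > 1L) {
    ov <- which(seg[-1L, "start"] < seg[-nrow(seg), "end"])
    if (length(ov))
      stop(sprintf("segments %d and %d overlap or are unsorted (end %.3f > start %.3f)",
                   ov[1], ov[1] + 1L, seg[ov[1], "end"], seg[ov[1] + 1L, "start"]),
           call. = FALSE)
  }
  if (min(seg) < 0 || max(seg) > contour_length + 1e-9)
    stop("segments must lie within [0, contour_length]", call. = FALSE)
  structure(list(segments = seg, contour_length = contour_length,
                 cell_id = as.character(cell_id), group = group),
            class = "cisternae_profile")
}

#' Lateral gap lengths between adjacent cisternae
#'
#' The length of each gap between consecutive segments,
#' \eqn{g_i = start_{i+1} - end_i}: interior gaps only, never the distance
#' from a terminal segment to the contour ends. A single-segment profile has
#' no gaps and an undefined (`NA`) mean.
#'
#' @param profile a [cisternae_profile()].
#' @return list of class `gap_set`: `gaps` (um), `mean_gap`, `n_segments`,
#'   `cell_id`, `group`.
#' @export
gap_lengths <- function(profile) {
  stopifnot(inherits(profile, "cisternae_profile"))
  seg <- profile$segments
  n <- nrow(seg)
  gaps <- if (n < 2L) numeric(0) else seg[-1L, "start"] - seg[-n, "end"]
  structure(list(gaps = unname(gaps),
                 mean_gap = if (length(gaps)) mean(gaps) else NA_real_,
                 n_segments = n, cell_id = profile$cell_id,
                 group = profile$group),
            class = "gap_set")
}

#' Compare cisternae gap lengths between two groups
#'
#' Pools gap lengths per group across profiles, summarises them
#' (n, mean, SD, plus per-cell mean gaps) and compares the two groups with a
#' two-sided Mann-Whitney test.
#'
#' @param profiles list of [cisternae_profile()] objects; group labels are
#'   taken from the profiles unless `groups` is given.
#' @param groups optional character vector overriding per-profile groups.
#' @param by `"gap"` (each gap one observation, the default) or `"cell"`
#'   (per-cell mean gap as the observation).
#' @return list: `summary` data frame (group, n, mean, sd), `per_cell`
#'   data frame of per-cell means, and `test` (Mann-Whitney `hcm_test`).
#' @export
compare_gap_groups <- function(profiles, groups = NULL, by = c("gap", "cell")) {
  by <- match.arg(by)
  if (is.null(groups))
    groups <- vapply(profiles, function(p) as.character(p$group), "")
  if (length(groups) != length(profiles))
    stop("groups must be parallel to profiles", call. = FALSE)
  gs <- lapply(profiles, gap_lengths)
  per_cell <- data.frame(
    cell_id = vapply(gs, function(g) g$cell_id, ""),
    group = groups,
    n_gaps = vapply(gs, function(g) length(g$gaps), 0L),
    mean_gap = vapply(gs, function(g) g$mean_gap, 0),
    stringsAsFactors = FALSE)
  lv <- unique(groups)
  if (length(lv) != 2L)
    stop("exactly two groups are required, got: ",
         paste(lv, collapse = ", "), call. = FALSE)
  pooled <- lapply(lv, function(g) {
    if (by == "gap") unlist(lapply(gs[groups == g], function(x) x$gaps))
    else per_cell$mean_gap[per_cell$group == g & !is.na(per_cell$mean_gap)]
  })
  bad <- lv[vapply(pooled, length, 0L) == 0L]
  if (length(bad))
    stop("group '", bad[1], "' contributes no gaps (single-segment profiles ",
         "have none); cannot compare", call. = FALSE)
  summary_df <- data.frame(group = lv,
                           n = vapply(pooled, length, 0L),
                           mean = vapply(pooled, mean, 0),
                           sd = vapply(pooled, sd, 0),
                           stringsAsFactors = FALSE)
  test <- mann_whitney(pooled[[1]], pooled[[2]],
                       labels = lv)
  list(summary = summary_df, per_cell = per_cell, test = test, by = by)
}

#' Read / write cisternae profile CSVs
#'
#' Long format, one row per segment: `cell_id, group, contour_length_um,
#' segment_index, start_um, end_um`.
#'
#' @param path CSV path.
#' @return `read_cisternae_profiles()`: a list of [cisternae_profile()].
#' @export
read_cisternae_profiles <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "contour_length_um", "start_um", "end_um")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("profile CSV lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  lapply(split(df, df$cell_id), function(d) {
    d <- d[order(d$start_um), ]
    cisternae_profile(cbind(d$start_um, d$end_um), d$contour_length_um[1],
                      cell_id = d$cell_id[1],
                      group = if ("group" %in% names(d)) d$group[1] else NA)
  })
}

#' @rdname read_cisternae_profiles
#' @param profiles list of [cisternae_profile()] objects.
#' @export
write_cisternae_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    data.frame(cell_id = p$cell_id, group = p$group,
               contour_length_um = p$contour_length,
               segment_index = seq_len(nrow(p$segments)),
               start_um = p$segments[, "start"],
               end_um = p$segments[, "end"], stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
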