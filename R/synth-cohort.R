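#' Specification of a synthetic measurement cohort
#'
#' Describes a cohort of per-cell relative nuclear positions organised by
#' group (e.g. genotype) and age. Per-(group, age) means let a cohort encode
#' an onset design: groups identical at early ages and diverging at later
#' ones, as seen when a phenotype appears with the onset of electromotility
#' around P12.
#'
#' @param n_cells_per_group integer, cells per group per age (scalar or
#'   named per group).
#' @param group_means named list: for each group either a scalar mean or a
#'   vector named by age.
#' @param group_sds as `group_means`; all values >= 0.
#' @param ages character vector of age labels, in chronological order.
#' @param seed integer; the cohort is a pure function of the spec.
#' @return object of class `synthetic_cohort_spec`.
#' @export
cohort_spec <- function(n_cells_per_group, group_means, group_sds,
                        ages = "P14", seed = 1L) {
  if (is.null(names(group_means)) || is.null(names(group_sds)) ||
      !setequal(names(group_means), names(group_sds)))
    stop("group_means and group_sds must be named by the same groups",
         call. = FALSE)
  if (length(names(group_means)) == 0L)
    stop("at least one group is required", call. = FALSE)
  if (any(unlist(group_sds) < 0)) stop("sd < 0 is not allowed", call. = FALSE)
  n <- n_cells_per_group
  if (length(n) == 1L) n <- setNames(rep(n, length(group_means)),
                                     names(group_means))
  if (any(n < 1)) stop("groups must be non-empty", call. = FALSE)
  structure(list(n_cells_per_group = n, group_means = group_means,
                 group_sds = group_sds, ages = as.character(ages),
                 seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

.per_age <- function(x, ages, what) {
  if (length(x) == 1L && is.null(names(x))) return(setNames(rep(x, length(ages)), ages))
  if (!all(ages %in% names(x)))
    stop(what, " must be a scalar or named by every age", call. = FALSE)
  x[ages]
}

#' Generate a synthetic cohort of relative nuclear positions
#'
#' Draws per-cell values from truncated normal distributions on `[0, 1]`
#' (inverse-CDF sampling, so identical seeds give bit-identical cohorts).
#'
#' @param spec a [cohort_spec()].
#' @return list: `table` (data frame `cell_id, group, age, value`) and
#'   `truth` (the spec plus the drawn values, i.e. per-cell ground truth).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  groups <- names(spec$group_means)
  rows <- .with_seed(spec$seed, {
    out <- list()
    for (age in spec$ages) {
      for (g in groups) {
        mu <- .per_age(unlist(spec$group_means[[g]]), spec$ages, "group_means")[[age]]
        sd_g <- .per_age(unlist(spec$group_sds[[g]]), spec$ages, "group_sds")[[age]]
        n <- spec$n_cells_per_group[[g]]
        vals <- .rtruncnorm01(n, mu, sd_g)
        out[[paste(age, g)]] <- data.frame(
          cell_id = sprintf("%s_%s_%03d", g, age, seq_len(n)),
          group = g, age = age, value = vals, stringsAsFactors = FALSE)
      }
    }
    out
  })
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table, truth = list(spec = spec, values = table))
}

# truncated normal on [0, 1] by inverse-CDF; degenerates to clamped constant
# when sd = 0
.rtruncnorm01 <- function(n, mean, sd) {
  if (sd == 0) return(rep(min(1, max(0, mean)), n))
  plo <- pnorm(0, mean, sd); phi <- pnorm(1, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic cisternae profile with known gaps
#'
#' Lays out `segment_lengths` in order, separated by `gap_lengths`, along a
#' contour of length `contour_length`. With `randomize = TRUE` the whole
#' layout is shifted by a random offset drawn within the available slack;
#' gaps are unaffected either way.
#'
#' @param contour_length um.
#' @param segment_lengths lengths of the cisternae segments, um (>= 1).
#' @param gap_lengths lengths of the interior gaps, um; must number one
#'   fewer than the segments (empty for a single segment).
#' @param seed integer, used only when `randomize = TRUE`.
#' @param randomize randomly offset the layout along the contour.
#' @param cell_id,group labels attached to the profile.
#' @return list: `profile` (a [cisternae_profile()]) and `truth`
#'   (`gap_lengths` as requested).
#' @export
generate_cisternae_profile <- function(contour_length, segment_lengths,
                                       gap_lengths = numeric(0), seed = 1L,
                                       randomize = FALSE, cell_id = "cell",
                                       group = NA_character_) {
  if (length(segment_lengths) < 1L) stop("need at least one segment",
                                         call. = FALSE)
  if (length(gap_lengths) != length(segment_lengths) - 1L)
    stop("need exactly one gap fewer than segments", call. = FALSE)
  if (any(segment_lengths <= 0)) stop("segment lengths must be > 0",
                                      call. = FALSE)
  if (any(gap_lengths < 0)) stop("gap lengths must be >= 0", call. = FALSE)
  total <- sum(segment_lengths) + sum(gap_lengths)
  if (total > contour_length + 1e-9)
    stop(sprintf("segments + gaps (%.3f um) exceed the contour (%.3f um)",
                 total, contour_length), call. = FALSE)
  offset <- if (randomize)
    .with_seed(seed, runif(1, 0, contour_length - total)) else 0
  starts <- offset + cumsum(c(0, segment_lengths[-length(segment_lengths)] +
                                gap_lengths))
  ends <- starts + segment_lengths
  prof <- cisternae_profile(cbind(starts, ends), contour_length,
                            cell_id = cell_id, group = group)
  list(profile = prof, truth = list(gap_lengths = gap_lengths))
}

#' Generate a cohort of synthetic cisternae profiles for two groups
#'
#' Gap lengths are drawn from group-specific normal distributions truncated
#' at zero; segment lengths are drawn uniformly. Mirrors the design of a
#' TEM gap-length comparison between genotypes.
#'
#' @param n_cells_per_group cells per group.
#' @param gap_mean,gap_sd named (by group) gap-length means / sds, um.
#' @param n_segments segments per cell.
#' @param segment_range uniform range of segment lengths, um.
#' @param seed integer.
#' @return list of [cisternae_profile()] objects with group labels set.
#' @export
generate_cisternae_cohort <- function(n_cells_per_group = 8,
                                      gap_mean = c(wt = 0.5, mut = 2.0),
                                      gap_sd = c(wt = 0.1, mut = 0.1),
                                      n_segments = 5, segment_range = c(1.5, 3),
                                      seed = 1L) {
  stopifnot(setequal(names(gap_mean), names(gap_sd)))
  .with_seed(seed, {
    profs <- list()
    for (g in names(gap_mean)) {
      for (i in seq_len(n_cells_per_group)) {
        segs <- runif(n_segments, segment_range[1], segment_range[2])
        gaps <- pmax(0, rnorm(n_segments - 1, gap_mean[[g]], gap_sd[[g]]))
        contour <- sum(segs) + sum(gaps) + 5
        id <- sprintf("%s_%02d", g, i)
        profs[[id]] <- generate_cisternae_profile(
          contour, segs, gaps, randomize = FALSE,
          cell_id = id, group = g)$profile
      }
    }
    profs
  })
}
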