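#' Pipeline configuration
#'
#' Validated configuration for the end-to-end simulate - quantify - compare
#' pipeline. Accepts a named list or a YAML file path; unknown keys are
#' rejected so typos cannot silently fall back to defaults. The
#' configuration round-trips losslessly through YAML.
#'
#' Keys and defaults: `seed` (1); `band_width` (1.1 um); `threshold_method`
#' ("otsu"); `region_span` (200 um); `alpha`/`q` (0.05); `curvature` (0.3);
#' `n_image_cells` (4) with `image_enrichment` (named k per group);
#' `write_images` (FALSE); `cohort` (n_per_group, ages, group means/sds per
#' age); `cisternae` (n_per_group, gap_mean, gap_sd per group).
#'
#' @param x named list, YAML path, or `NULL` for all defaults.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(x = NULL) {
  if (is.character(x) && length(x) == 1L) x <- yaml::read_yaml(x)
  if (is.null(x)) x <- list()
  stopifnot(is.list(x))
  defaults <- list(
    seed = 1L,
    band_width = 1.1,
    threshold_method = "otsu",
    region_span = 200,
    alpha = 0.05,
    q = 0.05,
    curvature = 0.3,
    n_image_cells = 4L,
    image_enrichment = list(control = 1, enriched = 3),
    write_images = FALSE,
    cohort = list(
      n_per_group = 10L,
      ages = c("P8", "P10", "P12", "P14"),
      group_means = list(het = list(P8 = 0.75, P10 = 0.75, P12 = 0.75, P14 = 0.75),
                         ko = list(P8 = 0.75, P10 = 0.75, P12 = 0.50, P14 = 0.50)),
      group_sds = list(het = 0.05, ko = 0.08)),
    cisternae = list(n_per_group = 6L,
                     gap_mean = list(wt = 0.5, mut = 2.0),
                     gap_sd = list(wt = 0.1, mut = 0.1)))
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, x)
  if (!is.numeric(cfg$band_width) || cfg$band_width <= 0)
    stop("band_width must be > 0", call. = FALSE)
  if (cfg$region_span <= 0) stop("region_span must be > 0", call. = FALSE)
  if (!cfg$threshold_method %in% c("otsu", "isodata"))
    stop("threshold_method must be 'otsu' or 'isodata'", call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha >= 1 || cfg$q <= 0 || cfg$q >= 1)
    stop("alpha and q must lie in (0, 1)", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_image_cells <- as.integer(cfg$n_image_cells)
  cfg$cohort$n_per_group <- as.integer(cfg$cohort$n_per_group)
  cfg$cisternae$n_per_group <- as.integer(cfg$cisternae$n_per_group)
  cfg$cohort$ages <- as.character(cfg$cohort$ages)
  structure(cfg, class = "pipeline_config")
}

#' Write a configuration to YAML
#' @param config a [pipeline_config()].
#' @param path output file.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full simulate - quantify - compare pipeline
#'
#' Stage 1 simulates ground-truthed inputs (image stacks with landmark
#' annotations, a multi-age position cohort, cisternae profiles); stage 2
#' quantifies them (axis positions, recruitment indices, gap lengths);
#' stage 3 runs the cohort comparisons (onset analysis across ages,
#' gap-group Mann-Whitney, normality checks). All outputs are CSV/JSON in
#' `out_dir`; a `manifest.json` records the package version, configuration
#' and per-stage row counts. Given the same configuration (including seed)
#' the output tables are byte-identical across runs.
#'
#' @param config a [pipeline_config()], or anything accepted by it.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the output paths and key results.
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline_log.jsonl")
  if (file.exists(log_path)) unlink(log_path)
  log_line <- function(stage, ...) {
    rec <- list(stage = stage, ...)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE, sep = "")
  }

  ## stage 1 + 2a: synthetic image cells -> landmarks -> positions, recruitment
  groups_k <- cfg$image_enrichment
  cell_groups <- rep(names(groups_k), length.out = cfg$n_image_cells)
  stacks <- list(); lm_rows <- list(); truth_pos <- numeric(0)
  for (i in seq_len(cfg$n_image_cells)) {
    g <- cell_groups[i]
    spec <- cell_spec(axis_curvature = cfg$curvature,
                      true_relative_position = 0.75,
                      ne_enrichment_factor = groups_k[[g]])
    sim <- generate_cell_image(spec, seed = (cfg$seed %% 100000L) * 1000L + i)
    id <- sprintf("img_%02d", i)
    stacks[[id]] <- sim$stack
    lm <- landmarks_from_truth(sim$truth, sim$stack,
                               nucleus_from = "segmented",
                               method = cfg$threshold_method)
    lm_rows[[id]] <- data.frame(
      cell_id = id, group = g, age = "P9",
      ax = lm$apical[1], ay = lm$apical[2], az = lm$apical[3],
      nx = lm$nucleus_centroid[1], ny = lm$nucleus_centroid[2],
      nz = lm$nucleus_centroid[3],
      bx = lm$basal[1], by = lm$basal[2], bz = lm$basal[3],
      units = "um", stringsAsFactors = FALSE)
    truth_pos[id] <- sim$truth$true_relative_position
    if (isTRUE(cfg$write_images)) {
      dir.create(file.path(out_dir, "images"), showWarnings = FALSE)
      write_image_stack(sim$stack, file.path(out_dir, "images", id))
    }
  }
  landmarks <- do.call(rbind, lm_rows)
  f_landmarks <- file.path(out_dir, "landmarks.csv")
  write.csv(landmarks, f_landmarks, row.names = FALSE)
  positions <- batch_positions(landmarks)
  positions$true_relative_position <- unname(truth_pos[positions$cell_id])
  f_positions <- file.path(out_dir, "positions.csv")
  write.csv(positions, f_positions, row.names = FALSE)
  log_line("positions", rows = nrow(positions),
           failed = sum(positions$status != "ok"))

  recruit <- batch_recruitment(stacks, groups = cell_groups,
                               band_width = cfg$band_width,
                               method = cfg$threshold_method)
  f_recruit <- file.path(out_dir, "recruitment.csv")
  write.csv(recruit, f_recruit, row.names = FALSE)
  log_line("recruitment", rows = nrow(recruit),
           failed = sum(recruit$status != "ok"))

  ## stage 1 + 2b: position cohort across ages, onset comparison
  cs <- cohort_spec(cfg$cohort$n_per_group,
                    cfg$cohort$group_means, cfg$cohort$group_sds,
                    ages = cfg$cohort$ages, seed = cfg$seed + 1L)
  cohort <- generate_cohort(cs)
  f_cohort <- file.path(out_dir, "cohort.csv")
  write.csv(cohort$table, f_cohort, row.names = FALSE)
  onset <- onset_analysis(cohort$table, ages = cfg$cohort$ages, q = cfg$q)
  f_onset <- file.path(out_dir, "onset.csv")
  write.csv(onset$table, f_onset, row.names = FALSE)
  norm <- normality_check(cohort$table$value, cohort$table$group,
                          alpha = cfg$alpha)
  f_norm <- file.path(out_dir, "normality.csv")
  write.csv(norm, f_norm, row.names = FALSE)
  log_line("cohort", rows = nrow(cohort$table),
           onset_age = if (is.na(onset$onset_age)) NA else onset$onset_age)

  ## stage 1 + 2c: cisternae profiles, gap comparison
  profs <- generate_cisternae_cohort(
    n_cells_per_group = cfg$cisternae$n_per_group,
    gap_mean = unlist(cfg$cisternae$gap_mean),
    gap_sd = unlist(cfg$cisternae$gap_sd),
    seed = cfg$seed + 2L)
  f_profiles <- file.path(out_dir, "cisternae_profiles.csv")
  write_cisternae_profiles(profs, f_profiles)
  gaps_long <- do.call(rbind, lapply(profs, function(p) {
    gl <- gap_lengths(p)
    if (!length(gl$gaps)) return(NULL)
    data.frame(cell_id = gl$cell_id, group = gl$group,
               gap_index = seq_along(gl$gaps), gap_um = gl$gaps,
               stringsAsFactors = FALSE)
  }))
  rownames(gaps_long) <- NULL
  f_gaps <- file.path(out_dir, "gaps.csv")
  write.csv(gaps_long, f_gaps, row.names = FALSE)
  cmp <- compare_gap_groups(profs)
  gap_summary <- cmp$summary
  gap_summary$mann_whitney_p <- cmp$test$p_value
  f_gapcmp <- file.path(out_dir, "gap_comparison.csv")
  write.csv(gap_summary, f_gapcmp, row.names = FALSE)
  log_line("cisternae", rows = nrow(gaps_long), p = cmp$test$p_value)

  ## manifest
  cfg_file <- file.path(out_dir, "config.yaml")
  write_pipeline_config(cfg, cfg_file)
  manifest <- list(
    package = "hcmorph",
    version = as.character(packageVersion("hcmorph")),
    config_md5 = unname(tools::md5sum(cfg_file)),
    seed = cfg$seed,
    tables = list(landmarks = nrow(landmarks), positions = nrow(positions),
                  recruitment = nrow(recruit), cohort = nrow(cohort$table),
                  onset = nrow(onset$table), gaps = nrow(gaps_long)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(out_dir = out_dir,
                 files = c(landmarks = f_landmarks, positions = f_positions,
                           recruitment = f_recruit, cohort = f_cohort,
                           onset = f_onset, normality = f_norm,
                           profiles = f_profiles, gaps = f_gaps,
                           gap_comparison = f_gapcmp),
                 onset_age = onset$onset_age,
                 gap_p = cmp$test$p_value,
                 positions = positions, recruitment = recruit))
}
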