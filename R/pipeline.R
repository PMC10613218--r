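#' End-to-end run configuration
#'
#' Bundles everything one batch analysis needs: the synthetic-scene
#' parameters (or, in future, paths to real data), channel roles, the
#' detector, profile and contact settings, the output directory and the
#' seed. Every procedure constant is echoed into the run's config file so
#' runs are self-describing.
#'
#' @param scene A [scene_params()] template; each cell uses
#'   `seed = seed + cell index`.
#' @param n_cells Number of cells (scenes) in the batch.
#' @param channels Named list of channel roles: `vesicle`, `marker`,
#'   `mito`, `nucleus`.
#' @param detector A [detector_config()].
#' @param profile A [profile_config()] for marker scoring (40-px lines).
#' @param mmcs_length_px Profile length for contact scoring (50-px lines).
#' @param mmcs_background `"auto"` or numeric; see [detect_mmcs()].
#' @param calibrate_threshold Calibrate the detector quality threshold from
#'   a blank noise image (recommended for synthetic data, whose intensity
#'   scale differs from the instrument scale of the default thresholds).
#' @param run_mmcs Score mitochondrion contacts as part of the run.
#' @param out_dir Optional output directory for CSV artifacts.
#' @param seed Base seed for the whole run.
#' @return A `run_config` object.
#' @export
run_config <- function(scene = scene_params(), n_cells = 5,
                       channels = list(vesicle = "CD63", marker = "marker",
                                       mito = "mito", nucleus = "DAPI"),
                       detector = detector_config(),
                       profile = profile_config(direction_mode = "toward-marker"),
                       mmcs_length_px = 50, mmcs_background = "auto",
                       calibrate_threshold = TRUE, run_mmcs = TRUE,
                       out_dir = NULL, seed = 1L) {
  stopifnot(inherits(scene, "scene_params"), inherits(detector, "detector_config"),
            inherits(profile, "profile_config"), n_cells >= 1)
  if (!all(c("vesicle", "marker") %in% names(channels))) {
    abort("`channels` must name at least the vesicle and marker roles.",
          class = "vesicoloc_parameter_error")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full quantification pipeline on a synthetic batch
#'
#' For each cell: generate the scene, freeze the per-channel display ranges
#' on the first cell and convert to 8-bit, detect vesicles by
#' scale-normalized LoG, score each detection against the marker channel by
#' the 40-px line-profile peak-overlap rule, and (optionally) score
#' mitochondrion contacts along 50-px profiles with perinuclear/peripheral
#' assignment. Deterministic given the config seed.
#'
#' @param config A [run_config()].
#' @return A `vesicoloc_run` object: tibbles `detections`, `calls`,
#'   `contacts`, `cell_summary`, plus the frozen display ranges, calibrated
#'   threshold and config. When `config$out_dir` is set, CSV artifacts and
#'   a YAML config echo are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ch <- config$channels
  detections <- list(); calls <- list(); contacts <- list(); summary_rows <- list()
  ranges <- NULL; threshold <- config$detector$quality_threshold

  for (cell in seq_len(config$n_cells)) {
    p <- config$scene
    p$seed <- config$seed + cell
    gen <- generate_scene(p)
    scene <- gen$scene; stack <- gen$stack
    if (is.null(ranges)) {
      ranges <- auto_display_range(stack)
      if (config$calibrate_threshold) {
        blank <- render_blank_plane(p, seed = config$seed)
        rv <- ranges[[ch$vesicle]]
        blank8 <- pmin(pmax(round_half_up(
          255 * (blank - rv$low) / (rv$high - rv$low)), 0), 255)
        threshold <- calibrate_quality_threshold(blank8,
                                                 config$detector$diameter_px)
      }
    }
    stack8 <- to_8bit(stack, ranges)
    det_cfg <- config$detector
    det_cfg$quality_threshold <- threshold
    det <- detect_spots(get_plane(stack8, ch$vesicle), det_cfg)
    cell_calls <- score_vesicles(det, stack8, ch$vesicle, ch$marker,
                                 config$profile)
    part <- partition_cell_regions(scene$nucleus_mask, scene$cell_mask)
    cell_calls <- assign_regions(cell_calls, part)

    cell_contacts <- NULL
    region_counts <- tibble(perinuclear = NA_integer_,
                            peripheral = NA_integer_,
                            whole_cell = NA_integer_)
    if (config$run_mmcs && !is.null(ch$mito) && any(scene$mito_mask)) {
      cell_contacts <- detect_mmcs(det, stack8, ch$vesicle, ch$mito,
                                   scene$mito_mask,
                                   length_px = config$mmcs_length_px,
                                   background = config$mmcs_background)
      cell_contacts <- assign_regions(cell_contacts, part)
      region_counts <- count_contacts_by_region(cell_contacts, part)
      contacts[[cell]] <- mutate(cell_contacts, cell_id = cell, .before = 1)
    }
    detections[[cell]] <- mutate(det, cell_id = cell, .before = 1)
    calls[[cell]] <- mutate(cell_calls, cell_id = cell, .before = 1)
    summary_rows[[cell]] <- dplyr::bind_cols(
      tibble(cell_id = cell, n_vesicles = nrow(det),
             n_true_vesicles = nrow(scene$truth),
             pct_marker_positive = percent_marker_positive(cell_calls),
             true_pct_marker_positive =
               if (nrow(scene$truth)) 100 * mean(scene$truth$is_marker_positive)
               else NA_real_),
      region_counts)
  }

  run <- structure(
    list(config = config,
         display_ranges = ranges,
         quality_threshold = threshold,
         detections = list_rbind(detections),
         calls = list_rbind(calls),
         contacts = if (length(contacts)) list_rbind(contacts) else
           tibble(cell_id = integer(), vesicle_id = integer(), x = numeric(),
                  y = numeric(), is_contact = logical()),
         cell_summary = list_rbind(summary_rows)),
    class = "vesicoloc_run")

  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(run$detections, file.path(dir, "detections.csv"))
  readr::write_csv(run$calls, file.path(dir, "calls.csv"))
  readr::write_csv(run$contacts, file.path(dir, "contacts.csv"))
  readr::write_csv(run$cell_summary, file.path(dir, "cell_summary.csv"))
  cfg <- run$config
  echo <- list(
    seed = cfg$seed, n_cells = cfg$n_cells,
    channels = cfg$channels,
    detector = unclass(cfg$detector),
    calibrated_quality_threshold = run$quality_threshold,
    profile = unclass(cfg$profile),
    mmcs = list(length_px = cfg$mmcs_length_px,
                background = as.character(cfg$mmcs_background)),
    display_ranges = lapply(run$display_ranges, unclass),
    scene = lapply(unclass(cfg$scene), function(x) {
      if (is.numeric(x)) as.numeric(x) else x
    })
  )
  yaml::write_yaml(echo, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @export
print.vesicoloc_run <- function(x, ...) {
  cat(sprintf("<vesicoloc_run> %d cell(s), %d detection(s)\n",
              x$config$n_cells, nrow(x$detections)))
  cat(sprintf("  marker-positive: %.1f%% (true %.1f%%)\n",
              percent_marker_positive(x$calls),
              mean(x$cell_summary$true_pct_marker_positive)))
  if (any(!is.na(x$cell_summary$whole_cell))) {
    cat(sprintf("  contacts/cell: %.1f (%.1f perinuclear, %.1f peripheral)\n",
                mean(x$cell_summary$whole_cell),
                mean(x$cell_summary$perinuclear),
                mean(x$cell_summary$peripheral)))
  }
  invisible(x)
}

#' @describeIn run_pipeline Per-vesicle colocalization calls of a run.
#' @param x A `vesicoloc_run`.
#' @param ... Unused.
#' @export
tidy.vesicoloc_run <- function(x, ...) x$calls

#' @describeIn run_pipeline One-row summary of a run: cells, detections,
#'   estimated and true marker-positive percentages, mean contacts per cell.
#' @export
glance.vesicoloc_run <- function(x, ...) {
  tibble(
    n_cells = x$config$n_cells,
    n_detections = nrow(x$detections),
    pct_marker_positive = percent_marker_positive(x$calls),
    true_pct_marker_positive = mean(x$cell_summary$true_pct_marker_positive),
    mean_contacts_per_cell = mean(x$cell_summary$whole_cell),
    quality_threshold = x$quality_threshold
  )
}
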