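# Pipeline orchestration: simulate/read -> quantify -> compare, with an
# audit trail of every filter decision and reproducible outputs.

#' Quantify a cohort of tracks
#'
#' Runs the quantification stages on a validated track-point table: step
#' computation, pause detection, inclusion filtering, per-animal
#' aggregation, speed-frequency histograms and (when punctum widths are
#' available) axon-caliber estimation. Quantification is independent of any
#' downstream statistics.
#'
#' @param points A track-point table ([read_track_table()] /
#'   [simulate_cohort()]).
#' @param epsilon Pause tolerance in um (default 0.1); see [track_steps()].
#' @param bin_width Speed-histogram bin width in um/s (default 0.2).
#' @param min_frames,max_pause_images Inclusion-rule thresholds
#'   ([flag_inclusion()]).
#' @param histogram,caliber Compute the histogram / caliber stages (default
#'   `TRUE`).
#' @param warn_minima Warn about animals below the reporting minima
#'   (default `TRUE`).
#' @return A list of tibbles: `steps` (all steps, with an `included`
#'   column), `track_metrics`, `summary` (per animal, with `caliber_um`
#'   when computed), `histogram`, `group_profile`, `axon_calibers`, and
#'   `filter_log` (per-animal exclusion counts per rule).
#' @export
quantify_cohort <- function(points, epsilon = 0.1, bin_width = 0.2,
                            min_frames = 5, max_pause_images = 10,
                            histogram = TRUE, caliber = TRUE,
                            warn_minima = TRUE) {
  pts <- validate_track_table(points)
  steps <- track_steps(pts, epsilon = epsilon)
  metrics <- flag_inclusion(track_metrics(steps), min_frames = min_frames,
                            max_pause_images = max_pause_images)
  inc_keys <- metrics[metrics$included, c("animal_id", "axon_id", "track_id")]
  steps <- dplyr::left_join(
    steps,
    metrics[c("animal_id", "axon_id", "track_id", "included")],
    by = c("animal_id", "axon_id", "track_id")
  )
  summary <- animal_summary(metrics, warn_minima = warn_minima)

  filter_log <- dplyr::summarise(
    dplyr::group_by(metrics, .data$animal_id, .data$group),
    n_input = dplyr::n(),
    n_included = sum(.data$included),
    n_too_short = sum(.data$exclusion_reason == "too_short", na.rm = TRUE),
    n_long_pause = sum(.data$exclusion_reason == "long_pause", na.rm = TRUE),
    n_anterograde = sum(.data$exclusion_reason == "anterograde", na.rm = TRUE),
    .groups = "drop"
  )

  hist <- NULL
  profile <- NULL
  if (histogram) {
    hist <- speed_histogram(steps[steps$included, ], bin_width = bin_width)
    profile <- group_speed_profile(hist)
  }

  axon_cal <- NULL
  if (caliber && any(!is.na(pts$width_um))) {
    inc_pts <- dplyr::semi_join(pts, inc_keys,
                                by = c("animal_id", "axon_id", "track_id"))
    axon_cal <- axon_caliber(inc_pts)
    an_cal <- animal_caliber(axon_cal)
    summary <- dplyr::left_join(
      summary, an_cal[c("animal_id", "group", "caliber_um")],
      by = c("animal_id", "group")
    )
  }

  list(steps = steps, track_metrics = metrics, summary = summary,
       histogram = hist, group_profile = profile, axon_calibers = axon_cal,
       filter_log = filter_log)
}

blind_map <- function(labels, seed) {
  blinded <- sprintf("blind_%02d", seq_along(labels))
  real <- withr::with_seed(seed, sample(labels))
  stats::setNames(real, blinded)  # blinded -> real
}

#' Run the full pipeline
#'
#' Simulates (or reads) a cohort, quantifies it, compares the per-animal
#' metrics between groups, and writes the report bundle to `output_dir`:
#' `tracks.csv` (simulated cohorts), `summary.csv`, `steps.csv`,
#' `histogram.csv`, `group_profile.csv`, `comparisons.csv`,
#' `filter_log.csv`, and `config.yaml` for provenance. Outputs are
#' deterministic given the same configuration and seed. With
#' `blind = TRUE`, group labels are replaced by a keyed mapping before any
#' statistics are computed and unblinded only in the written report,
#' mirroring genotype-blinded tracking.
#'
#' @param input A `sim_params` object, a preset name (see
#'   [preset_params()]), or a path to a track-table CSV.
#' @param output_dir Directory for the report bundle (`NULL` writes
#'   nothing).
#' @param epsilon,bin_width,min_frames,max_pause_images Quantification
#'   parameters (see [quantify_cohort()]).
#' @param control Control group label for many-to-one comparisons; defaults
#'   to the simulation preset's control.
#' @param paired Within-animal paired design; defaults to the preset's
#'   design, else `FALSE`.
#' @param alpha Significance level (default 0.05, two-tailed throughout).
#' @param seed Integer seed controlling simulation and blinding.
#' @param blind Blind group labels during statistics?
#' @param force Force a statistical branch (see [compare_metrics()]).
#' @param compare Run the statistics stage (default `TRUE`);
#'   quantification outputs are identical either way.
#' @param warn_minima Passed to [quantify_cohort()].
#' @return (Invisibly) a list with `points`, the [quantify_cohort()]
#'   bundle, `comparisons`, and the effective `config`.
#' @export
run_pipeline <- function(input, output_dir = NULL, epsilon = 0.1,
                         bin_width = 0.2, min_frames = 5,
                         max_pause_images = 10, control = NULL,
                         paired = NULL, alpha = 0.05, seed = NULL,
                         blind = FALSE, force = NULL, compare = TRUE,
                         warn_minima = TRUE) {
  simulated <- FALSE
  params <- NULL
  if (inherits(input, "sim_params")) {
    params <- input
  } else if (is.character(input) && length(input) == 1 && !file.exists(input)) {
    params <- preset_params(input)
  }
  if (!is.null(params)) {
    simulated <- TRUE
    cohort <- simulate_cohort(params, seed = seed)
    points <- cohort$points
    if (is.null(control)) control <- params$control
    if (is.null(paired)) paired <- params$paired
  } else if (is.character(input) && file.exists(input)) {
    points <- read_track_table(input)
    if (is.null(paired)) paired <- FALSE
  } else if (is.data.frame(input)) {
    points <- validate_track_table(input)
    if (is.null(paired)) paired <- FALSE
  } else {
    abort("input must be sim_params, a preset name, a CSV path, or a track table",
          class = "endotrack_param_error")
  }

  groups <- unique(points$group)
  if (!is.null(control) && !control %in% groups) {
    abort(sprintf("control group '%s' not present in the input (groups: %s)",
                  control, paste(groups, collapse = ", ")),
          class = "endotrack_validation_error")
  }

  q <- quantify_cohort(points, epsilon = epsilon, bin_width = bin_width,
                       min_frames = min_frames,
                       max_pause_images = max_pause_images,
                       warn_minima = warn_minima)

  comparisons <- NULL
  if (compare && length(groups) >= 2) {
    s <- q$summary
    if (blind) {
      map <- blind_map(groups, seed = if (is.null(seed)) 0L else seed + 7L)
      rev_map <- stats::setNames(names(map), map)  # real -> blinded
      s$group <- unname(rev_map[s$group])
      bl_control <- if (is.null(control)) NULL else unname(rev_map[control])
      comparisons <- compare_metrics(s, control = bl_control, paired = paired,
                                     alpha = alpha, force = force)
      # unblind for the report
      for (b in names(map)) {
        comparisons$contrast <- gsub(b, map[[b]], comparisons$contrast,
                                     fixed = TRUE)
      }
    } else {
      comparisons <- compare_metrics(s, control = control, paired = paired,
                                     alpha = alpha, force = force)
    }
  }

  config <- list(
    input = if (simulated) {
      list(kind = "simulation",
           groups = as.list(stats::setNames(params$groups$n_animals,
                                            params$groups$group)))
    } else {
      list(kind = "track_table", path = if (is.character(input)) input else "<in-memory>")
    },
    epsilon = epsilon, bin_width = bin_width, min_frames = min_frames,
    max_pause_images = max_pause_images,
    control = control, paired = isTRUE(paired), alpha = alpha,
    seed = seed, blind = blind,
    force = if (is.null(force)) "auto" else force
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (simulated) {
      write_track_table(points, file.path(output_dir, "tracks.csv"))
    }
    write_summary_table(q$summary, file.path(output_dir, "summary.csv"))
    readr::write_csv(q$steps, file.path(output_dir, "steps.csv"), na = "")
    readr::write_csv(q$filter_log, file.path(output_dir, "filter_log.csv"), na = "")
    if (!is.null(q$histogram)) {
      readr::write_csv(q$histogram, file.path(output_dir, "histogram.csv"), na = "")
      readr::write_csv(q$group_profile,
                       file.path(output_dir, "group_profile.csv"), na = "")
    }
    if (!is.null(comparisons)) {
      readr::write_csv(comparisons, file.path(output_dir, "comparisons.csv"),
                       na = "")
    }
    yaml::write_yaml(config, file.path(output_dir, "config.yaml"))
  }

  invisible(list(points = points, quantification = q,
                 comparisons = comparisons, config = config))
}
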