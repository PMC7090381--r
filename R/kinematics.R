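# Frame-to-frame kinematics: step speeds, pause detection, track filtering
# and per-animal aggregation. The animal is the unit of inference; all
# track-level metrics are aggregated per animal before any hypothesis test.

#' Frame-to-frame step table
#'
#' Computes one record per frame-to-frame step of every track: an n-point
#' track yields exactly n - 1 steps. Speed is the Euclidean in-plane
#' displacement divided by the frame interval (not the axial component
#' alone), so an 11-frame track contributes 10 step speeds. A step is
#' classified as paused when its displacement magnitude is below `epsilon`,
#' the positional tolerance standing in for "remained in the same position".
#'
#' @param points A track-point table (see [read_track_table()]).
#' @param epsilon Pause tolerance in micrometres; displacements below this are
#'   paused steps. Default 0.1 um, roughly the localisation granularity of
#'   manual spot tracking at high digital zoom.
#' @return A tibble with one row per step: track identity, `step` (1-based),
#'   `dt_s`, signed axial displacement `dx_um` (+x = retrograde), `dy_um`,
#'   displacement magnitude `disp_um`, `speed_um_s`, and `paused`.
#' @export
#' @examples
#' pts <- simulate_cohort(preset_params("null"), seed = 1)$points
#' steps <- track_steps(pts, epsilon = 0.1)
track_steps <- function(points, epsilon = 0.1) {
  stopifnot(epsilon >= 0)
  pts <- dplyr::arrange(as_tibble(points), .data$animal_id, .data$axon_id,
                        .data$track_id, .data$frame)
  if (nrow(pts) == 0) {
    abort("no track points supplied", class = "endotrack_validation_error")
  }
  key <- track_key(pts)
  n <- nrow(pts)
  same <- c(FALSE, key[-1] == key[-n])
  npts <- tabulate(factor(key, levels = unique(key)))
  if (any(npts < 2)) {
    short <- unique(key)[npts < 2][1]
    abort(sprintf("track '%s' has a single point; no frame-to-frame step can be computed", short),
          class = "endotrack_empty_steps_error")
  }
  i2 <- which(same)                      # row of the step's end point
  dx <- pts$x_um[i2] - pts$x_um[i2 - 1L]
  dy <- pts$y_um[i2] - pts$y_um[i2 - 1L]
  dt <- pts$t_s[i2] - pts$t_s[i2 - 1L]
  if (any(dt <= 0)) {
    abort("non-positive frame interval encountered", class = "endotrack_validation_error")
  }
  disp <- sqrt(dx * dx + dy * dy)
  step_idx <- sequence(npts - 1L)
  tibble(
    animal_id = pts$animal_id[i2],
    group = pts$group[i2],
    axon_id = pts$axon_id[i2],
    track_id = pts$track_id[i2],
    step = step_idx,
    dt_s = dt,
    dx_um = dx,
    dy_um = dy,
    disp_um = disp,
    speed_um_s = disp / dt,
    paused = disp < epsilon
  )
}

#' Maximal pause runs
#'
#' Finds the maximal runs of consecutive paused steps in each track. A run of
#' L paused steps corresponds to L + 1 consecutive images at the same
#' position, which is the quantity the long-pause exclusion rule is stated
#' in (`length_images` column).
#'
#' @param steps A step table from [track_steps()].
#' @return A tibble with one row per pause run: track identity,
#'   `start_step`, `length_steps`, `length_images` (= `length_steps + 1`).
#' @export
pause_runs <- function(steps) {
  st <- dplyr::arrange(as_tibble(steps), .data$animal_id, .data$axon_id,
                       .data$track_id, .data$step)
  n <- nrow(st)
  if (n == 0 || !any(st$paused)) {
    return(tibble(animal_id = character(), axon_id = character(),
                  track_id = character(), start_step = integer(),
                  length_steps = integer(), length_images = integer()))
  }
  key <- track_key(st)
  same <- c(FALSE, key[-1] == key[-n])
  p <- st$paused
  start <- p & !(same & c(FALSE, p[-n]))
  run_id <- cumsum(start)
  run_id[!p] <- 0L
  starts <- which(start)
  len <- tabulate(run_id[p], nbins = length(starts))
  tibble(
    animal_id = st$animal_id[starts],
    axon_id = st$axon_id[starts],
    track_id = st$track_id[starts],
    start_step = st$step[starts],
    length_steps = len,
    length_images = len + 1L
  )
}

#' Per-track metrics
#'
#' Summarises each track from its step table. The mean speed is taken over
#' ALL steps of the tracked run, paused steps included -- the speed over the
#' entire run, not the speed solely when motile. Also computed: the fastest
#' single step, pause counts, the longest pause run (in steps and in
#' consecutive images), net axial displacement, and the direction census used
#' by the anterograde exclusion rule.
#'
#' @param steps A step table from [track_steps()].
#' @return A tibble with one row per track.
#' @export
track_metrics <- function(steps) {
  st <- dplyr::arrange(as_tibble(steps), .data$animal_id, .data$axon_id,
                       .data$track_id, .data$step)
  n <- nrow(st)
  if (n == 0) {
    abort("no steps supplied", class = "endotrack_validation_error")
  }
  key <- track_key(st)
  first <- c(TRUE, key[-1] != key[-n])
  idx <- cumsum(first)                      # consecutive track index
  n_tr <- idx[n]
  n_steps <- tabulate(idx, nbins = n_tr)
  moving <- !st$paused
  sums <- rowsum(
    cbind(speed = st$speed_um_s, paused = as.numeric(st$paused),
          dx = st$dx_um, moving = as.numeric(moving),
          antero = as.numeric(moving & st$dx_um < 0)),
    idx, reorder = FALSE
  )
  max_speed <- vapply(split(st$speed_um_s, idx), max, numeric(1))

  # longest pause run per track, by run-boundary scan
  p <- st$paused
  run_start <- p & !(c(FALSE, p[-n]) & !first)
  run_id <- cumsum(run_start)
  run_id[!p] <- 0L
  longest <- integer(n_tr)
  if (any(p)) {
    run_len <- tabulate(run_id[p])
    run_track <- idx[run_start]
    mx <- tapply(run_len, run_track, max)
    longest[as.integer(names(mx))] <- as.integer(mx)
  }

  firsts <- which(first)
  m <- tibble(
    animal_id = st$animal_id[firsts],
    group = st$group[firsts],
    axon_id = st$axon_id[firsts],
    track_id = st$track_id[firsts],
    n_steps = n_steps,
    mean_speed_um_s = unname(sums[, "speed"]) / n_steps,
    max_step_speed_um_s = unname(max_speed),
    n_paused = as.integer(sums[, "paused"]),
    net_dx_um = unname(sums[, "dx"]),
    n_moving = as.integer(sums[, "moving"]),
    n_moving_antero = as.integer(sums[, "antero"])
  )
  m$longest_pause_steps <- longest
  m$longest_pause_images <- ifelse(longest > 0L, longest + 1L, 0L)
  m$n_points <- m$n_steps + 1L
  m$has_pause <- m$n_paused > 0L
  m
}

#' Apply the track inclusion rules
#'
#' Flags each track as included or excluded according to the analysis rules:
#' (a) tracks observed for fewer than `min_frames` consecutive frames are
#' excluded as too short; (b) tracks that pause for more than
#' `max_pause_images` consecutive images are excluded (long pausers risk
#' phototoxicity artefacts); (c) tracks moving solely in the anterograde
#' direction are excluded. Rule (c) requires at least one non-paused step,
#' every non-paused step to have negative axial displacement (anterograde
#' under the +x = retrograde convention) and a negative net axial
#' displacement. Rules are tested in the order a, b, c and the first match
#' is recorded as the exclusion reason.
#'
#' @param metrics A per-track metrics table from [track_metrics()].
#' @param min_frames Minimum track length in frames (default 5).
#' @param max_pause_images Longest tolerated pause, in consecutive images at
#'   the same position (default 10).
#' @return `metrics` with logical `included` and character
#'   `exclusion_reason` (`NA`, `"too_short"`, `"long_pause"`,
#'   `"anterograde"`) columns added.
#' @export
flag_inclusion <- function(metrics, min_frames = 5, max_pause_images = 10) {
  m <- as_tibble(metrics)
  solely_antero <- m$n_moving >= 1L &
    m$n_moving_antero == m$n_moving &
    m$net_dx_um < 0
  reason <- rep(NA_character_, nrow(m))
  reason[solely_antero] <- "anterograde"
  reason[m$longest_pause_images > max_pause_images] <- "long_pause"
  reason[m$n_points < min_frames] <- "too_short"
  m$included <- is.na(reason)
  m$exclusion_reason <- reason
  m
}

#' Per-animal transport summary
#'
#' Aggregates included tracks to the per-animal metrics that are the unit of
#' inference: the mean speed (average over tracks of the per-track mean
#' speed), the maximum speed (the fastest per-track mean speed; the fastest
#' single step is kept as an auxiliary column), the pooled percentage of time
#' paused (paused steps over all steps of all tracks), and the percentage of
#' pausing endosomes (tracks with at least one pause). A per-track-averaged
#' variant of % time paused is reported as an auxiliary column.
#'
#' @param metrics A per-track metrics table with inclusion flags
#'   ([flag_inclusion()]); excluded tracks are dropped here.
#' @param warn_minima Warn when an animal has fewer than `min_tracks`
#'   included tracks or fewer than `min_axons` distinct axons, the study
#'   minima for a reportable animal.
#' @param min_tracks,min_axons The per-animal minima (defaults 6 and 2).
#' @return A tibble with one row per animal (and group, for paired designs
#'   where an animal contributes axons to both classes).
#' @export
animal_summary <- function(metrics, warn_minima = TRUE,
                           min_tracks = 6, min_axons = 2) {
  m <- as_tibble(metrics)
  if (!"included" %in% names(m)) {
    m <- flag_inclusion(m)
  }
  all_animals <- dplyr::distinct(m, .data$animal_id, .data$group)
  m <- m[m$included, ]
  if (nrow(m) == 0) {
    abort("no included tracks to summarise",
          class = "endotrack_empty_animal_error")
  }
  kept <- dplyr::distinct(m, .data$animal_id, .data$group)
  lost <- dplyr::anti_join(all_animals, kept, by = c("animal_id", "group"))
  if (nrow(lost) > 0) {
    abort(sprintf("animal '%s' (group '%s') has no included tracks",
                  lost$animal_id[1], lost$group[1]),
          class = "endotrack_empty_animal_error")
  }
  s <- dplyr::summarise(
    dplyr::group_by(m, .data$animal_id, .data$group),
    n_tracks = dplyr::n(),
    n_axons = dplyr::n_distinct(.data$axon_id),
    total_steps = sum(.data$n_steps),
    total_paused = sum(.data$n_paused),
    max_speed_um_s = max(.data$mean_speed_um_s),
    max_step_speed_um_s = max(.data$max_step_speed_um_s),
    pct_time_paused_track_avg = mean(100 * .data$n_paused / .data$n_steps),
    pct_pausing_endosomes = 100 * mean(.data$has_pause),
    mean_speed_um_s = mean(.data$mean_speed_um_s),
    .groups = "drop"
  )
  s$pct_time_paused <- 100 * s$total_paused / s$total_steps
  s$n_steps <- s$total_steps
  s <- s[c("animal_id", "group", "n_tracks", "n_axons", "n_steps",
           "mean_speed_um_s", "max_speed_um_s", "max_step_speed_um_s",
           "pct_time_paused", "pct_time_paused_track_avg",
           "pct_pausing_endosomes")]
  if (warn_minima) {
    low <- s$n_tracks < min_tracks | s$n_axons < min_axons
    if (any(low)) {
      warn(sprintf(
        "animal(s) below the reporting minima (>= %d tracks from >= %d axons): %s",
        min_tracks, min_axons,
        paste(unique(s$animal_id[low]), collapse = ", ")
      ))
    }
  }
  s
}

#' Per-animal speed-frequency histogram
#'
#' Bins all individual frame-to-frame step speeds of each animal (paused
#' steps included) into bins `[k*w, (k+1)*w)` from zero and expresses each
#' bin as a percentage of that animal's steps, so every animal's histogram
#' sums to 100. All animals share a common bin grid covering the fastest
#' observed step.
#'
#' @param steps A step table from [track_steps()]; normally restricted to
#'   included tracks first.
#' @param bin_width Bin width in um/s (default 0.2).
#' @return A tibble with columns `animal_id`, `group`, `bin`, `bin_lo`,
#'   `bin_mid` and `pct`.
#' @export
speed_histogram <- function(steps, bin_width = 0.2) {
  stopifnot(bin_width > 0)
  st <- as_tibble(steps)
  if (nrow(st) == 0) {
    abort("no steps supplied", class = "endotrack_validation_error")
  }
  bin <- floor(st$speed_um_s / bin_width)
  nb <- max(bin) + 1L
  st$bin <- bin
  s <- dplyr::summarise(
    dplyr::group_by(st, .data$animal_id, .data$group, .data$bin),
    n = dplyr::n(), .groups = "drop_last"
  )
  s <- dplyr::mutate(s, pct = 100 * .data$n / sum(.data$n))
  s <- dplyr::ungroup(s)
  grid <- tidyr::expand_grid(
    dplyr::distinct(st, .data$animal_id, .data$group),
    bin = 0:(nb - 1L)
  )
  out <- dplyr::left_join(grid, s[c("animal_id", "group", "bin", "pct")],
                          by = c("animal_id", "group", "bin"))
  out$pct[is.na(out$pct)] <- 0
  out$bin_lo <- out$bin * bin_width
  out$bin_mid <- (out$bin + 0.5) * bin_width
  dplyr::arrange(out[c("animal_id", "group", "bin", "bin_lo", "bin_mid", "pct")],
                 .data$group, .data$animal_id, .data$bin)
}

#' Group speed-distribution curve
#'
#' Averages per-animal histogram percentages within each group and attaches
#' the standard error of the mean across animals, producing the group speed
#' distribution curves (mean +/- SEM per bin).
#'
#' @param hist A per-animal histogram from [speed_histogram()].
#' @return A tibble with columns `group`, `bin`, `bin_mid`, `mean_pct`,
#'   `sem_pct` and `n_animals`.
#' @export
group_speed_profile <- function(hist) {
  h <- as_tibble(hist)
  dplyr::summarise(
    dplyr::group_by(h, .data$group, .data$bin, .data$bin_mid),
    mean_pct = mean(.data$pct),
    sem_pct = stats::sd(.data$pct) / sqrt(dplyr::n()),
    n_animals = dplyr::n(),
    .groups = "drop"
  )
}
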