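# Track-table I/O and validation.
#
# The interchange dialect is plain CSV (UTF-8, one header row) with one row
# per endosome per frame:
#   animal_id, group, axon_id, track_id, frame, t_s, x_um, y_um, width_um
# Coordinates are in micrometres in a per-axon frame with +x pointing in the
# retrograde direction (toward the cell body); width_um is the punctum extent
# orthogonal to the transport axis and may be empty.

TRACK_COLS <- c(
  "animal_id", "group", "axon_id", "track_id",
  "frame", "t_s", "x_um", "y_um", "width_um"
)

SUMMARY_COLS <- c(
  "animal_id", "group", "n_tracks", "mean_speed_um_s", "max_speed_um_s",
  "pct_time_paused", "pct_pausing_endosomes", "caliber_um"
)

track_col_types <- function() {
  readr::cols(
    animal_id = readr::col_character(),
    group = readr::col_character(),
    axon_id = readr::col_character(),
    track_id = readr::col_character(),
    frame = readr::col_integer(),
    t_s = readr::col_double(),
    x_um = readr::col_double(),
    y_um = readr::col_double(),
    width_um = readr::col_double()
  )
}

#' Read a track table
#'
#' Reads a CSV track table (one row per endosome per frame) and validates it.
#' Rows are grouped into tracks by `(animal_id, axon_id, track_id)` and sorted
#' by frame; see [validate_track_table()] for the checks applied.
#'
#' @param path Path to a CSV file with columns `animal_id`, `group`,
#'   `axon_id`, `track_id`, `frame`, `t_s`, `x_um`, `y_um`, `width_um`.
#' @return A validated tibble of track points, ordered by animal, axon,
#'   track and frame.
#' @seealso [write_track_table()], [validate_track_table()]
#' @export
#' @examples
#' pts <- simulate_cohort(preset_params("null"), seed = 1)$points
#' f <- tempfile(fileext = ".csv")
#' write_track_table(pts, f)
#' identical(dim(read_track_table(f)), dim(pts))
read_track_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("track table not found: '%s'", path), class = "endotrack_io_error")
  }
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(TRACK_COLS, header)
  if (length(missing) > 0) {
    abort(
      sprintf("track table '%s' is missing column(s): %s",
              path, paste(missing, collapse = ", ")),
      class = "endotrack_format_error"
    )
  }
  pts <- readr::read_csv(path, col_types = track_col_types())
  pts <- dplyr::arrange(pts[TRACK_COLS], .data$animal_id, .data$axon_id,
                        .data$track_id, .data$frame)
  validate_track_table(pts)
}

#' Validate a table of track points
#'
#' Checks the track-table invariants: required columns present; frames
#' strictly increasing and gap-free (consecutive) within each track; time
#' strictly increasing with frame; positive punctum widths where present; a
#' single group label per axon. A warning is raised when `t_s` deviates from
#' `frame * dt` by more than 1e-6 s for the animal's common frame interval.
#'
#' @param points A data frame of track points (see [read_track_table()]).
#' @return The input as a tibble, invisibly ordered by animal, axon, track
#'   and frame.
#' @export
validate_track_table <- function(points) {
  missing <- setdiff(TRACK_COLS, names(points))
  if (length(missing) > 0) {
    abort(sprintf("track table is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "endotrack_format_error")
  }
  pts <- dplyr::arrange(as_tibble(points)[TRACK_COLS], .data$animal_id,
                        .data$axon_id, .data$track_id, .data$frame)
  if (nrow(pts) == 0) {
    return(invisible(pts))
  }
  if (any(pts$frame < 0)) {
    abort("frame indices must be non-negative", class = "endotrack_validation_error")
  }
  key <- track_key(pts)
  new_track <- c(TRUE, key[-1] != key[-length(key)])
  dframe <- c(NA_integer_, diff(pts$frame))
  dframe[new_track] <- NA_integer_
  bad_mono <- which(!is.na(dframe) & dframe <= 0)
  if (length(bad_mono) > 0) {
    abort(sprintf("frames are not strictly increasing within track '%s'",
                  key[bad_mono[1]]),
          class = "endotrack_validation_error")
  }
  bad_gap <- which(!is.na(dframe) & dframe > 1)
  if (length(bad_gap) > 0) {
    abort(sprintf("frame gap within track '%s' (frames %d -> %d); tracks must cover consecutive frames",
                  key[bad_gap[1]], pts$frame[bad_gap[1] - 1], pts$frame[bad_gap[1]]),
          class = "endotrack_validation_error")
  }
  dt <- c(NA_real_, diff(pts$t_s))
  dt[new_track] <- NA_real_
  if (any(!is.na(dt) & dt <= 0)) {
    bad <- which(!is.na(dt) & dt <= 0)[1]
    abort(sprintf("timestamps are not strictly increasing within track '%s'", key[bad]),
          class = "endotrack_validation_error")
  }
  if (any(!is.na(pts$width_um) & pts$width_um <= 0)) {
    abort("width_um must be positive where present",
          class = "endotrack_validation_error")
  }
  ag <- dplyr::distinct(pts, .data$animal_id, .data$axon_id, .data$group)
  dup <- ag[duplicated(ag[c("animal_id", "axon_id")]), ]
  if (nrow(dup) > 0) {
    abort(sprintf("axon '%s' of animal '%s' carries more than one group label",
                  dup$axon_id[1], dup$animal_id[1]),
          class = "endotrack_validation_error")
  }
  check_frame_clock(pts)
  invisible(pts)
}

# t_s is expected to equal frame * dt for the animal's frame interval; the
# interval itself is recovered as the median within-track time step.
check_frame_clock <- function(pts, tol = 1e-6) {
  iv <- frame_intervals(pts)
  pts2 <- dplyr::left_join(pts, iv, by = "animal_id")
  off <- abs(pts2$t_s - pts2$frame * pts2$dt_s)
  bad <- !is.na(off) & off > tol
  if (any(bad)) {
    warn(sprintf(
      "t_s deviates from frame * dt by up to %.3g s for %d point(s) (first: animal '%s', frame %d)",
      max(off[bad]), sum(bad), pts2$animal_id[which(bad)[1]], pts2$frame[which(bad)[1]]
    ))
  }
  invisible(pts)
}

track_key <- function(points) {
  paste(points$animal_id, points$axon_id, points$track_id, sep = "/")
}

#' Recover the frame interval of each animal's movie
#'
#' @param points A track-point table.
#' @return A tibble with columns `animal_id` and `dt_s`, the per-movie frame
#'   interval in seconds (median within-track time step).
#' @export
frame_intervals <- function(points) {
  pts <- dplyr::arrange(as_tibble(points), .data$animal_id, .data$axon_id,
                        .data$track_id, .data$frame)
  key <- track_key(pts)
  same <- c(FALSE, key[-1] == key[-length(key)])
  dt <- diff(pts$t_s)
  d <- tibble(animal_id = pts$animal_id[-1][same[-1]], dt_s = dt[same[-1]])
  if (nrow(d) == 0) {
    return(tibble(animal_id = unique(pts$animal_id), dt_s = NA_real_))
  }
  dplyr::summarise(dplyr::group_by(d, .data$animal_id),
                   dt_s = stats::median(.data$dt_s), .groups = "drop")
}

#' Write a track table
#'
#' Writes track points as CSV in the package dialect, with deterministic
#' column order and rows sorted by animal, axon, track and frame so that a
#' given cohort always serialises identically.
#'
#' @param points A track-point table (see [read_track_table()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_track_table <- function(points, path) {
  pts <- validate_track_table(points)
  readr::write_csv(pts, path, na = "")
  invisible(path)
}

#' Write or read a per-animal summary table
#'
#' Serialises the per-animal metrics that form the unit of inference (one row
#' per animal and group): track count, mean and maximum speed, pausing
#' percentages and axon caliber. Rows are sorted by group then animal.
#'
#' @param summary A per-animal summary table (see [animal_summary()]); extra
#'   columns are preserved after the standard ones.
#' @param path File path.
#' @return `path` (write) or a tibble (read).
#' @export
write_summary_table <- function(summary, path) {
  s <- as_tibble(summary)
  missing <- setdiff(SUMMARY_COLS, names(s))
  for (m in missing) s[[m]] <- NA_real_
  s <- s[c(SUMMARY_COLS, setdiff(names(s), SUMMARY_COLS))]
  s <- dplyr::arrange(s, .data$group, .data$animal_id)
  readr::write_csv(s, path, na = "")
  invisible(path)
}

#' @rdname write_summary_table
#' @export
read_summary_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("summary table not found: '%s'", path), class = "endotrack_io_error")
  }
  s <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(SUMMARY_COLS, names(s))
  if (length(missing) > 0) {
    abort(sprintf("summary table '%s' is missing column(s): %s",
                  path, paste(missing, collapse = ", ")),
          class = "endotrack_format_error")
  }
  s
}
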