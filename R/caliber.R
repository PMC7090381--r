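# Axon caliber from the transverse extent of transported puncta: the
# distance between the upper and lower margins of the fluorescent endosome,
# orthogonal to the transport direction, proxies the axon's diameter.

#' Per-axon caliber estimate
#'
#' Estimates each axon's caliber as the mean punctum width measured along
#' the axon. To sample along the length rather than per frame (repeated
#' width readings of a dwelling endosome are pseudo-replicates), widths are
#' subsampled to one measurement per `bin_um`-wide axial position bin: the
#' earliest-frame reading in each bin is used. Axons with fewer than
#' `min_measurements` retained readings are flagged with a warning; ten is
#' the study minimum for a reportable axon.
#'
#' @param points A track-point table with a `width_um` column; rows with
#'   missing width are ignored.
#' @param bin_um Axial bin width in micrometres (default 1).
#' @param min_measurements Minimum measurements per axon before a warning is
#'   raised (default 10).
#' @return A tibble with one row per axon: `animal_id`, `group`, `axon_id`,
#'   `n_measurements`, `caliber_um`.
#' @export
axon_caliber <- function(points, bin_um = 1, min_measurements = 10) {
  stopifnot(bin_um > 0)
  pts <- as_tibble(points)
  pts <- pts[!is.na(pts$width_um), ]
  if (nrow(pts) == 0) {
    abort("no width measurements available", class = "endotrack_validation_error")
  }
  pts$pos_bin <- floor(pts$x_um / bin_um)
  pts <- dplyr::arrange(pts, .data$animal_id, .data$axon_id, .data$frame)
  one <- dplyr::slice_head(
    dplyr::group_by(pts, .data$animal_id, .data$group, .data$axon_id, .data$pos_bin),
    n = 1
  )
  est <- dplyr::summarise(
    dplyr::group_by(one, .data$animal_id, .data$group, .data$axon_id),
    n_measurements = dplyr::n(),
    caliber_um = mean(.data$width_um),
    .groups = "drop"
  )
  low <- est$n_measurements < min_measurements
  if (any(low)) {
    warn(sprintf("axon(s) with fewer than %d width measurements: %s",
                 min_measurements,
                 paste(paste0(est$animal_id[low], "/", est$axon_id[low]),
                       collapse = ", ")))
  }
  est
}

#' Per-animal caliber
#'
#' Averages per-axon mean widths into a per-animal mean caliber (unweighted
#' across axons). Three axons per animal is the study design; a warning is
#' raised for any other count.
#'
#' @param axon_calibers A per-axon table from [axon_caliber()].
#' @param expected_axons Number of axons expected per animal (default 3).
#' @return A tibble with one row per animal: `animal_id`, `group`,
#'   `n_axons`, `caliber_um`.
#' @export
animal_caliber <- function(axon_calibers, expected_axons = 3) {
  a <- as_tibble(axon_calibers)
  if (nrow(a) == 0) {
    abort("no axon caliber estimates supplied", class = "endotrack_validation_error")
  }
  s <- dplyr::summarise(
    dplyr::group_by(a, .data$animal_id, .data$group),
    n_axons = dplyr::n(),
    caliber_um = mean(.data$caliber_um),
    .groups = "drop"
  )
  off <- s$n_axons != expected_axons
  if (any(off)) {
    warn(sprintf("animal(s) with a number of measured axons != %d: %s",
                 expected_axons, paste(unique(s$animal_id[off]), collapse = ", ")))
  }
  s
}
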