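# Two-state run-and-pause cohort simulator.
#
# Motility is a discrete-time two-state Markov chain at frame resolution
# (the 2.4-3.2 s acquisition interval cannot resolve sub-frame switching):
# each step is either a run (axial displacement v * dt with v lognormal,
# retrograde by convention, flipped anterograde with probability q_antero)
# or a pause (zero true displacement). Isotropic localisation noise is added
# to every coordinate of every frame, and each frame carries a punctum-width
# reading around the axon's true caliber. The long-run pause fraction of the
# chain is pi_P = p_MP / (p_MP + p_PM).

#' Per-group motility parameters
#'
#' One row of the group-parameter table of [sim_params()].
#'
#' @param group Group label (genotype or axon class).
#' @param n_animals Animals in this group.
#' @param v_med_um_s Median of the lognormal moving-speed distribution
#'   (um/s).
#' @param sigma_v Lognormal shape (sd of log speed).
#' @param p_mp,p_pm Per-frame move-to-pause and pause-to-move transition
#'   probabilities.
#' @param q_antero Probability that a moving step is anterograde (axial
#'   displacement sign flipped).
#' @param caliber_um,caliber_sd_um Mean and between-axon sd of true axon
#'   caliber (um).
#' @return A one-row tibble.
#' @export
sim_group <- function(group, n_animals, v_med_um_s = 2.0, sigma_v = 0.35,
                      p_mp = 0.15, p_pm = 0.5, q_antero = 0.02,
                      caliber_um = 2.5, caliber_sd_um = 0.3) {
  tibble(group = group, n_animals = as.integer(n_animals),
         v_med_um_s = v_med_um_s, sigma_v = sigma_v,
         p_mp = p_mp, p_pm = p_pm, q_antero = q_antero,
         caliber_um = caliber_um, caliber_sd_um = caliber_sd_um)
}

#' Simulation parameters for a synthetic cohort
#'
#' Bundles per-group motility parameters with the cohort-level design:
#' animals per group, ~50 tracks per animal, frame intervals drawn once per
#' animal from 2.4-3.2 s, track lengths geometric above a minimum, and a
#' small between-animal lognormal multiplier on moving speed. In paired
#' designs (`paired = TRUE`) the same animals contribute axons to every
#' group (axon classes within one nerve) and share their animal-level speed
#' multiplier, which is what makes the within-animal contrast informative.
#'
#' @param groups A tibble of per-group parameters, rows from [sim_group()].
#' @param dt_range Frame-interval range in seconds (per-animal scalar drawn
#'   uniformly; default `c(2.4, 3.2)`).
#' @param paired Same animals measured in every group?
#' @param control Control group label (stored for downstream comparisons).
#' @param tracks_per_animal Endosome tracks per animal and group (default
#'   50).
#' @param n_axons Axons per animal and group over which tracks are spread
#'   (default 3, the caliber design).
#' @param len_min_steps,len_mean_steps Minimum and mean track length in
#'   steps; lengths are `len_min_steps + Geometric` (defaults 4 and 9, i.e.
#'   5-frame minimum and ~10 frames on average).
#' @param sigma_loc_um Localisation noise sd per coordinate (default
#'   0.02 um).
#' @param animal_cv Between-animal coefficient of variation of the speed
#'   multiplier (default 0.05).
#' @param width_cv Within-axon coefficient of variation of per-frame width
#'   readings (default 0.08).
#' @param start_state Initial hidden state: `"stationary"` (drawn from the
#'   chain's stationary distribution; default) or `"moving"`.
#' @return A `sim_params` object.
#' @export
sim_params <- function(groups, dt_range = c(2.4, 3.2), paired = FALSE,
                       control = NULL, tracks_per_animal = 50, n_axons = 3,
                       len_min_steps = 4, len_mean_steps = 9,
                       sigma_loc_um = 0.02, animal_cv = 0.05,
                       width_cv = 0.08,
                       start_state = c("stationary", "moving")) {
  g <- as_tibble(groups)
  need <- c("group", "n_animals", "v_med_um_s", "sigma_v", "p_mp", "p_pm",
            "q_antero", "caliber_um", "caliber_sd_um")
  missing <- setdiff(need, names(g))
  if (length(missing) > 0) {
    abort(sprintf("group parameter table is missing: %s",
                  paste(missing, collapse = ", ")),
          class = "endotrack_param_error")
  }
  probs <- c(g$p_mp, g$p_pm, g$q_antero)
  if (any(probs < 0 | probs > 1)) {
    abort("transition and anterograde probabilities must lie in [0, 1]",
          class = "endotrack_param_error")
  }
  if (any(g$v_med_um_s <= 0) || any(g$sigma_v < 0) || any(g$caliber_um <= 0)) {
    abort("v_med_um_s and caliber_um must be positive; sigma_v non-negative",
          class = "endotrack_param_error")
  }
  if (sigma_loc_um < 0) {
    abort("sigma_loc_um must be non-negative", class = "endotrack_param_error")
  }
  if (anyDuplicated(g$group)) {
    abort("group labels must be unique", class = "endotrack_param_error")
  }
  if (paired && length(unique(g$n_animals)) != 1) {
    abort("paired designs need the same n_animals in every group",
          class = "endotrack_param_error")
  }
  if (len_mean_steps < len_min_steps) {
    abort("len_mean_steps must be >= len_min_steps",
          class = "endotrack_param_error")
  }
  structure(
    list(groups = g, dt_range = dt_range, paired = paired, control = control,
         tracks_per_animal = as.integer(tracks_per_animal),
         n_axons = as.integer(n_axons),
         len_min_steps = as.integer(len_min_steps),
         len_mean_steps = len_mean_steps,
         sigma_loc_um = sigma_loc_um, animal_cv = animal_cv,
         width_cv = width_cv, start_state = match.arg(start_state)),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("<sim_params> %d group(s), %s design, %d tracks/animal, dt in [%.1f, %.1f] s\n",
              nrow(x$groups), if (x$paired) "paired" else "independent",
              x$tracks_per_animal, x$dt_range[1], x$dt_range[2]))
  print(as.data.frame(x$groups), row.names = FALSE)
  invisible(x)
}

#' Named preset cohorts
#'
#' Parameter bundles mimicking the study designs. Parameter values are
#' synthetic implementer choices (no quantitative motility parameters are
#' published for any genotype); only the cohort structure follows the
#' study designs.
#'
#' \describe{
#'   \item{`"null"`}{Three identical groups of 8 animals; used for type-I
#'     error calibration.}
#'   \item{`"motor_vs_sensory"`}{Paired design, 5 animals, motor (ChATpos)
#'     axons faster and thicker than sensory (ChATneg), pausing matched.}
#'   \item{`"tdp43_9mo"`}{Non-transgenic control (n = 11), wildtype-transgene
#'     control (n = 8), and two mutant groups (n = 6 and 8) with 25% lower
#'     median moving speed and doubled move-to-pause probability.}
#'   \item{`"fus_18mo"`}{Two groups of 7; moving-speed matched, mutants pause
#'     more.}
#' }
#'
#' @param name Preset name.
#' @return A `sim_params` object.
#' @export
preset_params <- function(name) {
  presets <- c("null", "motor_vs_sensory", "tdp43_9mo", "fus_18mo")
  if (!is.character(name) || length(name) != 1 || !name %in% presets) {
    abort(sprintf("unknown preset '%s'; available presets: %s",
                  paste(name, collapse = ","), paste(presets, collapse = ", ")),
          class = "endotrack_param_error")
  }
  switch(
    name,
    null = sim_params(
      dplyr::bind_rows(
        sim_group("NTg", 8),
        sim_group("TgA", 8),
        sim_group("TgB", 8)
      ),
      control = "NTg"
    ),
    motor_vs_sensory = sim_params(
      dplyr::bind_rows(
        sim_group("ChATpos", 5, v_med_um_s = 2.2, caliber_um = 3.5,
                  caliber_sd_um = 0.25),
        sim_group("ChATneg", 5, v_med_um_s = 1.8, caliber_um = 1.8,
                  caliber_sd_um = 0.20)
      ),
      paired = TRUE
    ),
    tdp43_9mo = sim_params(
      dplyr::bind_rows(
        sim_group("NTg", 11),
        sim_group("TDP43_WT", 8),
        sim_group("TDP43_M337V_het", 6, v_med_um_s = 1.5, p_mp = 0.30),
        sim_group("TDP43_M337V_hom", 8, v_med_um_s = 1.5, p_mp = 0.30)
      ),
      control = "NTg"
    ),
    fus_18mo = sim_params(
      dplyr::bind_rows(
        sim_group("Fus_WT", 7),
        sim_group("Fus_D14_het", 7, p_mp = 0.27)
      )
    )
  )
}

#' Simulate a synthetic cohort
#'
#' Draws a full cohort of endosome tracks from the two-state run-and-pause
#' model. Reproducible: the same parameters and seed always give an
#' identical cohort.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @param include_states Keep the hidden per-step state sequences in the
#'   ground-truth output (default `TRUE`; switch off in tight simulation
#'   loops).
#' @return A list: `points` (track-point tibble in the track-table dialect),
#'   `truth` with `groups` (per-group true mean moving speed and stationary
#'   pause fraction pi_P), `animals` (per-animal frame interval and speed
#'   multiplier), and optionally `states` (per-step hidden states, `"M"` /
#'   `"P"`).
#' @export
simulate_cohort <- function(params, seed = NULL, include_states = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(seed)) {
    sim_cohort_impl(params, include_states)
  } else {
    withr::with_seed(as.integer(seed), sim_cohort_impl(params, include_states))
  }
}

sim_cohort_impl <- function(params, include_states) {
  g <- params$groups
  paired <- params$paired

  # animal-level draws (shared across groups when paired)
  if (paired) {
    n_an <- g$n_animals[1]
    animal_ids <- sprintf("a%02d", seq_len(n_an))
    an_dt <- stats::runif(n_an, params$dt_range[1], params$dt_range[2])
    an_mult <- exp(stats::rnorm(n_an, 0, params$animal_cv))
    an_tbl <- tibble(animal_id = animal_ids, dt_s = an_dt,
                     speed_multiplier = an_mult)
  }

  per_group <- vector("list", nrow(g))
  an_rows <- vector("list", nrow(g))
  for (gi in seq_len(nrow(g))) {
    gp <- g[gi, ]
    n_an <- gp$n_animals
    if (paired) {
      ids <- an_tbl$animal_id
      dts <- an_tbl$dt_s
      mults <- an_tbl$speed_multiplier
    } else {
      ids <- sprintf("%s_a%02d", gp$group, seq_len(n_an))
      dts <- stats::runif(n_an, params$dt_range[1], params$dt_range[2])
      mults <- exp(stats::rnorm(n_an, 0, params$animal_cv))
    }
    an_rows[[gi]] <- tibble(animal_id = ids, group = gp$group, dt_s = dts,
                            speed_multiplier = mults)

    n_tr_an <- params$tracks_per_animal
    n_tr <- n_an * n_tr_an
    tr_animal <- rep(seq_len(n_an), each = n_tr_an)
    # axon calibers per animal x axon; tracks spread across axons round-robin
    cal <- pmax(0.3, stats::rnorm(n_an * params$n_axons,
                                  gp$caliber_um, gp$caliber_sd_um))
    tr_axon <- rep(rep_len(seq_len(params$n_axons), n_tr_an), n_an)
    tr_cal <- cal[(tr_animal - 1L) * params$n_axons + tr_axon]

    L <- params$len_min_steps +
      stats::rgeom(n_tr, prob = 1 / (1 + params$len_mean_steps - params$len_min_steps))
    dt_tr <- dts[tr_animal]
    vmed_tr <- gp$v_med_um_s * mults[tr_animal]

    max_len <- max(L)
    paused_m <- matrix(FALSE, nrow = max_len, ncol = n_tr)
    dx_m <- matrix(0, nrow = max_len, ncol = n_tr)
    lam <- gp$p_mp + gp$p_pm
    pi_p <- if (lam > 0) gp$p_mp / lam else 0
    state <- if (params$start_state == "stationary") {
      stats::runif(n_tr) < pi_p
    } else {
      rep(FALSE, n_tr)
    }
    for (s in seq_len(max_len)) {
      if (s > 1L) {
        u <- stats::runif(n_tr)
        state <- (state & u >= gp$p_pm) | (!state & u < gp$p_mp)
      }
      v <- stats::rlnorm(n_tr, log(vmed_tr), gp$sigma_v)
      dir <- ifelse(stats::runif(n_tr) < gp$q_antero, -1, 1)
      dx_m[s, ] <- ifelse(state, 0, dir * v * dt_tr)
      paused_m[s, ] <- state
    }

    sel <- outer(seq_len(max_len), L, "<=")
    dx_long <- dx_m[sel]                    # column-major => track-major
    paused_long <- paused_m[sel]
    cs <- cumsum(dx_long)
    ends <- cumsum(L)
    base <- rep(c(0, cs[ends[-n_tr]]), times = L)
    x_end <- cs - base

    n_pts <- L + 1L
    pt_track <- rep(seq_len(n_tr), times = n_pts)
    pt_frame <- sequence(n_pts) - 1L
    x_true <- numeric(sum(n_pts))
    x_true[pt_frame > 0L] <- x_end
    npt <- length(x_true)
    x_obs <- x_true + stats::rnorm(npt, 0, params$sigma_loc_um)
    y_obs <- stats::rnorm(npt, 0, params$sigma_loc_um)
    w_true <- tr_cal[pt_track]
    w_obs <- pmax(0.05, stats::rnorm(npt, w_true, params$width_cv * w_true))

    tr_in_an <- rep_len(seq_len(n_tr_an), n_tr)  # track index within animal
    points <- tibble(
      animal_id = ids[tr_animal][pt_track],
      group = gp$group,
      axon_id = sprintf("%s_ax%d", gp$group, tr_axon)[pt_track],
      track_id = sprintf("t%03d", tr_in_an)[pt_track],
      frame = pt_frame,
      t_s = pt_frame * dt_tr[pt_track],
      x_um = x_obs,
      y_um = y_obs,
      width_um = w_obs
    )
    states <- NULL
    if (include_states) {
      st_track <- rep(seq_len(n_tr), times = L)
      states <- tibble(
        animal_id = ids[tr_animal][st_track],
        group = gp$group,
        axon_id = sprintf("%s_ax%d", gp$group, tr_axon)[st_track],
        track_id = sprintf("t%03d", tr_in_an)[st_track],
        step = sequence(L),
        state = ifelse(paused_long, "P", "M")
      )
    }
    per_group[[gi]] <- list(points = points, states = states)
  }

  points <- dplyr::arrange(
    dplyr::bind_rows(lapply(per_group, `[[`, "points")),
    .data$animal_id, .data$axon_id, .data$track_id, .data$frame
  )
  states <- NULL
  if (include_states) {
    states <- dplyr::arrange(
      dplyr::bind_rows(lapply(per_group, `[[`, "states")),
      .data$animal_id, .data$axon_id, .data$track_id, .data$step
    )
  }
  lam <- g$p_mp + g$p_pm
  truth_groups <- tibble(
    group = g$group,
    mean_moving_speed_um_s = g$v_med_um_s * exp(g$sigma_v^2 / 2) *
      exp(params$animal_cv^2 / 2),
    pi_pause = ifelse(lam > 0, g$p_mp / lam, 0)
  )
  list(
    points = points,
    truth = list(groups = truth_groups,
                 animals = dplyr::bind_rows(an_rows),
                 states = states),
    params = params
  )
}

#' Simulate a single track
#'
#' Convenience wrapper drawing one track of one animal from one group of a
#' parameter bundle; useful for inspecting the generative model.
#'
#' @param params A [sim_params()] object.
#' @param group Group label to draw from.
#' @param seed Integer seed.
#' @return A list with `points` (one track) and `states` (its hidden state
#'   sequence).
#' @export
simulate_track <- function(params, group, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!group %in% params$groups$group) {
    abort(sprintf("unknown group '%s'", group), class = "endotrack_param_error")
  }
  p1 <- params
  p1$groups <- p1$groups[p1$groups$group == group, ]
  p1$groups$n_animals <- 1L
  p1$tracks_per_animal <- 1L
  p1$n_axons <- 1L
  p1$paired <- FALSE
  out <- simulate_cohort(p1, seed = seed, include_states = TRUE)
  list(points = out$points, states = out$truth$states)
}
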