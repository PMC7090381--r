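test_that("step computation follows the displacement/interval definition", {
  # an 11-frame track yields exactly 10 frame-to-frame speeds
  st <- track_steps(make_track(x = seq(0, 5, by = 0.5)))
  expect_equal(nrow(st), 10L)

  # forced arithmetic: x = 0, 2.5, 5.0 um at dt = 2.5 s -> 1.0 um/s each
  st <- track_steps(make_track(x = c(0, 2.5, 5.0), dt = 2.5))
  expect_equal(st$speed_um_s, c(1, 1))
  expect_false(any(st$paused))

  # stationary 5-point track: 4 steps, all zero speed, all paused
  st <- track_steps(make_track(x = rep(1.3, 5)), epsilon = 0.1)
  expect_equal(nrow(st), 4L)
  expect_equal(st$speed_um_s, rep(0, 4))
  expect_true(all(st$paused))

  # speed uses the 2-D Euclidean displacement, not the axial component
  tr <- make_track(x = c(0, 3), dt = 1)
  tr$y_um <- c(0, 4)
  expect_equal(track_steps(tr)$speed_um_s, 5)

  expect_error(track_steps(make_track(x = 0)),
               class = "endotrack_empty_steps_error")
})

test_that("pause runs are maximal and match a brute-force scan", {
  no_pause <- track_steps(make_track(x = cumsum(c(0, rep(1, 6)))))
  expect_equal(nrow(pause_runs(no_pause)), 0L)

  # paused at step indices 2,3,4 only -> one run, start 2, length 3
  st <- track_steps(track_from_steps(c("R", "P", "P", "P", "R", "R")),
                    epsilon = 0.5)
  runs <- pause_runs(st)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$start_step, 2L)
  expect_equal(runs$length_steps, 3L)
  expect_equal(runs$length_images, 4L)

  # random boolean patterns against the scan oracle
  set.seed(5)
  for (i in 1:25) {
    p <- runif(sample(2:12, 1)) < 0.45
    types <- ifelse(p, "P", "R")
    runs <- pause_runs(track_steps(track_from_steps(types), epsilon = 0.5))
    orc <- oracle_runs(p)
    expect_equal(nrow(runs), length(orc))
    if (length(orc) > 0) {
      expect_equal(runs$start_step, vapply(orc, `[[`, numeric(1), "start"))
      expect_equal(runs$length_steps, vapply(orc, `[[`, numeric(1), "len"))
    }
  }
})

test_that("track mean speed is taken over the entire run, pauses included", {
  # displacements 2,0,2,0 um at dt = 2 s -> speeds 1,0,1,0 -> mean 0.5
  tr <- make_track(x = c(0, 2, 2, 4, 4), dt = 2)
  m <- track_metrics(track_steps(tr, epsilon = 0.1))
  expect_equal(m$mean_speed_um_s, 0.5)
  expect_true(m$has_pause)
  expect_equal(m$n_paused, 2L)

  # fully stationary admissible track: mean speed 0
  m0 <- track_metrics(track_steps(make_track(x = rep(0, 6)), epsilon = 0.1))
  expect_equal(m0$mean_speed_um_s, 0)

  # mean including pauses <= mean over motile steps only, whenever pausing
  pts <- simulate_cohort(sim_params(sim_group("g", 2), tracks_per_animal = 20),
                         seed = 9)$points
  st <- track_steps(pts)
  m <- track_metrics(st)
  motile <- dplyr::summarise(
    dplyr::group_by(st[!st$paused, ], .data$animal_id, .data$axon_id, .data$track_id),
    motile_mean = mean(.data$speed_um_s), .groups = "drop")
  j <- dplyr::inner_join(m[m$has_pause, ], motile,
                         by = c("animal_id", "axon_id", "track_id"))
  expect_gt(nrow(j), 5)
  expect_true(all(j$mean_speed_um_s <= j$motile_mean))
})

test_that("the three exclusion rules fire with the documented reasons", {
  # 4-frame track: too short
  m <- flag_inclusion(track_metrics(track_steps(make_track(x = 0:3))))
  expect_false(m$included)
  expect_equal(m$exclusion_reason, "too_short")

  # stationary for 11 consecutive images inside a 20-frame run: long pause
  types <- c(rep("R", 4), rep("P", 10), rep("R", 5))  # 19 steps = 20 frames
  m <- flag_inclusion(track_metrics(track_steps(track_from_steps(types),
                                                epsilon = 0.5)))
  expect_false(m$included)
  expect_equal(m$exclusion_reason, "long_pause")

  # exactly 10 consecutive images at one position is still tolerated
  types <- c(rep("R", 4), rep("P", 9), rep("R", 5))
  m <- flag_inclusion(track_metrics(track_steps(track_from_steps(types),
                                                epsilon = 0.5)))
  expect_true(m$included)

  # 8-frame track moving solely anterograde
  m <- flag_inclusion(track_metrics(track_steps(track_from_steps(rep("A", 7)),
                                                epsilon = 0.5)))
  expect_false(m$included)
  expect_equal(m$exclusion_reason, "anterograde")

  # anterograde steps mixed with a retrograde net path are kept
  m <- flag_inclusion(track_metrics(track_steps(
    track_from_steps(c("R", "R", "A", "R", "R", "R")), epsilon = 0.5)))
  expect_true(m$included)
})

test_that("tightening thresholds shrinks pauses and the included set monotonically", {
  pts <- simulate_cohort(sim_params(sim_group("g", 2, p_mp = 0.3, p_pm = 0.3),
                                    tracks_per_animal = 30), seed = 11)$points
  st_eps <- track_steps(pts, epsilon = 0.1)
  st_0 <- track_steps(pts, epsilon = 0)
  expect_lte(sum(st_0$paused), sum(st_eps$paused))

  m <- track_metrics(st_eps)
  inc10 <- flag_inclusion(m, max_pause_images = 10)
  inc5 <- flag_inclusion(m, max_pause_images = 5)
  expect_true(all(which(inc5$included) %in% which(inc10$included)))
})

test_that("per-animal aggregation matches its definitions and the oracle", {
  # two tracks, mean speeds 1 and 2, no pausing
  t1 <- make_track(x = cumsum(c(0, rep(1, 5))), dt = 1, track = "t1")
  t2 <- make_track(x = cumsum(c(0, rep(2, 5))), dt = 1, track = "t2", axon = "x2")
  m <- flag_inclusion(track_metrics(track_steps(dplyr::bind_rows(t1, t2))))
  s <- animal_summary(m, warn_minima = FALSE)
  expect_equal(s$mean_speed_um_s, 1.5)
  expect_equal(s$max_speed_um_s, 2.0)
  expect_equal(s$pct_time_paused, 0)
  expect_equal(s$pct_pausing_endosomes, 0)
  expect_gte(s$max_speed_um_s, s$mean_speed_um_s)

  # 2 of 4 tracks pausing -> 50% pausing endosomes
  mk <- function(id, pausing) {
    types <- if (pausing) c("R", "P", "R", "R", "R") else rep("R", 5)
    track_from_steps(types, track = id)
  }
  pts <- dplyr::bind_rows(mk("t1", TRUE), mk("t2", TRUE),
                          mk("t3", FALSE), mk("t4", FALSE))
  m <- flag_inclusion(track_metrics(track_steps(pts, epsilon = 0.5)))
  expect_warning(s <- animal_summary(m), "minima")
  expect_equal(s$pct_pausing_endosomes, 50)

  # simulated animal: all four metrics equal brute-force recomputation
  pts <- simulate_cohort(sim_params(sim_group("g", 1), tracks_per_animal = 40),
                         seed = 13)$points
  q <- quantify_cohort(pts, warn_minima = FALSE)
  inc_steps <- q$steps[q$steps$included, ]
  orc <- oracle_animal_metrics(inc_steps)
  expect_equal(q$summary$mean_speed_um_s, orc$mean_speed)
  expect_equal(q$summary$max_speed_um_s, orc$max_speed)
  expect_equal(q$summary$pct_time_paused, orc$pct_time_paused)
  expect_equal(q$summary$pct_pausing_endosomes, orc$pct_pausing)

  # step-count conservation: per-animal steps = sum over tracks of (points-1)
  counts <- table(paste(pts$animal_id, pts$axon_id, pts$track_id))
  inc <- q$track_metrics[q$track_metrics$included, ]
  key_inc <- paste(inc$animal_id, inc$axon_id, inc$track_id)
  expect_equal(sum(q$summary$n_steps), sum(counts[key_inc] - 1))

  expect_error(animal_summary(m[0, ]), class = "endotrack_empty_animal_error")
})

test_that("speed histograms are per-animal percentages on a shared grid", {
  tr <- make_track(x = cumsum(c(0, rep(1, 6))), dt = 1)  # all speeds 1.0
  h <- speed_histogram(track_steps(tr), bin_width = 0.2)
  expect_equal(h$pct[h$bin == 5], 100)   # [1.0, 1.2)
  expect_equal(sum(h$pct), 100)

  pts <- simulate_cohort(sim_params(sim_group("g", 3), tracks_per_animal = 15),
                         seed = 17)$points
  st <- track_steps(pts)
  h <- speed_histogram(st, bin_width = 0.25)
  sums <- tapply(h$pct, h$animal_id, sum)
  expect_equal(as.numeric(sums), rep(100, 3))

  for (an in unique(h$animal_id)) {
    sp <- st$speed_um_s[st$animal_id == an]
    nb <- max(h$bin) + 1
    expect_equal(h$pct[h$animal_id == an][order(h$bin[h$animal_id == an])],
                 oracle_hist(sp, 0.25, nb))
  }

  prof <- group_speed_profile(h)
  expect_equal(unique(prof$n_animals), 3L)
  expect_equal(sum(prof$mean_pct), 100)
})
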