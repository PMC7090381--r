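# Fixture builders and independent brute-force oracles. The oracles are
# deliberately naive (loops, full enumeration) and share no code with the
# package internals they check.

make_track <- function(x, y = 0, dt = 2.5, animal = "a1", axon = "x1",
                       track = "t1", group = "g", width = NA_real_) {
  n <- length(x)
  tibble::tibble(
    animal_id = animal, group = group, axon_id = axon, track_id = track,
    frame = seq_len(n) - 1L, t_s = (seq_len(n) - 1L) * dt,
    x_um = x, y_um = rep_len(y, n), width_um = rep_len(width, n)
  )
}

# track points from a step-type string: R = retrograde 1 um, A = anterograde
# 1 um, P = stay put. dt = 1 s.
track_from_steps <- function(types, animal = "a1", axon = "x1", track = "t1") {
  dx <- vapply(types, function(s) switch(s, R = 1, A = -1, P = 0), numeric(1))
  make_track(x = cumsum(c(0, dx)), dt = 1, animal = animal, axon = axon,
             track = track)
}

# --- oracles ---------------------------------------------------------------

# maximal runs of TRUE by explicit scan
oracle_runs <- function(p) {
  runs <- list()
  i <- 1
  while (i <= length(p)) {
    if (p[i]) {
      j <- i
      while (j < length(p) && p[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(start = i, len = j - i + 1)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  runs
}

# inclusion decision straight from the rules, computed with loops from raw
# coordinates
oracle_filter <- function(x, y, dt, eps, min_frames = 5, max_pause_images = 10) {
  n <- length(x)
  if (n < min_frames) return("too_short")
  disp <- numeric(n - 1); dx <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    dx[i] <- x[i + 1] - x[i]
    disp[i] <- sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
  }
  paused <- disp < eps
  longest <- 0
  for (r in oracle_runs(paused)) longest <- max(longest, r["len"])
  if (longest > 0 && longest + 1 > max_pause_images) return("long_pause")
  moving <- which(!paused)
  if (length(moving) >= 1 && all(dx[moving] < 0) && sum(dx) < 0) {
    return("anterograde")
  }
  "included"
}

# per-animal metrics recomputed naively from a per-step table
oracle_animal_metrics <- function(steps_one_animal) {
  sp <- split(steps_one_animal,
              paste(steps_one_animal$axon_id, steps_one_animal$track_id))
  track_means <- vapply(sp, function(d) mean(d$speed_um_s), numeric(1))
  pauses <- vapply(sp, function(d) sum(d$paused), numeric(1))
  nsteps <- vapply(sp, nrow, numeric(1))
  list(
    mean_speed = mean(track_means),
    max_speed = max(track_means),
    pct_time_paused = 100 * sum(pauses) / sum(nsteps),
    pct_pausing = 100 * mean(pauses > 0)
  )
}

oracle_hist <- function(speeds, w, nbins) {
  counts <- numeric(nbins)
  for (s in speeds) {
    b <- floor(s / w) + 1
    if (b <= nbins) counts[b] <- counts[b] + 1
  }
  100 * counts / length(speeds)
}

# textbook paired t
oracle_paired_t <- function(a, b) {
  d <- a - b; n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), n - 1))
}

# textbook pooled two-sample t
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# one-way ANOVA F by explicit sums-of-squares decomposition
oracle_anova_f <- function(values, groups) {
  gm <- mean(values)
  lv <- unique(groups)
  ssb <- 0; ssw <- 0
  for (g in lv) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - gm)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  df1 <- length(lv) - 1; df2 <- length(values) - length(lv)
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, p = pf(f, df1, df2, lower.tail = FALSE))
}

# exact two-tailed Mann-Whitney p by direct enumeration over combinations,
# counting pairwise wins (ties half) rather than via ranks
oracle_mw_exact <- function(a, b) {
  u_of <- function(x, y) {
    u <- 0
    for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
    u
  }
  pooled <- c(a, b)
  n1 <- length(a)
  mu <- n1 * length(b) / 2
  uo <- u_of(a, b)
  sets <- combn(length(pooled), n1)
  us <- apply(sets, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  list(u = uo, p = mean(abs(us - mu) >= abs(uo - mu) - 1e-9))
}
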