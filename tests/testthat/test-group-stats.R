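test_that("paired t behaves at its symmetry point and matches the closed form", {
  # differences constructed sign-symmetric with sum 0 -> t = 0, p = 1
  d <- tibble::tibble(
    animal_id = rep(sprintf("a%d", 1:4), 2),
    group = rep(c("A", "B"), each = 4),
    v = c(1, 2, 3, 4, 1 + c(-0.2, 0.2, -0.1, 0.1) + c(0, 1, 2, 3))
  )
  cmp <- compare_two_paired(d, "v", "group")
  expect_equal(unname(cmp$statistic), 0, tolerance = 1e-12)
  expect_equal(cmp$p_value, 1, tolerance = 1e-12)

  # constant differences: degenerate
  d2 <- tibble::tibble(animal_id = rep(sprintf("a%d", 1:5), 2),
                       group = rep(c("A", "B"), each = 5),
                       v = c(2:6, 1:5))
  expect_error(compare_two_paired(d2, "v", "group"),
               class = "endotrack_degenerate_error")

  # random paired data against the textbook computation
  set.seed(33)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    a <- rnorm(n, 1.5, 0.4); b <- rnorm(n, 1.2, 0.4)
    d3 <- tibble::tibble(animal_id = rep(sprintf("a%d", 1:n), 2),
                         group = rep(c("A", "B"), each = n), v = c(a, b))
    cmp <- compare_two_paired(d3, "v", "group")
    orc <- oracle_paired_t(a, b)
    expect_equal(unname(cmp$statistic), orc$t, tolerance = 1e-12)
    expect_equal(cmp$p_value, orc$p, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney U: exact enumeration and approximation are correct", {
  # identical multisets: U at its null midpoint, exact p = 1
  mw <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw$statistic, 4.5)
  expect_equal(mw$p_value, 1)
  expect_equal(mw$method, "exact")

  # complete separation of 3 vs 3: U = 0, exact two-tailed p = 2/20 = 0.1
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 0.1)

  # enumeration equals the naive pairwise-count oracle, ties included
  set.seed(44)
  for (i in 1:8) {
    a <- sample(1:6, sample(3:6, 1), replace = TRUE)
    b <- sample(1:6, sample(3:6, 1), replace = TRUE)
    mw <- mann_whitney_u(a, b)
    orc <- oracle_mw_exact(a, b)
    expect_equal(mw$statistic, orc$u)
    expect_equal(mw$p_value, orc$p)
  }

  # tie-free exact p agrees with the distribution-based reference
  set.seed(45)
  a <- rnorm(6); b <- rnorm(7)
  mw <- mann_whitney_u(a, b)
  ref <- wilcox.test(a, b, exact = TRUE)
  expect_equal(mw$statistic, unname(ref$statistic))
  expect_equal(mw$p_value, ref$p.value, tolerance = 1e-12)

  # large-sample path: tie-corrected normal approximation with continuity
  set.seed(46)
  a <- round(rnorm(15, 0, 1), 1); b <- round(rnorm(12, 0.4, 1), 1)
  mw <- mann_whitney_u(a, b)
  expect_equal(mw$method, "normal approximation")
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(mw$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("two-group routing follows the gate and the pooled t matches the closed form", {
  set.seed(55)
  a <- rnorm(10, 1.6, 0.2); b <- rnorm(9, 1.3, 0.2)
  d <- tibble::tibble(animal_id = sprintf("a%d", 1:19),
                      group = rep(c("A", "B"), c(10, 9)), v = c(a, b))
  cmp <- compare_two_independent(d, "v", "group")
  expect_equal(cmp$test, "unpaired t (pooled)")
  orc <- oracle_pooled_t(a, b)
  expect_equal(unname(cmp$statistic), orc$t, tolerance = 1e-12)
  expect_equal(cmp$p_value, orc$p, tolerance = 1e-12)

  forced <- compare_two_independent(d, "v", "group", force = "mann_whitney")
  expect_match(forced$test, "Mann-Whitney")

  # strongly non-normal groups at n >= 8 route to Mann-Whitney
  set.seed(56)
  d2 <- tibble::tibble(animal_id = sprintf("a%d", 1:60),
                       group = rep(c("A", "B"), each = 30),
                       v = c(rlnorm(30, 0, 2)^2, rlnorm(30, 0.5, 2)^2))
  cmp2 <- compare_two_independent(d2, "v", "group")
  expect_match(cmp2$test, "Mann-Whitney")
  expect_false(cmp2$normal)
})

test_that("ANOVA omnibus agrees with the sums-of-squares decomposition", {
  set.seed(66)
  d <- tibble::tibble(
    animal_id = sprintf("a%d", 1:18),
    group = rep(c("ctl", "g1", "g2"), each = 6),
    v = rnorm(18, rep(c(1.5, 1.2, 1.0), each = 6), 0.25)
  )
  cmp <- compare_vs_control(d, "v", "group", control = "ctl", force = "anova")
  orc <- oracle_anova_f(d$v, d$group)
  expect_equal(unname(cmp$statistic), orc$f, tolerance = 1e-12)
  expect_equal(cmp$p_value, orc$p, tolerance = 1e-12)
})

test_that("Dunnett adjusted p-values match multcomp and dominate the raw p", {
  skip_if_not_installed("multcomp")
  set.seed(77)
  for (i in 1:3) {
    d <- data.frame(
      group = factor(rep(c("ctl", "g1", "g2", "g3"), times = c(8, 6, 7, 8))),
      v = rnorm(29, rep(c(1.5, 1.35, 1.2, 1.5), times = c(8, 6, 7, 8)), 0.2)
    )
    cc <- dunnett_test(d, "v", "group", control = "ctl")
    fit <- stats::aov(v ~ group, data = d)
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
    ref <- summary(gl, test = multcomp::adjusted("single-step"))
    expect_equal(unname(cc$statistic), unname(ref$test$tstat), tolerance = 1e-9)
    expect_equal(unname(cc$p_adjusted), unname(as.numeric(ref$test$pvalues)),
                 tolerance = 2e-3)
    expect_true(all(cc$p_adjusted >= cc$p_value - 1e-12))
  }
})

test_that("Dunnett adjustment agrees with a brute-force max-|t| null simulation", {
  set.seed(78)
  d <- data.frame(group = factor(rep(c("ctl", "g1", "g2"), each = 7)),
                  v = rnorm(21, rep(c(1.0, 1.25, 1.0), each = 7), 0.2))
  cc <- dunnett_test(d, "v", "group", control = "ctl")
  # simulate the null distribution of max |t_i| over both contrasts
  ns <- c(7, 7, 7); df <- sum(ns) - 3
  nrep <- 40000
  set.seed(79)
  maxt <- replicate(nrep, {
    g <- lapply(ns, function(n) rnorm(n))
    mse <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1))) / df
    t1 <- (mean(g[[2]]) - mean(g[[1]])) / sqrt(mse * (2 / 7))
    t2 <- (mean(g[[3]]) - mean(g[[1]])) / sqrt(mse * (2 / 7))
    max(abs(t1), abs(t2))
  })
  for (j in 1:2) {
    p_mc <- mean(maxt >= abs(cc$statistic[j]))
    expect_equal(cc$p_adjusted[j], p_mc, tolerance = 0.02)
  }
})

test_that("Dunn comparisons use tie-corrected mean-rank z with Bonferroni", {
  set.seed(88)
  d <- data.frame(group = rep(c("ctl", "g1", "g2"), each = 8),
                  v = round(rnorm(24, rep(c(0, 1, 0), each = 8)), 1))
  cc <- dunn_test(d, "v", "group", control = "ctl")
  # independent recomputation
  r <- rank(d$v); N <- 24
  ties <- table(d$v)
  s2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  for (g in c("g1", "g2")) {
    z <- (mean(r[d$group == g]) - mean(r[d$group == "ctl"])) /
      sqrt(s2 * (1 / 8 + 1 / 8))
    row <- cc[cc$contrast == paste(g, "- ctl"), ]
    expect_equal(row$statistic, z, tolerance = 1e-12)
    expect_equal(row$p_adjusted, min(1, 2 * 2 * pnorm(-abs(z))),
                 tolerance = 1e-12)
  }
})

test_that("the decision tree is deterministic and records its routing", {
  set.seed(99)
  d <- tibble::tibble(
    animal_id = sprintf("a%d", 1:24),
    group = rep(c("ctl", "g1", "g2"), each = 8),
    v = rnorm(24, rep(c(1.5, 1.1, 1.5), each = 8), 0.2)
  )
  c1 <- compare_vs_control(d, "v", "group", control = "ctl")
  c2 <- compare_vs_control(d, "v", "group", control = "ctl")
  expect_identical(tidy(c1), tidy(c2))
  expect_identical(glance(c1)$test, glance(c2)$test)
  expect_true(all(tidy(c1)$p_adjusted >= 0 & tidy(c1)$p_adjusted <= 1))

  # exchangeable groups (identical value multisets): F = 0, nothing rejected
  d0 <- tibble::tibble(animal_id = sprintf("a%d", 1:15),
                       group = rep(c("ctl", "g1", "g2"), each = 5),
                       v = rep(c(1, 2, 3, 4, 5), 3))
  c0 <- compare_vs_control(d0, "v", "group", control = "ctl", force = "anova")
  expect_equal(unname(c0$statistic), 0, tolerance = 1e-12)
  expect_false(any(c0$contrasts$significant))

  expect_error(compare_vs_control(d[d$group != "g2", ], "v", "group", "ctl"),
               class = "endotrack_stat_error")
  expect_error(compare_vs_control(d, "v", "group", control = "nope"),
               class = "endotrack_stat_error")
})

test_that("compare_metrics produces a tidy panel across metrics", {
  co <- simulate_cohort(preset_params("fus_18mo"), seed = 21)
  q <- quantify_cohort(co$points, warn_minima = FALSE)
  rep <- compare_metrics(q$summary)
  expect_true(all(c("metric", "test", "contrast", "p_value", "p_adjusted",
                    "design", "omnibus_p") %in% names(rep)))
  expect_setequal(unique(rep$metric),
                  c("mean_speed_um_s", "max_speed_um_s", "pct_time_paused",
                    "pct_pausing_endosomes", "caliber_um"))
  expect_true(all(rep$design == "two-group-independent"))
})
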