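# Group comparisons with the animal as the unit of inference.
#
# Decision tree: metrics are assumed normally distributed unless the
# D'Agostino-Pearson omnibus test says otherwise. Two independent groups:
# unpaired t (pooled variance by default) vs Mann-Whitney U. Within-animal
# motor-vs-sensory contrasts: paired t. Three or more groups: one-way ANOVA
# with Dunnett's comparisons against the control vs Kruskal-Wallis with
# Dunn's comparisons against the control. All tests two-tailed, alpha 0.05.

new_comparison <- function(metric, design, test, statistic, p_value,
                           contrasts, normality, normal, alpha,
                           notes = character()) {
  structure(
    list(
      metric = metric, design = design, test = test,
      statistic = statistic, p_value = p_value,
      contrasts = contrasts, normality = normality, normal = normal,
      alpha = alpha, two_tailed = TRUE, notes = notes
    ),
    class = "endo_comparison"
  )
}

#' @export
print.endo_comparison <- function(x, ...) {
  cat(sprintf("<endo_comparison> metric: %s\n", x$metric))
  cat(sprintf("  design: %s | test: %s | two-tailed alpha = %g\n",
              x$design, x$test, x$alpha))
  if (!is.null(x$normal)) {
    cat(sprintf("  normality verdict: %s\n",
                if (isTRUE(x$normal)) "normal (gate passed)" else "non-normal"))
  }
  cat(sprintf("  omnibus: %s = %.4g, p = %.4g\n",
              names(x$statistic)[1], x$statistic[[1]], x$p_value))
  if (!is.null(x$contrasts) && nrow(x$contrasts) > 0) {
    cat("  contrasts:\n")
    print(as.data.frame(x$contrasts), row.names = FALSE)
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Tidy a group-comparison result
#'
#' `tidy()` returns one row per contrast (for two-group designs, the single
#' contrast); `glance()` returns a one-row summary of the omnibus test and
#' the decision-tree routing.
#'
#' @param x An `endo_comparison` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.endo_comparison <- function(x, ...) {
  cc <- x$contrasts
  dplyr::bind_cols(
    tibble(metric = rep(x$metric, nrow(cc)), test = rep(x$test, nrow(cc))),
    cc
  )
}

#' @rdname tidy.endo_comparison
#' @exportS3Method generics::glance
glance.endo_comparison <- function(x, ...) {
  tibble(
    metric = x$metric, design = x$design, test = x$test,
    statistic = x$statistic[[1]], p_value = x$p_value,
    normal = if (is.null(x$normal)) NA else x$normal,
    alpha = x$alpha, two_tailed = TRUE
  )
}

group_levels <- function(g) {
  if (is.factor(g)) levels(droplevels(g)) else unique(g)
}

#' Paired two-group comparison (within-animal contrast)
#'
#' Two-tailed paired t test for metrics measured twice in the same animals
#' (e.g. motor ChAT+ versus sensory ChAT- axons of one cohort). Pairs are
#' formed on `id`; the contrast is `first level - second level`.
#'
#' @param data Data frame with one row per animal x group.
#' @param value Name of the metric column.
#' @param group Name of the two-level grouping column.
#' @param id Name of the pairing column (default `"animal_id"`).
#' @param alpha Significance level (default 0.05, two-tailed).
#' @param metric Label stored in the result (defaults to `value`).
#' @return An `endo_comparison` object.
#' @export
compare_two_paired <- function(data, value, group, id = "animal_id",
                               alpha = 0.05, metric = value) {
  d <- as_tibble(data)
  stopifnot(value %in% names(d), group %in% names(d), id %in% names(d))
  lv <- group_levels(d[[group]])
  if (length(lv) != 2) {
    abort("paired comparison requires exactly 2 groups",
          class = "endotrack_stat_error")
  }
  wide <- tidyr::pivot_wider(d[c(id, group, value)],
                             names_from = dplyr::all_of(group),
                             values_from = dplyr::all_of(value))
  if (anyNA(wide[lv])) {
    abort("paired comparison requires both group values for every animal",
          class = "endotrack_stat_error")
  }
  a <- wide[[lv[1]]]
  b <- wide[[lv[2]]]
  if (length(a) < 2) {
    abort("paired comparison requires n >= 2 pairs", class = "endotrack_stat_error")
  }
  if (stats::var(a - b) == 0) {
    abort("paired differences have zero variance; the paired t statistic is undefined",
          class = "endotrack_degenerate_error")
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  contrast <- sprintf("%s - %s", lv[1], lv[2])
  cc <- tibble(
    contrast = contrast,
    estimate = unname(tt$estimate),
    statistic = unname(tt$statistic),
    p_value = tt$p.value,
    p_adjusted = tt$p.value,
    significant = tt$p.value < alpha
  )
  new_comparison(
    metric = metric, design = "two-group-paired", test = "paired t",
    statistic = c(t = unname(tt$statistic)), p_value = tt$p.value,
    contrasts = cc, normality = NULL, normal = NULL, alpha = alpha
  )
}

#' Independent two-group comparison
#'
#' Routes through the normality gate: both groups consistent with normality
#' (see [normality_gate()]) gives a two-tailed unpaired t test
#' (pooled-variance by default); otherwise a Mann-Whitney U test
#' ([mann_whitney_u()]).
#'
#' @inheritParams compare_two_paired
#' @param var_equal Use the pooled-variance t (default `TRUE`, the classical
#'   convention); `FALSE` gives Welch.
#' @param force Force a branch regardless of the gate: `"t"` or
#'   `"mann_whitney"` (`NULL`, the default, follows the gate).
#' @return An `endo_comparison` object.
#' @export
compare_two_independent <- function(data, value, group, alpha = 0.05,
                                    var_equal = TRUE, force = NULL,
                                    metric = value) {
  d <- as_tibble(data)
  stopifnot(value %in% names(d), group %in% names(d))
  lv <- group_levels(d[[group]])
  if (length(lv) != 2) {
    abort("independent two-group comparison requires exactly 2 groups",
          class = "endotrack_stat_error")
  }
  a <- d[[value]][d[[group]] == lv[1]]
  b <- d[[value]][d[[group]] == lv[2]]
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs n >= 2", class = "endotrack_stat_error")
  }
  gate <- normality_gate(d, value, group, alpha = alpha)
  normal <- attr(gate, "normal")
  branch <- if (is.null(force)) (if (normal) "t" else "mann_whitney") else
    match.arg(force, c("t", "mann_whitney"))
  contrast <- sprintf("%s - %s", lv[1], lv[2])
  if (branch == "t") {
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      abort("both groups have zero variance; the t statistic is undefined",
            class = "endotrack_degenerate_error")
    }
    tt <- stats::t.test(a, b, var.equal = var_equal)
    cc <- tibble(contrast = contrast,
                 estimate = unname(tt$estimate[1] - tt$estimate[2]),
                 statistic = unname(tt$statistic),
                 p_value = tt$p.value, p_adjusted = tt$p.value,
                 significant = tt$p.value < alpha)
    new_comparison(metric, "two-group-independent",
                   if (var_equal) "unpaired t (pooled)" else "Welch t",
                   c(t = unname(tt$statistic)), tt$p.value, cc, gate, normal,
                   alpha)
  } else {
    mw <- mann_whitney_u(a, b)
    cc <- tibble(contrast = contrast,
                 estimate = stats::median(a) - stats::median(b),
                 statistic = mw$statistic,
                 p_value = mw$p_value, p_adjusted = mw$p_value,
                 significant = mw$p_value < alpha)
    new_comparison(metric, "two-group-independent",
                   paste0("Mann-Whitney U (", mw$method, ")"),
                   c(U = mw$statistic), mw$p_value, cc, gate, normal, alpha)
  }
}

#' Mann-Whitney U test
#'
#' Two-tailed Mann-Whitney U. For small samples (both groups n <= 8) the
#' exact two-tailed p-value is obtained by full enumeration of all
#' `choose(n1 + n2, n1)` assignments of the pooled (possibly tied) values,
#' as twice-the-tail mass of |U - n1*n2/2|. Larger samples use the normal
#' approximation with tie-corrected variance and a 0.5 continuity
#' correction. U counts pairs where the first sample exceeds the second,
#' ties counting one half.
#'
#' @param x,y Numeric samples.
#' @param exact Force the exact enumeration (`TRUE`), the normal
#'   approximation (`FALSE`), or pick by sample size (`NULL`, default:
#'   exact when both n <= 8).
#' @return A list: `statistic` (U for `x`), `p_value`, `method`
#'   (`"exact"` or `"normal approximation"`).
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) abort("empty sample", class = "endotrack_stat_error")
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (is.null(exact)) exact <- max(n1, n2) <= 8
  if (exact) {
    idx <- utils::combn(n1 + n2, n1)
    rs <- colSums(matrix(r[idx], nrow = n1))
    u_all <- rs - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    list(statistic = u_obs, p_value = p, method = "exact")
  } else {
    nties <- table(pooled)
    sigma2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(nties^3 - nties) / ((n1 + n2) * (n1 + n2 - 1)))
    if (sigma2 <= 0) {
      abort("all pooled values tied; U statistic degenerate",
            class = "endotrack_degenerate_error")
    }
    cc <- sign(u_obs - mu) * 0.5
    z <- (u_obs - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(statistic = u_obs, p_value = p, method = "normal approximation")
  }
}

#' Dunnett comparisons against a control
#'
#' Two-sided Dunnett many-to-one comparisons after a one-way layout: each
#' treatment mean is contrasted with the control using the pooled error
#' variance, and p-values are adjusted for the familywise error over the
#' k - 1 contrasts via the exact multivariate-t distribution of the maximum
#' absolute statistic (correlations `sqrt(n_i n_j / ((n_i + n0)(n_j + n0)))`,
#' error degrees of freedom N - k). The quasi-Monte-Carlo evaluation of the
#' multivariate-t tail is run under a fixed local seed so results are
#' reproducible.
#'
#' @param data Data frame, one row per animal.
#' @param value,group Column names of the metric and the grouping factor.
#' @param control Label of the control group.
#' @param alpha Familywise significance level (default 0.05).
#' @return A tibble with one row per treatment-vs-control contrast:
#'   `contrast`, `estimate`, `statistic` (t), `df`, `p_value` (unadjusted),
#'   `p_adjusted` (Dunnett), `significant`.
#' @export
dunnett_test <- function(data, value, group, control, alpha = 0.05) {
  d <- as_tibble(data)
  g <- as.character(d[[group]])
  v <- d[[value]]
  lv <- unique(g)
  if (!control %in% lv) {
    abort(sprintf("control group '%s' not present", control),
          class = "endotrack_stat_error")
  }
  trt <- setdiff(lv, control)
  ns <- vapply(lv, function(l) sum(g == l), numeric(1))
  means <- vapply(lv, function(l) mean(v[g == l]), numeric(1))
  vars <- vapply(lv, function(l) stats::var(v[g == l]), numeric(1))
  if (any(ns < 2)) abort("each group needs n >= 2", class = "endotrack_stat_error")
  N <- sum(ns); k <- length(lv)
  df <- N - k
  mse <- sum((ns - 1) * vars) / df
  if (mse == 0) {
    abort("zero pooled variance; Dunnett statistics undefined",
          class = "endotrack_degenerate_error")
  }
  n0 <- ns[control]
  tstat <- (means[trt] - means[control]) / sqrt(mse * (1 / ns[trt] + 1 / n0))
  lam <- sqrt(ns[trt] / (ns[trt] + n0))
  corr <- outer(lam, lam)
  diag(corr) <- 1
  p_adj <- vapply(abs(tstat), function(tq) {
    pr <- withr::with_seed(20240101, mvtnorm::pmvt(
      lower = rep(-tq, length(trt)), upper = rep(tq, length(trt)),
      df = df, corr = corr, algorithm = mvtnorm::GenzBretz(abseps = 1e-5)
    ))
    max(0, min(1, 1 - as.numeric(pr)))
  }, numeric(1))
  p_raw <- 2 * stats::pt(-abs(unname(tstat)), df)
  # the multivariate-t tail is quasi-Monte-Carlo (abs. error ~1e-5); clamp
  # into the exact envelope p <= p_dunnett <= (k-1) * p so that dominance
  # over the raw p holds even for extreme statistics
  p_adj <- pmin(pmax(unname(p_adj), p_raw), length(trt) * p_raw, 1)
  tibble(
    contrast = sprintf("%s - %s", trt, control),
    estimate = unname(means[trt] - means[control]),
    statistic = unname(tstat),
    df = df,
    p_value = p_raw,
    p_adjusted = p_adj,
    significant = p_adj < alpha
  )
}

#' Dunn comparisons against a control
#'
#' Rank-based many-to-one comparisons after Kruskal-Wallis: z statistics on
#' mean ranks with tie-corrected variance, adjusted over the k - 1 control
#' contrasts (Bonferroni by default; any `p.adjust` method is accepted).
#'
#' @inheritParams dunnett_test
#' @param adjust Multiplicity adjustment across the control contrasts
#'   (default `"bonferroni"`).
#' @return A tibble with one row per treatment-vs-control contrast.
#' @export
dunn_test <- function(data, value, group, control, alpha = 0.05,
                      adjust = "bonferroni") {
  d <- as_tibble(data)
  g <- as.character(d[[group]])
  v <- d[[value]]
  lv <- unique(g)
  if (!control %in% lv) {
    abort(sprintf("control group '%s' not present", control),
          class = "endotrack_stat_error")
  }
  trt <- setdiff(lv, control)
  N <- length(v)
  r <- rank(v)
  rbar <- vapply(lv, function(l) mean(r[g == l]), numeric(1))
  ns <- vapply(lv, function(l) sum(g == l), numeric(1))
  nties <- table(v)
  sigma2 <- N * (N + 1) / 12 - sum(nties^3 - nties) / (12 * (N - 1))
  z <- (rbar[trt] - rbar[control]) / sqrt(sigma2 * (1 / ns[trt] + 1 / ns[control]))
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p, method = adjust)
  tibble(
    contrast = sprintf("%s - %s", trt, control),
    estimate = unname(rbar[trt] - rbar[control]),
    statistic = unname(z),
    p_value = unname(p),
    p_adjusted = unname(p_adj),
    significant = unname(p_adj) < alpha
  )
}

#' Multi-group comparison against a control
#'
#' The many-to-one arm of the decision tree (three or more groups, e.g.
#' genotypes against the non-transgenic control): when every group passes
#' the normality gate, a one-way ANOVA omnibus F is followed by two-sided
#' Dunnett comparisons of each group against the control at familywise
#' alpha; otherwise a Kruskal-Wallis omnibus H is followed by Dunn's
#' comparisons against the control (Bonferroni over the k - 1 contrasts by
#' default).
#'
#' @inheritParams compare_two_independent
#' @param control Label of the control group.
#' @param force Force a branch: `"anova"` or `"kruskal"` (`NULL` follows the
#'   gate).
#' @param dunn_adjust Adjustment used by [dunn_test()].
#' @return An `endo_comparison` object.
#' @export
compare_vs_control <- function(data, value, group, control, alpha = 0.05,
                               force = NULL, dunn_adjust = "bonferroni",
                               metric = value) {
  d <- as_tibble(data)
  stopifnot(value %in% names(d), group %in% names(d))
  lv <- group_levels(d[[group]])
  if (length(lv) < 3) {
    abort("fewer than 3 groups; use compare_two_independent() or compare_two_paired()",
          class = "endotrack_stat_error")
  }
  if (!control %in% lv) {
    abort(sprintf("control group '%s' not present in '%s'", control, group),
          class = "endotrack_stat_error")
  }
  gate <- normality_gate(d, value, group, alpha = alpha)
  normal <- attr(gate, "normal")
  branch <- if (is.null(force)) (if (normal) "anova" else "kruskal") else
    match.arg(force, c("anova", "kruskal"))
  if (branch == "anova") {
    fit <- stats::lm(stats::reformulate(group, value), data = d)
    an <- stats::anova(fit)
    fstat <- an$`F value`[1]
    p <- an$`Pr(>F)`[1]
    cc <- dunnett_test(d, value, group, control, alpha = alpha)
    new_comparison(metric, "multi-group-vs-control",
                   "one-way ANOVA + Dunnett",
                   c(F = fstat), p, cc, gate, normal, alpha)
  } else {
    kw <- stats::kruskal.test(d[[value]], factor(d[[group]]))
    cc <- dunn_test(d, value, group, control, alpha = alpha,
                    adjust = dunn_adjust)
    new_comparison(metric, "multi-group-vs-control",
                   sprintf("Kruskal-Wallis + Dunn (%s)", dunn_adjust),
                   c(H = unname(kw$statistic)), kw$p.value, cc, gate, normal,
                   alpha)
  }
}

#' Compare all per-animal metrics between groups
#'
#' Runs the appropriate decision-tree comparison for each metric of a
#' per-animal summary table and returns a tidy report. The design is chosen
#' from the arguments: `paired = TRUE` gives within-animal paired t tests;
#' otherwise two groups give the gated t / Mann-Whitney comparison, and
#' three or more (with `control`) the gated ANOVA + Dunnett /
#' Kruskal-Wallis + Dunn comparison.
#'
#' @param summary A per-animal summary ([animal_summary()]), optionally with
#'   a `caliber_um` column.
#' @param metrics Character vector of metric columns to compare; defaults to
#'   the standard panel present in `summary`.
#' @param control Control group label (required for >= 3 groups).
#' @param paired Within-animal paired design?
#' @param group,id Column names.
#' @param alpha Significance level.
#' @param force Force a statistical branch (see the individual comparison
#'   functions); applies to all metrics.
#' @return A tibble with one row per metric x contrast (columns as
#'   [tidy.endo_comparison()] plus `design`, omnibus `omnibus_statistic`
#'   and `omnibus_p`).
#' @export
compare_metrics <- function(summary, metrics = NULL, control = NULL,
                            paired = FALSE, group = "group",
                            id = "animal_id", alpha = 0.05, force = NULL) {
  s <- as_tibble(summary)
  if (is.null(metrics)) {
    panel <- c("mean_speed_um_s", "max_speed_um_s", "pct_time_paused",
               "pct_pausing_endosomes", "caliber_um")
    metrics <- intersect(panel, names(s))
  }
  lv <- group_levels(s[[group]])
  purrr::map_dfr(metrics, function(mname) {
    cmp <- if (paired) {
      compare_two_paired(s, mname, group, id = id, alpha = alpha)
    } else if (length(lv) == 2) {
      compare_two_independent(s, mname, group, alpha = alpha, force = force)
    } else {
      if (is.null(control)) {
        abort("control group label required for >= 3 groups",
              class = "endotrack_stat_error")
      }
      compare_vs_control(s, mname, group, control = control, alpha = alpha,
                         force = force)
    }
    td <- tidy(cmp)
    td$design <- cmp$design
    td$omnibus_statistic <- cmp$statistic[[1]]
    td$omnibus_p <- cmp$p_value
    td
  })
}
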