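# D'Agostino-Pearson omnibus normality test and the normality gate that
# routes metrics to parametric or nonparametric comparisons.

#' D'Agostino-Pearson omnibus normality test
#'
#' The K-squared omnibus statistic combines a transformed sample skewness
#' (D'Agostino 1970) and a transformed sample kurtosis (Anscombe & Glynn
#' 1983), each approximately standard normal under normality; their sum of
#' squares is referred to a chi-squared distribution with 2 degrees of
#' freedom. Requires n >= 8 (the skewness transformation is undefined
#' below).
#'
#' @param x Numeric vector, n >= 8.
#' @return A one-row tibble: `n`, `skewness` (g1), `kurtosis` (g2, not
#'   excess), `z_skew`, `z_kurt`, `statistic` (K-squared), `p_value`.
#' @references D'Agostino, Belanger & D'Agostino Jr (1990), The American
#'   Statistician 44:316-321.
#' @export
#' @examples
#' dagostino_pearson(rnorm(50))
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) {
    abort(sprintf("the omnibus normality test requires n >= 8 (got n = %d)", n),
          class = "endotrack_stat_error")
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    abort("zero variance sample", class = "endotrack_degenerate_error")
  }
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2

  # skewness: D'Agostino's Z via the Johnson SU transformation
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  if (y == 0) y <- 1  # limiting value; zero skewness maps to z = asinh(1/alpha)-ish guard
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe-Glynn Z via the Wilson-Hilferty cube-root
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (g2 - eb2) / sqrt(vb2)
  sqrtbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtbeta1 * (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1^2))
  denom <- 1 + xs * sqrt(2 / (a - 4))
  term2 <- sign(denom) * ((1 - 2 / a) / abs(denom))^(1 / 3)
  z_kurt <- ((1 - 2 / (9 * a)) - term2) / sqrt(2 / (9 * a))

  k2 <- z_skew^2 + z_kurt^2
  tibble(
    n = n, skewness = g1, kurtosis = g2,
    z_skew = z_skew, z_kurt = z_kurt,
    statistic = k2,
    p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE)
  )
}

#' Normality gate for group comparisons
#'
#' Applies the convention that data are assumed normally distributed unless
#' the D'Agostino-Pearson omnibus test provides evidence to the contrary.
#' Each group is tested at level `alpha`; a group is flagged non-normal only
#' when the test rejects AND the group has at least `min_n` observations
#' (the test's validity floor -- at the study's animal counts of 5-11 the
#' omnibus test cannot even run below 8, so small groups default to the
#' normality assumption). The overall verdict is non-normal if any group is.
#'
#' @param data A data frame with one row per animal.
#' @param value Name of the numeric metric column.
#' @param group Name of the grouping column.
#' @param alpha Test level (default 0.05).
#' @param min_n Minimum group size at which the omnibus test is consulted
#'   (default 8).
#' @return A tibble with one row per group (`group`, `n`, `statistic`,
#'   `p_value`, `normal`) and an attribute `"normal"` carrying the overall
#'   verdict (`TRUE` = all groups consistent with normality).
#' @export
normality_gate <- function(data, value, group, alpha = 0.05, min_n = 8) {
  d <- as_tibble(data)
  stopifnot(value %in% names(d), group %in% names(d))
  sp <- split(d[[value]], d[[group]])
  ns <- vapply(sp, function(v) sum(!is.na(v)), integer(1))
  if (any(ns < 2)) {
    abort(sprintf("group '%s' has fewer than 2 values", names(sp)[ns < 2][1]),
          class = "endotrack_stat_error")
  }
  rows <- purrr::map2_dfr(sp, names(sp), function(v, g) {
    n <- sum(!is.na(v))
    if (n < min_n) {
      tibble(group = g, n = n, statistic = NA_real_, p_value = NA_real_,
             normal = TRUE)
    } else {
      t <- dagostino_pearson(v)
      tibble(group = g, n = n, statistic = t$statistic, p_value = t$p_value,
             normal = t$p_value >= alpha)
    }
  })
  attr(rows, "normal") <- all(rows$normal)
  rows
}
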