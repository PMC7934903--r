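#' Wilcoxon signed-rank test (normal approximation with z)
#'
#' One-sample signed-rank test of paired differences against zero, in the
#' normal-approximation form whose z statistic is commonly reported for
#' choice-preference data. Zero differences are dropped before ranking, ties
#' get average ranks and the tie-corrected variance, and the z value is
#' signed by the direction of the effect. The continuity correction is on by
#' default; at the population sizes used here it changes z only in the
#' second decimal.
#'
#' @param differences numeric vector of paired differences (e.g. per-bee
#'   choice fractions minus 0.5).
#' @param continuity logical, apply the 0.5 continuity correction.
#' @return Tibble of class `magbee_test`: `statistic_name`, `statistic`
#'   (the z value), `p` (two-sided), `n` (non-zero differences), `note`.
#' @export
wilcoxon_signed_rank <- function(differences, continuity = TRUE) {
  d <- differences[!is.na(differences)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble(statistic_name = "wilcoxon_z", statistic = NA_real_,
                  p = NA_real_, n = 0L, note = "all differences zero"))
  }
  r <- rank(abs(d))
  t_plus <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) {
    return(tibble(statistic_name = "wilcoxon_z", statistic = NA_real_,
                  p = NA_real_, n = n, note = "degenerate variance"))
  }
  dev <- t_plus - mu
  cc <- if (continuity) 0.5 * sign(dev) else 0
  z <- (dev - cc) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  note <- if (any(duplicated(abs(d)))) "ties present" else ""
  tibble(statistic_name = "wilcoxon_z", statistic = z, p = p,
         n = as.integer(n), note = note)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' k - 1 degrees of freedom (delegates to [stats::kruskal.test()]).
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 observations).
#' @return Tibble of class layout as [wilcoxon_signed_rank()], with
#'   `statistic` the H (chi-square) value and a `df` column.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) < 2)) abort("each group needs >= 2 observations")
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1) {
    return(tibble(statistic_name = "kruskal_wallis_H", statistic = NA_real_,
                  df = length(groups) - 1L, p = NA_real_,
                  n = length(x), note = "all values identical"))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  tibble(statistic_name = "kruskal_wallis_H",
         statistic = unname(kt$statistic),
         df = as.integer(unname(kt$parameter)),
         p = kt$p.value, n = length(x), note = "")
}

#' Spearman rank correlation
#'
#' Pearson correlation of tie-averaged ranks, with a t-approximation
#' two-sided p value.
#'
#' @param x,y numeric vectors of equal length (n >= 5).
#' @return List: `rho`, `p`, `n`.
#' @export
spearman_rank <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 5) abort("need n >= 5 for the Spearman correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}
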