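# Agreement battery for paired threshold strategies: Bland-Altman
# limits of agreement, proportional-bias regression, Spearman rank
# correlation, Wilcoxon signed-rank test and pointwise bias maps.
#
# The Spearman and Wilcoxon procedures are implemented from their
# definitions (midranks for ties, normal approximation with continuity
# correction for larger samples) rather than delegated, so that the
# test suite can check them against an independent reference
# implementation.

#' Bland-Altman agreement summary
#'
#' Differences `d = x - y`; bias is their mean and the 95% limits of
#' agreement are `bias +/- 1.96 * sd(d)` (sample SD, n - 1 denominator;
#' no small-sample t correction).
#'
#' @param x,y paired measurements (equal length, n >= 2).
#' @return object of class `agreement_summary`: `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n` and the difference convention.
#' @examples
#' bland_altman(c(1, 3), c(1, 1))  # bias 1, LoA 1 +/- 1.96*sqrt(2)
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop_perisim("x and y must have equal length")
  if (length(x) < 2L) stop_perisim("at least 2 pairs are required")
  d <- x - y
  s <- stats::sd(d)
  structure(list(bias = mean(d), sd_diff = s,
                 loa_low = mean(d) - 1.96 * s,
                 loa_high = mean(d) + 1.96 * s,
                 n = length(d), convention = "difference = x - y"),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("<agreement_summary> bias %.3f (95%% LoA %.3f, %.3f), n = %d [%s]\n",
              x$bias, x$loa_low, x$loa_high, x$n, x$convention))
  invisible(x)
}

#' Proportional-bias regression
#'
#' Ordinary least squares of the paired differences `d = x - y` on the
#' pair means `(x + y)/2`; the t statistic tests slope != 0 with n - 2
#' degrees of freedom.  A significant slope means the disagreement
#' grows (or shrinks) with the magnitude of the measured quantity.
#'
#' @param x,y paired measurements, n >= 3.
#' @return list with `slope`, `intercept`, `t`, `p`, `se`, `n`.
#' @export
proportional_bias <- function(x, y) {
  if (length(x) != length(y)) stop_perisim("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop_perisim("at least 3 pairs are required")
  d <- x - y
  m <- (x + y) / 2
  sxx <- sum((m - mean(m))^2)
  if (sxx == 0) stop_perisim("pair means have zero variance")
  if (stats::var(d) == 0)    # constant difference: exactly no slope
    return(list(slope = 0, intercept = d[1], t = 0, p = 1, se = 0, n = n))
  slope <- sum((m - mean(m)) * (d - mean(d))) / sxx
  intercept <- mean(d) - slope * mean(m)
  res <- d - intercept - slope * m
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  tstat <- if (se == 0) sign(slope) * Inf else slope / se
  list(slope = slope, intercept = intercept, t = tstat,
       p = 2 * stats::pt(-abs(tstat), df = n - 2), se = se, n = n)
}

#' Spearman rank correlation
#'
#' Pearson correlation of the midranks; the two-sided p-value uses the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2
#' degrees of freedom (the standard asymptotic form).
#'
#' @param x,y paired vectors, n >= 3.
#' @return list with `rho`, `p`, `n`; constant input is rejected (rho
#'   undefined).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop_perisim("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop_perisim("at least 3 pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_perisim("rho is undefined for constant input")
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; absolute differences are midranked;
#' the statistic is the sum of ranks of the positive differences.  For
#' more than 25 non-zero differences (or in the presence of ties) the
#' normal approximation with continuity correction and tie-corrected
#' variance is used, otherwise the exact null distribution.
#'
#' @param x,y paired vectors.
#' @param exact_limit sample-size bound for the exact distribution.
#' @return list with `statistic` (V), `z` (`NA` for the exact path),
#'   `p`, `n` (non-zero differences), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 25L) {
  if (length(x) != length(y)) stop_perisim("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, z = NA_real_, p = 1, n = 0L,
                method = "no non-zero differences"))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (n <= exact_limit && !has_ties) {
    p <- min(1, 2 * min(stats::psignrank(V, n),
                        stats::psignrank(V - 1, n, lower.tail = FALSE)))
    list(statistic = V, z = NA_real_, p = p, n = n, method = "exact")
  } else {
    mu <- n * (n + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(V - mu) * 0.5
    z <- (V - mu - cc) / sqrt(sig2)
    list(statistic = V, z = z, p = min(1, 2 * stats::pnorm(-abs(z))), n = n,
         method = "normal approximation with continuity correction")
  }
}

#' Pointwise Bland-Altman bias map across subjects
#'
#' For matrices of per-subject fields (rows = subjects, columns = the
#' 66 matched locations), computes the per-location bias and SD of the
#' paired differences `a - b` across subjects.
#'
#' @param fields_a,fields_b numeric matrices with identical dimensions
#'   and subject order.
#' @param grid optional `perim_grid` supplying coordinates for the
#'   output.
#' @return data frame with `x`, `y` (if a grid is given), `bias`, `sd`,
#'   `n`; attribute `convention` states the difference direction.
#' @export
pointwise_bias_map <- function(fields_a, fields_b, grid = NULL) {
  stopifnot(is.matrix(fields_a), is.matrix(fields_b))
  if (!all(dim(fields_a) == dim(fields_b)))
    stop_perisim("field matrices must have identical dimensions ",
                 "(same subjects, same locations)")
  d <- fields_a - fields_b
  out <- data.frame(bias = colMeans(d), sd = apply(d, 2L, stats::sd),
                    n = nrow(d))
  if (!is.null(grid)) {
    stopifnot(grid_size(grid) == ncol(d))
    out <- cbind(grid$points, out)
  }
  attr(out, "convention") <- "difference = a - b"
  out
}
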