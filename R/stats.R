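#' Paired Student's t-test
#'
#' Two-sided t-test for dependent observations:
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences
#' `d = baseline - tra`, with `n - 1` degrees of freedom.
#'
#' @param baseline,tra paired numeric vectors of equal length >= 2.
#' @return list of class `stat_result`: `statistic`, `df`, `p_value`,
#'   per-state `mean`/`sd`, `n`, `test`.
#' @export
paired_t_test <- function(baseline, tra) {
  check_pairs(baseline, tra)
  d <- baseline - tra
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) stopf("degenerate test: paired differences have zero variance")
  tstat <- mean(d) / (sd_d / sqrt(n))
  new_stat_result("paired t", statistic = tstat, df = n - 1,
                  p_value = 2 * stats::pt(-abs(tstat), n - 1),
                  baseline = baseline, tra = tra)
}

#' Shapiro-Wilk normality test
#'
#' Royston's approximation of the Shapiro-Wilk W statistic and p-value
#' (via `stats::shapiro.test`), restricted here to the small-sample
#' range 3-50 where the cohort sizes of paired sonomicrometry studies
#' live.
#'
#' @param values numeric vector, 3 <= n <= 50, non-constant.
#' @return `stat_result` with `statistic` (W) and `p_value`.
#' @export
shapiro_wilk <- function(values) {
  n <- length(values)
  if (n < 3 || n > 50) stopf("shapiro_wilk requires 3 <= n <= 50, got %d", n)
  if (stats::sd(values) == 0) stopf("degenerate test: values have zero variance")
  sw <- stats::shapiro.test(values)
  new_stat_result("Shapiro-Wilk", statistic = unname(sw$statistic), df = NA,
                  p_value = sw$p.value, baseline = values, tra = NULL)
}

#' Exact Wilcoxon signed-rank test for paired data
#'
#' Two-sided signed-rank test on the paired differences. Zero
#' differences are dropped (Wilcoxon's convention) and ties receive
#' mid-ranks. For up to 25 informative pairs the null distribution of
#' `W+` is computed exactly by convolution over the (doubled, hence
#' integer) rank values, which remains exact under ties; beyond that a
#' normal approximation with continuity and tie correction is used.
#' The two-sided p is `2 * min(P(W <= w), P(W >= w))`, capped at 1.
#'
#' @param baseline,tra paired numeric vectors.
#' @param exact_limit largest number of informative pairs for the exact
#'   method (default 25).
#' @return `stat_result` with `statistic` (W+), `p_value`, `n`
#'   (informative pairs), and `method` ("exact" or "normal").
#' @export
wilcoxon_signed_rank <- function(baseline, tra, exact_limit = 25) {
  check_pairs(baseline, tra)
  d <- baseline - tra
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stopf("degenerate test: all paired differences are zero")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  if (n <= exact_limit) {
    p <- wilcoxon_exact_p(r, w_plus)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    # variance with tie correction: sum(r^2)/4
    sigma <- sqrt(sum(r^2) / 4)
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  res <- new_stat_result("Wilcoxon signed rank", statistic = w_plus, df = NA,
                         p_value = p, baseline = baseline, tra = tra)
  res$n_informative <- n
  res$method <- method
  res
}

# Exact two-sided p for W+ given the mid-ranks of |d|. Doubling the
# ranks makes them integers, so the null distribution is a 0/1
# convolution over 2r_i; exact also under ties.
wilcoxon_exact_p <- function(r, w_plus) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  dist <- numeric(total + 1)  # index k+1 = P(2*W = k) * 2^n
  dist[1] <- 1
  for (v in r2) {
    shifted <- c(rep(0, v), dist[seq_len(total + 1 - v)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  w2 <- as.integer(round(2 * w_plus))
  p_le <- sum(dist[seq_len(w2 + 1)])
  p_ge <- sum(dist[(w2 + 1):(total + 1)])
  min(1, 2 * min(p_le, p_ge))
}

check_pairs <- function(baseline, tra) {
  if (length(baseline) != length(tra))
    stopf("paired vectors differ in length (%d vs %d)",
          length(baseline), length(tra))
  if (length(baseline) < 2) stopf("need n >= 2 pairs")
  if (anyNA(baseline) || anyNA(tra)) stopf("paired values must be non-missing")
  invisible(TRUE)
}

new_stat_result <- function(test, statistic, df, p_value, baseline, tra) {
  structure(
    list(test = test, statistic = statistic, df = df, p_value = p_value,
         n = length(baseline),
         mean_baseline = mean(baseline), sd_baseline = stats::sd(baseline),
         mean_tra = if (is.null(tra)) NA_real_ else mean(tra),
         sd_tra = if (is.null(tra)) NA_real_ else stats::sd(tra)),
    class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g (n = %d)\n", x$test,
              x$statistic,
              if (is.na(x$df)) "" else sprintf(", df = %g", x$df),
              x$p_value, x$n))
  invisible(x)
}
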