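#' Per-template count to absolute cell number
#'
#' qPCR counts are reported per fixed DNA template mass (20 ng for blood
#' CTCs, 60 ng for organ DTCs; 60 ng corresponds to about 10,000 murine
#' cells, i.e. 6 pg DNA per cell). The absolute count in the whole organ is
#' the per-template count times `organ_scale`, which defaults to
#' (total organ DNA ng) / (template ng).
#'
#' @param count_per_template Measured count (>= 0), vectorized.
#' @param template_ng Template mass (default 60).
#' @param organ_scale Direct scaling factor; overrides `organ_dna_ng`.
#' @param organ_dna_ng Total DNA yield of the organ (default 6000 ng, giving
#'   `organ_scale = 100` for a 60 ng template).
#' @return Absolute cell count.
#' @export
dtc_absolute_count <- function(count_per_template, template_ng = 60,
                               organ_scale = NULL, organ_dna_ng = 6000) {
  if (any(count_per_template < 0)) stopf("counts must be >= 0")
  if (is.null(organ_scale)) organ_scale <- organ_dna_ng / template_ng
  if (organ_scale <= 0) stopf("organ_scale must be > 0")
  count_per_template * organ_scale
}

#' Sample Pearson correlation coefficient
#'
#' Computed from the sum formulas; errors on degenerate (zero-variance)
#' input rather than returning `NA`.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`.
#' @return `r` in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stopf("x and y must have equal length")
  if (n < 3L) stopf("need at least 3 pairs")
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2); syy <- sum(yc^2)
  if (sxx == 0 || syy == 0) stopf("zero variance: correlation undefined")
  r <- sum(xc * yc) / sqrt(sxx * syy)
  clamp(r, -1, 1)
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Zero differences are dropped and tied absolute differences mid-ranked.
#' For `n <= exact_max` (default 25) the two-sided p-value comes from the
#' exact null distribution of the positive-rank sum, enumerated by dynamic
#' programming over the (doubled, hence integer) rank weights — valid with
#' ties. Above that, a normal approximation with continuity and tie
#' correction is used.
#'
#' @param differences Paired differences (or supply `x` and `y`).
#' @param x,y Optional paired samples; `differences = x - y`.
#' @param exact_max Largest `n` for which the exact distribution is used.
#' @return List `statistic` (V, positive-rank sum), `p_value` (two-sided),
#'   `n` (nonzero pairs), `method`, `degenerate` (all differences zero).
#' @export
wilcoxon_signed_rank <- function(differences = NULL, x = NULL, y = NULL,
                                 exact_max = 25L) {
  if (is.null(differences)) {
    if (is.null(x) || is.null(y)) stopf("supply differences or both x and y")
    differences <- x - y
  }
  d <- differences[differences != 0]
  if (length(d) == 0L)
    return(list(statistic = 0, p_value = NA_real_, n = 0L,
                method = "degenerate", degenerate = TRUE))
  n <- length(d)
  r <- rank(abs(d))                       # average ranks for ties
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    # doubled ranks are integers; DP over the sign-flip generating function
    w <- as.integer(round(2 * r))
    total <- sum(w)
    probs <- numeric(total + 1L); probs[1L] <- 1
    for (wi in w) {
      shifted <- c(numeric(wi), probs[seq_len(total + 1L - wi)])
      probs <- (probs + shifted) / 2
    }
    v2 <- as.integer(round(2 * V))
    p_le <- sum(probs[seq_len(v2 + 1L)])
    p_ge <- sum(probs[(v2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = V, p_value = p, n = n, method = method, degenerate = FALSE)
}

#' Two-sample t-test
#'
#' Pooled-variance Student's t by default (the classical "two-sample
#' t-test"); Welch's unequal-variance form by `var_equal = FALSE`.
#' Two-sided.
#'
#' @param group1,group2 Numeric vectors, each `n >= 2`.
#' @param var_equal Pooled (default `TRUE`) or Welch.
#' @return List `t`, `df`, `p_value`.
#' @export
two_sample_t_test <- function(group1, group2, var_equal = TRUE) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2L || n2 < 2L) stopf("each group needs at least 2 values")
  m1 <- mean(group1); m2 <- mean(group2)
  v1 <- stats::var(group1); v2 <- stats::var(group2)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    if (sp2 == 0) stopf("zero pooled variance")
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    if (se2 == 0) stopf("zero variance")
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Mean, SD and 95% confidence interval of the mean
#'
#' Sample SD uses `n - 1`; the CI is t-based:
#' `mean +- t(0.975, n-1) * SD / sqrt(n)`.
#'
#' @param values Numeric vector, `n >= 2`.
#' @param conf Confidence level (default 0.95).
#' @return List `mean`, `sd`, `ci` (length-2), `n`.
#' @export
group_summary <- function(values, conf = 0.95) {
  n <- length(values)
  if (n < 2L) stopf("need at least 2 values")
  m <- mean(values); s <- stats::sd(values)
  half <- stats::qt(1 - (1 - conf) / 2, n - 1) * s / sqrt(n)
  list(mean = m, sd = s, ci = c(m - half, m + half), n = n)
}
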