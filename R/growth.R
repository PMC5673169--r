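#' Exponential growth fit for one tumor
#'
#' The primary tumor is modeled as `x(t) = N0 * exp(a * t)`: `N0` engrafted
#' cells at day 0 growing at rate constant `a` (1/day). Taking logs turns the
#' fit into ordinary least squares of `ln(cells)` on day: `a` is the slope and
#' `N0 = exp(intercept)`.
#'
#' @param days Numeric vector of measurement days (>= 2 values).
#' @param cells Positive cell numbers aligned to `days`.
#' @return A `growth_fit` with fields `N0`, `a`, `rss` (residual sum of
#'   squares in log space), `n_points`, `rate_was_fixed = FALSE`.
#' @seealso [fit_n0_fixed_rate()] for treated animals, [volume_to_cells()].
#' @export
fit_exponential <- function(days, cells) {
  if (length(days) < 2L) stopf("need at least 2 points to fit a rate")
  if (length(days) != length(cells)) stopf("days and cells must be aligned")
  if (any(cells <= 0)) stopf("all cell counts must be > 0 (log undefined)")
  fit <- stats::lm.fit(cbind(1, days), log(cells))
  co <- fit$coefficients
  growth_fit(N0 = exp(co[[1]]), a = co[[2]],
             rss = sum(fit$residuals^2), n_points = length(days),
             rate_was_fixed = FALSE)
}

#' Intercept-only fit at a fixed growth rate
#'
#' For treated animals the post-treatment points no longer follow free
#' exponential growth, so the cohort-mean control rate `a_fixed` is imposed
#' and only `N0` is estimated from points strictly before the first treatment
#' event: `ln N0 = mean(ln cells_i - a_fixed * day_i)`, i.e. `N0` is the
#' geometric mean of the per-point back-projections to day 0.
#'
#' @param days,cells Measurements; only those with `day < treatment_start_day`
#'   enter the fit when `treatment_start_day` is given.
#' @param a_fixed Growth rate constant to impose (1/day).
#' @param treatment_start_day First treatment day, or `NULL` to use all points.
#' @param mouse_id Used in error messages.
#' @return A `growth_fit` with `rate_was_fixed = TRUE`.
#' @export
fit_n0_fixed_rate <- function(days, cells, a_fixed, treatment_start_day = NULL,
                              mouse_id = "?") {
  if (length(days) != length(cells)) stopf("days and cells must be aligned")
  if (!is.null(treatment_start_day)) {
    keep <- days < treatment_start_day
    days <- days[keep]; cells <- cells[keep]
  }
  if (length(days) < 1L)
    stopf("mouse %s: no pre-treatment measurement available", mouse_id)
  if (any(cells <= 0)) stopf("mouse %s: non-positive cell count", mouse_id)
  z <- log(cells) - a_fixed * days
  lnN0 <- mean(z)
  growth_fit(N0 = exp(lnN0), a = a_fixed,
             rss = sum((z - lnN0)^2), n_points = length(days),
             rate_was_fixed = TRUE)
}

growth_fit <- function(N0, a, rss, n_points, rate_was_fixed) {
  if (N0 <= 0) stopf("N0 must be positive")
  if (rss < -1e-12) stopf("negative residual sum of squares")
  structure(list(N0 = unname(N0), a = unname(a), rss = max(rss, 0),
                 n_points = n_points, rate_was_fixed = rate_was_fixed),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> N0 = %.4g cells, a = %.4g /day%s (rss %.3g, n %d)\n",
              x$N0, x$a, if (x$rate_was_fixed) " [fixed]" else "",
              x$rss, x$n_points))
  invisible(x)
}

#' Primary-tumor size evaluator from a fit
#'
#' @param fit A `growth_fit`.
#' @return A vectorized function `x_p(t)` returning cells at day `t`.
#' @export
primary_size_fun <- function(fit) {
  stopifnot(inherits(fit, "growth_fit"))
  N0 <- fit$N0; a <- fit$a
  function(t) N0 * exp(a * t)
}

#' Compare exponential, Gompertz and spheroid growth models
#'
#' Fits three candidate growth laws to one animal's (day, cells) series and
#' reports residual sums of squares on comparable scales plus a best-model
#' flag:
#' * exponential `x = N0 exp(a t)` (linear in log space),
#' * Gompertz `x = K exp(-b exp(-c t))` (nonlinear least squares in log
#'   space, multi-start from data-driven values),
#' * spheroid: linear radial growth `r(t) = r0 + k t` with
#'   `x = (4/3) pi r^3 * 1e9`, fitted by least squares on the radius.
#'
#' RSS values are reported in log-cell space for all models so they can be
#' compared; the spheroid fit itself is performed on the radius scale.
#' Non-convergent nonlinear fits are flagged and the remaining models still
#' returned.
#'
#' @param days,cells Measurements, `length >= 4`, cells > 0.
#' @return A data.frame with one row per model: `model`, `rss_log`,
#'   `converged`, and the fitted parameters in `params` (list column);
#'   attribute `best` holds the lowest-RSS converged model.
#' @export
compare_growth_models <- function(days, cells) {
  if (length(days) < 4L) stopf("need at least 4 points for model comparison")
  if (any(cells <= 0)) stopf("cells must be positive")
  ln <- log(cells)

  res <- list()

  ef <- fit_exponential(days, cells)
  res$exponential <- list(rss_log = ef$rss, converged = TRUE,
                          params = list(N0 = ef$N0, a = ef$a))

  # Gompertz: log x = log K - b exp(-c t); multi-start nls on log scale
  gomp <- tryCatch({
    best <- NULL
    K0 <- max(cells) * c(1.5, 5, 50)
    c0 <- c(0.05, 0.2, 0.5)
    for (K in K0) for (cc in c0) {
      b0 <- max(log(K) - ln[1], 0.1)
      f <- tryCatch(stats::nls(ln ~ log(K) - b * exp(-c * days),
                               start = list(K = K, b = b0, c = cc),
                               control = stats::nls.control(maxiter = 200, warnOnly = FALSE),
                               lower = c(K = max(cells), b = 1e-8, c = 1e-8),
                               algorithm = "port"),
                    error = function(e) NULL)
      if (!is.null(f)) {
        r <- sum(stats::resid(f)^2)
        if (is.null(best) || r < best$rss) {
          p <- as.list(stats::coef(f))
          best <- list(rss = r, params = p)
        }
      }
    }
    best
  }, error = function(e) NULL)
  res$gompertz <- if (is.null(gomp)) {
    list(rss_log = NA_real_, converged = FALSE, params = list())
  } else list(rss_log = gomp$rss, converged = TRUE, params = gomp$params)

  # spheroid: radius from volume, linear fit on radius; RSS re-expressed in
  # log-cell space for comparability
  r_obs <- (3 * (cells / CELLS_PER_CM3) / (4 * pi))^(1 / 3)
  sf <- stats::lm.fit(cbind(1, days), r_obs)
  r_hat <- pmax(cbind(1, days) %*% sf$coefficients, 1e-12)
  x_hat <- (4 / 3) * pi * r_hat^3 * CELLS_PER_CM3
  res$spheroid <- list(rss_log = sum((log(x_hat) - ln)^2), converged = TRUE,
                       params = list(r0 = unname(sf$coefficients[1]),
                                     k = unname(sf$coefficients[2])))

  out <- data.frame(model = names(res),
                    rss_log = vapply(res, function(z) z$rss_log, 0),
                    converged = vapply(res, function(z) z$converged, TRUE),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$params <- I(lapply(res, function(z) z$params))
  ok <- which(out$converged)
  attr(out, "best") <- out$model[ok][which.min(out$rss_log[ok])]
  out
}

#' Cohort summary of growth fits
#'
#' Arithmetic mean and sample SD of the rate constants and engrafted cell
#' numbers across animals, fixed-width histogram bin counts for `N0`
#' spanning `[0, max(N0)]`, and a non-Gaussianity note when the `N0` SD
#' exceeds its mean (the hallmark of the heavy-tailed engraftment
#' distribution).
#'
#' @param fits List of `growth_fit` objects.
#' @param n_bins Number of histogram bins for `N0` (default 10).
#' @return List with `a_mean`, `a_sd`, `n0_mean`, `n0_sd`, `n`, `n0_breaks`,
#'   `n0_counts`, `n0_non_gaussian`.
#' @export
cohort_growth_summary <- function(fits, n_bins = 10L) {
  if (length(fits) < 1L) stopf("empty cohort")
  stopifnot(all(vapply(fits, inherits, TRUE, "growth_fit")))
  a <- vapply(fits, function(f) f$a, 0)
  n0 <- vapply(fits, function(f) f$N0, 0)
  one <- length(fits) == 1L
  breaks <- seq(0, max(n0), length.out = n_bins + 1L)
  if (max(n0) == 0) breaks <- seq(0, 1, length.out = n_bins + 1L)
  counts <- as.vector(table(cut(n0, breaks, include.lowest = TRUE)))
  list(a_mean = mean(a), a_sd = if (one) NA_real_ else stats::sd(a),
       n0_mean = mean(n0), n0_sd = if (one) NA_real_ else stats::sd(n0),
       n = length(fits),
       n0_breaks = breaks, n0_counts = counts,
       n0_non_gaussian = !one && stats::sd(n0) > mean(n0))
}
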