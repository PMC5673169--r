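#' Colonization-model parameters
#'
#' Parameters of the Iwata-type colonization model in which a primary tumor
#' of `x` cells sheds metastasis-founding cells at rate
#' `beta(x) = m * x^(delta/3)` per day. `delta` is the fractal dimension of
#' the tumor vasculature: 2 corresponds to surface-limited blood supply,
#' 3 to a fully perfused volume, 0 to destroyed vasculature (constant
#' seeding `m`).
#'
#' @param m Colonization coefficient, per (cell x day), >= 0.
#' @param delta Fractal dimension in `[0, 3]`.
#' @param a Growth rate constant (1/day).
#' @param N0 Engrafted cell number at day 0 (>= 1).
#' @param T Observation horizon (days, >= 0).
#' @param lung_fraction Fraction of departing cells that lodge in the assayed
#'   organ (default 1).
#' @param multi_generation Should colonies themselves seed new colonies with
#'   the same `(m, delta)` evaluated on their own size? Default `FALSE`.
#' @param k_ctc Proportionality between the instantaneous intravasation rate
#'   `beta(x_p(T))` and the measured CTC count (default 1).
#' @return An object of class `spread_params`.
#' @export
spread_params <- function(m, delta, a, N0, T,
                          lung_fraction = 1, multi_generation = FALSE,
                          k_ctc = 1) {
  if (m < 0) stopf("m must be >= 0")
  if (delta < 0 || delta > 3) stopf("delta must lie in [0, 3]")
  if (N0 < 1) stopf("N0 must be >= 1")
  if (T < 0) stopf("T must be >= 0")
  if (lung_fraction < 0 || lung_fraction > 1) stopf("lung_fraction in [0, 1]")
  structure(list(m = m, delta = delta, a = a, N0 = N0, T = T,
                 lung_fraction = lung_fraction,
                 multi_generation = isTRUE(multi_generation),
                 k_ctc = k_ctc),
            class = "spread_params")
}

#' @export
print.spread_params <- function(x, ...) {
  cat(sprintf("<spread_params> m=%.4g /(cell day), delta=%.3g, a=%.3g /day, N0=%.4g, T=%g d\n",
              x$m, x$delta, x$a, x$N0, x$T))
  invisible(x)
}

#' Colonization rate beta(x) = m x^(delta/3)
#'
#' @param x Primary-tumor size in cells (>= 0), vectorized.
#' @param m Colonization coefficient.
#' @param delta Fractal dimension in `[0, 3]`.
#' @return Seeding rate in cells/day.
#' @export
colonization_rate <- function(x, m, delta) {
  if (any(x < 0)) stopf("tumor size must be non-negative")
  if (delta < 0 || delta > 3) stopf("delta must lie in [0, 3]")
  m * x^(delta / 3)
}

#' Expected number of metastatic colonies by time T
#'
#' Closed form of `integral_0^T beta(N0 e^(a s)) ds` for exponential primary
#' growth; serves as the deterministic oracle for the stochastic simulator.
#'
#' @param params A [spread_params()].
#' @return Expected first-generation colony count Lambda(T).
#' @export
expected_colony_count <- function(params) {
  stopifnot(inherits(params, "spread_params"))
  with(params, {
    g <- a * delta / 3
    C <- m * N0^(delta / 3)
    if (abs(g) < 1e-300) C * T else C * expm1(g * T) / g
  })
}

#' Expected total disseminated cells by time T (first generation)
#'
#' Each colony founded at time `s` has grown to `exp(a (T - s))` cells by
#' `T`; integrating against the seeding intensity gives
#' `D(T) = lf * m * N0^(d/3) * e^(aT) * (1 - e^(-a(1-d/3)T)) / (a(1-d/3))`
#' for `delta != 3`, and `lf * m * N0 * T * e^(aT)` at `delta = 3`.
#'
#' @param params A [spread_params()].
#' @return Expected disseminated-cell total in the assayed organ.
#' @export
expected_total_dtc <- function(params) {
  stopifnot(inherits(params, "spread_params"))
  with(params, {
    q <- a * (delta / 3 - 1)           # exponent of the birth-time integrand
    C <- m * N0^(delta / 3) * exp(a * T)
    h <- if (abs(q) < 1e-300) T else expm1(q * T) / q
    lung_fraction * C * h
  })
}

#' Stochastic simulation of metastatic seeding
#'
#' Colony birth times are drawn from an inhomogeneous Poisson process with
#' intensity `beta(x_p(t))` by thinning against the bound `beta(x_p(T))`
#' (the intensity is non-decreasing for `a >= 0`). Each colony starts at one
#' cell and grows exponentially at the primary's rate; with
#' `multi_generation = TRUE` colonies recursively seed further colonies with
#' the same `(m, delta)` evaluated on their own size. A time-rescaling
#' sampler (`method = "rescale"`, analytic inversion of the cumulative
#' intensity) is provided as a cross-check on the thinning route.
#'
#' @param params A [spread_params()].
#' @param seed Integer RNG seed; identical seeds give identical results.
#' @param method `"thinning"` (default) or `"rescale"`.
#' @return A `spread_result`: `colony_birth_times`, `colony_sizes_at_T`,
#'   `n_colonies`, `dtc_total`, `ctc_rate_at_T`, `primary_size_at_T`.
#' @export
simulate_spread <- function(params, seed, method = c("thinning", "rescale")) {
  stopifnot(inherits(params, "spread_params"))
  method <- match.arg(method)
  set.seed(as.integer(seed))
  p <- params
  xT <- p$N0 * exp(p$a * p$T)
  births <- if (p$m == 0 || p$T == 0) {
    numeric()
  } else if (method == "thinning") {
    B <- colonization_rate(xT, p$m, p$delta)
    if (!is.finite(B)) stopf("non-finite intensity bound")
    n_prop <- stats::rpois(1L, B * p$T)
    t_prop <- stats::runif(n_prop, 0, p$T)
    lam <- colonization_rate(p$N0 * exp(p$a * t_prop), p$m, p$delta)
    sort(t_prop[stats::runif(n_prop) * B <= lam])
  } else {
    lam_T <- expected_colony_count(p)
    n <- stats::rpois(1L, lam_T)
    u <- sort(stats::runif(n, 0, lam_T))
    g <- p$a * p$delta / 3
    C <- p$m * p$N0^(p$delta / 3)
    if (abs(g) < 1e-300) u / C else log1p(g * u / C) / g
  }

  if (p$multi_generation && length(births)) {
    # colonies seed with the same (m, delta) on their own exponential size
    queue <- births
    all_births <- births
    while (length(queue)) {
      tb <- queue[1]; queue <- queue[-1]
      Bc <- colonization_rate(exp(p$a * (p$T - tb)), p$m, p$delta)
      span <- p$T - tb
      nc <- stats::rpois(1L, Bc * span)
      if (nc > 0) {
        tc <- stats::runif(nc, tb, p$T)
        lamc <- colonization_rate(exp(p$a * (tc - tb)), p$m, p$delta)
        acc <- tc[stats::runif(nc) * Bc <= lamc]
        if (length(acc)) {
          all_births <- c(all_births, acc)
          queue <- c(queue, acc)
        }
      }
    }
    births <- sort(all_births)
  }

  sizes <- exp(p$a * (p$T - births))
  structure(list(
    colony_birth_times = births,
    colony_sizes_at_T = sizes,
    n_colonies = length(births),
    dtc_total = p$lung_fraction * sum(sizes),
    ctc_rate_at_T = colonization_rate(xT, p$m, p$delta),
    primary_size_at_T = xT
  ), class = "spread_result")
}

#' @export
print.spread_result <- function(x, ...) {
  cat(sprintf("<spread_result> %d colonies, DTC total %.4g cells, CTC rate %.4g /day\n",
              x$n_colonies, x$dtc_total, x$ctc_rate_at_T))
  invisible(x)
}

#' Calibrate the colonization coefficient from a reference animal
#'
#' The expected disseminated total is linear in `m`, so with the fractal
#' dimension pinned at `delta_ref` (2: surface-limited supply) for the
#' reference animal — by convention the control mouse with the largest
#' primary tumor — the coefficient is
#' `m = dtc_target / D(T; m = 1, delta_ref)`.
#'
#' @param fit The reference animal's `growth_fit`.
#' @param T Observation horizon for that animal (days).
#' @param dtc_target Its measured absolute disseminated-cell count.
#' @param delta_ref Reference fractal dimension (default 2).
#' @param lung_fraction Organ-lodging fraction (default 1).
#' @return The colonization coefficient `m` in 1/(cell x day).
#' @export
calibrate_colonization_coefficient <- function(fit, T, dtc_target,
                                               delta_ref = 2,
                                               lung_fraction = 1) {
  stopifnot(inherits(fit, "growth_fit"))
  if (dtc_target <= 0) stopf("dtc_target must be positive")
  D1 <- expected_total_dtc(spread_params(m = 1, delta = delta_ref, a = fit$a,
                                         N0 = fit$N0, T = T,
                                         lung_fraction = lung_fraction))
  if (D1 <= 0) stopf("reference expectation is zero (T = 0?); cannot calibrate")
  dtc_target / D1
}

#' Infer the fractal dimension from a disseminated-cell count
#'
#' Bisection on `delta` in `[0, 3]` against the deterministic expectation
#' `D(T; delta)`, which is strictly increasing in `delta` whenever the
#' primary exceeds one cell. Targets below `D(delta = 0)` or above
#' `D(delta = 3)` return the clamped endpoint with `clamped = TRUE`.
#' A stochastic mode (bisection on seeded replicate means) is available for
#' cross-checking but the deterministic expectation is the default for
#' reproducibility.
#'
#' @param fit `growth_fit` for the animal (supplies `a`, `N0`).
#' @param T Observation horizon (days).
#' @param m Calibrated colonization coefficient.
#' @param dtc_target Measured absolute disseminated-cell count (>= 0).
#' @param lung_fraction Organ-lodging fraction.
#' @param rel_tol Relative tolerance on `|D - target|` (default 1e-6).
#' @param mode `"deterministic"` (default) or `"stochastic"`.
#' @param n_rep,seed Replicates and seed for stochastic mode.
#' @return List `delta`, `clamped`, `dtc_at_delta`.
#' @export
infer_delta_from_dtc <- function(fit, T, m, dtc_target, lung_fraction = 1,
                                 rel_tol = 1e-6,
                                 mode = c("deterministic", "stochastic"),
                                 n_rep = 200L, seed = 1L) {
  stopifnot(inherits(fit, "growth_fit"))
  mode <- match.arg(mode)
  if (dtc_target < 0) stopf("dtc_target must be >= 0")
  Dfun <- function(delta) {
    pp <- spread_params(m = m, delta = delta, a = fit$a, N0 = fit$N0, T = T,
                        lung_fraction = lung_fraction)
    if (mode == "deterministic") expected_total_dtc(pp)
    else mean(vapply(seq_len(n_rep),
                     function(i) simulate_spread(pp, seed = seed + i)$dtc_total, 0))
  }
  lo <- 0; hi <- 3
  D_lo <- Dfun(lo); D_hi <- Dfun(hi)
  if (dtc_target <= D_lo) return(list(delta = 0, clamped = TRUE, dtc_at_delta = D_lo))
  if (dtc_target >= D_hi) return(list(delta = 3, clamped = TRUE, dtc_at_delta = D_hi))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    D_mid <- Dfun(mid)
    if (abs(D_mid - dtc_target) <= rel_tol * dtc_target || (hi - lo) < 1e-13) break
    if (D_mid < dtc_target) lo <- mid else hi <- mid
  }
  list(delta = mid, clamped = FALSE, dtc_at_delta = D_mid)
}

#' Infer the fractal dimension from the circulating-cell rate
#'
#' Inverts the colonization rate at the end of the experiment:
#' `delta = 3 (ln(rate) - ln(m)) / ln(x_p(T))`, clamped to `[0, 3]`.
#' The measured per-template CTC count is converted to an absolute per-day
#' intravasation rate by the configurable factor `k_ctc`
#' (`rate = ctc_count / k_ctc` when a raw count is supplied via
#' `ctc_count`).
#'
#' @param fit `growth_fit` for the animal.
#' @param T Observation horizon (days).
#' @param m Colonization coefficient.
#' @param ctc_absolute_rate Absolute intravasation rate (cells/day); if
#'   missing, computed as `ctc_count / k_ctc`.
#' @param ctc_count,k_ctc Raw count and conversion factor alternative.
#' @return List `delta`, `clamped`.
#' @export
infer_delta_from_ctc <- function(fit, T, m, ctc_absolute_rate = NULL,
                                 ctc_count = NULL, k_ctc = 1) {
  stopifnot(inherits(fit, "growth_fit"))
  if (is.null(ctc_absolute_rate)) {
    if (is.null(ctc_count)) stopf("supply ctc_absolute_rate or ctc_count")
    ctc_absolute_rate <- ctc_count / k_ctc
  }
  if (ctc_absolute_rate <= 0) return(list(delta = 0, clamped = TRUE))
  xT <- fit$N0 * exp(fit$a * T)
  if (xT <= 1) stopf("primary size at T must exceed 1 cell")
  delta <- 3 * (log(ctc_absolute_rate) - log(m)) / log(xT)
  clamped <- delta < 0 || delta > 3
  list(delta = clamp(delta, 0, 3), clamped = clamped)
}
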