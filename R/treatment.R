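#' Treatment schedule
#'
#' Describes the chemotherapy and/or hypofractionated radiotherapy applied to
#' one animal. Chemotherapy (a single cisplatin dose) acts as an
#' exponentially decaying first-order kill on the S-phase fraction and, from
#' `delta_switch_lag` days after the dose, switches the vasculature's fractal
#' dimension to `delta_post`. Radiotherapy is delivered as `n_fractions`
#' instantaneous fractions on consecutive days, each multiplying the primary
#' size by the linear-quadratic survival fraction; with
#' `field = "primary_only"` (default, RT is a local therapy) colonies are
#' unaffected by RT, while chemotherapy is systemic and hits colonies too.
#'
#' @param chemo `NULL` or a list with `dose_day`, `k0` (kill amplitude,
#'   1/day), `lambda_d` (drug decay rate, 1/day), `f_S` (S-phase fraction in
#'   `[0,1]`), `delta_post` (post-treatment fractal dimension in `[0,3]`,
#'   `NA` to keep the pre-treatment value), `delta_switch_lag` (days after
#'   the dose at which the switch happens, default 1).
#' @param radio `NULL` or a list with `start_day`, `n_fractions` (default 5),
#'   `dose_per_fraction` (Gy, default 10), `alpha` (1/Gy), `beta_lq`
#'   (1/Gy^2), `field` ("primary_only" or "systemic").
#' @return An object of class `treatment_schedule`.
#' @export
treatment_schedule <- function(chemo = NULL, radio = NULL) {
  if (!is.null(chemo)) {
    chemo <- utils::modifyList(
      list(dose_day = NA_real_, k0 = 0, lambda_d = 0, f_S = 1,
           delta_post = NA_real_, delta_switch_lag = 1), chemo)
    if (!is_number(chemo$dose_day)) stopf("chemo needs a dose_day")
    if (chemo$k0 < 0 || chemo$lambda_d < 0) stopf("chemo rates must be >= 0")
    if (chemo$f_S < 0 || chemo$f_S > 1) stopf("f_S must lie in [0, 1]")
    if (!is.na(chemo$delta_post) && (chemo$delta_post < 0 || chemo$delta_post > 3))
      stopf("delta_post must lie in [0, 3]")
  }
  if (!is.null(radio)) {
    radio <- utils::modifyList(
      list(start_day = NA_real_, n_fractions = 5L, dose_per_fraction = 10,
           alpha = 0.05, beta_lq = 0.005, field = "primary_only"), radio)
    if (!is_number(radio$start_day)) stopf("radio needs a start_day")
    if (radio$n_fractions < 1L) stopf("need at least one fraction")
    if (radio$dose_per_fraction < 0) stopf("dose must be >= 0")
    radio$field <- match.arg(radio$field, c("primary_only", "systemic"))
  }
  structure(list(chemo = chemo, radio = radio), class = "treatment_schedule")
}

#' Linear-quadratic survival fraction
#'
#' `SF(d) = exp(-alpha d - beta_lq d^2)` after a single radiation dose `d`.
#'
#' @param dose Dose in Gy (>= 0), vectorized.
#' @param alpha Linear coefficient (1/Gy).
#' @param beta_lq Quadratic coefficient (1/Gy^2).
#' @return Surviving fraction in (0, 1].
#' @export
lq_survival_fraction <- function(dose, alpha, beta_lq) {
  if (any(dose < 0)) stopf("dose must be >= 0")
  exp(-alpha * dose - beta_lq * dose^2)
}

#' Chemotherapy kill rate at time t
#'
#' First-order kill on the S-phase fraction with exponential drug decay:
#' `k(t) = k0 * f_S * exp(-lambda_d (t - dose_day))` for `t >= dose_day`,
#' zero before.
#'
#' @param t Day (vectorized).
#' @param chemo Chemo block of a [treatment_schedule()].
#' @return Kill rate (1/day).
#' @export
chemo_kill_rate <- function(t, chemo) {
  if (is.null(chemo)) return(rep(0, length(t)))
  ifelse(t >= chemo$dose_day,
         chemo$k0 * chemo$f_S * exp(-chemo$lambda_d * (t - chemo$dose_day)),
         0)
}

# cumulative chemo kill integral K(t) = int_0^t k(u) du (closed form)
chemo_kill_integral <- function(t, chemo) {
  if (is.null(chemo)) return(rep(0, length(t)))
  tt <- pmax(t - chemo$dose_day, 0)
  if (chemo$lambda_d == 0) chemo$k0 * chemo$f_S * tt
  else chemo$k0 * chemo$f_S * (1 - exp(-chemo$lambda_d * tt)) / chemo$lambda_d
}

rt_fraction_days <- function(radio) {
  if (is.null(radio)) return(numeric())
  radio$start_day + seq_len(radio$n_fractions) - 1
}

#' Treated primary-tumor trajectory
#'
#' Solves `dx/dt = a x - k(t) x` between events in closed form (the chemo
#' kill integrates analytically) and applies the per-fraction LQ survival
#' factor instantaneously at the start of each radiotherapy day. The
#' returned evaluator is right-continuous at event times: `x(t_frac)` is the
#' post-irradiation value.
#'
#' @param fit `growth_fit` (for treated groups: the fixed cohort-mean rate
#'   pathway).
#' @param schedule A [treatment_schedule()].
#' @param horizon Optional horizon; events after it are ignored with a
#'   warning.
#' @return A vectorized function `x_p(t)` (cells), with the schedule stored
#'   in attributes.
#' @export
treated_primary_trajectory <- function(fit, schedule, horizon = NULL) {
  stopifnot(inherits(fit, "growth_fit"), inherits(schedule, "treatment_schedule"))
  frac_days <- rt_fraction_days(schedule$radio)
  if (!is.null(horizon)) {
    late <- frac_days > horizon
    if (any(late)) {
      warning("radiotherapy fractions after the horizon are ignored")
      frac_days <- frac_days[!late]
    }
    if (!is.null(schedule$chemo) && schedule$chemo$dose_day > horizon)
      warning("chemotherapy dose after the horizon has no effect on [0, horizon]")
  }
  SF <- if (length(frac_days))
    lq_survival_fraction(schedule$radio$dose_per_fraction,
                         schedule$radio$alpha, schedule$radio$beta_lq) else 1
  N0 <- fit$N0; a <- fit$a; chemo <- schedule$chemo
  f <- function(t) {
    n_frac <- vapply(t, function(ti) sum(frac_days <= ti), 0)
    N0 * exp(a * t - chemo_kill_integral(t, chemo)) * SF^n_frac
  }
  attr(f, "frac_days") <- frac_days
  attr(f, "survival_per_fraction") <- SF
  attr(f, "schedule") <- schedule
  attr(f, "fit") <- fit
  f
}

# delta as a function of time under a possible post-chemo switch
delta_at <- function(t, delta_pre, schedule) {
  chemo <- schedule$chemo
  if (is.null(chemo) || is.na(chemo$delta_post)) return(rep(delta_pre, length(t)))
  t_sw <- chemo$dose_day + chemo$delta_switch_lag
  ifelse(t >= t_sw, chemo$delta_post, delta_pre)
}

# colony growth factor from birth time s to T under systemic chemo (and,
# for a systemic RT field, per-fraction survival after birth)
colony_growth_factor <- function(s, T, a, schedule) {
  chemo <- schedule$chemo
  g <- exp(a * (T - s) - (chemo_kill_integral(T, chemo) - chemo_kill_integral(s, chemo)))
  if (!is.null(schedule$radio) && schedule$radio$field == "systemic") {
    SF <- lq_survival_fraction(schedule$radio$dose_per_fraction,
                               schedule$radio$alpha, schedule$radio$beta_lq)
    fd <- rt_fraction_days(schedule$radio)
    n_after <- vapply(s, function(si) sum(fd > si & fd <= T), 0)
    g <- g * SF^n_after
  }
  g
}

#' Expected disseminated total under treatment
#'
#' Deterministic counterpart of [simulate_treated_mouse()]:
#' `D(T) = lf * int_0^T m x_p(s)^(delta(s)/3) G(s, T) ds`, where `x_p` is the
#' treated trajectory, `delta(s)` switches one `delta_switch_lag` after the
#' chemo dose, and `G(s, T)` is the colony growth factor including systemic
#' chemo kill. Integrated piecewise between event days by adaptive
#' quadrature.
#'
#' @param fit `growth_fit`.
#' @param schedule A [treatment_schedule()].
#' @param params A [spread_params()] supplying `m`, `delta` (pre-treatment),
#'   `T`, `lung_fraction`.
#' @return Expected disseminated-cell total.
#' @export
expected_total_dtc_treated <- function(fit, schedule, params) {
  stopifnot(inherits(params, "spread_params"))
  xp <- treated_primary_trajectory(fit, schedule, horizon = params$T)
  m <- params$m; lf <- params$lung_fraction; T <- params$T; a <- fit$a
  integrand <- function(s) {
    d <- delta_at(s, params$delta, schedule)
    m * xp(s)^(d / 3) * colony_growth_factor(s, T, a, schedule)
  }
  brk <- c(0, attr(xp, "frac_days"))
  if (!is.null(schedule$chemo)) {
    brk <- c(brk, schedule$chemo$dose_day,
             schedule$chemo$dose_day + schedule$chemo$delta_switch_lag)
  }
  brk <- sort(unique(c(brk[brk >= 0 & brk <= T], T)))
  tot <- 0
  for (i in seq_len(length(brk) - 1L)) {
    tot <- tot + stats::integrate(integrand, brk[i], brk[i + 1L],
                                  rel.tol = 1e-10, abs.tol = 0,
                                  subdivisions = 400L)$value
  }
  lf * tot
}

# exact supremum of the treated seeding intensity on [0, T]: between events
# log x_p has slope a - k(t) with k decaying, hence is convex, so the
# maximum of x_p over each closed inter-event interval sits at an endpoint
# (using the pre-irradiation left limit at fraction days).
treated_intensity_bound <- function(fit, schedule, params) {
  xp <- treated_primary_trajectory(fit, schedule, horizon = params$T)
  fd <- attr(xp, "frac_days")
  SF <- attr(xp, "survival_per_fraction")
  ev <- sort(unique(c(0, fd[fd <= params$T], params$T)))
  x_right <- xp(ev)                      # post-event values
  x_left <- xp(ev) / ifelse(ev %in% fd, SF, 1)  # pre-irradiation left limits
  xmax <- max(x_right, x_left)
  dmax <- params$delta
  if (!is.null(schedule$chemo) && !is.na(schedule$chemo$delta_post))
    dmax <- c(params$delta, schedule$chemo$delta_post)
  params$m * max(1, max(xmax^(dmax / 3)))
}

#' Stochastic simulation of a treated animal
#'
#' Runs the seeding simulator with the treated primary trajectory: colony
#' births follow an inhomogeneous Poisson process with intensity
#' `m x_p(t)^(delta(t)/3)` (thinning against an exact event-endpoint bound),
#' the fractal dimension switches to `delta_post` at
#' `dose_day + delta_switch_lag`, and colonies experience the systemic chemo
#' kill but not primary-field radiotherapy. `mode = "expectation"` returns
#' the deterministic expectation instead.
#'
#' @param fit `growth_fit`.
#' @param schedule A [treatment_schedule()].
#' @param params A [spread_params()].
#' @param seed RNG seed (stochastic mode).
#' @param mode `"stochastic"` (default) or `"expectation"`.
#' @return A `spread_result` (in expectation mode `dtc_total` is `D(T)` and
#'   colony lists are empty).
#' @export
simulate_treated_mouse <- function(fit, schedule, params, seed = 1L,
                                   mode = c("stochastic", "expectation")) {
  stopifnot(inherits(schedule, "treatment_schedule"), inherits(params, "spread_params"))
  mode <- match.arg(mode)
  xp <- treated_primary_trajectory(fit, schedule, horizon = params$T)
  T <- params$T; m <- params$m; a <- fit$a
  if (mode == "expectation") {
    D <- expected_total_dtc_treated(fit, schedule, params)
    return(structure(list(
      colony_birth_times = numeric(), colony_sizes_at_T = numeric(),
      n_colonies = NA_integer_, dtc_total = D,
      ctc_rate_at_T = m * xp(T)^(delta_at(T, params$delta, schedule) / 3),
      primary_size_at_T = xp(T)
    ), class = "spread_result"))
  }
  set.seed(as.integer(seed))
  births <- numeric()
  if (m > 0 && T > 0) {
    B <- treated_intensity_bound(fit, schedule, params)
    if (!is.finite(B)) stopf("non-finite intensity bound")
    n_prop <- stats::rpois(1L, B * T)
    t_prop <- stats::runif(n_prop, 0, T)
    lam <- m * xp(t_prop)^(delta_at(t_prop, params$delta, schedule) / 3)
    births <- sort(t_prop[stats::runif(n_prop) * B <= lam])
  }
  sizes <- colony_growth_factor(births, T, a, schedule)
  structure(list(
    colony_birth_times = births, colony_sizes_at_T = sizes,
    n_colonies = length(births),
    dtc_total = params$lung_fraction * sum(sizes),
    ctc_rate_at_T = m * xp(T)^(delta_at(T, params$delta, schedule) / 3),
    primary_size_at_T = xp(T)
  ), class = "spread_result")
}

#' One-at-a-time error propagation for a simulated DTC count
#'
#' Reruns the full per-animal simulation with each listed parameter moved to
#' its mean plus or minus one standard deviation, all other parameters at
#' baseline. The per-parameter half-range is `(max - min) / 2` and the
#' reported error is the quadrature sum of half-ranges; the raw min/max
#' envelope is also returned. Perturbations leaving a parameter's valid
#' range are clamped and flagged. In stochastic mode all runs share the
#' baseline seed.
#'
#' @param fit `growth_fit`.
#' @param schedule A [treatment_schedule()] (may be empty for controls).
#' @param params A [spread_params()].
#' @param perturb Named numeric vector of standard deviations; names resolve
#'   to `spread_params` fields (`m`, `delta`, `a`, `N0`) or chemo/radio
#'   fields (`delta_post`, `k0`, `lambda_d`, `f_S`, `alpha`, `beta_lq`).
#' @param mode,seed Passed to [simulate_treated_mouse()].
#' @return List `dtc_sim` (baseline), `err`, `envelope` (min/max), per-
#'   parameter `half_ranges`, and `clamped` names.
#' @export
propagate_errors <- function(fit, schedule, params, perturb,
                             mode = c("expectation", "stochastic"), seed = 1L) {
  mode <- match.arg(mode)
  if (any(perturb < 0)) stopf("standard deviations must be >= 0")
  run <- function(fit_, schedule_, params_) {
    simulate_treated_mouse(fit_, schedule_, params_, seed = seed, mode = mode)$dtc_total
  }
  baseline <- run(fit, schedule, params)
  bounds <- list(m = c(0, Inf), delta = c(0, 3), a = c(-Inf, Inf),
                 N0 = c(1, Inf), delta_post = c(0, 3), k0 = c(0, Inf),
                 lambda_d = c(0, Inf), f_S = c(0, 1),
                 alpha = c(0, Inf), beta_lq = c(0, Inf))
  clamped <- character()
  half_ranges <- numeric(0)
  env_lo <- baseline; env_hi <- baseline
  for (nm in names(perturb)) {
    sdv <- perturb[[nm]]
    vals <- numeric(2)
    for (j in 1:2) {
      shift <- if (j == 1) sdv else -sdv
      fit_ <- fit; schedule_ <- schedule; params_ <- params
      get_base <- function() {
        if (nm %in% c("m", "delta", "N0")) params[[nm]]
        else if (nm == "a") fit$a
        else if (!is.null(schedule$chemo) && nm %in% names(schedule$chemo)) schedule$chemo[[nm]]
        else if (!is.null(schedule$radio) && nm %in% names(schedule$radio)) schedule$radio[[nm]]
        else stopf("unknown parameter '%s'", nm)
      }
      v <- get_base() + shift
      b <- bounds[[nm]] %||% c(-Inf, Inf)
      if (v < b[1] || v > b[2]) {
        v <- clamp(v, b[1], b[2])
        clamped <- union(clamped, nm)
      }
      if (nm %in% c("m", "delta", "N0")) params_[[nm]] <- v
      else if (nm == "a") fit_$a <- v
      else if (!is.null(schedule$chemo) && nm %in% names(schedule$chemo)) schedule_$chemo[[nm]] <- v
      else schedule_$radio[[nm]] <- v
      vals[j] <- run(fit_, schedule_, params_)
    }
    half_ranges[nm] <- (max(vals) - min(vals)) / 2
    env_lo <- min(env_lo, vals); env_hi <- max(env_hi, vals)
  }
  list(dtc_sim = baseline,
       err = sqrt(sum(half_ranges^2)),
       envelope = c(min = env_lo, max = env_hi),
       half_ranges = half_ranges,
       clamped = clamped)
}

#' Does the simulation match the measurement within its error?
#'
#' `TRUE` iff `|dtc_sim - dtc_pcr| <= err` (closed interval).
#'
#' @param dtc_sim Simulated disseminated total.
#' @param err Propagated simulation error (>= 0).
#' @param dtc_pcr Measured absolute disseminated count.
#' @return Logical.
#' @export
match_within_error <- function(dtc_sim, err, dtc_pcr) {
  if (any(err < 0)) stopf("err must be >= 0")
  abs(dtc_sim - dtc_pcr) <= err
}
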