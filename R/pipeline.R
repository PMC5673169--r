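#' Pipeline configuration
#'
#' @param delta_ref Fractal dimension pinned for the reference mouse when
#'   calibrating `m` (default 2: surface-limited supply).
#' @param k_ctc CTC count to intravasation-rate conversion factor.
#' @param organ_scale Per-template to absolute DTC scaling (default 100,
#'   i.e. 6000 ng organ DNA / 60 ng template).
#' @param lung_fraction Organ-lodging fraction.
#' @param chemo_schedule,radio_schedule [treatment_schedule()]s applied to
#'   the treated groups (chemo `delta_post` is inferred per mouse, so leave
#'   it `NA`).
#' @param perturb Named SD vector for one-at-a-time error propagation; by
#'   default the control-cohort growth-rate SD is used for `a` once known.
#' @param organ Organ whose DTC count drives the spread inference
#'   (default `"lung"`).
#' @param seed Master seed recorded with the outputs.
#' @return A config list.
#' @export
pipeline_config <- function(delta_ref = 2, k_ctc = 1, organ_scale = 100,
                            lung_fraction = 1,
                            chemo_schedule = NULL, radio_schedule = NULL,
                            perturb = NULL, organ = "lung", seed = 1L) {
  list(delta_ref = delta_ref, k_ctc = k_ctc, organ_scale = organ_scale,
       lung_fraction = lung_fraction, chemo_schedule = chemo_schedule,
       radio_schedule = radio_schedule, perturb = perturb, organ = organ,
       seed = seed)
}

#' Infer the post-treatment fractal dimension
#'
#' Bisection on `delta_post` in `[0, 3]` against the treated deterministic
#' expectation (monotone increasing in `delta_post`), holding the
#' pre-switch dimension and all other parameters fixed. Targets outside the
#' attainable range clamp to the endpoint with a flag — clamped animals are
#' the ones whose measured counts the model cannot reach.
#'
#' @param fit `growth_fit` for the animal.
#' @param schedule [treatment_schedule()] with a chemo block.
#' @param params [spread_params()] carrying the pre-switch `delta`.
#' @param dtc_target Measured absolute disseminated count.
#' @param rel_tol Relative tolerance on the matched expectation.
#' @return List `delta_post`, `clamped`, `dtc_at_delta`.
#' @export
infer_delta_post_treatment <- function(fit, schedule, params, dtc_target,
                                       rel_tol = 1e-6) {
  if (is.null(schedule$chemo)) stopf("schedule has no chemo block to switch")
  Dfun <- function(dp) {
    s <- schedule
    s$chemo$delta_post <- dp
    expected_total_dtc_treated(fit, s, params)
  }
  lo <- 0; hi <- 3
  D_lo <- Dfun(lo); D_hi <- Dfun(hi)
  if (dtc_target <= D_lo)
    return(list(delta_post = 0, clamped = TRUE, dtc_at_delta = D_lo))
  if (dtc_target >= D_hi)
    return(list(delta_post = 3, clamped = TRUE, dtc_at_delta = D_hi))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    D_mid <- Dfun(mid)
    if (abs(D_mid - dtc_target) <= rel_tol * dtc_target || (hi - lo) < 1e-13) break
    if (D_mid < dtc_target) lo <- mid else hi <- mid
  }
  list(delta_post = mid, clamped = FALSE, dtc_at_delta = D_mid)
}

#' Run the full analysis pipeline on a cohort
#'
#' Control branch: palpation correction, per-mouse exponential fits, cohort
#' summary, colonization-coefficient calibration on the reference mouse
#' (largest primary at necropsy, fractal dimension pinned at
#' `delta_ref`), per-mouse fractal-dimension inference from DTCs and from
#' CTCs, the paired Wilcoxon comparison of the two routes, and the Pearson
#' correlation of final size with CTC count.
#'
#' Treated branches: fixed-rate fits on pre-treatment points using the
#' control-mean rate, a whole-experiment fractal dimension from the CTC
#' rate, the simulated disseminated count with and without the post-chemo
#' dimension switch, the chosen post-treatment dimension matching the
#' measurement, one-at-a-time error propagation, and the within-error match
#' flag.
#'
#' All per-mouse tables are sorted by final primary size ascending.
#'
#' @param control_records List of control [mouse_record()]s (>= 2).
#' @param chemo_records,radio_records Optional treated records.
#' @param config A [pipeline_config()].
#' @return List `control_table`, `chemo_table`, `radio_table`, `m`,
#'   `a_mean`, `a_sd`, `summary`, `stats` (Wilcoxon + Pearson),
#'   `config`.
#' @export
run_pipeline <- function(control_records, chemo_records = list(),
                         radio_records = list(), config = pipeline_config()) {
  if (length(control_records) < 2L) stopf("need at least 2 control animals")

  corr <- lapply(control_records, correct_palpation_series)
  fits <- lapply(corr, function(r)
    fit_exponential(r$days, volume_to_cells(r$palpated_volumes)))
  summ <- cohort_growth_summary(fits)
  a_bar <- summ$a_mean

  final_cells <- vapply(corr, function(r)
    volume_to_cells(r$palpated_volumes[length(r$palpated_volumes)]), 0)
  horizons <- vapply(corr, function(r) r$necropsy_day, 0)
  dtc_abs <- vapply(corr, function(r)
    dtc_absolute_count(r$dtc_counts[[config$organ]],
                       organ_scale = config$organ_scale), 0)

  ref <- which.max(final_cells)
  m <- calibrate_colonization_coefficient(
    fits[[ref]], T = horizons[ref], dtc_target = dtc_abs[ref],
    delta_ref = config$delta_ref, lung_fraction = config$lung_fraction)

  ctab <- do.call(rbind, lapply(seq_along(corr), function(i) {
    r <- corr[[i]]; f <- fits[[i]]
    dd <- infer_delta_from_dtc(f, T = horizons[i], m = m,
                               dtc_target = dtc_abs[i],
                               lung_fraction = config$lung_fraction)
    dc <- infer_delta_from_ctc(f, T = horizons[i], m = m,
                               ctc_count = r$ctc_count, k_ctc = config$k_ctc)
    dsim_ctc <- expected_total_dtc(spread_params(
      m = m, delta = dc$delta, a = f$a, N0 = f$N0, T = horizons[i],
      lung_fraction = config$lung_fraction))
    data.frame(mouse_id = r$mouse_id, N0 = f$N0, a = f$a,
               rate_was_fixed = f$rate_was_fixed, rss = f$rss,
               correction_factor = r$correction_factor,
               final_cells = final_cells[i],
               ctc_per20ng = r$ctc_count, dtc_pcr = dtc_abs[i],
               delta_dtc = dd$delta, delta_dtc_clamped = dd$clamped,
               delta_ctc = dc$delta, delta_ctc_clamped = dc$clamped,
               dtc_sim_dtc = dd$dtc_at_delta, dtc_sim_ctc = dsim_ctc,
               stringsAsFactors = FALSE)
  }))
  ctab <- ctab[order(ctab$final_cells), , drop = FALSE]

  wil <- wilcoxon_signed_rank(ctab$delta_dtc - ctab$delta_ctc)
  pea <- tryCatch(pearson_correlation(ctab$final_cells, ctab$ctc_per20ng),
                  error = function(e) NA_real_)

  perturb <- config$perturb %||% c(a = summ$a_sd)

  treat_branch <- function(records, schedule) {
    if (length(records) == 0L || is.null(schedule)) return(NULL)
    rows <- lapply(records, function(rec) {
      rec <- correct_palpation_series(rec)
      f <- tryCatch(
        fit_n0_fixed_rate(rec$days, volume_to_cells(rec$palpated_volumes),
                          a_fixed = a_bar,
                          treatment_start_day = rec$treatment_start_day,
                          mouse_id = rec$mouse_id),
        error = function(e) e)
      if (inherits(f, "error")) {
        warning(sprintf("mouse %s skipped: %s", rec$mouse_id, conditionMessage(f)))
        return(NULL)
      }
      T_i <- rec$necropsy_day
      dtc_i <- dtc_absolute_count(rec$dtc_counts[[config$organ]],
                                  organ_scale = config$organ_scale)
      xp <- treated_primary_trajectory(f, schedule, horizon = T_i)
      # whole-experiment dimension from the end-of-experiment CTC rate
      # (reflects the end-state geometry; reported and used for the
      # no-switch simulation)
      rate <- rec$ctc_count / config$k_ctc
      d_comp <- if (!is.na(rate) && rate > 0 && xp(T_i) > 1)
        clamp(3 * (log(rate) - log(m)) / log(xp(T_i)), 0, 3) else config$delta_ref
      # pre-switch geometry: the untreated reference dimension
      pp <- spread_params(m = m, delta = config$delta_ref, a = f$a, N0 = f$N0,
                          T = T_i, lung_fraction = config$lung_fraction)
      pp_comp <- spread_params(m = m, delta = d_comp, a = f$a, N0 = f$N0,
                               T = T_i, lung_fraction = config$lung_fraction)
      sched0 <- schedule
      if (!is.null(sched0$chemo)) sched0$chemo$delta_post <- NA_real_  # no switch
      dtc_sim_fixed <- expected_total_dtc_treated(f, sched0, pp_comp)
      if (!is.null(schedule$chemo)) {
        post <- infer_delta_post_treatment(f, schedule, pp, dtc_i)
        sched1 <- schedule
        sched1$chemo$delta_post <- post$delta_post
        pe <- propagate_errors(f, sched1, pp, perturb, mode = "expectation",
                               seed = config$seed)
        data.frame(mouse_id = rec$mouse_id, N0 = f$N0, a = f$a,
                   rate_was_fixed = TRUE, rss = f$rss,
                   correction_factor = rec$correction_factor,
                   final_cells = xp(T_i),
                   PT_treat_start = xp(rec$treatment_start_day),
                   dtc_pcr = dtc_i, delta_computed = d_comp,
                   dtc_sim_no_switch = dtc_sim_fixed,
                   chosen_delta_after_treatment = post$delta_post,
                   delta_post_clamped = post$clamped,
                   dtc_sim = post$dtc_at_delta, err = pe$err,
                   match = match_within_error(post$dtc_at_delta, pe$err, dtc_i),
                   stringsAsFactors = FALSE)
      } else {
        pe <- propagate_errors(f, schedule, pp_comp, perturb,
                               mode = "expectation", seed = config$seed)
        data.frame(mouse_id = rec$mouse_id, N0 = f$N0, a = f$a,
                   rate_was_fixed = TRUE, rss = f$rss,
                   correction_factor = rec$correction_factor,
                   final_cells = xp(T_i),
                   PT_treat_start = xp(rec$treatment_start_day),
                   dtc_pcr = dtc_i, delta_computed = d_comp,
                   dtc_sim_no_switch = dtc_sim_fixed,
                   chosen_delta_after_treatment = NA_real_,
                   delta_post_clamped = NA,
                   dtc_sim = dtc_sim_fixed, err = pe$err,
                   match = match_within_error(dtc_sim_fixed, pe$err, dtc_i),
                   stringsAsFactors = FALSE)
      }
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows) == 0L) return(NULL)
    tab <- do.call(rbind, rows)
    tab[order(tab$final_cells), , drop = FALSE]
  }

  chemo_tab <- treat_branch(chemo_records, config$chemo_schedule)
  radio_tab <- treat_branch(radio_records, config$radio_schedule)

  list(control_table = ctab, chemo_table = chemo_tab, radio_table = radio_tab,
       m = m, a_mean = a_bar, a_sd = summ$a_sd, summary = summ,
       stats = list(wilcoxon_delta = wil, pearson_size_ctc = pea),
       config = config)
}

#' Group-level vessel-density comparison
#'
#' Per-tumor mean densities per group plus the control-versus-treatment
#' two-sample t-tests and group summaries.
#'
#' @param density_by_group Named list (`control`, `chemo`, `radio`) of
#'   numeric vectors of per-tumor mean densities (per mm^2).
#' @return List of `summaries` ([group_summary()] per group) and `tests`
#'   (pooled t-test of each treated group against control).
#' @export
vessel_group_comparison <- function(density_by_group) {
  if (is.null(density_by_group$control)) stopf("control densities required")
  summaries <- lapply(density_by_group, function(v)
    if (length(v) >= 2) group_summary(v) else list(mean = mean(v), sd = NA, n = length(v)))
  tests <- list()
  for (g in setdiff(names(density_by_group), "control")) {
    if (length(density_by_group[[g]]) >= 2)
      tests[[g]] <- two_sample_t_test(density_by_group$control,
                                      density_by_group[[g]])
  }
  list(summaries = summaries, tests = tests)
}
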