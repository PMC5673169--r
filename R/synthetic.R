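#' Log-normal parameters from a target mean and SD
#'
#' @param mean,sd Target arithmetic mean and SD of the log-normal.
#' @return List `meanlog`, `sdlog`.
#' @export
lognormal_params_from_moments <- function(mean, sd) {
  if (mean <= 0 || sd < 0) stopf("mean must be > 0 and sd >= 0")
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log1p(cv2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# default size -> fractal dimension rule: larger tumors are better
# vascularized (delta increases with log final size, ~2 at 5e7 cells)
default_delta_rule <- function(xT) clamp(0.12 * log(xT) - 0.1, 0, 3)

#' Generate a synthetic control cohort
#'
#' Emulates the untreated arm of a xenograft experiment: per-animal growth
#' rates `a_i ~ Normal(a_mean, a_sd)` truncated positive, engrafted cell
#' numbers `N0_i` log-normal (heavy-tailed, SD > mean by default),
#' palpated volumes with a per-mouse systematic bias plus multiplicative
#' measurement noise, a necropsy weight derived from the true final size,
#' and forward-model CTC/DTC counts (Poisson on absolute numbers, reported
#' per template). Each mouse draws from its own RNG stream keyed by
#' `(seed, mouse id)`, so growing the cohort never reshuffles existing
#' animals.
#'
#' @param n Number of animals.
#' @param a_mean,a_sd Growth-rate distribution (1/day); defaults 0.260 and
#'   0.043.
#' @param n0_mean,n0_sd Engraftment distribution (cells); defaults 1.44e6
#'   and 2.37e6.
#' @param days Measurement days (default `c(0, 2, 4, 7, 9, 11, 14)`).
#' @param noise_cv Palpation noise coefficient of variation (default 0.10).
#' @param bias_cv Per-mouse systematic palpation bias CV (default 0.15);
#'   the necropsy-weight correction is what removes this.
#' @param weight_cv Necropsy-weight noise CV (default 0.05).
#' @param m Colonization coefficient (default 0.05).
#' @param delta Fractal dimension: a number (fixed for the whole cohort), a
#'   function of final size in cells, or `NULL` for the default increasing
#'   size rule.
#' @param lung_fraction,k_ctc,organ_scale Model and assay conversion
#'   factors.
#' @param count_noise Draw PCR counts as Poisson (`TRUE`, default) or use
#'   rounded expectations (`FALSE`; combined with zero CVs this gives the
#'   exactly invertible noiseless world — then counts are left unrounded).
#' @param seed Master RNG seed.
#' @return List `records` (list of [mouse_record()]) and `truth`
#'   (data.frame of per-mouse generating parameters and expectations).
#' @export
generate_control_cohort <- function(n, a_mean = 0.260, a_sd = 0.043,
                                    n0_mean = 1.44e6, n0_sd = 2.37e6,
                                    days = c(0, 2, 4, 7, 9, 11, 14),
                                    noise_cv = 0.10, bias_cv = 0.15,
                                    weight_cv = 0.05,
                                    m = 0.05, delta = NULL,
                                    lung_fraction = 1, k_ctc = 1,
                                    organ_scale = 100,
                                    count_noise = TRUE, seed = 1L) {
  if (n < 1L) stopf("n must be >= 1")
  if (a_sd < 0 || noise_cv < 0 || bias_cv < 0 || weight_cv < 0)
    stopf("dispersion parameters must be >= 0")
  lp <- lognormal_params_from_moments(n0_mean, n0_sd)
  T_end <- max(days)
  delta_fun <- if (is.null(delta)) default_delta_rule
    else if (is.function(delta)) delta
    else function(xT) rep(delta, length(xT))

  records <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("C%02d", i)
    set.seed(derive_seed(seed, id))
    a_i <- repeat_until_positive(function() stats::rnorm(1, a_mean, a_sd))
    N0_i <- stats::rlnorm(1, lp$meanlog, lp$sdlog)
    x <- N0_i * exp(a_i * days)
    bias <- if (bias_cv > 0) stats::rlnorm(1, 0, cv_to_sdlog(bias_cv)) else 1
    eps <- if (noise_cv > 0) stats::rlnorm(length(days), 0, cv_to_sdlog(noise_cv))
           else rep(1, length(days))
    vols <- cells_to_volume(x) * bias * eps
    w_noise <- if (weight_cv > 0) stats::rlnorm(1, 0, cv_to_sdlog(weight_cv)) else 1
    weight <- cells_to_volume(x[length(x)]) * TUMOR_DENSITY_G_PER_CM3 * w_noise

    xT <- x[length(x)]
    d_i <- delta_fun(xT)
    pp <- spread_params(m = m, delta = d_i, a = a_i, N0 = N0_i, T = T_end,
                        lung_fraction = lung_fraction, k_ctc = k_ctc)
    dtc_expected <- expected_total_dtc(pp)
    ctc_rate <- colonization_rate(xT, m, d_i)
    if (count_noise) {
      dtc_template <- stats::rpois(1, dtc_expected / organ_scale)
      ctc_template <- stats::rpois(1, k_ctc * ctc_rate)
    } else {
      dtc_template <- dtc_expected / organ_scale
      ctc_template <- k_ctc * ctc_rate
    }
    records[[i]] <- mouse_record(
      mouse_id = id, group = "control", days = days,
      palpated_volumes = vols, necropsy_weight = weight,
      necropsy_day = T_end, ctc_count = ctc_template,
      dtc_counts = c(lung = dtc_template))
    truth[[i]] <- data.frame(
      mouse_id = id, a = a_i, N0 = N0_i, delta = d_i, m = m,
      final_cells = xT, dtc_expected = dtc_expected,
      ctc_rate = ctc_rate, bias = bias, stringsAsFactors = FALSE)
  }
  list(records = records, truth = do.call(rbind, truth))
}

repeat_until_positive <- function(draw) {
  for (i in 1:1000) {
    v <- draw()
    if (v > 0) return(v)
  }
  stopf("could not draw a positive value in 1000 attempts")
}

cv_to_sdlog <- function(cv) sqrt(log1p(cv^2))

#' Generate a synthetic treated cohort
#'
#' As [generate_control_cohort()], but the palpated sizes follow the treated
#' primary trajectory under `schedule`, and DTC counts come from the treated
#' spread expectation including the post-chemo fractal-dimension switch.
#' Measurement days strictly before the first treatment event are guaranteed
#' (error otherwise).
#'
#' @inheritParams generate_control_cohort
#' @param group `"chemo"` or `"radio"`.
#' @param schedule A [treatment_schedule()]; its chemo `delta_post` (if
#'   `NA`) is filled per mouse by `delta_post_rule`.
#' @param delta_post_rule Function `delta_pre -> delta_post`, or a number;
#'   default reduces the fractal dimension by 1 (floored at 0), mimicking
#'   vessel-tree damage.
#' @return List `records`, `truth` (with `delta_post`, treated expectations).
#' @export
generate_treated_cohort <- function(n, group = c("chemo", "radio"),
                                    schedule,
                                    a_mean = 0.260, a_sd = 0.043,
                                    n0_mean = 1.44e6, n0_sd = 2.37e6,
                                    days = c(0, 2, 4, 7, 9, 11, 14),
                                    noise_cv = 0.10, bias_cv = 0.15,
                                    weight_cv = 0.05,
                                    m = 0.05, delta = NULL,
                                    delta_post_rule = NULL,
                                    lung_fraction = 1, k_ctc = 1,
                                    organ_scale = 100,
                                    count_noise = TRUE, seed = 1L) {
  group <- match.arg(group)
  stopifnot(inherits(schedule, "treatment_schedule"))
  t_start <- min(c(if (!is.null(schedule$chemo)) schedule$chemo$dose_day,
                   if (!is.null(schedule$radio)) schedule$radio$start_day))
  if (!any(days < t_start))
    stopf("schedule starts on/before the first measurement day")
  lp <- lognormal_params_from_moments(n0_mean, n0_sd)
  T_end <- max(days)
  delta_fun <- if (is.null(delta)) default_delta_rule
    else if (is.function(delta)) delta
    else function(xT) rep(delta, length(xT))
  post_fun <- if (is.null(delta_post_rule)) function(d) pmax(0, d - 1)
    else if (is.function(delta_post_rule)) delta_post_rule
    else function(d) rep(delta_post_rule, length(d))

  records <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("%s%02d", switch(group, chemo = "CH", radio = "RT"), i)
    set.seed(derive_seed(seed, id))
    a_i <- repeat_until_positive(function() stats::rnorm(1, a_mean, a_sd))
    N0_i <- stats::rlnorm(1, lp$meanlog, lp$sdlog)
    fit_i <- growth_fit(N0 = N0_i, a = a_i, rss = 0, n_points = 0L,
                        rate_was_fixed = TRUE)
    # untreated-equivalent delta from the would-be untreated final size
    d_i <- delta_fun(N0_i * exp(a_i * T_end))
    sched_i <- schedule
    if (!is.null(sched_i$chemo) && is.na(sched_i$chemo$delta_post))
      sched_i$chemo$delta_post <- post_fun(d_i)
    xp <- treated_primary_trajectory(fit_i, sched_i, horizon = T_end)
    x <- xp(days)
    bias <- if (bias_cv > 0) stats::rlnorm(1, 0, cv_to_sdlog(bias_cv)) else 1
    eps <- if (noise_cv > 0) stats::rlnorm(length(days), 0, cv_to_sdlog(noise_cv))
           else rep(1, length(days))
    vols <- cells_to_volume(x) * bias * eps
    w_noise <- if (weight_cv > 0) stats::rlnorm(1, 0, cv_to_sdlog(weight_cv)) else 1
    weight <- cells_to_volume(x[length(x)]) * TUMOR_DENSITY_G_PER_CM3 * w_noise

    pp <- spread_params(m = m, delta = d_i, a = a_i, N0 = N0_i, T = T_end,
                        lung_fraction = lung_fraction, k_ctc = k_ctc)
    dtc_expected <- expected_total_dtc_treated(fit_i, sched_i, pp)
    ctc_rate <- m * xp(T_end)^(delta_at(T_end, d_i, sched_i) / 3)
    if (count_noise) {
      dtc_template <- stats::rpois(1, dtc_expected / organ_scale)
      ctc_template <- stats::rpois(1, k_ctc * ctc_rate)
    } else {
      dtc_template <- dtc_expected / organ_scale
      ctc_template <- k_ctc * ctc_rate
    }
    records[[i]] <- mouse_record(
      mouse_id = id, group = group, days = days,
      palpated_volumes = vols, necropsy_weight = weight,
      necropsy_day = T_end, ctc_count = ctc_template,
      dtc_counts = c(lung = dtc_template),
      treatment_start_day = t_start)
    truth[[i]] <- data.frame(
      mouse_id = id, a = a_i, N0 = N0_i, delta = d_i,
      delta_post = if (!is.null(sched_i$chemo)) sched_i$chemo$delta_post else NA_real_,
      m = m, final_cells = x[length(x)], dtc_expected = dtc_expected,
      ctc_rate = ctc_rate, bias = bias, stringsAsFactors = FALSE)
  }
  list(records = records, truth = do.call(rbind, truth))
}

#' Generate a synthetic stained histology slide
#'
#' Draws `n_vessels` non-overlapping stained disks (with slight per-pixel
#' colour jitter) on a tissue-coloured background, optionally with a paler
#' necrotic region (and its mask). Ground truth (count, centres, radii) is
#' recorded for recovery tests.
#'
#' @param width,height Raster size in pixels.
#' @param mpp Microns per pixel.
#' @param n_vessels Number of vessel disks.
#' @param radius_range_um Uniform radius range in microns (default
#'   `c(4, 10)`).
#' @param stain_rgb,tissue_rgb,necrosis_rgb Colours (sRGB in `[0,1]`).
#' @param colour_jitter Half-width of the uniform per-pixel RGB jitter
#'   (default 0.015).
#' @param necrosis_fraction Fraction of image width covered by a necrotic
#'   band on the left (0 disables; vessels are only placed outside it).
#' @param min_gap_px Minimum background gap between disks (default 2).
#' @param max_tries Rejection-sampling cap per disk.
#' @param seed RNG seed.
#' @return List `image` ([slide_image()] with masks when necrosis is
#'   present) and `truth` (`n_vessels`, `centers`, `radii_um`,
#'   `area_um2`, `seed`).
#' @export
generate_slide <- function(width = 120L, height = 120L, mpp = 2,
                           n_vessels = 30L, radius_range_um = c(4, 10),
                           stain_rgb = c(0.80, 0.15, 0.25),
                           tissue_rgb = c(0.91, 0.82, 0.86),
                           necrosis_rgb = c(0.96, 0.93, 0.90),
                           colour_jitter = 0.015,
                           necrosis_fraction = 0,
                           min_gap_px = 2L, max_tries = 2000L, seed = 1L) {
  set.seed(as.integer(seed))
  img <- array(0, dim = c(height, width, 3L))
  for (ch in 1:3) img[, , ch] <- tissue_rgb[ch]
  masks <- list()
  nec_cols <- 0L
  if (necrosis_fraction > 0) {
    nec_cols <- max(1L, round(necrosis_fraction * width))
    nec <- matrix(FALSE, height, width)
    nec[, seq_len(nec_cols)] <- TRUE
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[nec] <- necrosis_rgb[ch]
      img[, , ch] <- plane
    }
    masks$tumor_region <- matrix(TRUE, height, width)
    masks$necrosis <- nec
  }

  centers <- matrix(0, 0, 2)
  radii_px <- numeric()
  rpx <- radius_range_um / mpp
  for (v in seq_len(n_vessels)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      r <- stats::runif(1, rpx[1], rpx[2])
      cx <- stats::runif(1, nec_cols + r + 1, width - r)
      cy <- stats::runif(1, r + 1, height - r)
      if (cx - r < nec_cols + 1) next
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
              radii_px + r + min_gap_px)) {
        centers <- rbind(centers, c(cx, cy))
        radii_px <- c(radii_px, r)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stopf("could not place vessel %d of %d; lower n_vessels or density", v, n_vessels)
  }

  cols <- matrix(rep(seq_len(width), each = height), height, width)
  rows <- matrix(rep(seq_len(height), width), height, width)
  stained <- matrix(FALSE, height, width)
  for (v in seq_along(radii_px)) {
    d2 <- (cols - centers[v, 1])^2 + (rows - centers[v, 2])^2
    stained <- stained | (d2 <= radii_px[v]^2)
  }
  n_stained <- sum(stained)
  for (ch in 1:3) {
    plane <- img[, , ch]
    jit <- if (colour_jitter > 0)
      stats::runif(n_stained, -colour_jitter, colour_jitter) else 0
    plane[stained] <- clamp(stain_rgb[ch] + jit, 0, 1)
    img[, , ch] <- plane
  }

  list(image = slide_image(img, pixel_size = mpp, masks = masks),
       truth = list(n_vessels = n_vessels,
                    centers_px = centers, radii_um = radii_px * mpp,
                    area_um2 = pi * (radii_px * mpp)^2,
                    stained_mask = stained, seed = seed))
}
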