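# shared fixtures and independent oracles

make_record <- function(id = "M1", group = "control", N0 = 1e6, a = 0.26,
                        days = c(0, 3, 7, 10, 14), noise = NULL,
                        weight = NULL, ctc = 10, dtc = c(lung = 5),
                        treatment_start_day = NULL) {
  vols <- N0 * exp(a * days) / 1e9
  if (!is.null(noise)) vols <- vols * noise
  if (is.null(weight)) weight <- N0 * exp(a * max(days)) / 1e9
  mouse_record(mouse_id = id, group = group, days = days,
               palpated_volumes = vols, necropsy_weight = weight,
               necropsy_day = max(days), ctc_count = ctc, dtc_counts = dtc,
               treatment_start_day = treatment_start_day)
}

# closed-form normal equations for simple linear regression of y on x
normal_equations <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# quadrature oracles for the spread expectations
lambda_quad <- function(p) {
  stats::integrate(function(s) colonization_rate(p$N0 * exp(p$a * s), p$m, p$delta),
                   0, p$T, rel.tol = 1e-12, abs.tol = 0)$value
}
dtc_quad <- function(p) {
  p$lung_fraction *
    stats::integrate(function(s) colonization_rate(p$N0 * exp(p$a * s), p$m, p$delta) *
                       exp(p$a * (p$T - s)),
                     0, p$T, rel.tol = 1e-12, abs.tol = 0)$value
}

# brute-force 2^n enumeration oracle for the signed-rank two-sided p-value
wilcoxon_brute <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Vs <- apply(signs, 1, function(s) sum(r[s]))
  p_le <- mean(Vs <= V)
  p_ge <- mean(Vs >= V)
  min(1, 2 * min(p_le, p_ge))
}

# flood fill on a binary mask from one seed pixel (independent of region_grow)
flood_fill <- function(mask, seed_idx, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  queue <- seed_idx
  out[seed_idx] <- TRUE
  offs <- if (connectivity == 4L) list(c(-1,0), c(1,0), c(0,-1), c(0,1))
          else list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    r <- ((cur - 1) %% nr) + 1
    cc <- ((cur - 1) %/% nr) + 1
    for (o in offs) {
      r2 <- r + o[1]; c2 <- cc + o[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        j <- (c2 - 1) * nr + r2
        if (mask[j] && !out[j]) {
          out[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  out
}

# simple two-colour test slide: stained disks on a uniform background
disk_slide <- function(centers, radii_px, size = 60L, mpp = 2,
                       stain = c(0.80, 0.15, 0.25),
                       bg = c(0.91, 0.82, 0.86)) {
  img <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) img[, , ch] <- bg[ch]
  cols <- matrix(rep(seq_len(size), each = size), size, size)
  rows <- matrix(rep(seq_len(size), size), size, size)
  mask <- matrix(FALSE, size, size)
  for (i in seq_len(nrow(centers))) {
    mask <- mask | ((cols - centers[i, 1])^2 + (rows - centers[i, 2])^2 <= radii_px[i]^2)
  }
  for (ch in 1:3) {
    pl <- img[, , ch]; pl[mask] <- stain[ch]; img[, , ch] <- pl
  }
  list(image = slide_image(img, pixel_size = mpp), mask = mask)
}
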