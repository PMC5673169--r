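par_rg <- segmentation_params(kmeans_k = 2L)

test_that("candidate detection finds stain and ignores background", {
  white <- slide_image(array(1, dim = c(30, 30, 3)), pixel_size = 1)
  expect_false(any(identify_candidate_pixels(white, par_rg)))

  sl <- disk_slide(centers = matrix(c(30, 30), 1), radii_px = 10, size = 60)
  cand <- identify_candidate_pixels(sl$image, par_rg)
  expect_true(all(cand[sl$mask]))          # disk interior all candidate
  expect_false(any(cand[!sl$mask]))        # background untouched

  # mask area vs analytic disk area within 2% at radius >= 20 px
  big <- disk_slide(centers = matrix(c(60, 60), 1), radii_px = 25, size = 120)
  cand_big <- identify_candidate_pixels(big$image, par_rg)
  expect_lt(abs(sum(cand_big) - pi * 25^2) / (pi * 25^2), 0.02)
})

test_that("region growing reduces to seeds at zero tolerance and separates disks", {
  sl <- disk_slide(centers = rbind(c(15, 15), c(45, 45)), radii_px = c(6, 6))
  seeds <- identify_candidate_pixels(sl$image, par_rg)

  p0 <- segmentation_params(tolerance = 0)
  lab0 <- region_grow(sl$image, seeds, p0)
  expect_equal(lab0 > 0, seeds)
  expect_equal(max(lab0), 2L)

  lab <- region_grow(sl$image, seeds, par_rg)
  expect_equal(max(lab), 2L)
})

test_that("region growing equals a flood-fill oracle on two-colour images", {
  sl <- disk_slide(centers = rbind(c(20, 35), c(44, 12)), radii_px = c(8, 5))
  # seed: one pixel inside each disk
  seeds <- matrix(FALSE, 60, 60)
  seeds[35, 20] <- TRUE  # row, col
  seeds[12, 44] <- TRUE
  lab <- region_grow(sl$image, seeds, par_rg)
  oracle <- flood_fill(sl$mask, which(seeds)[1]) |
    flood_fill(sl$mask, which(seeds)[2])
  expect_equal(lab > 0, oracle)
})

test_that("region growing is independent of seed enumeration order", {
  g <- generate_slide(n_vessels = 12, seed = 21)
  seeds <- identify_candidate_pixels(g$image, par_rg)
  lab_fwd <- region_grow(g$image, seeds, par_rg)
  # flip the image (reverses scan order), grow, flip back
  flip <- function(m) m[nrow(m):1, ncol(m):1]
  img_fl <- g$image
  for (ch in 1:3) img_fl$pixels[, , ch] <- flip(g$image$pixels[, , ch])
  lab_rev <- region_grow(img_fl, flip(seeds), par_rg)
  expect_equal(flip(lab_rev) > 0, lab_fwd > 0)
})

test_that("k-means segmentation recovers well-separated colours deterministically", {
  sl <- disk_slide(centers = rbind(c(15, 45), c(40, 20)), radii_px = c(7, 9))
  km <- kmeans_segment(sl$image, par_rg)
  expect_false(attr(km, "degenerate"))
  km_plain <- km
  attr(km_plain, "degenerate") <- NULL
  expect_equal(km_plain, sl$mask)

  # repeatability under the fixed seed
  km2 <- kmeans_segment(sl$image, par_rg)
  expect_identical(unname(km), unname(km2))

  # cross-method agreement with region growing on a synthetic slide
  g <- generate_slide(n_vessels = 20, seed = 8)
  seeds <- identify_candidate_pixels(g$image, par_rg)
  n_rg <- filter_and_mask(region_grow(g$image, seeds, par_rg), g$image, par_rg)$count
  n_km <- filter_and_mask(label_components(kmeans_segment(g$image, par_rg)),
                          g$image, par_rg)$count
  expect_equal(n_rg, n_km)

  mono <- slide_image(array(0.5, dim = c(20, 20, 3)), pixel_size = 1)
  km_d <- kmeans_segment(mono, par_rg)
  expect_true(attr(km_d, "degenerate"))
  expect_false(any(km_d))
})

test_that("area filtering enforces the threshold and the 50% exclusion rule", {
  # one object of 9 px at 1 um/px -> 9.0 um^2 < 10.3 um^2: removed
  img <- array(0, dim = c(20, 20, 3))
  for (ch in 1:3) img[, , ch] <- c(0.91, 0.82, 0.86)[ch]
  lab <- matrix(0L, 20, 20)
  lab[5:7, 5:7] <- 1L           # 9 px
  lab[12:15, 12:16] <- 2L       # 20 px
  si <- slide_image(img, pixel_size = 1)
  fm <- filter_and_mask(lab, si, segmentation_params(min_object_area = 10.3))
  expect_equal(fm$count, 1L)
  expect_equal(fm$object_areas_um2, 20)

  fm0 <- filter_and_mask(lab, si, segmentation_params(min_object_area = 0))
  expect_equal(fm0$count, 2L)

  # object overlapping the excluded zone by > 50% is dropped
  masks <- list(tumor_region = matrix(TRUE, 20, 20),
                margin_exclusion = {
                  m <- matrix(FALSE, 20, 20); m[, 1:13] <- TRUE; m
                })
  si_m <- slide_image(img, pixel_size = 1, masks = masks)
  fm_m <- filter_and_mask(lab, si_m, segmentation_params(min_object_area = 0),
                          masked = TRUE)
  # object 1 (cols 5:7) fully inside exclusion -> dropped;
  # object 2 spans cols 12:16, 8 of 20 px excluded (40%) -> kept
  expect_equal(fm_m$count, 1L)

  expect_error(
    filter_and_mask(lab, slide_image(img, 1), segmentation_params(),
                    masked = TRUE),
    "tumor_region")
})

test_that("counts are monotone non-increasing in the area threshold", {
  for (s in 1:5) {
    g <- generate_slide(n_vessels = 25, radius_range_um = c(2.2, 8), seed = s)
    seeds <- identify_candidate_pixels(g$image, par_rg)
    lab <- region_grow(g$image, seeds, par_rg)
    cnt <- vapply(c(0, 10.3, 17.7, 60, 150), function(th)
      filter_and_mask(lab, g$image, segmentation_params(min_object_area = th))$count,
      0L)
    expect_true(all(diff(cnt) <= 0))
  }
})

test_that("vessel density divides counts by analyzed area and averages sections", {
  secs <- list(list(count = 10L, area_mm2 = 0.5),
               list(count = 30L, area_mm2 = 1.0))
  vd <- vessel_density(secs)
  expect_equal(vd$per_section$density, c(20, 30))
  expect_equal(vd$tumor_mean_density, 25)
  expect_error(vessel_density(list(list(count = 1L, area_mm2 = 0))), "zero analyzed area")
})

test_that("density is invariant under translation and 90-degree rotation", {
  g <- generate_slide(n_vessels = 15, seed = 31)
  seg <- function(img) {
    seeds <- identify_candidate_pixels(img, par_rg)
    fm <- filter_and_mask(region_grow(img, seeds, par_rg), img, par_rg)
    fm$count / fm$area_mm2
  }
  d0 <- seg(g$image)
  rot <- g$image
  rot$pixels <- aperm(g$image$pixels, c(2, 1, 3))[dim(g$image$pixels)[2]:1, , ]
  expect_equal(seg(rot), d0)

  # translation: interior disks shifted inside a background canvas of the
  # same total area keep count and density
  sl <- disk_slide(centers = rbind(c(20, 20), c(40, 35)), radii_px = c(5, 6),
                   size = 80)
  shift <- function(img, dr, dc, bg = c(0.91, 0.82, 0.86)) {
    out <- img
    for (ch in 1:3) {
      pl <- matrix(bg[ch], 80, 80)
      pl[(1 + dr):80, (1 + dc):80] <- img$pixels[1:(80 - dr), 1:(80 - dc), ch]
      out$pixels[, , ch] <- pl
    }
    out
  }
  expect_equal(seg(shift(sl$image, 9, 13)), seg(sl$image))
})

test_that("necrotic regions are excluded in viable mode", {
  g <- generate_slide(n_vessels = 12, necrosis_fraction = 0.3, seed = 4)
  seeds <- identify_candidate_pixels(g$image, segmentation_params(kmeans_k = 3L))
  lab <- region_grow(g$image, seeds, segmentation_params(kmeans_k = 3L))
  fm_whole <- filter_and_mask(lab, g$image, par_rg, mode = "whole", masked = TRUE)
  fm_viab <- filter_and_mask(lab, g$image, par_rg, mode = "viable", masked = TRUE)
  expect_equal(fm_whole$count, 12L)   # vessels are placed outside necrosis
  expect_equal(fm_viab$count, 12L)
  expect_lt(fm_viab$area_mm2, fm_whole$area_mm2)
})
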