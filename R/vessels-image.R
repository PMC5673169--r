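#' Histology slide raster
#'
#' A stained histology section as an RGB raster (values in `[0, 1]`,
#' row-major, origin top-left) with an isotropic physical pixel size and
#' optional aligned binary masks (`tumor_region`, `margin_exclusion`,
#' `necrosis`).
#'
#' @param pixels Numeric array `height x width x 3` in `[0, 1]`.
#' @param pixel_size Microns per pixel (> 0).
#' @param masks Optional named list of logical matrices of the same
#'   `height x width`.
#' @return An object of class `slide_image`.
#' @export
slide_image <- function(pixels, pixel_size, masks = list()) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stopf("pixels must be a height x width x 3 RGB array")
  if (!is_number(pixel_size) || pixel_size <= 0) stopf("pixel_size must be > 0")
  hw <- dim(pixels)[1:2]
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!identical(dim(m), hw)) stopf("mask '%s' shape differs from pixels", nm)
    masks[[nm]] <- m > 0
  }
  structure(list(pixels = pixels, pixel_size = pixel_size, masks = masks),
            class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<slide_image> %d x %d px at %.3g um/px (%.3g x %.3g mm); masks: %s\n",
              d[1], d[2], x$pixel_size,
              d[1] * x$pixel_size / 1000, d[2] * x$pixel_size / 1000,
              if (length(x$masks)) paste(names(x$masks), collapse = ", ") else "none"))
  invisible(x)
}

#' Convert an sRGB raster to CIE L*a*b*
#'
#' Uses the D65 white point and the 2 degree standard observer
#' (via [grDevices::convertColor()]).
#'
#' @param pixels `h x w x 3` sRGB array in `[0, 1]`.
#' @return `h x w x 3` array of (L*, a*, b*).
#' @export
rgb_to_lab <- function(pixels) {
  d <- dim(pixels)
  flat <- matrix(pixels, ncol = 3L)
  lab <- grDevices::convertColor(flat, from = "sRGB", to = "Lab", scale.in = 1)
  array(lab, dim = d)
}

# single colour helper
rgb1_to_lab <- function(rgb) {
  as.numeric(grDevices::convertColor(matrix(rgb, nrow = 1L),
                                     from = "sRGB", to = "Lab", scale.in = 1))
}

#' Segmentation parameters
#'
#' @param stain `"permanent_red"` (CD31 chromogen, red) or `"dab"` (brown).
#' @param thresholds Named list of candidate-pixel thresholds on the L*, a*,
#'   b* channels (`L_min`, `L_max`, `a_min`, `a_max`, `b_min`, `b_max`; only
#'   those supplied are enforced). Defaults depend on the stain:
#'   Permanent Red is selected by high a* (`a_min = 25`), DAB by darkness
#'   plus warm hue (`L_max = 65`, `a_min = 5`, `b_min = 15`).
#' @param tolerance Region-growing colour tolerance: maximum Euclidean
#'   L*a*b* distance from a neighbour to the growing region's running mean
#'   colour (default 12).
#' @param connectivity Pixel connectivity, 4 or 8 (default 8).
#' @param min_object_area Post-processing area threshold in square microns
#'   (default 10.3; 17.7 is the stricter alternative).
#' @param kmeans_k Number of colour clusters for the k-means route
#'   (default 3: stain, tissue, background).
#' @param kmeans_seed RNG seed for the k-means++ initialization.
#' @param reference_rgb Reference stain colour (sRGB in `[0,1]`) used to pick
#'   the stained k-means cluster; default depends on the stain.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(stain = c("permanent_red", "dab"),
                                thresholds = NULL, tolerance = 12,
                                connectivity = 8L, min_object_area = 10.3,
                                kmeans_k = 3L, kmeans_seed = 42L,
                                reference_rgb = NULL) {
  stain <- match.arg(stain)
  if (is.null(thresholds)) {
    thresholds <- switch(stain,
      permanent_red = list(a_min = 25),
      dab = list(L_max = 65, a_min = 5, b_min = 15))
  }
  if (is.null(reference_rgb)) {
    reference_rgb <- switch(stain,
      permanent_red = c(0.80, 0.15, 0.25),
      dab = c(0.45, 0.30, 0.15))
  }
  if (tolerance < 0) stopf("tolerance must be >= 0")
  if (!connectivity %in% c(4L, 8L)) stopf("connectivity must be 4 or 8")
  if (min_object_area < 0) stopf("min_object_area must be >= 0")
  if (kmeans_k < 2L) stopf("kmeans_k must be >= 2")
  structure(list(stain = stain, thresholds = thresholds, tolerance = tolerance,
                 connectivity = as.integer(connectivity),
                 min_object_area = min_object_area,
                 kmeans_k = as.integer(kmeans_k),
                 kmeans_seed = as.integer(kmeans_seed),
                 reference_rgb = reference_rgb),
            class = "segmentation_params")
}

#' Candidate stained pixels in L*a*b* space
#'
#' Thresholds each pixel's (L*, a*, b*) coordinates; a pixel is a candidate
#' iff every configured channel bound holds. Candidates seed the region
#' growing in [region_grow()].
#'
#' @param image A [slide_image()].
#' @param params A [segmentation_params()].
#' @return Logical matrix, `TRUE` at candidate pixels.
#' @export
identify_candidate_pixels <- function(image, params) {
  stopifnot(inherits(image, "slide_image"), inherits(params, "segmentation_params"))
  lab <- rgb_to_lab(image$pixels)
  L <- lab[, , 1]; A <- lab[, , 2]; B <- lab[, , 3]
  th <- params$thresholds
  mask <- matrix(TRUE, nrow(L), ncol(L))
  if (!is.null(th$L_min)) mask <- mask & (L >= th$L_min)
  if (!is.null(th$L_max)) mask <- mask & (L <= th$L_max)
  if (!is.null(th$a_min)) mask <- mask & (A >= th$a_min)
  if (!is.null(th$a_max)) mask <- mask & (A <= th$a_max)
  if (!is.null(th$b_min)) mask <- mask & (B >= th$b_min)
  if (!is.null(th$b_max)) mask <- mask & (B <= th$b_max)
  mask
}

# neighbour offsets for the given connectivity
neighbour_offsets <- function(connectivity) {
  if (connectivity == 4L)
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  else
    cbind(dr = rep(c(-1L, 0L, 1L), each = 3L),
          dc = rep(c(-1L, 0L, 1L), times = 3L))[-5L, , drop = FALSE]
}

#' Label connected components of a binary mask
#'
#' Breadth-first labelling in row-major scan order; labels are assigned in
#' the order components are first encountered, so the result is
#' deterministic.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return Integer matrix of labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  offs <- neighbour_offsets(connectivity)
  lab <- 0L
  idx <- which(mask)                     # column-major, but deterministic
  for (start in idx) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- integer(256L); queue[1L] <- start
    head <- 1L; tail <- 1L
    labels[start] <- lab
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      r <- ((cur - 1L) %% nr) + 1L
      cc <- ((cur - 1L) %/% nr) + 1L
      for (k in seq_len(nrow(offs))) {
        r2 <- r + offs[k, 1L]; c2 <- cc + offs[k, 2L]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
          j <- (c2 - 1L) * nr + r2
          if (mask[j] && labels[j] == 0L) {
            labels[j] <- lab
            tail <- tail + 1L
            if (tail > length(queue)) queue <- c(queue, integer(length(queue)))
            queue[tail] <- j
          }
        }
      }
    }
  }
  labels
}

#' Seeded region growing in L*a*b* space
#'
#' Grows each connected seed component breadth-first: a neighbouring pixel
#' joins the region if the Euclidean L*a*b* distance between its colour and
#' the region's running mean colour is at most `params$tolerance`. The mean
#' is updated as pixels join. With `criterion = "seed"` the comparison is
#' against the frozen mean colour of the initial seed component instead.
#' Deterministic given the row-major scan order.
#'
#' @param image A [slide_image()].
#' @param seeds Logical seed mask (e.g. from [identify_candidate_pixels()]).
#' @param params A [segmentation_params()].
#' @param criterion `"running_mean"` (default) or `"seed"`.
#' @return Integer label matrix of grown objects (0 = background).
#' @export
region_grow <- function(image, seeds, params,
                        criterion = c("running_mean", "seed")) {
  stopifnot(inherits(image, "slide_image"))
  criterion <- match.arg(criterion)
  nr <- nrow(seeds); nc <- ncol(seeds)
  if (!any(seeds)) return(matrix(0L, nr, nc))
  lab_img <- rgb_to_lab(image$pixels)
  n <- nr * nc
  labL <- lab_img[, , 1]; labA <- lab_img[, , 2]; labB <- lab_img[, , 3]
  seed_labels <- label_components(seeds, params$connectivity)
  n_comp <- max(seed_labels)
  labels <- seed_labels
  offs <- neighbour_offsets(params$connectivity)
  tol2 <- params$tolerance^2
  for (comp in seq_len(n_comp)) {
    members <- which(seed_labels == comp)
    sL <- sum(labL[members]); sA <- sum(labA[members]); sB <- sum(labB[members])
    cnt <- length(members)
    frozen <- criterion == "seed"
    mL <- sL / cnt; mA <- sA / cnt; mB <- sB / cnt
    queue <- members
    head <- 1L; tail <- length(queue)
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      r <- ((cur - 1L) %% nr) + 1L
      cc <- ((cur - 1L) %/% nr) + 1L
      for (k in seq_len(nrow(offs))) {
        r2 <- r + offs[k, 1L]; c2 <- cc + offs[k, 2L]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
          j <- (c2 - 1L) * nr + r2
          if (labels[j] == 0L) {
            d2 <- (labL[j] - mL)^2 + (labA[j] - mA)^2 + (labB[j] - mB)^2
            if (d2 <= tol2) {
              labels[j] <- comp
              tail <- tail + 1L
              if (tail > length(queue)) queue <- c(queue, integer(length(queue)))
              queue[tail] <- j
              if (!frozen) {
                sL <- sL + labL[j]; sA <- sA + labA[j]; sB <- sB + labB[j]
                cnt <- cnt + 1L
                mL <- sL / cnt; mA <- sA / cnt; mB <- sB / cnt
              }
            }
          }
        }
      }
    }
  }
  labels
}

#' k-means colour segmentation of stained pixels
#'
#' Clusters all pixels' (L*, a*, b*) vectors with k-means (k-means++
#' initialization under a fixed seed, then Lloyd iterations); the stained
#' mask is the cluster whose centroid lies nearest (Euclidean, L*a*b*) to
#' the reference stain colour. Because every pixel is assigned by its colour
#' alone, the mask is invariant to pixel order.
#'
#' @param image A [slide_image()].
#' @param params A [segmentation_params()].
#' @return Logical stained-pixel mask; attribute `degenerate` is `TRUE` for
#'   a single-colour image (mask then empty).
#' @export
kmeans_segment <- function(image, params) {
  stopifnot(inherits(image, "slide_image"), inherits(params, "segmentation_params"))
  lab_img <- rgb_to_lab(image$pixels)
  d <- dim(lab_img)
  X <- matrix(lab_img, ncol = 3L)
  if (all(abs(sweep(X, 2, X[1, ])) < 1e-9)) {
    out <- matrix(FALSE, d[1], d[2])
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  k <- min(params$kmeans_k, nrow(unique(X)))
  centers <- kmeanspp_init(X, k, params$kmeans_seed)
  km <- stats::kmeans(X, centers = centers, iter.max = 100L, algorithm = "Lloyd")
  ref <- rgb1_to_lab(params$reference_rgb)
  dists <- colSums((t(km$centers) - ref)^2)
  stained <- which.min(dists)
  out <- matrix(km$cluster == stained, d[1], d[2])
  attr(out, "degenerate") <- FALSE
  out
}

# k-means++ seeding: first centre = farthest-point-weighted draws under a
# fixed RNG seed
kmeanspp_init <- function(X, k, seed) {
  set.seed(seed)
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  d2 <- colSums((t(X) - centers[1, ])^2)
  if (k > 1L) for (i in 2:k) {
    if (sum(d2) <= 0) {
      centers[i, ] <- X[sample.int(n, 1L), ]
    } else {
      centers[i, ] <- X[sample.int(n, 1L, prob = d2), ]
    }
    d2 <- pmin(d2, colSums((t(X) - centers[i, ])^2))
  }
  unique_rows <- !duplicated(round(centers, 9))
  centers[unique_rows, , drop = FALSE]
}

#' Area filtering and mask restriction of segmented objects
#'
#' Applies the post-processing threshold (`min_object_area`, square microns;
#' object area = pixel count x pixel_size^2) and restricts analysis to the
#' tumor region minus margin exclusion (minus necrosis in `"viable"` mode).
#' Objects whose overlap with excluded zones exceeds 50% are dropped
#' entirely; others are kept whole. The analyzed area (mm^2) is the area of
#' the retained analysis region.
#'
#' @param labels Integer label matrix from [region_grow()] or
#'   [label_components()] of a k-means mask.
#' @param image The [slide_image()] the labels came from (for `pixel_size`
#'   and `masks`).
#' @param params A [segmentation_params()].
#' @param mode `"whole"` (entire tumor) or `"viable"` (necrosis excluded).
#' @param masked Use the slide's masks? If `TRUE`, `tumor_region` must be
#'   present. Default: masked iff the slide carries any masks.
#' @return List: `labels` (filtered), `count`, `object_areas_um2`,
#'   `area_mm2` (analyzed area).
#' @export
filter_and_mask <- function(labels, image, params,
                            mode = c("whole", "viable"),
                            masked = length(image$masks) > 0) {
  stopifnot(inherits(image, "slide_image"), inherits(params, "segmentation_params"))
  mode <- match.arg(mode)
  px2 <- image$pixel_size^2
  nr <- nrow(labels); nc <- ncol(labels)

  analysis <- matrix(TRUE, nr, nc)
  if (masked) {
    if (is.null(image$masks$tumor_region))
      stopf("masked mode requires a tumor_region mask")
    analysis <- image$masks$tumor_region
    if (!is.null(image$masks$margin_exclusion))
      analysis <- analysis & !image$masks$margin_exclusion
    if (mode == "viable" && !is.null(image$masks$necrosis))
      analysis <- analysis & !image$masks$necrosis
  }

  keep <- labels
  ids <- setdiff(unique(as.vector(labels)), 0L)
  excluded <- !analysis
  object_areas <- numeric(0)
  count <- 0L
  for (id in ids) {
    members <- labels == id
    area_um2 <- sum(members) * px2
    drop <- area_um2 < params$min_object_area
    if (!drop && masked) {
      frac_out <- sum(members & excluded) / sum(members)
      drop <- frac_out > 0.5
    }
    if (drop) {
      keep[members] <- 0L
    } else {
      count <- count + 1L
      object_areas <- c(object_areas, area_um2)
    }
  }
  list(labels = keep, count = count,
       object_areas_um2 = object_areas,
       area_mm2 = sum(analysis) * px2 / 1e6)
}

#' Microvessel density over sections
#'
#' Per-section density = retained object count / analyzed area (per mm^2);
#' the per-tumor value is the arithmetic mean over its sections.
#'
#' @param sections List of [filter_and_mask()] results (>= 1).
#' @return A `vessel_density_result`: data.frame `per_section`
#'   (`section`, `count`, `area_mm2`, `density`) and `tumor_mean_density`.
#' @export
vessel_density <- function(sections) {
  if (length(sections) < 1L) stopf("need at least one section")
  areas <- vapply(sections, function(s) s$area_mm2, 0)
  if (any(areas <= 0)) stopf("zero analyzed area in at least one section")
  counts <- vapply(sections, function(s) s$count, 0L)
  dens <- counts / areas
  structure(list(
    per_section = data.frame(section = seq_along(sections), count = counts,
                             area_mm2 = areas, density = dens),
    tumor_mean_density = mean(dens)
  ), class = "vessel_density_result")
}

#' @export
print.vessel_density_result <- function(x, ...) {
  cat(sprintf("<vessel_density_result> %d sections, mean density %.1f /mm^2\n",
              nrow(x$per_section), x$tumor_mean_density))
  print(x$per_section, row.names = FALSE)
  invisible(x)
}

#' Full vessel-density pipeline for one slide
#'
#' Candidate detection, region growing (or k-means), area filtering and
#' masking for a single section.
#'
#' @param image A [slide_image()].
#' @param params A [segmentation_params()].
#' @param algorithm `"region_growing"` (default) or `"kmeans"`.
#' @param mode,masked Passed to [filter_and_mask()].
#' @return A [filter_and_mask()] result.
#' @export
segment_slide <- function(image, params = segmentation_params(),
                          algorithm = c("region_growing", "kmeans"),
                          mode = "whole", masked = length(image$masks) > 0) {
  algorithm <- match.arg(algorithm)
  labels <- if (algorithm == "region_growing") {
    seeds <- identify_candidate_pixels(image, params)
    region_grow(image, seeds, params)
  } else {
    label_components(kmeans_segment(image, params), params$connectivity)
  }
  filter_and_mask(labels, image, params, mode = mode, masked = masked)
}
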