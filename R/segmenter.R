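#' Estimate the physiological-normal background of a FAF image
#'
#' The grading protocol defines lesions relative to "physiological normal"
#' tissue, whose apparent intensity varies radially because of vignetting.
#' The background model is a low-order radial polynomial (in even powers of
#' the normalized distance from the image center) fit by least squares to
#' the median-filtered image over non-excluded pixels, with an iterative
#' trimming pass so lesion pixels left in the fit do not drag it.
#'
#' @param image A [faf_image()].
#' @param exclude List of [feature_mask()] objects (or binary matrices)
#'   whose union is left out of the fit.
#' @param poly_order Number of even radial terms beyond the constant
#'   (default 2: r^2 and r^4).
#' @param median_size Half-width of the median prefilter window (0 skips).
#' @param trim_iters Robustness iterations dropping pixels with residuals
#'   beyond 2.5 MAD.
#' @param max_fit_px Pixel subsample cap for the least-squares fit.
#' @return A `background_model`: list with `surface` (matrix), `coef`
#'   (constant first), `global_level` (median of non-excluded intensities).
#' @export
estimate_background <- function(image, exclude = list(), poly_order = 2L,
                                median_size = 2L, trim_iters = 2L,
                                max_fit_px = 40000L) {
  stopifnot(inherits(image, "faf_image"))
  px <- image$pixels
  keep <- matrix(TRUE, nrow(px), ncol(px))
  for (m in exclude) keep <- keep & !as_mask_matrix(m)
  if (!any(keep)) stop("estimation error: exclusions cover the whole image",
                       call. = FALSE)
  sm <- if (median_size > 0) {
    EBImage::medianFilter(px, median_size)
  } else px

  h <- nrow(px); w <- ncol(px)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  s2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+") /
    ((h / 2)^2 + (w / 2)^2) / 1  # normalized squared radius (half-diagonal)
  basis <- function(v) {
    out <- matrix(1, length(v), poly_order + 1L)
    for (k in seq_len(poly_order)) out[, k + 1L] <- v^k
    out
  }
  idx <- which(keep)
  if (length(idx) > max_fit_px) {
    idx <- idx[seq(1L, length(idx), length.out = max_fit_px)]
  }
  y <- sm[idx]; xv <- s2[idx]
  for (it in 0:trim_iters) {
    fit <- stats::lm.fit(basis(xv), y)
    if (it == trim_iters) break
    res <- fit$residuals
    mad <- stats::median(abs(res - stats::median(res))) * 1.4826
    if (mad <= 0) break
    ok <- abs(res - stats::median(res)) <= 2.5 * mad
    if (all(ok)) break
    y <- y[ok]; xv <- xv[ok]
  }
  co <- fit$coefficients
  surface <- matrix(basis(as.vector(s2)) %*% co, h, w)
  surface <- pmax(surface, 1e-6)
  structure(list(surface = surface, coef = co,
                 global_level = stats::median(px[keep])),
            class = "background_model")
}

# per-component geometry used by the disc and ring gates
component_stats <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(NULL)
  idx <- which(lab > 0L)
  l <- lab[idx]
  rr <- ((idx - 1L) %% nrow(lab)) + 1L
  cc <- ((idx - 1L) %/% nrow(lab)) + 1L
  area <- tabulate(l, n)
  cx <- rowsum(as.numeric(cc), l)[, 1] / area
  cy <- rowsum(as.numeric(rr), l)[, 1] / area
  vx <- rowsum(as.numeric(cc)^2, l)[, 1] / area - cx^2
  vy <- rowsum(as.numeric(rr)^2, l)[, 1] / area - cy^2
  vxy <- rowsum(as.numeric(cc) * as.numeric(rr), l)[, 1] / area - cx * cy
  tr <- vx + vy; det <- vx * vy - vxy^2
  disc_root <- sqrt(pmax(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc_root; l2 <- pmax(tr / 2 - disc_root, 0)
  axis_ratio <- ifelse(l1 > 0, sqrt(l2 / l1), 1)
  data.frame(label = seq_len(n), area_px = area, cx = cx, cy = cy,
             axis_ratio = axis_ratio)
}

keep_labels <- function(lab, labels) {
  out <- matrix(FALSE, nrow(lab), ncol(lab))
  out[lab %in% labels[labels > 0]] <- TRUE
  out
}

drop_small <- function(m, min_px) {
  if (!any(m) || min_px <= 1) return(m)
  lab <- label_components8(m)
  keep <- which(tabulate(lab[lab > 0L], max(lab)) >= min_px)
  keep_labels(lab, keep)
}

#' Segment the optic disc
#'
#' The disc is the largest dark, approximately elliptical region whose
#' centroid lies in the nasal third of the image (right third for a right
#' eye).  Candidates are pixels darker than `dark_frac` of the local
#' background; after morphological cleaning and hole filling, components
#' are gated on area and elongation.  An empty mask is the no-disc signal
#' used by cohort quality control.
#'
#' @param image A [faf_image()].
#' @param background Optional [estimate_background()] model (computed if
#'   missing).
#' @param dark_frac Darkness threshold relative to the background.
#' @param area_mm2_range Admissible disc area range.
#' @param min_axis_ratio Minimum minor/major axis ratio (rejects elongated
#'   dark structures such as vessel trunks).
#' @return A [feature_mask()] (possibly empty).
#' @export
segment_disc <- function(image, background = NULL, dark_frac = 0.5,
                         area_mm2_range = c(0.8, 8), min_axis_ratio = 0.45) {
  if (is.null(background)) background <- estimate_background(image)
  sm <- EBImage::medianFilter(image$pixels, 2L)
  cand <- sm < background$surface * dark_frac
  if (any(cand)) {
    k <- EBImage::makeBrush(5L, "disc")
    cand <- EBImage::opening(cand * 1, k) > 0
    cand <- EBImage::fillHull(cand * 1) > 0
  }
  if (!any(cand)) return(feature_mask(matrix(FALSE, image$height, image$width), "disc"))
  lab <- label_components8(cand)
  st <- component_stats(lab)
  px_area <- image$mm_per_pixel^2
  nasal_ok <- if (image$laterality == "right") {
    st$cx > 2 * image$width / 3
  } else st$cx < image$width / 3
  ok <- st$area_px * px_area >= area_mm2_range[1] &
    st$area_px * px_area <= area_mm2_range[2] &
    st$axis_ratio >= min_axis_ratio & nasal_ok
  if (!any(ok)) {
    return(feature_mask(matrix(FALSE, image$height, image$width), "disc"))
  }
  best <- st$label[ok][which.max(st$area_px[ok])]
  feature_mask(keep_labels(lab, best), "disc")
}

#' Segment hypo-autofluorescence
#'
#' Implements the protocol's darkness rule: a pixel is hypo-AF when its
#' relative darkness `(background - I) / (background - disc_mean)` is at
#' least `threshold` (default 0.9, i.e. at least 90% as dark as the optic
#' disc).  The disc itself and a peripapillary exclusion zone around it are
#' removed (peripapillary atrophy is not hypo-AF under the protocol), and
#' speckle components below `min_size_px` are dropped.
#'
#' @param image A [faf_image()].
#' @param disc Non-empty disc [feature_mask()]; its mean intensity is the
#'   darkness reference.
#' @param background A [estimate_background()] model (computed if missing).
#' @param threshold Relative-darkness threshold in (0, 1].
#' @param peripapillary_mm Exclusion margin around the disc boundary (mm).
#' @param min_size_px Minimum component size in pixels.
#' @return A [feature_mask()].
#' @export
segment_hypo_af <- function(image, disc, background = NULL, threshold = 0.9,
                            peripapillary_mm = 0.3, min_size_px = 20L) {
  if (!feature_present(disc)) {
    stop("missing reference: empty disc mask", call. = FALSE)
  }
  if (is.null(background)) background <- estimate_background(image, exclude = list(disc))
  sm <- EBImage::medianFilter(image$pixels, 2L)
  disc_mean <- mean(image$pixels[as_mask_matrix(disc)])
  denom <- pmax(background$surface - disc_mean, 1e-6)
  darkness <- (background$surface - sm) / denom
  cand <- darkness >= threshold
  margin_px <- ceiling(peripapillary_mm / image$mm_per_pixel)
  dm <- as_mask_matrix(disc)
  if (margin_px > 0) {
    k <- EBImage::makeBrush(2L * margin_px + 1L, "disc")
    dm <- EBImage::dilate(dm * 1, k) > 0
  }
  cand <- cand & !dm
  feature_mask(drop_small(cand, min_size_px), "hypo_AF")
}

#' Segment hyper-autofluorescence
#'
#' Pixels brighter than the physiological background by a margin `k`
#' (default 0.25, i.e. `I >= background * 1.25`) are hyper-AF candidates.
#' The perimacular ring is excluded per the protocol, small speckle is
#' dropped, and (optionally) fleck-sized components below
#' `fleck_max_mm2` are excluded.
#'
#' @param image A [faf_image()].
#' @param background A [estimate_background()] model (computed if missing).
#' @param ring Ring [feature_mask()] to exclude (may be empty).
#' @param k Relative brightness margin.
#' @param min_size_px Minimum component size (pixels).
#' @param fleck_max_mm2 If non-`NULL`, additionally exclude components
#'   smaller than this area (fleck exclusion).
#' @param close_px Brush size for morphological closing bridging vessel
#'   occlusions (0 disables).
#' @return A [feature_mask()].
#' @export
segment_hyper_af <- function(image, background = NULL, ring = NULL,
                             k = 0.25, min_size_px = 20L,
                             fleck_max_mm2 = NULL, close_px = 5L) {
  if (is.null(background)) background <- estimate_background(image)
  sm <- EBImage::medianFilter(image$pixels, 2L)
  cand <- sm >= background$surface * (1 + k)
  if (any(cand) && close_px > 0) {
    cand <- EBImage::closing(cand * 1, EBImage::makeBrush(close_px, "disc")) > 0
  }
  if (!is.null(ring)) cand <- cand & !as_mask_matrix(ring)
  cand <- drop_small(cand, min_size_px)
  if (!is.null(fleck_max_mm2)) {
    big <- drop_small(cand, ceiling(fleck_max_mm2 / image$mm_per_pixel^2))
    cand <- big
  }
  feature_mask(cand, "hyper_AF")
}

#' Segment the perimacular ring
#'
#' Bright candidates (same brightness rule as hyper-AF) restricted to a
#' macular radius window are bridged across vessel crossings by
#' morphological closing; components subtending less than `min_arc_deg`
#' about the fovea are discarded (compact macular hyper-AF blobs are not
#' ring material).  The surviving candidates form a ring only if their
#' angular coverage about the fovea strictly exceeds 0.5 — the protocol's
#' "more than 50% of a complete circle" rule — otherwise the returned mask
#' is empty.
#'
#' @param image A [faf_image()].
#' @param background A [estimate_background()] model (computed if missing).
#' @param fovea_xy Center for the angular test (defaults to the image's
#'   fovea).
#' @param k Relative brightness margin.
#' @param radius_window_mm Macular window (mm from fovea) for candidates.
#' @param min_arc_deg Minimum angular span of a candidate component.
#' @param min_size_px Minimum component size (pixels).
#' @param close_px Closing brush size bridging vessel crossings.
#' @param n_sectors Sectors for the angular-coverage test.
#' @return A [feature_mask()] plus attributes `coverage` and `is_ring`.
#' @export
segment_ring <- function(image, background = NULL, fovea_xy = NULL,
                         k = 0.25, radius_window_mm = c(0.5, 4),
                         min_arc_deg = 60, min_size_px = 20L,
                         close_px = 7L, n_sectors = 360L) {
  if (is.null(background)) background <- estimate_background(image)
  if (is.null(fovea_xy)) fovea_xy <- image$fovea_xy
  sm <- EBImage::medianFilter(image$pixels, 2L)
  dmap <- distance_from_fovea_map(image)
  cand <- sm >= background$surface * (1 + k) &
    dmap >= radius_window_mm[1] & dmap < radius_window_mm[2]
  empty <- feature_mask(matrix(FALSE, image$height, image$width), "ring")
  if (!any(cand)) {
    attr(empty, "coverage") <- 0; attr(empty, "is_ring") <- FALSE
    return(empty)
  }
  if (close_px > 0) {
    cand <- EBImage::closing(cand * 1, EBImage::makeBrush(close_px, "disc")) > 0
    cand <- cand & dmap >= radius_window_mm[1] & dmap < radius_window_mm[2]
  }
  cand <- drop_small(cand, min_size_px)
  if (any(cand)) {
    lab <- label_components8(cand)
    keep <- integer(0)
    for (l in seq_len(max(lab))) {
      comp <- lab == l
      span <- ring_angular_coverage(comp, fovea_xy, n_sectors)$coverage * 360
      if (span >= min_arc_deg) keep <- c(keep, l)
    }
    cand <- keep_labels(lab, keep)
  }
  if (!any(cand)) {
    attr(empty, "coverage") <- 0; attr(empty, "is_ring") <- FALSE
    return(empty)
  }
  cov <- ring_angular_coverage(cand, fovea_xy, n_sectors)
  if (!cov$is_ring) {
    attr(empty, "coverage") <- cov$coverage; attr(empty, "is_ring") <- FALSE
    return(empty)
  }
  out <- feature_mask(cand, "ring")
  attr(out, "coverage") <- cov$coverage; attr(out, "is_ring") <- TRUE
  out
}

#' Segment retinal vessels
#'
#' Vessels are dark, thin, tubular structures stemming from the optic disc.
#' A multi-scale black top-hat (grayscale closing minus image, over a range
#' of disc-shaped structuring elements spanning vessel calibers) gives a
#' tubularity response that is thresholded relative to the local background;
#' candidate components not connected to the disc region within a gap
#' tolerance are dropped.
#'
#' @param image A [faf_image()].
#' @param disc Disc [feature_mask()] anchoring the connectivity rule; if
#'   empty, no connectivity filtering is applied.
#' @param background A [estimate_background()] model (computed if missing).
#' @param scales_px Structuring-element diameters (px) spanning vessel
#'   calibers.
#' @param response_frac Threshold on the top-hat response as a fraction of
#'   the local background.
#' @param gap_px Gap tolerance (px) for connectivity to the disc.
#' @param min_size_px Minimum component size after connectivity filtering.
#' @return A [feature_mask()].
#' @export
segment_vessels <- function(image, disc = NULL, background = NULL,
                            scales_px = c(5L, 9L, 13L), response_frac = 0.2,
                            gap_px = 6L, min_size_px = 30L) {
  if (is.null(background)) background <- estimate_background(image)
  sm <- EBImage::medianFilter(image$pixels, 1L)
  resp <- matrix(0, image$height, image$width)
  for (s in scales_px) {
    k <- EBImage::makeBrush(s, "disc")
    bt <- EBImage::closing(sm, k) - sm
    resp <- pmax(resp, bt)
  }
  cand <- resp >= background$surface * response_frac
  if (!any(cand)) return(feature_mask(cand, "vessels"))
  if (!is.null(disc) && feature_present(disc)) {
    grown <- EBImage::dilate(as_mask_matrix(disc) * 1,
                             EBImage::makeBrush(2L * gap_px + 1L, "disc")) > 0
    bridged <- EBImage::dilate(cand * 1,
                               EBImage::makeBrush(2L * gap_px + 1L, "disc")) > 0
    lab <- label_components8(bridged | grown)
    disc_labels <- unique(lab[grown & lab > 0L])
    cand <- cand & matrix(lab %in% disc_labels, nrow(lab), ncol(lab))
  }
  feature_mask(drop_small(cand, min_size_px), "vessels")
}

#' Run the full rule-based segmentation protocol on one image
#'
#' Orchestrates the per-feature segmenters in dependency order: background
#' estimate, disc, vessels, background re-estimate excluding disc and
#' vessels, ring, hyper-AF (ring excluded), hypo-AF (disc-referenced).
#' When no disc is found, hypo-AF (which needs the disc as its darkness
#' reference) and the vessel connectivity rule are skipped and those masks
#' are returned empty — the image would be discarded by cohort QC anyway.
#'
#' @param image A [faf_image()].
#' @param params Optional named list overriding per-feature parameters:
#'   sub-lists `disc`, `hypo`, `hyper`, `ring`, `vessels` are passed as
#'   extra arguments to the respective `segment_*` function.
#' @return Named list of five [feature_mask()] objects.
#' @export
segment_features <- function(image, params = list()) {
  bg0 <- estimate_background(image)
  disc <- do.call(segment_disc,
                  c(list(image = image, background = bg0), params$disc))
  vessels <- do.call(segment_vessels,
                     c(list(image = image, disc = disc, background = bg0),
                       params$vessels))
  excl <- list(disc, vessels)
  bg <- estimate_background(image, exclude = excl)
  ring <- do.call(segment_ring,
                  c(list(image = image, background = bg), params$ring))
  hyper <- do.call(segment_hyper_af,
                   c(list(image = image, background = bg, ring = ring),
                     params$hyper))
  hypo <- if (feature_present(disc)) {
    do.call(segment_hypo_af,
            c(list(image = image, disc = disc, background = bg),
              params$hypo))
  } else feature_mask(matrix(FALSE, image$height, image$width), "hypo_AF")
  list(disc = disc, hypo_AF = hypo, hyper_AF = hyper, ring = ring,
       vessels = vessels)
}
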