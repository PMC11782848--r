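#' Per-pixel distance from the fovea
#'
#' Euclidean distance from each pixel center to the fovea, in millimetres.
#' This map underpins the annulus profiles and fixed-radius foveal areas.
#'
#' @param image A [faf_image()].
#' @return Numeric matrix of distances (mm), same dimensions as the image;
#'   zero at the fovea pixel.
#' @export
distance_from_fovea_map <- function(image) {
  stopifnot(inherits(image, "faf_image"))
  dx <- (seq_len(image$width) - image$fovea_xy[1])
  dy <- (seq_len(image$height) - image$fovea_xy[2])
  # outer sum of squared offsets: rows are y, cols are x
  d2 <- outer(dy^2, dx^2, "+")
  sqrt(d2) * image$mm_per_pixel
}

#' Annulus profile of a feature about the fovea
#'
#' Distributes a feature's area over concentric 0.5 mm annuli centred on the
#' fovea: bin k collects feature pixels at distance `[k*w, (k+1)*w)` mm, and
#' each bin's proportion is its area divided by the total feature area.  The
#' binning is a partition (half-open intervals, last bin extended to the
#' image's maximal fovea distance) so no pixel is counted twice.
#'
#' @param mask A [feature_mask()] aligned to `image`.
#' @param image A [faf_image()].
#' @param bin_width_mm Annulus width in mm (default 0.5).
#' @return A list of class `annulus_profile` with `bin_edges` (mm),
#'   `proportions`, `area_mm2` per bin and `total_area_mm2`.  An empty mask
#'   yields all-zero proportions and `total_area_mm2 = 0`.
#' @export
annulus_profile <- function(mask, image, bin_width_mm = 0.5) {
  stopifnot(inherits(image, "faf_image"), bin_width_mm > 0)
  m <- as_mask_matrix(mask)
  if (!identical(dim(m), dim(image$pixels))) {
    stop("alignment error: mask and image dimensions differ", call. = FALSE)
  }
  dmap <- distance_from_fovea_map(image)
  dmax <- max(dmap)
  n_bins <- max(1L, ceiling(dmax / bin_width_mm))
  edges <- seq(0, by = bin_width_mm, length.out = n_bins + 1L)
  px_area <- image$mm_per_pixel^2
  idx <- pmin(floor(dmap[m] / bin_width_mm), n_bins - 1L) + 1L
  counts <- tabulate(idx, nbins = n_bins)
  areas <- counts * px_area
  total <- sum(areas)
  props <- if (total > 0) areas / total else rep(0, n_bins)
  structure(list(bin_edges = edges, proportions = props,
                 area_mm2 = areas, total_area_mm2 = total),
            class = "annulus_profile")
}

#' Feature area within a fixed radius of the fovea
#'
#' Area (mm^2) of feature pixels strictly closer to the fovea than
#' `radius_mm`.  The 1.5 mm radius corresponds to the inner 3 mm ETDRS ring
#' used for foveal hyper-autofluorescence burden; multiply by 1e6 for
#' micrometre-squared reporting.
#'
#' @inheritParams annulus_profile
#' @param radius_mm Positive radius in mm.
#' @return Area in mm^2.
#' @export
area_within_radius <- function(mask, image, radius_mm) {
  if (!is.numeric(radius_mm) || length(radius_mm) != 1L || radius_mm <= 0) {
    stop("radius_mm must be a single positive number", call. = FALSE)
  }
  m <- as_mask_matrix(mask)
  if (!identical(dim(m), dim(image$pixels))) {
    stop("alignment error: mask and image dimensions differ", call. = FALSE)
  }
  dmap <- distance_from_fovea_map(image)
  sum(m & (dmap < radius_mm)) * image$mm_per_pixel^2
}

#' Angular completeness of a candidate ring
#'
#' Bins the angular positions of mask pixels about a center into equal
#' sectors (default 360 one-degree sectors) and reports the fraction of
#' sectors occupied.  Following the grading protocol's requirement that a
#' perimacular ring be more than 50% of a complete circle, `is_ring` uses a
#' strict inequality: coverage of exactly 0.5 is not a ring.
#'
#' @param mask A [feature_mask()] or binary matrix; must be non-empty.
#' @param center_xy Pixel coordinate `c(x, y)` about which angles are taken.
#' @param n_sectors Number of equal angular sectors (default 360).
#' @return List with `coverage` in `[0, 1]`, `is_ring`, and
#'   `occupied_sectors`.
#' @export
ring_angular_coverage <- function(mask, center_xy, n_sectors = 360L) {
  m <- as_mask_matrix(mask)
  if (!any(m)) stop("undefined coverage: empty mask", call. = FALSE)
  stopifnot(n_sectors >= 1L)
  idx <- which(m, arr.ind = TRUE)
  ang <- atan2(idx[, "row"] - center_xy[2], idx[, "col"] - center_xy[1])
  ang <- (ang + 2 * pi) %% (2 * pi)
  sector <- pmin(floor(ang / (2 * pi / n_sectors)), n_sectors - 1L) + 1L
  occ <- length(unique(sector))
  cov <- occ / n_sectors
  list(coverage = cov, is_ring = cov > 0.5, occupied_sectors = occ)
}

#' Write annulus profiles as a delimited table
#'
#' @param profiles Named list of `annulus_profile` objects (names are
#'   feature labels).
#' @param path Output CSV path.
#' @return The table, invisibly (columns: feature, bin_start_mm, bin_end_mm,
#'   proportion, area_mm2).
#' @export
write_annulus_profiles <- function(profiles, path) {
  rows <- lapply(names(profiles), function(f) {
    p <- profiles[[f]]
    tibble::tibble(
      feature = f,
      bin_start_mm = head(p$bin_edges, -1L),
      bin_end_mm = tail(p$bin_edges, -1L),
      proportion = p$proportions,
      area_mm2 = p$area_mm2
    )
  })
  out <- dplyr::bind_rows(rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
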