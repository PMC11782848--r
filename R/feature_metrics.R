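#' Is a feature present on an image?
#'
#' Presence is the weakest possible detection call: a feature counts as
#' present when the mask marks at least some part of the image.
#'
#' @param mask A [feature_mask()] or binary matrix.
#' @return `TRUE` iff at least one pixel is set.
#' @export
feature_present <- function(mask) {
  any(as_mask_matrix(mask))
}

#' Physical area of a feature mask
#'
#' Area is the number of set pixels multiplied by the pixel area
#' (`mm_per_pixel^2`), yielding mm^2.
#'
#' @param mask A [feature_mask()] or binary matrix.
#' @param mm_per_pixel Isotropic scale in mm per pixel (> 0).
#' @return Area in mm^2.
#' @export
feature_area <- function(mask, mm_per_pixel) {
  if (!is.numeric(mm_per_pixel) || length(mm_per_pixel) != 1L ||
      mm_per_pixel <= 0) {
    stop("mm_per_pixel must be a single positive number", call. = FALSE)
  }
  sum(as_mask_matrix(mask)) * mm_per_pixel^2
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels touching
# only diagonally are merged with a union-find pass over the two diagonal
# shift directions.
label_components8 <- function(m) {
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(round(lab)), nrow = nrow(m))
  n <- max(lab)
  if (n <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-1, -w]), as.vector(lab[-h, -1]))   # up-right
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs) > 0L) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

#' Count connected components of a mask
#'
#' Counts 8-connected components.  With `split_touching = TRUE`, touching
#' blobs are further separated by a watershed on the distance transform
#' (markers at the local maxima of the distance map; `marker_tolerance`
#' controls the minimum depth, in pixels, separating two markers).
#'
#' @param mask A [feature_mask()] or binary matrix.
#' @param split_touching Split merged blobs by watershed (default `FALSE`;
#'   the plain 8-connected count is the reference behaviour).
#' @param marker_tolerance Watershed marker depth tolerance in pixels.
#' @return Non-negative integer component count; 0 iff the mask is empty.
#' @export
count_components <- function(mask, split_touching = FALSE,
                             marker_tolerance = 1) {
  m <- as_mask_matrix(mask)
  if (!any(m)) return(0L)
  if (!split_touching) {
    return(max(label_components8(m)))
  }
  dm <- EBImage::distmap(EBImage::Image(m * 1))
  ws <- EBImage::watershed(dm, tolerance = marker_tolerance)
  length(setdiff(unique(as.integer(EBImage::imageData(ws))), 0L))
}

#' Mean brightness under a mask
#'
#' Arithmetic mean of the image intensities over the masked region, on the
#' raw normalized `[0, 1]` scale (no vignetting correction).
#'
#' @param image A [faf_image()].
#' @param mask A non-empty [feature_mask()] aligned to `image`.
#' @return Mean intensity in `[0, 1]`.
#' @export
mean_brightness <- function(image, mask) {
  m <- as_mask_matrix(mask)
  if (!identical(dim(m), dim(image$pixels))) {
    stop("alignment error: mask and image dimensions differ", call. = FALSE)
  }
  if (!any(m)) {
    stop("undefined brightness: empty mask", call. = FALSE)
  }
  mean(image$pixels[m])
}

#' Vessel density of a vessel mask
#'
#' Ratio between the vessel area and the total image area: set pixels over
#' total pixels.
#'
#' @param mask A [feature_mask()] with `feature == "vessels"`.
#' @return Fraction in `[0, 1]`.
#' @export
vessel_density <- function(mask) {
  if (inherits(mask, "feature_mask") && mask$feature != "vessels") {
    stop("feature mismatch: vessel_density requires a vessels mask",
         call. = FALSE)
  }
  m <- as_mask_matrix(mask)
  sum(m) / length(m)
}

#' Quantify all features on one image
#'
#' Assembles the per-feature morphometric record: presence, area (mm^2),
#' 8-connected component count, mean brightness, and (vessels only) vessel
#' density.  Features with no supplied mask are reported absent with zero
#' area.
#'
#' @param image A [faf_image()].
#' @param masks List of [feature_mask()] objects, at most one per feature.
#' @param split_touching Passed to [count_components()].
#' @return A tibble with one row per feature: `feature`, `present`,
#'   `area_mm2`, `n_components`, `mean_brightness`, `vessel_density`.
#' @export
quantify <- function(image, masks = list(), split_touching = FALSE) {
  feats <- vapply(masks, function(m) m$feature, character(1))
  if (anyDuplicated(feats)) {
    stop("input error: duplicate masks for one feature", call. = FALSE)
  }
  for (m in masks) check_aligned(m, image)
  names(masks) <- feats
  rows <- lapply(FAF_FEATURES, function(f) {
    m <- masks[[f]]
    if (is.null(m) || !feature_present(m)) {
      return(tibble::tibble(
        feature = f, present = FALSE, area_mm2 = 0, n_components = 0L,
        mean_brightness = NA_real_, vessel_density = if (f == "vessels") 0 else NA_real_))
    }
    tibble::tibble(
      feature = f, present = TRUE,
      area_mm2 = feature_area(m, image$mm_per_pixel),
      n_components = as.integer(count_components(m, split_touching)),
      mean_brightness = mean_brightness(image, m),
      vessel_density = if (f == "vessels") vessel_density(m) else NA_real_)
  })
  dplyr::bind_rows(rows)
}
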