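#' @importFrom stats coef lm median pnorm pt quantile rnorm runif sd setNames
#' @importFrom utils head tail
NULL

FAF_FEATURES <- c("disc", "hypo_AF", "hyper_AF", "ring", "vessels")

#' Calibrated fundus autofluorescence image
#'
#' Constructs a `faf_image`: a grayscale 55-degree macula-centered FAF
#' acquisition with the physical calibration and metadata every downstream
#' computation needs.  Pixel intensities are stored as a numeric matrix in
#' `[0, 1]`, indexed `[row, col]`; pixel coordinates are 1-based `(x, y)` =
#' `(col, row)` with the pixel center at the integer coordinate.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`.
#' @param mm_per_pixel Isotropic physical scale in mm per pixel (> 0).
#' @param fovea_xy Pixel coordinate `c(x, y)` of the fovea center.  Defaults
#'   to the image center, appropriate for macula-centered scans.
#' @param laterality `"left"` or `"right"` eye.
#' @param acquisition_date Acquisition [Date] (or string coercible to one).
#' @param patient_id,eye_id Opaque identifiers.
#'
#' @return An object of class `faf_image`.
#' @export
faf_image <- function(pixels, mm_per_pixel,
                      fovea_xy = NULL,
                      laterality = c("right", "left"),
                      acquisition_date = as.Date("2010-01-01"),
                      patient_id = "P0", eye_id = "E0") {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!is.numeric(mm_per_pixel) || length(mm_per_pixel) != 1L ||
      !is.finite(mm_per_pixel) || mm_per_pixel <= 0) {
    stop("mm_per_pixel must be a single positive number", call. = FALSE)
  }
  rng <- range(pixels)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    stop("pixel intensities must lie in [0, 1]", call. = FALSE)
  }
  h <- nrow(pixels); w <- ncol(pixels)
  if (is.null(fovea_xy)) fovea_xy <- c((w + 1) / 2, (h + 1) / 2)
  fovea_xy <- as.numeric(fovea_xy)
  if (length(fovea_xy) != 2L || fovea_xy[1] < 1 || fovea_xy[1] > w ||
      fovea_xy[2] < 1 || fovea_xy[2] > h) {
    stop("invalid geometry: fovea_xy outside image bounds", call. = FALSE)
  }
  laterality <- match.arg(laterality)
  structure(list(
    pixels = pixels, height = h, width = w,
    mm_per_pixel = mm_per_pixel, fovea_xy = fovea_xy,
    laterality = laterality,
    acquisition_date = as.Date(acquisition_date),
    patient_id = patient_id, eye_id = eye_id
  ), class = "faf_image")
}

#' @export
print.faf_image <- function(x, ...) {
  cat(sprintf(
    "<faf_image> %dx%d px @ %.4f mm/px (%.1f mm field), %s eye, fovea (%.1f, %.1f)\n",
    x$width, x$height, x$mm_per_pixel, x$width * x$mm_per_pixel,
    x$laterality, x$fovea_xy[1], x$fovea_xy[2]))
  invisible(x)
}

#' Binary feature mask aligned to a FAF image
#'
#' @param pixels Logical or 0/1 matrix, same dimensions as its image.
#' @param feature One of `"disc"`, `"hypo_AF"`, `"hyper_AF"`, `"ring"`,
#'   `"vessels"`.
#' @param image_ref Identifier of the image the mask aligns to.
#'
#' @return An object of class `feature_mask`; `pixels` is stored as a
#'   logical matrix.
#' @export
feature_mask <- function(pixels, feature, image_ref = NA_character_) {
  stopifnot(is.matrix(pixels))
  feature <- match.arg(feature, FAF_FEATURES)
  if (is.numeric(pixels)) {
    if (!all(pixels %in% c(0, 1))) {
      stop("mask must be strictly binary", call. = FALSE)
    }
    pixels <- pixels != 0
  }
  stopifnot(is.logical(pixels))
  pixels[is.na(pixels)] <- FALSE
  structure(list(pixels = pixels, feature = feature, image_ref = image_ref),
            class = "feature_mask")
}

#' @export
print.feature_mask <- function(x, ...) {
  cat(sprintf("<feature_mask> %s: %d / %d px set\n", x$feature,
              sum(x$pixels), length(x$pixels)))
  invisible(x)
}

# mask/image alignment guard shared by all binary-mask operations
check_aligned <- function(mask, image) {
  if (!identical(dim(mask$pixels), dim(image$pixels))) {
    stop("alignment error: mask and image dimensions differ", call. = FALSE)
  }
  invisible(TRUE)
}

as_mask_matrix <- function(mask) {
  if (inherits(mask, "feature_mask")) mask$pixels else mask != 0
}
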