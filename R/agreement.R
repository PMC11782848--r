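#' Dice similarity coefficient between two masks
#'
#' Twice the overlap area divided by the total area of the two masks:
#' `2|A n B| / (|A| + |B|)`; 1 for perfect overlap, 0 for none.  When both
#' masks are empty the score is 1 by convention and the attribute
#' `both_empty` is set so aggregates can exclude such pairs (segmentation
#' summaries are conventionally computed only over images where the feature
#' was gradable).
#'
#' @param mask_a,mask_b Aligned [feature_mask()] objects or binary matrices.
#' @return Dice score in `[0, 1]` with attribute `both_empty`.
#' @export
dice <- function(mask_a, mask_b) {
  a <- as_mask_matrix(mask_a); b <- as_mask_matrix(mask_b)
  if (!identical(dim(a), dim(b))) {
    stop("alignment error: mask dimensions differ", call. = FALSE)
  }
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) {
    return(structure(1, both_empty = TRUE))
  }
  structure(2 * sum(a & b) / (sa + sb), both_empty = FALSE)
}

#' Mean Dice of a candidate against multiple reference gradings
#'
#' For double-graded images the candidate is scored against each grading and
#' the unweighted mean is reported.
#'
#' @param candidate A [feature_mask()] or binary matrix.
#' @param references Non-empty list of reference masks.
#' @return Mean Dice score.
#' @export
mean_reference_dice <- function(candidate, references) {
  if (!is.list(references) || length(references) == 0L) {
    stop("input error: at least one reference mask required", call. = FALSE)
  }
  mean(vapply(references, function(r) as.numeric(dice(candidate, r)),
              numeric(1)))
}

#' Tally image-level presence agreement
#'
#' Builds the 2x2 detection confusion counts from paired presence calls,
#' with the first element of each pair (the grader) as ground truth and the
#' second (the model) as prediction.
#'
#' @param reference Logical vector of ground-truth presence per image.
#' @param candidate Logical vector of predicted presence, same length.
#' @return A `detection_tally`: list with integer `tp`, `fp`, `fn`, `tn`.
#' @export
detection_tally <- function(reference, candidate) {
  stopifnot(length(reference) == length(candidate))
  reference <- as.logical(reference); candidate <- as.logical(candidate)
  structure(list(
    tp = sum(reference & candidate),
    fp = sum(!reference & candidate),
    fn = sum(reference & !candidate),
    tn = sum(!reference & !candidate)
  ), class = "detection_tally")
}

#' Accuracy, precision and recall from a detection tally
#'
#' `accuracy = (tp + tn) / total`, `precision = tp / (tp + fp)`,
#' `recall = tp / (tp + fn)`.  Precision or recall with a zero denominator
#' is reported as `NaN`, not 0.
#'
#' @param tally A `detection_tally` (from [detection_tally()]) or a list
#'   with fields `tp`, `fp`, `fn`, `tn`.
#' @return List with `accuracy`, `precision`, `recall`.
#' @export
detection_metrics <- function(tally) {
  tp <- tally$tp; fp <- tally$fp; fn <- tally$fn; tn <- tally$tn
  total <- tp + fp + fn + tn
  if (total == 0) stop("input error: empty tally", call. = FALSE)
  list(
    accuracy = (tp + tn) / total,
    precision = if (tp + fp > 0) tp / (tp + fp) else NaN,
    recall = if (tp + fn > 0) tp / (tp + fn) else NaN
  )
}

#' Per-feature validation report between two grading sources
#'
#' Compares candidate (model) masks against reference (grader) masks for a
#' set of images and summarizes, per feature: number of images, incidence
#' (fraction of images where the reference marks the feature), mean Dice
#' over gradable pairs, and presence/absence accuracy, precision, recall.
#'
#' @param reference,candidate Named lists (per image) of lists of
#'   [feature_mask()] objects keyed by feature; the two lists must cover the
#'   same image ids.
#' @param exclude_both_empty Exclude both-empty pairs from the Dice mean
#'   (default `TRUE`; such pairs carry no segmentation information).
#' @return A tibble with one row per feature: `feature`, `n_images`,
#'   `incidence`, `mean_dice`, `accuracy`, `precision`, `recall`.
#' @export
validation_report <- function(reference, candidate,
                              exclude_both_empty = TRUE) {
  ids <- names(reference)
  stopifnot(setequal(ids, names(candidate)))
  rows <- lapply(FAF_FEATURES, function(f) {
    dices <- numeric(0); ref_p <- logical(0); cand_p <- logical(0)
    for (id in ids) {
      rm <- reference[[id]][[f]]; cm <- candidate[[id]][[f]]
      if (is.null(rm) && is.null(cm)) next
      ref_set <- !is.null(rm) && feature_present(rm)
      cand_set <- !is.null(cm) && feature_present(cm)
      ref_p <- c(ref_p, ref_set); cand_p <- c(cand_p, cand_set)
      if (!is.null(rm) && !is.null(cm)) {
        d <- dice(cm, rm)
        if (!(exclude_both_empty && isTRUE(attr(d, "both_empty")))) {
          dices <- c(dices, as.numeric(d))
        }
      }
    }
    n <- length(ref_p)
    if (n == 0L) return(NULL)
    met <- detection_metrics(detection_tally(ref_p, cand_p))
    tibble::tibble(
      feature = f, n_images = n, incidence = mean(ref_p),
      mean_dice = if (length(dices)) mean(dices) else NA_real_,
      accuracy = met$accuracy, precision = met$precision,
      recall = met$recall)
  })
  dplyr::bind_rows(rows)
}
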