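#' Write a feature mask as a binary PNG
#'
#' Masks are stored one file per feature as 8-bit PNG with 0 background and
#' 255 feature, conventionally named `<image_id>_<feature>.png`.
#'
#' @param mask A [feature_mask()] or binary matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  m <- as_mask_matrix(mask)
  png::writePNG(m * 1, path)
  invisible(path)
}

#' Read a binary feature mask from PNG
#'
#' Any nonzero pixel is treated as set; multi-channel rasters are reduced
#' by their first channel.
#'
#' @param path PNG path.
#' @param feature Feature label for the resulting mask.
#' @return A [feature_mask()].
#' @export
read_mask_png <- function(path, feature) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  feature_mask(m > 0, feature)
}

#' Write a FAF image as grayscale PNG
#'
#' @param image A [faf_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_faf_png <- function(image, path) {
  png::writePNG(pmin(pmax(image$pixels, 0), 1), path)
  invisible(path)
}

# read a grayscale raster (PNG or TIFF) normalized to [0, 1] by the
# maximum of its integer dtype (8- or 16-bit), averaging channels if needed
read_raster <- function(path) {
  lower <- tolower(path)
  m <- if (grepl("\\.png$", lower)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", lower)) {
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  if (length(dim(m)) == 3L) m <- apply(m, c(1, 2), mean)
  m
}

#' Read a calibrated FAF image from disk
#'
#' @param path PNG or TIFF path (8- or 16-bit grayscale; intensities are
#'   normalized to `[0, 1]` by the dtype maximum).
#' @param mm_per_pixel Physical scale (required).
#' @param ... Further metadata passed to [faf_image()].
#' @return A [faf_image()].
#' @export
read_faf_image <- function(path, mm_per_pixel, ...) {
  faf_image(read_raster(path), mm_per_pixel, ...)
}

#' Load a dataset from a manifest
#'
#' The manifest is a CSV with one row per image: `image_path`,
#' `patient_id`, `eye_id`, `date` (ISO-8601), `order_in_day`, `age`,
#' `gene`, `mm_per_pixel`, optional `laterality`, `fovea_x`/`fovea_y`
#' override, optional per-feature mask path columns `mask_disc`,
#' `mask_hypo_AF`, `mask_hyper_AF`, `mask_ring`, `mask_vessels`, and
#' optional variant columns.  Paths are resolved relative to the manifest.
#' Invalid rows (missing file, missing scale, shape-mismatched mask,
#' unparseable date) are rejected with a per-row report; in strict mode any
#' invalid row aborts the load.
#'
#' @param manifest_path Manifest CSV path.
#' @param strict Abort on the first invalid row (default `FALSE`).
#' @return List with `records` (per-image list of `image`, `masks`, `meta`),
#'   `errors` (tibble: row, message), and `manifest` (the parsed table).
#' @export
load_dataset <- function(manifest_path, strict = FALSE) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(normalizePath(manifest_path))
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  records <- list()
  errors <- list()
  reject <- function(i, msg) {
    if (strict) stop(sprintf("row %d: %s", i, msg), call. = FALSE)
    errors[[length(errors) + 1L]] <<- tibble::tibble(row = i, message = msg)
  }
  mask_cols <- intersect(paste0("mask_", FAF_FEATURES), names(man))
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    if (is.null(row$mm_per_pixel) || is.na(row$mm_per_pixel) ||
        row$mm_per_pixel <= 0) { reject(i, "missing or invalid mm_per_pixel"); next }
    date <- tryCatch(as.Date(row$date), error = function(e) NA)
    if (is.na(date)) { reject(i, "unparseable date"); next }
    ipath <- resolve(row$image_path)
    if (!file.exists(ipath)) { reject(i, paste("missing file:", row$image_path)); next }
    fovea <- if (!is.null(row$fovea_x) && !is.na(row$fovea_x)) {
      c(row$fovea_x, row$fovea_y)
    } else NULL
    img <- tryCatch(
      faf_image(read_raster(ipath), row$mm_per_pixel, fovea_xy = fovea,
                laterality = if (!is.null(row$laterality) && !is.na(row$laterality)) row$laterality else "right",
                acquisition_date = date,
                patient_id = as.character(row$patient_id),
                eye_id = as.character(row$eye_id)),
      error = function(e) conditionMessage(e))
    if (is.character(img)) { reject(i, img); next }
    masks <- list()
    bad <- FALSE
    for (mc in mask_cols) {
      if (is.na(row[[mc]]) || !nzchar(row[[mc]])) next
      f <- sub("^mask_", "", mc)
      mpath <- resolve(row[[mc]])
      if (!file.exists(mpath)) { reject(i, paste("missing file:", row[[mc]])); bad <- TRUE; break }
      mk <- read_mask_png(mpath, f)
      if (!identical(dim(mk$pixels), dim(img$pixels))) {
        reject(i, paste("shape mismatch:", row[[mc]])); bad <- TRUE; break
      }
      masks[[f]] <- mk
    }
    if (bad) next
    records[[length(records) + 1L]] <- list(image = img, masks = masks,
                                            meta = row)
  }
  list(records = records,
       errors = if (length(errors)) dplyr::bind_rows(errors)
                else tibble::tibble(row = integer(0), message = character(0)),
       manifest = tibble::as_tibble(man))
}

log_stage <- function(lines, stage, n_in, n_out, t0) {
  line <- sprintf("stage=%s in=%d out=%d elapsed_s=%.2f", stage, n_in, n_out,
                  as.numeric(Sys.time()) - t0)
  message(line)
  c(lines, line)
}

#' Run the full analysis pipeline
#'
#' Composes the method end to end: ingest (a synthetic cohort or a manifest
#' of images and masks), optional rule-based segmentation, per-image
#' quantification, quality-control filtering, per-day deduplication,
#' first-presentation aggregation by gene, and per-eye progression.  Every
#' stage logs its input and output counts; output is deterministic for a
#' fixed config and seed.
#'
#' @param config Named list or YAML path.  Keys: `seed`; either
#'   `cohort_spec` (data frame or CSV path for [generate_cohort()], with
#'   optional `p_missing_disc`, `p_extra_scan`) or `manifest` (path for
#'   [load_dataset()]); `segment` (logical: run [segment_features()] on
#'   images lacking masks); `qc` (default `TRUE`); `progression_features`
#'   (default `c("ring", "hypo_AF")`); `strict`.
#' @param out_dir Output directory for result tables and the log.
#' @return List with `visits`, `per_gene` (per feature), `slopes`,
#'   `log`; tables are also written as CSV under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  t0 <- as.numeric(Sys.time())
  lines <- character(0)

  if (!is.null(config$cohort_spec)) {
    spec <- config$cohort_spec
    if (is.character(spec)) spec <- utils::read.csv(spec, stringsAsFactors = FALSE)
    visits <- generate_cohort(
      spec, seed = seed,
      p_missing_disc = if (is.null(config$p_missing_disc)) 0 else config$p_missing_disc,
      p_extra_scan = if (is.null(config$p_extra_scan)) 0 else config$p_extra_scan)
    lines <- log_stage(lines, "generate_cohort", nrow(spec), nrow(visits), t0)
  } else if (!is.null(config$manifest)) {
    ds <- load_dataset(config$manifest, strict = isTRUE(config$strict))
    lines <- log_stage(lines, "load_dataset", nrow(ds$manifest),
                       length(ds$records), t0)
    rows <- lapply(ds$records, function(rec) {
      masks <- rec$masks
      if (isTRUE(config$segment) && length(masks) == 0L) {
        masks <- segment_features(rec$image)
      }
      q <- quantify(rec$image, unname(masks))
      q$patient_id <- as.character(rec$meta$patient_id)
      q$eye_id <- as.character(rec$meta$eye_id)
      q$date <- as.Date(rec$meta$date)
      q$order_in_day <- if (!is.null(rec$meta$order_in_day)) rec$meta$order_in_day else 1L
      q$age <- if (!is.null(rec$meta$age)) rec$meta$age else NA_real_
      q$gene <- if (!is.null(rec$meta$gene)) rec$meta$gene else NA_character_
      q
    })
    visits <- dplyr::bind_rows(rows)
    lines <- log_stage(lines, "quantify", length(ds$records), nrow(visits), t0)
  } else {
    stop("config must provide cohort_spec or manifest", call. = FALSE)
  }

  if (!identical(config$qc, FALSE)) {
    n_in <- nrow(visits)
    visits <- qc_filter(visits)
    lines <- log_stage(lines, "qc_filter", n_in, nrow(visits), t0)
  }
  n_in <- nrow(visits)
  visits <- dedup_daily(visits)
  lines <- log_stage(lines, "dedup_daily", n_in, nrow(visits), t0)

  fp <- first_presentation(visits)
  lines <- log_stage(lines, "first_presentation", nrow(visits), nrow(fp), t0)
  feats <- setdiff(unique(fp$feature), "disc")
  per_gene <- dplyr::bind_rows(lapply(feats, function(f) {
    tb <- aggregate_by_gene(fp, f)
    tb$feature <- f
    tb
  }))
  names(per_gene)[names(per_gene) == "mean"] <- "mean_area_mm2"
  names(per_gene)[names(per_gene) == "sd"] <- "sd_area_mm2"
  names(per_gene)[names(per_gene) == "se"] <- "se_area_mm2"
  lines <- log_stage(lines, "aggregate_by_gene", nrow(fp), nrow(per_gene), t0)

  prog_feats <- if (is.null(config$progression_features)) {
    intersect(c("ring", "hypo_AF"), feats)
  } else config$progression_features
  slopes <- dplyr::bind_rows(lapply(prog_feats, function(f) {
    pr <- progression_rate(visits, f)
    if (nrow(pr$per_patient) == 0L) return(NULL)
    out <- pr$per_patient
    names(out)[names(out) == "patient_slope"] <- "slope_mm2_per_year"
    out$feature <- f
    out
  }))
  lines <- log_stage(lines, "progression", nrow(visits),
                     if (is.null(slopes)) 0L else nrow(slopes), t0)

  out <- list(visits = visits, per_gene = per_gene, slopes = slopes,
              log = lines)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(visits, file.path(out_dir, "visits.csv"), row.names = FALSE)
    utils::write.csv(per_gene, file.path(out_dir, "per_gene.csv"), row.names = FALSE)
    if (!is.null(slopes) && nrow(slopes)) {
      utils::write.csv(slopes, file.path(out_dir, "slopes.csv"), row.names = FALSE)
    }
    writeLines(lines, file.path(out_dir, "log.txt"))
  }
  out
}
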