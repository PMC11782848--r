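#' @importFrom rlang .data
NULL

# scan key shared by QC and dedup
scan_key <- function(visits) {
  paste(visits$patient_id, visits$eye_id, visits$date, visits$order_in_day,
        sep = "\r")
}

#' Quality-control filter: drop scans with no detected optic disc
#'
#' A missing optic disc marks a poor-quality or non-macula-centered
#' acquisition; all rows of such scans are removed.  The number of scans
#' in and out is attached as attribute `qc_counts`.
#'
#' @param visits Long visit table: one row per scan and feature, with
#'   columns `patient_id`, `eye_id`, `date`, `order_in_day`, `feature`,
#'   `present` (and any metadata).
#' @return The retained rows, order preserved.
#' @export
qc_filter <- function(visits) {
  keys <- scan_key(visits)
  disc_rows <- visits$feature == "disc"
  ok_keys <- unique(keys[disc_rows & visits$present])
  out <- visits[keys %in% ok_keys, , drop = FALSE]
  attr(out, "qc_counts") <- c(scans_in = length(unique(keys)),
                              scans_out = length(ok_keys))
  out
}

#' Keep one scan per eye per date
#'
#' When an eye has several scans on one date, the most recent (highest
#' `order_in_day`) is kept — later scans imply the operator re-imaged after
#' a poor acquisition.
#'
#' @param visits Long visit table (see [qc_filter()]).
#' @return Deduplicated rows, original order preserved.  Errors if two rows
#'   share an `(eye, date, order, feature)` quadruple.
#' @export
dedup_daily <- function(visits) {
  quad <- paste(visits$eye_id, visits$date, visits$order_in_day,
                visits$feature, sep = "\r")
  if (anyDuplicated(quad)) {
    stop("ambiguity error: duplicate (eye, date, order) scans", call. = FALSE)
  }
  grp <- paste(visits$eye_id, visits$date, sep = "\r")
  max_ord <- tapply(visits$order_in_day, grp, max)
  keep <- visits$order_in_day == max_ord[grp]
  visits[keep, , drop = FALSE]
}

#' Per-eye progression slopes averaged per patient
#'
#' For each eye with at least `min_dates` distinct visit dates, fits an
#' ordinary least-squares regression of the feature's metric against time
#' since the patient's first retained visit (in years, days/365.25), and
#' averages eye slopes per patient.
#'
#' @param visits Long visit table after QC and deduplication.
#' @param feature Feature whose metric is regressed.
#' @param metric Column name of the response (default `"area_mm2"`).
#' @param min_dates Minimum distinct dates per eligible eye (default 2).
#' @param min_span_years Minimum follow-up span per eye (default 0, no
#'   minimum).
#' @return List with `per_eye` (tibble: `patient_id`, `eye_id`, `slope`,
#'   `n_visits`, `span_years`) and `per_patient` (tibble: `patient_id`,
#'   `patient_slope`, `n_eyes`); patients with no eligible eye are absent
#'   from `per_patient`.
#' @export
progression_rate <- function(visits, feature, metric = "area_mm2",
                             min_dates = 2L, min_span_years = 0) {
  v <- visits[visits$feature == feature, , drop = FALSE]
  v <- tibble::as_tibble(v)
  if (nrow(v) == 0L) {
    return(list(per_eye = tibble::tibble(patient_id = character(0),
                                         eye_id = character(0),
                                         slope = numeric(0),
                                         n_visits = integer(0),
                                         span_years = numeric(0)),
                per_patient = tibble::tibble(patient_id = character(0),
                                             patient_slope = numeric(0),
                                             n_eyes = integer(0))))
  }
  first_date <- tapply(as.numeric(v$date), v$patient_id, min)
  v$years <- (as.numeric(v$date) - first_date[v$patient_id]) / 365.25
  groups <- split(seq_len(nrow(v)), paste(v$patient_id, v$eye_id, sep = "\r"))
  per_eye <- dplyr::bind_rows(lapply(groups, function(ix) {
    d <- v[ix, , drop = FALSE]
    nd <- length(unique(d$date))
    span <- max(d$years) - min(d$years)
    slope <- if (nd >= min_dates && span >= min_span_years) {
      unname(stats::coef(stats::lm(d[[metric]] ~ d$years))[2])
    } else NA_real_
    tibble::tibble(patient_id = d$patient_id[1], eye_id = d$eye_id[1],
                   slope = slope, n_visits = nd, span_years = span)
  }))
  per_eye <- dplyr::arrange(per_eye, .data$patient_id, .data$eye_id)
  per_patient <- per_eye |>
    dplyr::filter(!is.na(.data$slope)) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(patient_slope = mean(.data$slope),
                     n_eyes = dplyr::n(), .groups = "drop")
  list(per_eye = per_eye, per_patient = per_patient)
}

#' First-presentation cross-sectional record per patient
#'
#' Takes each patient's earliest retained visit date and, by default,
#' averages the two eyes' metrics on that date, giving one cross-sectional
#' record per patient and feature.
#'
#' @param visits Long visit table after QC and deduplication.
#' @param average_eyes Average eyes on the first date (default) or keep
#'   per-eye records.
#' @return Tibble: `patient_id`, `gene`, `age`, `date`, `feature`,
#'   `area_mm2` (plus `eye_id` when `average_eyes = FALSE`), carrying any
#'   severity/variant columns present.
#' @export
first_presentation <- function(visits, average_eyes = TRUE) {
  v <- tibble::as_tibble(visits)
  first_date <- tapply(as.numeric(v$date), v$patient_id, min)
  v <- v[as.numeric(v$date) == first_date[v$patient_id], , drop = FALSE]
  carry <- intersect(c("gene", "age", "allele1_severity", "allele2_severity",
                       "rpgr_aa"), names(v))
  grouping <- c("patient_id", if (!average_eyes) "eye_id", "feature")
  v |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grouping, carry, "date")))) |>
    dplyr::summarise(area_mm2 = mean(.data$area_mm2), .groups = "drop")
}

#' Per-gene cross-sectional aggregation
#'
#' Mean, sample SD and standard error of a feature metric per gene, with
#' patients as the statistical unit.  Genes with a single patient report
#' `NA` for SD and SE.
#'
#' @param records First-presentation records (see [first_presentation()]).
#' @param feature Feature to aggregate.
#' @param metric Metric column (default `"area_mm2"`).
#' @return Tibble: `gene`, `n`, `mean`, `sd`, `se`, sorted by decreasing
#'   mean.
#' @export
aggregate_by_gene <- function(records, feature, metric = "area_mm2") {
  r <- records[records$feature == feature, , drop = FALSE]
  tibble::as_tibble(r) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data[[metric]]),
                     sd = stats::sd(.data[[metric]]),
                     se = stats::sd(.data[[metric]]) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean))
}

#' Age-group assignment
#'
#' Half-open bins: `[0, 18)`, `[18, 30)`, `[30, 45)`, `[45, Inf)`; an age
#' exactly at a boundary falls in the older group.
#'
#' @param age Numeric vector of ages in years (>= 0).
#' @return Factor with levels `under18`, `18to30`, `30to45`, `over45`.
#' @export
assign_age_group <- function(age) {
  if (any(age < 0, na.rm = TRUE)) {
    stop("input error: negative age", call. = FALSE)
  }
  cut(age, c(0, 18, 30, 45, Inf), right = FALSE,
      labels = c("under18", "18to30", "30to45", "over45"))
}

#' ABCA4 genotype severity grouping
#'
#' Classifies two-allele ABCA4 genotypes by variant severity: two severe
#' variants form group A; a mild variant in trans with any other variant
#' forms group C (the mild allele dominates even when the partner allele's
#' severity is unknown); remaining combinations of known severity form
#' group B; anything else is unclassified.
#'
#' @param allele1,allele2 Character vectors with values among `"mild"`,
#'   `"moderate"`, `"severe"`, `"unknown"` (`NA` treated as unknown).
#' @return Factor with levels `A`, `B`, `C`, `unclassified`.
#' @export
assign_abca4_group <- function(allele1, allele2) {
  norm <- function(x) { x <- tolower(as.character(x)); x[is.na(x)] <- "unknown"; x }
  a1 <- norm(allele1); a2 <- norm(allele2)
  known <- c("mild", "moderate", "severe")
  out <- ifelse(a1 == "severe" & a2 == "severe", "A",
         ifelse(a1 == "mild" | a2 == "mild", "C",
         ifelse(a1 %in% known & a2 %in% known, "B", "unclassified")))
  factor(out, levels = c("A", "B", "C", "unclassified"))
}

#' RPGR variant region assignment
#'
#' Splits RPGR variants by affected amino-acid position: positions 600 to
#' 940 form region 1 (rod--cone-like phenotype), positions downstream of
#' 940 form region 2 (cone--rod-like), other positions are `other`.
#'
#' @param aa_position Integer vector of amino-acid positions (>= 1).
#' @return Factor with levels `region1`, `region2`, `other`.
#' @export
assign_rpgr_region <- function(aa_position) {
  if (any(aa_position < 1, na.rm = TRUE)) {
    stop("input error: non-positive amino-acid position", call. = FALSE)
  }
  out <- ifelse(is.na(aa_position), NA_character_,
         ifelse(aa_position >= 600 & aa_position <= 940, "region1",
         ifelse(aa_position > 940, "region2", "other")))
  factor(out, levels = c("region1", "region2", "other"))
}

#' Cross-sectional age trend of a foveal area
#'
#' Ordinary least-squares regression of area against age, reported as a
#' slope in micrometre-squared per year (input areas are mm^2) with the
#' standard t-test p-value.  Degenerate exactly-constant responses report
#' slope 0 with p = 1.
#'
#' @param age Ages in years.
#' @param area_mm2 Areas in mm^2 (e.g. hyper-AF area within 1.5 mm of the
#'   fovea).
#' @return List with `slope_um2_per_year`, `p_value`, `n`.
#' @export
age_trend <- function(age, area_mm2) {
  stopifnot(length(age) == length(area_mm2))
  if (length(age) < 3L) {
    stop("insufficient data: need at least 3 records", call. = FALSE)
  }
  if (stats::sd(area_mm2) == 0) {
    return(list(slope_um2_per_year = 0, p_value = 1, n = length(age)))
  }
  fit <- stats::lm(area_mm2 ~ age)
  co <- suppressWarnings(summary(fit)$coefficients)  # exact fits are legal input
  slope <- co["age", "Estimate"]
  se <- co["age", "Std. Error"]
  p <- if (!is.finite(se) || se == 0) {
    if (abs(slope) < 1e-12) 1 else 0
  } else co["age", "Pr(>|t|)"]
  list(slope_um2_per_year = slope * 1e6, p_value = p, n = length(age))
}
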