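#' Specification of a synthetic FAF phantom
#'
#' Describes a synthetic 55-degree macula-centered blue-FAF acquisition with
#' exact ground-truth geometry: radially vignetted background, dark
#' elliptical optic disc near the nasal edge, bifurcating vessel tree
#' stemming from the disc, perimacular hyper-autofluorescent ring, dark
#' hypo-AF lesions (darkness relative to the disc), bright hyper-AF lesions,
#' and additive sensor noise.  Defaults give a 768 x 768 canvas at
#' 0.0214 mm/px (about a 16.4 mm field, a 55-degree field on an emmetropic
#' eye).
#'
#' Lesion positions are in mm relative to the fovea (`x` temporal-positive
#' toward the disc-free side is not enforced; coordinates are image-frame).
#' `darkness` of a hypo-AF lesion is its relative darkness against the local
#' background, where 1 is exactly as dark as the optic disc; hyper lesion
#' and ring `brightness` are multiplicative factors on the local background.
#'
#' @param size Image side in pixels.
#' @param mm_per_pixel Scale in mm/px.
#' @param background_level Central background intensity.
#' @param vignette Radial polynomial coefficients `c(r2, r4)` of the
#'   vignetting profile `level * (1 + r2*s^2 + r4*s^4)`, `s` = radius over
#'   half-diagonal.
#' @param noise_sd Additive Gaussian intensity noise (0 disables).
#' @param laterality Eye; the disc sits in the nasal third (right edge for
#'   a right eye).
#' @param disc `NULL` to omit, else list with `semi_axes_mm` (c(x, y)),
#'   `darkness` in (0, 1], and optional `center_offset_mm` from the default
#'   nasal position.
#' @param vessels `NULL` to omit, else list with `n_trunks`, `depth`,
#'   `caliber_mm` (trunk diameter), `decay` (caliber per branch level),
#'   `step_mm`, `contrast` (vessel intensity as fraction of background).
#' @param ring `NULL` to omit, else list with `radius_mm` (center radius),
#'   `width_mm`, `completeness` in (0, 1], `brightness`, `start_deg`.
#' @param hypo Data frame of hypo-AF lesions: `x_mm`, `y_mm` (fovea-relative),
#'   `radius_mm`, `darkness`.
#' @param hyper Data frame of hyper-AF lesions: `x_mm`, `y_mm`, `radius_mm`,
#'   `brightness`.
#' @param seed Integer RNG seed; every random element (vessel walk, noise)
#'   derives from it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(size = 768L,
                         mm_per_pixel = 0.0214,
                         background_level = 0.55,
                         vignette = c(-0.30, -0.10),
                         noise_sd = 0.02,
                         laterality = "right",
                         disc = list(semi_axes_mm = c(0.80, 0.95),
                                     darkness = 0.85),
                         vessels = list(n_trunks = 4L, depth = 4L,
                                        caliber_mm = 0.14, decay = 0.72,
                                        step_mm = 0.55, contrast = 0.55),
                         ring = list(radius_mm = 2.0, width_mm = 0.4,
                                     completeness = 1.0, brightness = 1.40,
                                     start_deg = 0),
                         hypo = data.frame(x_mm = c(-2.6, 1.2),
                                           y_mm = c(-1.8, -2.9),
                                           radius_mm = c(0.9, 0.7),
                                           darkness = c(0.95, 0.95)),
                         hyper = data.frame(x_mm = -2.8, y_mm = 1.2,
                                            radius_mm = 0.55,
                                            brightness = 1.50),
                         seed = 1L) {
  stopifnot(size >= 64L, mm_per_pixel > 0, background_level > 0)
  if (!is.null(ring)) {
    stopifnot(ring$completeness > 0, ring$completeness <= 1,
              ring$radius_mm > ring$width_mm / 2)
  }
  half_field <- size * mm_per_pixel / 2
  check_inside <- function(x_mm, y_mm, r_mm) {
    if (any(abs(x_mm) + r_mm > half_field | abs(y_mm) + r_mm > half_field)) {
      stop("spec error: lesion geometry outside image bounds", call. = FALSE)
    }
  }
  if (!is.null(hypo) && nrow(hypo)) {
    stopifnot(all(hypo$darkness >= 0), all(hypo$darkness <= 1))
    check_inside(hypo$x_mm, hypo$y_mm, hypo$radius_mm)
  }
  if (!is.null(hyper) && nrow(hyper)) check_inside(hyper$x_mm, hyper$y_mm, hyper$radius_mm)
  structure(list(size = as.integer(size), mm_per_pixel = mm_per_pixel,
                 background_level = background_level, vignette = vignette,
                 noise_sd = noise_sd, laterality = laterality,
                 disc = disc, vessels = vessels, ring = ring,
                 hypo = hypo, hyper = hyper, seed = as.integer(seed)),
            class = "phantom_spec")
}

# evaluate the vignetted background surface of a spec
phantom_background <- function(spec) {
  n <- spec$size
  cx <- (n + 1) / 2
  s2 <- outer((seq_len(n) - cx)^2, (seq_len(n) - cx)^2, "+") /
    (2 * (n / 2)^2)  # (r / half-diagonal)^2
  spec$background_level *
    (1 + spec$vignette[1] * s2 + spec$vignette[2] * s2^2)
}

# indices of a rasterized disk (pixel centers within radius)
disk_indices <- function(n, cx, cy, r_px) {
  x0 <- max(1L, floor(cx - r_px)); x1 <- min(n, ceiling(cx + r_px))
  y0 <- max(1L, floor(cy - r_px)); y1 <- min(n, ceiling(cy + r_px))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- x0:x1; ys <- y0:y1
  inside <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r_px^2
  idx <- which(inside, arr.ind = TRUE)
  (x0 + idx[, 2] - 2L) * n + (y0 + idx[, 1] - 1L)
}

# rasterize a polyline tree as a mask: points (x, y) with per-point radius
stroke_points <- function(n, px, py, pr) {
  m <- matrix(FALSE, n, n)
  for (r in unique(round(pr, 2))) {
    sel <- round(pr, 2) == r
    rpx <- max(r, 0.5)
    off <- expand.grid(dy = -ceiling(rpx):ceiling(rpx),
                       dx = -ceiling(rpx):ceiling(rpx))
    off <- off[off$dx^2 + off$dy^2 <= rpx^2, , drop = FALSE]
    cx <- round(px[sel]); cy <- round(py[sel])
    for (k in seq_len(nrow(off))) {
      x <- cx + off$dx[k]; y <- cy + off$dy[k]
      ok <- x >= 1 & x <= n & y >= 1 & y <= n
      m[cbind(y[ok], x[ok])] <- TRUE
    }
  }
  m
}

# recursive bifurcating random-walk vessel tree seeded at the disc
grow_vessel_tree <- function(spec, disc_center_px) {
  v <- spec$vessels
  n <- spec$size
  step_px <- v$step_mm / spec$mm_per_pixel
  caliber_px <- v$caliber_mm / spec$mm_per_pixel
  px <- numeric(0); py <- numeric(0); pr <- numeric(0)
  # trunks leave the disc toward the temporal side, fanning vertically
  base_dir <- if (spec$laterality == "right") pi else 0
  fan <- seq(-0.9, 0.9, length.out = v$n_trunks)
  grow <- function(x, y, ang, level) {
    if (level > v$depth) return()
    r <- caliber_px / 2 * v$decay^(level - 1)
    n_steps <- max(3L, round(6 - level + stats::rpois(1, 2)))
    for (i in seq_len(n_steps)) {
      ang <- ang + stats::rnorm(1, 0, 0.18)
      nx <- x + cos(ang) * step_px
      ny <- y + sin(ang) * step_px
      n_sub <- max(2L, round(step_px))
      tt <- seq(0, 1, length.out = n_sub)
      px <<- c(px, x + (nx - x) * tt)
      py <<- c(py, y + (ny - y) * tt)
      pr <<- c(pr, rep(r, n_sub))
      x <- nx; y <- ny
      if (x < 2 || x > n - 1 || y < 2 || y > n - 1) return()
    }
    spread <- stats::runif(1, 0.35, 0.7)
    grow(x, y, ang + spread, level + 1)
    grow(x, y, ang - spread, level + 1)
  }
  for (a in fan) grow(disc_center_px[1], disc_center_px[2], base_dir + a, 1L)
  list(mask = stroke_points(n, px, py, pr))
}

#' Render a phantom FAF image with exact ground-truth masks
#'
#' Deterministic for a fixed seed.  Ground-truth masks are the exact
#' rasterized geometry; rendered intensities honor the relative-darkness
#' (hypo-AF, versus the mean rendered disc intensity) and brightness
#' (hyper-AF, ring) parameters against the local vignetted background, with
#' noise added last.  Mask exclusivity follows the grading protocol: ring
#' pixels are not part of the hyper-AF mask, disc pixels not part of the
#' hypo-AF mask.  Vessels are drawn last (they overlie lesions, as in real
#' fundus images), but ground truth for the other features is the
#' pre-occlusion geometry.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (a [faf_image()]), `masks` (named list of
#'   [feature_mask()]), and `truth` (tibble of analytic feature areas, mm^2,
#'   `NA` where no closed form applies).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  n <- spec$size
  mmpp <- spec$mm_per_pixel
  img <- phantom_background(spec)
  fovea <- c((n + 1) / 2, (n + 1) / 2)
  masks <- list()
  empty <- matrix(FALSE, n, n)
  analytic <- c(disc = NA_real_, hypo_AF = NA_real_, hyper_AF = NA_real_,
                ring = NA_real_, vessels = NA_real_)

  # ring: annulus about the fovea, completeness as an angular arc
  ring_mask <- empty
  if (!is.null(spec$ring)) {
    rg <- spec$ring
    dx <- outer(rep(1, n), seq_len(n) - fovea[1])
    dy <- outer(seq_len(n) - fovea[2], rep(1, n))
    dmm <- sqrt(dx^2 + dy^2) * mmpp
    in_annulus <- dmm >= rg$radius_mm - rg$width_mm / 2 &
      dmm < rg$radius_mm + rg$width_mm / 2
    if (rg$completeness < 1) {
      ang <- (atan2(dy, dx) + 2 * pi) %% (2 * pi)
      a0 <- rg$start_deg * pi / 180
      rel <- (ang - a0 + 2 * pi) %% (2 * pi)
      in_annulus <- in_annulus & rel < 2 * pi * rg$completeness
    }
    ring_mask <- in_annulus
    img[ring_mask] <- img[ring_mask] * rg$brightness
    analytic["ring"] <- rg$completeness * pi *
      ((rg$radius_mm + rg$width_mm / 2)^2 - (rg$radius_mm - rg$width_mm / 2)^2)
  }

  # hyper-AF lesions (protocol: the ring is not hyper-AF)
  hyper_mask <- empty
  if (!is.null(spec$hyper) && nrow(spec$hyper)) {
    for (i in seq_len(nrow(spec$hyper))) {
      le <- spec$hyper[i, ]
      idx <- disk_indices(n, fovea[1] + le$x_mm / mmpp,
                          fovea[2] + le$y_mm / mmpp, le$radius_mm / mmpp)
      img[idx] <- img[idx] * le$brightness
      hyper_mask[idx] <- TRUE
    }
    analytic["hyper_AF"] <- sum(pi * spec$hyper$radius_mm^2)
    hyper_mask <- hyper_mask & !ring_mask
  }

  # disc: dark ellipse in the nasal third
  disc_mask <- empty
  disc_ref <- NA_real_
  if (!is.null(spec$disc)) {
    dc <- spec$disc
    off <- if (is.null(dc$center_offset_mm)) c(0, 0) else dc$center_offset_mm
    edge_gap <- 0.08 * n
    cxp <- if (spec$laterality == "right") n - edge_gap else edge_gap
    cyp <- fovea[2]
    cxp <- cxp + off[1] / mmpp; cyp <- cyp + off[2] / mmpp
    ax <- dc$semi_axes_mm[1] / mmpp; ay <- dc$semi_axes_mm[2] / mmpp
    xs <- seq_len(n); ys <- seq_len(n)
    disc_mask <- outer((ys - cyp)^2 / ay^2, (xs - cxp)^2 / ax^2, "+") <= 1
    img[disc_mask] <- img[disc_mask] * (1 - dc$darkness)
    disc_ref <- mean(img[disc_mask])
    analytic["disc"] <- pi * dc$semi_axes_mm[1] * dc$semi_axes_mm[2]
  }

  # hypo-AF lesions: darkness relative to the disc against local background
  hypo_mask <- empty
  if (!is.null(spec$hypo) && nrow(spec$hypo)) {
    dref <- if (is.na(disc_ref)) 0 else disc_ref
    for (i in seq_len(nrow(spec$hypo))) {
      le <- spec$hypo[i, ]
      idx <- disk_indices(n, fovea[1] + le$x_mm / mmpp,
                          fovea[2] + le$y_mm / mmpp, le$radius_mm / mmpp)
      img[idx] <- img[idx] - le$darkness * (img[idx] - dref)
      hypo_mask[idx] <- TRUE
    }
    analytic["hypo_AF"] <- sum(pi * spec$hypo$radius_mm^2)
    hypo_mask <- hypo_mask & !disc_mask
  }

  # vessels last: they overlie everything
  vessel_mask <- empty
  if (!is.null(spec$vessels) && !is.null(spec$disc)) {
    cxp <- if (spec$laterality == "right") n - 0.08 * n else 0.08 * n
    tree <- grow_vessel_tree(spec, c(cxp, fovea[2]))
    vessel_mask <- tree$mask
    img[vessel_mask] <- img[vessel_mask] * spec$vessels$contrast
  }

  if (spec$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n)
  }
  img <- pmin(pmax(img, 0), 1)

  image <- faf_image(img, mmpp, fovea_xy = fovea,
                     laterality = spec$laterality)
  masks <- list(
    disc = feature_mask(disc_mask, "disc"),
    hypo_AF = feature_mask(hypo_mask, "hypo_AF"),
    hyper_AF = feature_mask(hyper_mask, "hyper_AF"),
    ring = feature_mask(ring_mask, "ring"),
    vessels = feature_mask(vessel_mask, "vessels")
  )
  truth <- tibble::tibble(feature = names(analytic),
                          analytic_area_mm2 = unname(analytic))
  list(image = image, masks = masks, truth = truth)
}

#' Longitudinal phantom series with controlled progression
#'
#' Generates a dated sequence of phantoms whose ground-truth feature areas
#' follow `area0 + slope * t` exactly: the ring's center radius and the
#' hypo/hyper lesion radii are solved from the target area at each visit.
#' Areas are clamped at zero (with a warning) if a negative slope exhausts
#' the feature.
#'
#' @param spec Baseline [phantom_spec()] (visit 1).
#' @param slopes Named numeric vector of mm^2/year slopes, names among
#'   `hypo_AF`, `hyper_AF`, `ring`.
#' @param visits Number of visits (>= 1).
#' @param interval_years Years between consecutive visits.
#' @param render If `FALSE`, skip image rasterization and return only the
#'   analytic ground-truth areas (fast path).
#' @param start_date Date of the first visit.
#' @return List with `areas` (tibble: visit, years, feature,
#'   analytic_area_mm2) and, when rendered, `phantoms` (list of
#'   [generate_phantom()] outputs) and `dates`.
#' @export
generate_series <- function(spec, slopes, visits, interval_years = 1,
                            render = TRUE,
                            start_date = as.Date("2010-01-01")) {
  stopifnot(inherits(spec, "phantom_spec"), visits >= 1)
  bad <- setdiff(names(slopes), c("hypo_AF", "hyper_AF", "ring"))
  if (length(bad)) stop("unsupported slope feature: ", bad[1], call. = FALSE)

  base_areas <- list(
    ring = if (!is.null(spec$ring))
      spec$ring$completeness * 2 * pi * spec$ring$radius_mm * spec$ring$width_mm,
    hypo_AF = if (!is.null(spec$hypo) && nrow(spec$hypo)) sum(pi * spec$hypo$radius_mm^2),
    hyper_AF = if (!is.null(spec$hyper) && nrow(spec$hyper)) sum(pi * spec$hyper$radius_mm^2)
  )
  half_field_area <- (spec$size * spec$mm_per_pixel)^2

  rows <- list(); phantoms <- list()
  day_offsets <- round((seq_len(visits) - 1) * interval_years * 365.25)
  dates <- start_date + day_offsets
  for (v in seq_len(visits)) {
    # acquisition dates are whole days; areas follow the linear model at the
    # realized acquisition time, so slope recovery from dates is exact
    t_yr <- day_offsets[v] / 365.25
    sp <- spec
    sp$seed <- spec$seed + v - 1L
    for (f in names(slopes)) {
      a0 <- base_areas[[f]]
      if (is.null(a0)) stop("spec error: feature ", f, " absent from baseline spec", call. = FALSE)
      target <- a0 + slopes[[f]] * t_yr
      if (target < 0) {
        warning("target area clamped at 0 for ", f, " at visit ", v)
        target <- 0
      }
      if (target > half_field_area) {
        stop("spec error: target area exceeds the imaged field", call. = FALSE)
      }
      if (f == "ring") {
        sp$ring$radius_mm <- target /
          (sp$ring$completeness * 2 * pi * sp$ring$width_mm)
        if (target == 0) sp$ring <- NULL
      } else {
        fac <- sqrt(target / a0)
        if (f == "hypo_AF") sp$hypo$radius_mm <- spec$hypo$radius_mm * fac
        else sp$hyper$radius_mm <- spec$hyper$radius_mm * fac
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        visit = v, years = t_yr, date = dates[v], feature = f,
        analytic_area_mm2 = target)
    }
    if (render) phantoms[[v]] <- generate_phantom(sp)
  }
  out <- list(areas = dplyr::bind_rows(rows), dates = dates)
  if (render) out$phantoms <- phantoms
  out
}

#' Synthetic multi-gene cohort with controlled distributions
#'
#' Draws a cohort of patients from per-gene distributions of baseline
#' feature area, progression slope, and age, and emits the long visit table
#' the cohort pipeline consumes (one row per visit and feature).  This is
#' the metrics-only fast path: no images are rendered, areas follow
#' `baseline + slope * t + noise` per eye.  Both eyes of a patient share the
#' baseline and slope; measurement noise is per scan.
#'
#' @param spec_tbl Data frame, one row per (gene, feature): columns `gene`,
#'   `feature`, `n_patients`, `area_mean`, `area_sd`, `slope_mean`,
#'   `slope_sd`, `n_visits`, `interval_years`, `age_mean`, `age_sd`,
#'   `noise_sd`.  Optional columns `allele1_severity`, `allele2_severity`,
#'   `rpgr_aa` are copied onto patients.
#' @param seed Integer RNG seed.
#' @param p_missing_disc Probability a visit's optic disc is not detected
#'   (such visits are what QC later removes).
#' @param p_extra_scan Probability a visit has a same-day repeat scan
#'   (exercises per-day deduplication).
#' @param start_date First-visit date for every patient.
#' @return Long tibble of visits: `patient_id`, `eye_id`, `date`,
#'   `order_in_day`, `age`, `gene`, severity/variant columns, `feature`,
#'   `present`, `area_mm2`, plus a `disc` presence row per scan.
#' @export
generate_cohort <- function(spec_tbl, seed = 1L, p_missing_disc = 0,
                            p_extra_scan = 0,
                            start_date = as.Date("2012-06-01")) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  spec_tbl <- tibble::as_tibble(spec_tbl)
  need <- c("gene", "feature", "n_patients", "area_mean", "area_sd",
            "slope_mean", "slope_sd", "n_visits", "interval_years",
            "age_mean", "age_sd", "noise_sd")
  miss <- setdiff(need, names(spec_tbl))
  if (length(miss)) stop("cohort spec missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)

  out <- list()
  pid_counter <- 0L
  for (g in unique(spec_tbl$gene)) {
    gspec <- spec_tbl[spec_tbl$gene == g, ]
    np <- gspec$n_patients[1]
    for (p in seq_len(np)) {
      pid_counter <- pid_counter + 1L
      pid <- sprintf("P%04d", pid_counter)
      age0 <- max(0, stats::rnorm(1, gspec$age_mean[1], gspec$age_sd[1]))
      nv <- gspec$n_visits[1]
      iv <- gspec$interval_years[1]
      # per-feature patient-level baseline and slope (shared across eyes)
      base <- stats::setNames(
        pmax(0, stats::rnorm(nrow(gspec), gspec$area_mean, gspec$area_sd)),
        gspec$feature)
      slp <- stats::setNames(
        stats::rnorm(nrow(gspec), gspec$slope_mean, gspec$slope_sd),
        gspec$feature)
      sev <- list(
        allele1_severity = if ("allele1_severity" %in% names(gspec)) gspec$allele1_severity[1] else NA_character_,
        allele2_severity = if ("allele2_severity" %in% names(gspec)) gspec$allele2_severity[1] else NA_character_,
        rpgr_aa = if ("rpgr_aa" %in% names(gspec)) gspec$rpgr_aa[1] else NA_integer_)
      feats <- gspec$feature
      nf <- length(feats)
      for (eye in c("L", "R")) {
        t_yr <- (seq_len(nv) - 1) * iv
        n_scans <- 1L + (stats::runif(nv) < p_extra_scan)
        scan_visit <- rep(seq_len(nv), n_scans)
        scan_ord <- sequence(n_scans)
        ns <- length(scan_visit)
        disc_ok <- stats::runif(ns) >= p_missing_disc
        t_scan <- t_yr[scan_visit]
        areas <- pmax(0, rep(base[feats], times = ns) +
                        rep(slp[feats], times = ns) * rep(t_scan, each = nf) +
                        stats::rnorm(nf * ns, 0, gspec$noise_sd[1]))
        out[[length(out) + 1L]] <- tibble::tibble(
          patient_id = pid, eye_id = paste0(pid, "_", eye),
          date = start_date + rep(round(t_scan * 365.25), each = nf + 1L),
          order_in_day = rep(scan_ord, each = nf + 1L),
          age = age0 + rep(t_scan, each = nf + 1L), gene = g,
          allele1_severity = sev$allele1_severity,
          allele2_severity = sev$allele2_severity,
          rpgr_aa = sev$rpgr_aa,
          feature = rep(c("disc", feats), times = ns),
          present = as.vector(rbind(disc_ok,
                                    matrix(areas > 0, nf, ns))),
          area_mm2 = as.vector(rbind(ifelse(disc_ok, 2.4, 0),
                                     matrix(areas, nf, ns))))
      }
    }
  }
  dplyr::bind_rows(out)
}
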