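test_that("phantom generation is deterministic under a fixed seed", {
  s <- small_phantom_spec(seed = 42)
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  expect_identical(a$image$pixels, b$image$pixels)
  for (f in names(a$masks)) expect_identical(a$masks[[f]]$pixels,
                                             b$masks[[f]]$pixels)
  c <- generate_phantom(small_phantom_spec(seed = 43))
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("requested lesion areas are honored within rasterization error", {
  spec <- small_phantom_spec(
    seed = 3, noise_sd = 0,
    hypo = data.frame(x_mm = -2, y_mm = 0, radius_mm = 1, darkness = 0.95))
  ph <- generate_phantom(spec)
  raster <- feature_area(ph$masks$hypo_AF, spec$mm_per_pixel)
  expect_equal(raster, pi, tolerance = 0.02)
  # generic bound: |raster - analytic| <= perimeter-pixel count x pixel area
  perim <- 2 * pi * 1 / spec$mm_per_pixel
  expect_lte(abs(raster - pi), (perim + 4) * spec$mm_per_pixel^2)
})

test_that("ring completeness parameter is honored by the ground truth", {
  spec <- small_phantom_spec(
    seed = 3, noise_sd = 0,
    ring = list(radius_mm = 2, width_mm = 0.4, completeness = 0.4,
                brightness = 1.4, start_deg = 45))
  ph <- generate_phantom(spec)
  cov <- ring_angular_coverage(ph$masks$ring, ph$image$fovea_xy)
  expect_equal(cov$coverage, 0.4, tolerance = 1 / 360)
})

test_that("ground-truth masks respect protocol exclusivity", {
  for (seed in c(1, 5, 9)) {
    ph <- generate_phantom(small_phantom_spec(seed = seed))
    expect_equal(sum(ph$masks$ring$pixels & ph$masks$hyper_AF$pixels), 0)
    expect_equal(sum(ph$masks$disc$pixels & ph$masks$hypo_AF$pixels), 0)
    expect_true(all(ph$image$pixels >= 0 & ph$image$pixels <= 1))
  }
})

test_that("rendered intensities honor darkness/brightness against background", {
  spec <- small_phantom_spec(seed = 6, noise_sd = 0, vessels = NULL)
  ph <- generate_phantom(spec)
  img <- ph$image$pixels
  bg <- fafquant:::phantom_background(spec)
  disc_mean <- mean(img[ph$masks$disc$pixels])
  hypo_px <- ph$masks$hypo_AF$pixels
  rel_dark <- (bg[hypo_px] - img[hypo_px]) / (bg[hypo_px] - disc_mean)
  expect_equal(mean(rel_dark), 0.95, tolerance = 0.01)
  ring_px <- ph$masks$ring$pixels
  expect_equal(mean(img[ring_px] / bg[ring_px]), 1.4, tolerance = 0.01)
})

test_that("out-of-bounds lesion geometry is rejected", {
  expect_error(small_phantom_spec(
    hypo = data.frame(x_mm = 9, y_mm = 0, radius_mm = 1, darkness = 0.9)),
    "spec error")
})

test_that("series areas follow area0 + slope * t exactly", {
  spec <- small_phantom_spec(
    seed = 2, noise_sd = 0, ring = NULL, hyper = NULL,
    hypo = data.frame(x_mm = -2, y_mm = 0, radius_mm = sqrt(5 / pi),
                      darkness = 0.95))
  flatline <- generate_series(spec, c(hypo_AF = 0), visits = 3,
                              render = FALSE)
  expect_equal(unique(flatline$areas$analytic_area_mm2), 5)

  shrink <- generate_series(spec, c(hypo_AF = -0.2), visits = 3,
                            render = FALSE)
  expect_equal(shrink$areas$analytic_area_mm2, c(5.0, 4.8, 4.6),
               tolerance = 1e-3)

  expect_error(generate_series(spec, c(ring = -0.2), visits = 2),
               "absent from baseline")
})

test_that("rendered series masks track the analytic areas", {
  spec <- small_phantom_spec(
    seed = 2, noise_sd = 0,
    hypo = data.frame(x_mm = -2, y_mm = 0, radius_mm = 1.1, darkness = 0.95))
  ser <- generate_series(spec, c(hypo_AF = -0.4, ring = -0.3), visits = 3,
                         render = TRUE)
  for (v in 1:3) {
    ph <- ser$phantoms[[v]]
    for (f in c("hypo_AF", "ring")) {
      target <- ser$areas$analytic_area_mm2[ser$areas$visit == v &
                                            ser$areas$feature == f]
      expect_equal(feature_area(ph$masks[[f]], spec$mm_per_pixel), target,
                   tolerance = 0.04)
    }
  }
})

test_that("noise-free series recovers the seeded slope end to end", {
  spec <- small_phantom_spec(seed = 2, noise_sd = 0)
  ser <- generate_series(spec, c(ring = -0.178), visits = 5,
                         interval_years = 1, render = FALSE)
  areas <- ser$areas
  visits <- tibble::tibble(
    patient_id = "P1", eye_id = "P1_R", date = areas$date,
    order_in_day = 1L, age = 30 + areas$years, gene = "EYS",
    feature = areas$feature, present = TRUE,
    area_mm2 = areas$analytic_area_mm2)
  pr <- progression_rate(visits, "ring")
  expect_equal(pr$per_patient$patient_slope, -0.178, tolerance = 1e-6)
})

test_that("degenerate cohort draws reproduce the specified means exactly", {
  spec <- tibble::tibble(gene = c("CHM", "ABCA4"), feature = "hypo_AF",
                         n_patients = 1, area_mean = c(43.72, 19.65),
                         area_sd = 0, slope_mean = 0, slope_sd = 0,
                         n_visits = 1, interval_years = 1,
                         age_mean = 40, age_sd = 0, noise_sd = 0)
  v <- generate_cohort(spec, seed = 1)
  hy <- v[v$feature == "hypo_AF", ]
  expect_equal(sort(unique(hy$area_mm2)), c(19.65, 43.72))
  expect_identical(generate_cohort(spec, seed = 1), v)
})

test_that("cohort sample means land within 2 SE of the seeded means", {
  spec <- tibble::tibble(gene = c("CHM", "ABCA4"), feature = "hypo_AF",
                         n_patients = 200, area_mean = c(43.72, 19.65),
                         area_sd = 5, slope_mean = 0, slope_sd = 0,
                         n_visits = 1, interval_years = 1,
                         age_mean = 40, age_sd = 12, noise_sd = 0)
  v <- generate_cohort(spec, seed = 1)
  fp <- first_presentation(dedup_daily(qc_filter(v)))
  agg <- aggregate_by_gene(fp, "hypo_AF")
  for (g in c("CHM", "ABCA4")) {
    row <- agg[agg$gene == g, ]
    expect_lte(abs(row$mean - spec$area_mean[spec$gene == g]), 2 * row$se)
  }
})
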