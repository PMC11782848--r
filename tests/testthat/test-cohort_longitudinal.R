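test_that("QC keeps exactly the scans with a segmented disc", {
  v <- dplyr::bind_rows(
    visit_row("P1", "P1_R", "2010-01-01", feature = "disc", present = TRUE),
    visit_row("P1", "P1_R", "2010-01-01", feature = "hypo_AF", area = 2),
    visit_row("P2", "P2_R", "2010-02-01", feature = "disc", present = FALSE,
              area = 0),
    visit_row("P2", "P2_R", "2010-02-01", feature = "hypo_AF", area = 3),
    visit_row("P3", "P3_L", "2010-03-01", feature = "disc", present = TRUE),
    visit_row("P3", "P3_L", "2010-03-01", feature = "hypo_AF", area = 4))
  out <- qc_filter(v)
  expect_setequal(unique(out$patient_id), c("P1", "P3"))
  expect_equal(out$patient_id, c("P1", "P1", "P3", "P3"))  # order preserved
  expect_equal(attr(out, "qc_counts"), c(scans_in = 3L, scans_out = 2L))

  all_good <- v[v$patient_id != "P2", ]
  expect_equal(qc_filter(all_good)$area_mm2, all_good$area_mm2)
  all_bad <- v[v$patient_id == "P2", ]
  expect_equal(nrow(qc_filter(all_bad)), 0L)
})

test_that("daily dedup keeps the most recent scan per eye-date", {
  v <- dplyr::bind_rows(
    visit_row("P1", "P1_R", "2010-01-01", ord = 1L, area = 1),
    visit_row("P1", "P1_R", "2010-01-01", ord = 2L, area = 2),
    visit_row("P1", "P1_R", "2010-06-01", ord = 1L, area = 3))
  out <- dedup_daily(v)
  expect_equal(nrow(out), 2L)
  expect_equal(out$area_mm2[out$date == as.Date("2010-01-01")], 2)

  unique_dates <- dplyr::bind_rows(
    visit_row("P1", "P1_R", "2010-01-01"),
    visit_row("P1", "P1_R", "2011-01-01"))
  expect_equal(dedup_daily(unique_dates), unique_dates)

  expect_error(dedup_daily(dplyr::bind_rows(
    visit_row("P1", "P1_R", "2010-01-01", ord = 1L),
    visit_row("P1", "P1_R", "2010-01-01", ord = 1L))), "ambiguity")
})

test_that("dedup matches a group-by/argmax oracle and is idempotent", {
  set.seed(19)
  rows <- list()
  for (i in 1:120) {
    eye <- sample(c("P1_R", "P1_L", "P2_R"), 1)
    date <- sample(as.Date("2010-01-01") + c(0, 40, 200), 1)
    rows[[i]] <- visit_row(substr(eye, 1, 2), eye, date, ord = i)
  }
  v <- dplyr::bind_rows(rows)
  out <- dedup_daily(v)
  oracle <- do.call(rbind, lapply(split(v, paste(v$eye_id, v$date)),
                                  function(d) d[which.max(d$order_in_day), ]))
  expect_setequal(paste(out$eye_id, out$date, out$order_in_day),
                  paste(oracle$eye_id, oracle$date, oracle$order_in_day))
  expect_equal(dedup_daily(out), out)
})

test_that("progression slope is exact on collinear data and averages eyes", {
  d0 <- as.Date("2015-01-01")
  # collinear in realized years: dates are whole days, so the response is
  # built from the same days/365.25 axis the regression reconstructs
  mk_eye <- function(eye, a0, slope, years) dplyr::bind_rows(lapply(
    seq_along(years), function(i) {
      days <- round(years[i] * 365.25)
      visit_row("P1", eye, d0 + days, area = a0 + slope * days / 365.25)
    }))
  one_eye <- mk_eye("P1_R", 5.0, -0.2, 0:2)
  pr <- progression_rate(one_eye, "hypo_AF")
  expect_equal(pr$per_eye$slope, -0.2, tolerance = 1e-12)
  expect_equal(pr$per_patient$patient_slope, -0.2, tolerance = 1e-12)

  two_eyes <- dplyr::bind_rows(mk_eye("P1_R", 1, -0.1, 0:1),
                               mk_eye("P1_L", 1, -0.3, 0:1))
  pr2 <- progression_rate(two_eyes, "hypo_AF")
  expect_equal(sort(pr2$per_eye$slope), c(-0.3, -0.1), tolerance = 1e-9)
  expect_equal(pr2$per_patient$patient_slope, -0.2, tolerance = 1e-9)

  # an eye with a single date is excluded, not zeroed
  single <- visit_row("P9", "P9_R", "2015-01-01")
  pr3 <- progression_rate(single, "hypo_AF")
  expect_true(is.na(pr3$per_eye$slope))
  expect_equal(nrow(pr3$per_patient), 0L)
})

test_that("noisy cohort slope recovery converges on the seeded rate", {
  spec <- tibble::tibble(gene = "EYS", feature = "ring", n_patients = 100,
                         area_mean = 5, area_sd = 0.5,
                         slope_mean = -0.178, slope_sd = 0,
                         n_visits = 5, interval_years = 1,
                         age_mean = 35, age_sd = 10, noise_sd = 0.2)
  v <- generate_cohort(spec, seed = 7)  # 200 eyes
  pr <- progression_rate(dedup_daily(qc_filter(v)), "ring")
  expect_equal(nrow(pr$per_eye), 200L)
  expect_equal(mean(pr$per_eye$slope), -0.178, tolerance = 0.02)
})

test_that("first presentation takes the earliest date and averages eyes", {
  v <- dplyr::bind_rows(
    visit_row("P1", "P1_R", "2010-05-01", area = 1.0),
    visit_row("P1", "P1_L", "2010-05-01", area = 3.0),
    visit_row("P1", "P1_R", "2015-05-01", area = 9.0))
  fp <- first_presentation(v)
  expect_equal(nrow(fp), 1L)
  expect_equal(fp$area_mm2, 2.0)
  expect_equal(fp$date, as.Date("2010-05-01"))

  per_eye <- first_presentation(v, average_eyes = FALSE)
  expect_equal(sort(per_eye$area_mm2), c(1, 3))

  single <- visit_row("P2", "P2_R", "2012-01-01", area = 7)
  expect_equal(first_presentation(single)$area_mm2, 7)
})

test_that("per-gene aggregation reports n, mean, SD and SE", {
  recs <- dplyr::bind_rows(
    visit_row("P1", "P1_R", "2010-01-01", area = 1),
    visit_row("P2", "P2_R", "2010-01-01", area = 2),
    visit_row("P3", "P3_R", "2010-01-01", area = 3),
    visit_row("P4", "P4_R", "2010-01-01", area = 5, gene = "GENE2"))
  fp <- first_presentation(recs)
  agg <- aggregate_by_gene(fp, "hypo_AF")
  g1 <- agg[agg$gene == "GENE1", ]
  expect_equal(g1$n, 3L)
  expect_equal(g1$mean, 2)
  expect_equal(g1$sd, 1)
  expect_equal(g1$se, 1 / sqrt(3))
  g2 <- agg[agg$gene == "GENE2", ]
  expect_equal(g2$mean, 5)
  expect_true(is.na(g2$sd) && is.na(g2$se))
})

test_that("age groups use half-open bins with the boundary in the older bin", {
  expect_equal(as.character(assign_age_group(c(17, 18, 29.9, 30, 44, 45, 80))),
               c("under18", "18to30", "18to30", "30to45", "30to45",
                 "over45", "over45"))
  expect_error(assign_age_group(-1), "negative")
})

test_that("ABCA4 severity grouping follows the two-allele rules", {
  expect_equal(as.character(assign_abca4_group("severe", "severe")), "A")
  expect_equal(as.character(assign_abca4_group("mild", "severe")), "C")
  expect_equal(as.character(assign_abca4_group("severe", "mild")), "C")
  expect_equal(as.character(assign_abca4_group("moderate", "severe")), "B")
  expect_equal(as.character(assign_abca4_group("moderate", "moderate")), "B")
  expect_equal(as.character(assign_abca4_group("mild", "unknown")), "C")
  expect_equal(as.character(assign_abca4_group("unknown", "severe")),
               "unclassified")
  expect_equal(as.character(assign_abca4_group(NA, NA)), "unclassified")

  # every genotype lands in exactly one group: counts partition the cohort
  sevs <- c("mild", "moderate", "severe", "unknown")
  grid <- expand.grid(a1 = sevs, a2 = sevs, stringsAsFactors = FALSE)
  groups <- assign_abca4_group(grid$a1, grid$a2)
  expect_false(any(is.na(groups)))
  expect_equal(sum(table(groups)), nrow(grid))
})

test_that("RPGR region split honors the 600-940 boundary", {
  expect_equal(as.character(assign_rpgr_region(c(700, 600, 940))),
               rep("region1", 3))
  expect_equal(as.character(assign_rpgr_region(c(941, 1000))),
               rep("region2", 2))
  expect_equal(as.character(assign_rpgr_region(c(100, 599))),
               rep("other", 2))
  expect_error(assign_rpgr_region(0), "position")
})

test_that("age trend returns an exact slope on collinear data", {
  ages <- seq(10, 60, by = 5)
  areas <- 0.5 + 691e-6 * ages  # 691 um^2/year in mm^2
  tr <- age_trend(ages, areas)
  expect_equal(tr$slope_um2_per_year, 691, tolerance = 1e-6)
  expect_lt(tr$p_value, 0.001)

  flat <- age_trend(ages, rep(0.4, length(ages)))
  expect_equal(flat$slope_um2_per_year, 0, tolerance = 1e-9)
  expect_equal(flat$p_value, 1)
  expect_error(age_trend(c(1, 2), c(1, 2)), "insufficient")
})

test_that("age trend recovers a seeded slope within 2 standard errors", {
  set.seed(31)
  n <- 300
  ages <- runif(n, 5, 80)
  slope_mm2 <- 691e-6
  areas <- 0.3 + slope_mm2 * ages + rnorm(n, 0, 0.2)
  tr <- age_trend(ages, areas)
  fit <- stats::lm(areas ~ ages)
  se_um2 <- summary(fit)$coefficients["ages", "Std. Error"] * 1e6
  expect_lte(abs(tr$slope_um2_per_year - 691), 2 * se_um2)
})
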