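# construct an image from a pure radial profile for background tests
vignetted_image <- function(n = 256, level = 0.6, v2 = -0.3, v4 = -0.1,
                            mmpp = 0.0428) {
  c0 <- (n + 1) / 2
  s2 <- outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, "+") / (2 * (n / 2)^2)
  faf_image(pmin(pmax(level * (1 + v2 * s2 + v4 * s2^2), 0), 1), mmpp)
}

test_that("background model is flat on a constant image", {
  img <- flat_image(0.6, n = 128)
  bg <- estimate_background(img)
  expect_equal(bg$global_level, 0.6)
  expect_equal(max(abs(bg$surface - 0.6)), 0, tolerance = 1e-6)
})

test_that("background fit recovers known vignetting coefficients within 1%", {
  img <- vignetted_image(level = 0.6, v2 = -0.3, v4 = -0.1)
  bg <- estimate_background(img)
  level_hat <- bg$coef[1]
  v2_hat <- bg$coef[2] / level_hat
  v4_hat <- bg$coef[3] / level_hat
  expect_equal(unname(level_hat), 0.6, tolerance = 0.01)
  expect_equal(unname(v2_hat), -0.3, tolerance = 0.01)
  expect_equal(unname(v4_hat), -0.1, tolerance = 0.01)
})

test_that("excluding dark lesions raises the background over lesion pixels", {
  img <- vignetted_image()
  px <- img$pixels
  lesion <- disk_mask(256, 100, 100, 30)$pixels
  px[lesion] <- px[lesion] * 0.1
  img2 <- faf_image(px, img$mm_per_pixel)
  bg_excl <- estimate_background(img2, exclude = list(lesion),
                                 trim_iters = 0L)
  bg_incl <- estimate_background(img2, trim_iters = 0L)
  expect_gte(mean(bg_excl$surface[lesion]), mean(bg_incl$surface[lesion]))
  expect_error(estimate_background(img2, exclude = list(matrix(TRUE, 256, 256))),
               "estimation error")
})

test_that("disc segmentation finds the phantom disc and knows its absence", {
  ph <- generate_phantom(small_phantom_spec(seed = 2, noise_sd = 0))
  d <- segment_disc(ph$image)
  expect_gte(as.numeric(dice(d, ph$masks$disc)), 0.8)

  no_disc <- generate_phantom(small_phantom_spec(seed = 2, noise_sd = 0,
                                                 disc = NULL, vessels = NULL))
  expect_false(feature_present(segment_disc(no_disc$image)))
  expect_false(feature_present(segment_disc(flat_image(0.5, n = 256))))
})

test_that("hypo-AF honors the 90% relative-darkness rule", {
  spec_dark <- small_phantom_spec(
    seed = 5, noise_sd = 0, vessels = NULL, ring = NULL, hyper = NULL,
    hypo = data.frame(x_mm = -2, y_mm = 0, radius_mm = 1, darkness = 0.95))
  ph <- generate_phantom(spec_dark)
  disc <- segment_disc(ph$image)
  hypo <- segment_hypo_af(ph$image, disc)
  expect_gte(as.numeric(dice(hypo, ph$masks$hypo_AF)), 0.9)

  spec_faint <- small_phantom_spec(
    seed = 5, noise_sd = 0, vessels = NULL, ring = NULL, hyper = NULL,
    hypo = data.frame(x_mm = -2, y_mm = 0, radius_mm = 1, darkness = 0.5))
  ph2 <- generate_phantom(spec_faint)
  disc2 <- segment_disc(ph2$image)
  hypo2 <- segment_hypo_af(ph2$image, disc2)
  # ambiguous (not definitely decreased) region is not annotated
  expect_equal(sum(hypo2$pixels & ph2$masks$hypo_AF$pixels), 0)

  expect_error(segment_hypo_af(ph$image,
                               feature_mask(matrix(FALSE, 384, 384), "disc")),
               "missing reference")
})

test_that("hypo-AF is monotone in the darkness threshold", {
  ph <- generate_phantom(small_phantom_spec(seed = 6, noise_sd = 0.02))
  disc <- segment_disc(ph$image)
  bg <- estimate_background(ph$image, exclude = list(disc))
  loose <- segment_hypo_af(ph$image, disc, bg, threshold = 0.8,
                           min_size_px = 0L)
  strict <- segment_hypo_af(ph$image, disc, bg, threshold = 0.9,
                            min_size_px = 0L)
  expect_true(all(loose$pixels[strict$pixels]))
})

test_that("peripapillary dark areas are excluded from hypo-AF", {
  # dark annulus hugging the disc: inside the 0.3 mm exclusion margin
  n <- 384; mmpp <- 0.0428
  spec <- small_phantom_spec(seed = 8, noise_sd = 0, vessels = NULL,
                             ring = NULL, hyper = NULL, hypo = NULL)
  ph <- generate_phantom(spec)
  px <- ph$image$pixels
  disc_px <- ph$masks$disc$pixels
  grown <- EBImage::dilate(disc_px * 1, EBImage::makeBrush(11L, "disc")) > 0
  periphery <- grown & !disc_px  # ~0.2 mm collar
  px[periphery] <- 0.01
  img <- faf_image(px, mmpp, laterality = "right")
  disc <- segment_disc(img)
  hypo <- segment_hypo_af(img, disc)
  expect_equal(sum(hypo$pixels & periphery), 0)
})

test_that("hyper-AF brightness rule includes 1.5x blobs, excludes the ring", {
  ph <- generate_phantom(small_phantom_spec(seed = 9, noise_sd = 0,
                                            vessels = NULL))
  bg <- estimate_background(ph$image)
  hyper <- segment_hyper_af(ph$image, bg, ring = ph$masks$ring)
  expect_gte(as.numeric(dice(hyper, ph$masks$hyper_AF)), 0.9)
  expect_equal(sum(hyper$pixels & ph$masks$ring$pixels), 0)
  expect_false(feature_present(segment_hyper_af(flat_image(0.5, n = 256))))
})

test_that("ring segmentation applies the >50% completeness gate", {
  ph <- generate_phantom(small_phantom_spec(seed = 10, noise_sd = 0))
  ring <- segment_ring(ph$image)
  expect_true(attr(ring, "is_ring"))
  expect_gte(attr(ring, "coverage"), 0.9)
  expect_gte(as.numeric(dice(ring, ph$masks$ring)), 0.8)

  arc <- generate_phantom(small_phantom_spec(
    seed = 10, noise_sd = 0,
    ring = list(radius_mm = 2, width_mm = 0.4, completeness = 0.4,
                brightness = 1.4, start_deg = 30)))
  ring40 <- segment_ring(arc$image)
  expect_false(feature_present(ring40))
  expect_false(attr(ring40, "is_ring"))

  expect_false(feature_present(segment_ring(flat_image(0.5, n = 256))))
})

test_that("vessel segmentation recovers the tree and enforces connectivity", {
  ph <- generate_phantom(small_phantom_spec(seed = 13, noise_sd = 0))
  disc <- segment_disc(ph$image)
  vessels <- segment_vessels(ph$image, disc)
  expect_gte(as.numeric(dice(vessels, ph$masks$vessels)), 0.6)
  expect_false(feature_present(segment_vessels(flat_image(0.5, n = 256))))

  # an isolated short dark ridge far from the disc is dropped
  px <- ph$image$pixels
  px[20:22, 30:70] <- px[20:22, 30:70] * 0.5
  img2 <- faf_image(px, ph$image$mm_per_pixel, laterality = "right")
  v2 <- segment_vessels(img2, disc)
  expect_equal(sum(v2$pixels[20:22, 30:70]), 0)
})

test_that("protocol outputs are exclusive, binary and deterministic", {
  ph <- generate_phantom(small_phantom_spec(seed = 14))
  seg1 <- segment_features(ph$image)
  seg2 <- segment_features(ph$image)
  for (f in names(seg1)) {
    expect_identical(seg1[[f]]$pixels, seg2[[f]]$pixels)
    expect_type(seg1[[f]]$pixels, "logical")
  }
  expect_equal(sum(seg1$ring$pixels & seg1$hyper_AF$pixels), 0)
  expect_equal(sum(seg1$disc$pixels & seg1$hypo_AF$pixels), 0)
})

test_that("noise-free phantom segmentation meets per-feature overlap floors", {
  ph <- generate_phantom(small_phantom_spec(seed = 15, noise_sd = 0))
  seg <- segment_features(ph$image)
  floors <- c(disc = 0.8, hypo_AF = 0.8, hyper_AF = 0.8, ring = 0.8,
              vessels = 0.6)
  for (f in names(floors)) {
    expect_gte(as.numeric(dice(seg[[f]], ph$masks[[f]])), floors[[f]])
  }
})
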