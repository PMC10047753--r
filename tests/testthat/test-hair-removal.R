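# DullRazor-style hair detection, inpainting and adaptive median smoothing.

test_that("hair-free and degenerate inputs give empty masks or errors", {
  const <- rgb_image(array(180, c(40, 40, 3)))
  hm <- detect_hair_mask(const)
  expect_equal(hm$coverage, 0)
  expect_error(detect_hair_mask(const, hair_config(closing_length = 8)),
               class = "sdpskin_validation_error")
  expect_error(detect_hair_mask(const, hair_config(closing_length = 101)),
               class = "sdpskin_validation_error")
  expect_error(detect_hair_mask(const, hair_config(threshold = 0)),
               class = "sdpskin_validation_error")
})

test_that("drawn strokes are detected and a filled disc is not", {
  f <- stroke_fixture(seed = 9)
  hm <- detect_hair_mask(f$img)
  recall <- sum(hm$mask * f$gt) / sum(f$gt)
  false_rate <- sum(hm$mask * (1 - f$gt)) / sum(1 - f$gt)
  expect_gte(recall, 0.8)
  expect_lt(false_rate, 0.02)

  d <- disc_image()
  expect_equal(detect_hair_mask(d$img)$coverage, 0)
})

test_that("raising the detection threshold never increases coverage", {
  f <- stroke_fixture(seed = 13)
  # add noise so intermediate thresholds bite
  px <- pmin(pmax(f$img$pixels + array(rnorm(length(f$img$pixels), sd = 4),
                                       dim(f$img$pixels)), 0), 255)
  img <- rgb_image(px)
  covs <- vapply(c(8, 20, 60, 120, 200),
                 function(th) detect_hair_mask(img, hair_config(threshold = th))$coverage,
                 numeric(1))
  expect_true(all(diff(covs) <= 1e-12))
})

test_that("inpainting interpolates across the hair", {
  img <- rgb_image(array(runif(30 * 30 * 3, 0, 255), c(30, 30, 3)))
  empty <- structure(list(mask = matrix(0L, 30, 30), coverage = 0),
                     class = "hair_mask")
  expect_equal(inpaint_hair(img, empty)$pixels, img$pixels)

  # single flagged pixel amid constant neighbours
  px <- array(100, c(20, 20, 3)); px[10, 10, ] <- 0
  m <- matrix(0L, 20, 20); m[10, 10] <- 1L
  hm <- structure(list(mask = m, coverage = mean(m)), class = "hair_mask")
  out <- inpaint_hair(rgb_image(px), hm)
  expect_equal(out$pixels[10, 10, ], c(100, 100, 100))

  # vertical stroke crossing a linear ramp: analytic ramp values recovered
  ramp <- array(0, c(40, 40, 3))
  for (ch in 1:3) ramp[, , ch] <- matrix(rep(seq(40, 200, length.out = 40),
                                             each = 40), 40, 40)
  px <- ramp
  gt <- matrix(0L, 40, 40); gt[, 20:21] <- 1L
  for (ch in 1:3) { p <- px[, , ch]; p[gt == 1] <- 0; px[, , ch] <- p }
  hm <- structure(list(mask = gt, coverage = mean(gt)), class = "hair_mask")
  out <- inpaint_hair(rgb_image(px), hm)
  expect_lte(max(abs(out$pixels[, 20:21, ] - ramp[, 20:21, ])), 2)

  all_mask <- structure(list(mask = matrix(1L, 40, 40), coverage = 1),
                        class = "hair_mask")
  expect_error(inpaint_hair(rgb_image(px), all_mask),
               class = "sdpskin_validation_error")
})

test_that("adaptive median smoothing follows the growing-window rule", {
  img <- rgb_image(array(runif(20 * 20 * 3, 0, 255), c(20, 20, 3)))
  empty <- structure(list(mask = matrix(0L, 20, 20), coverage = 0),
                     class = "hair_mask")
  expect_equal(adaptive_median_smooth(img, empty)$pixels, img$pixels)
  expect_error(adaptive_median_smooth(img, empty, max_window = 4),
               class = "sdpskin_validation_error")

  # impulse inside the mask amid a constant neighbourhood
  px <- array(90, c(15, 15, 3)); px[8, 8, ] <- 255
  m <- matrix(0L, 15, 15); m[8, 8] <- 1L
  hm <- structure(list(mask = m, coverage = mean(m)), class = "hair_mask")
  expect_equal(adaptive_median_smooth(rgb_image(px), hm)$pixels[8, 8, ],
               c(90, 90, 90))

  # full-rule equality against the brute-force nested-loop oracle
  set.seed(21)
  px <- array(sample(0:255, 16 * 16 * 3, replace = TRUE), c(16, 16, 3))
  m <- matrix(0L, 16, 16); m[6:10, 8] <- 1L; m[3, 12:14] <- 1L
  hm <- structure(list(mask = m, coverage = mean(m)), class = "hair_mask")
  got <- adaptive_median_smooth(rgb_image(px), hm, max_window = 5)
  expect_equal(got$pixels, oracle_adaptive_median(px, m, 5))
})

test_that("the composed hair removal repairs without collateral damage", {
  # hair-free image: essentially untouched
  set.seed(2)
  img <- rgb_image(array(runif(48 * 48 * 3, 150, 200), c(48, 48, 3)))
  out <- remove_hair(img)
  expect_lt(mean(abs(out$pixels - img$pixels)), 1)

  # hairy synthetic sample vs its clean twin: error strictly reduced
  spec <- ph2like_specs()[["melanoma-like"]]
  hairy <- generate_sample(spec, c(128, 128), with_hair = TRUE, seed = 23)
  clean <- generate_sample(spec, c(128, 128), with_hair = FALSE, seed = 23)
  repaired <- remove_hair(hairy$image, keep_stages = TRUE)
  mae_before <- mean(abs(hairy$image$pixels - clean$image$pixels))
  mae_after <- mean(abs(repaired$pixels - clean$image$pixels))
  expect_lt(mae_after, mae_before)

  # intermediate stages retrievable
  stages <- attr(repaired, "stages")
  expect_named(stages, c("mask", "inpainted", "smoothed"))
  expect_s3_class(stages$mask, "hair_mask")

  # pixels outside the dilated mask untouched
  dil <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(stages$mask$mask * 1), EBImage::makeBrush(3, "box"))) > 0
  changed <- apply(abs(repaired$pixels - hairy$image$pixels), c(1, 2), max) > 1e-9
  expect_equal(sum(changed & !dil), 0)

  # idempotence tendency: repairing reduces residual hair coverage
  expect_lte(detect_hair_mask(repaired)$coverage,
             detect_hair_mask(hairy$image)$coverage)
})
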