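# The SDP descriptor: channel pairs, oriented responses, code images, DoG
# denoising, grid histograms and the assembled feature vector.

test_that("the six opponent channel pairs are formed correctly", {
  set.seed(1)
  tr <- make_triple(matrix(0.3, 8, 8), matrix(runif(64), 8, 8),
                    matrix(runif(64), 8, 8))
  pairs <- make_channel_pairs(tr)
  expect_length(pairs, 6)
  expect_equal(vapply(pairs, `[[`, character(1), "tag"),
               c("HH", "SS", "VV", "HS", "HV", "SV"))
  hh <- pairs[[1]]
  expect_identical(hh$center, hh$neighbor)
  hs <- pairs[[4]]
  expect_true(all(hs$center == 0.3))
  expect_identical(hs$neighbor, tr$c2)
  # analogous tags for the other spaces
  rgb <- make_channel_pairs(make_triple(tr$c1, tr$c2, tr$c3, "RGB"))
  expect_equal(vapply(rgb, `[[`, character(1), "tag"),
               c("RR", "GG", "BB", "RG", "RB", "GB"))
})

test_that("pair responses equal the brute-force block loop", {
  bank <- build_mask_bank(0.6, 3.5, "left")
  const_pair <- make_channel_pairs(make_triple(matrix(0.4, 8, 8)))[[1]]
  expect_equal(pair_response(const_pair, bank$kernels$theta90),
               matrix(0, 8, 8), tolerance = 1e-12)

  set.seed(5)
  for (rep in 1:10) {
    ctr <- matrix(runif(64), 8, 8); nbr <- matrix(runif(64), 8, 8)
    pair <- structure(list(center = ctr, neighbor = nbr, tag = "HS"),
                      class = "channel_pair")
    k <- bank$kernels[[sample(8, 1)]]
    expect_equal(pair_response(pair, k), oracle_pair_response(ctr, nbr, k))
  }
})

test_that("the horizontal kernel wins on a vertical step edge", {
  step <- matrix(0, 12, 12); step[, 7:12] <- 1
  pair <- make_channel_pairs(make_triple(step))[[1]]
  bank <- build_mask_bank(1, 1, "left")
  on_edge <- vapply(bank$kernels, function(k) {
    abs(pair_response(pair, k)[6, 6])  # column adjacent to the step
  }, numeric(1))
  # the horizontal-gradient kernel attains the maximum (theta = 180 ties by
  # symmetry); the vertical-gradient kernel responds strictly less
  expect_equal(on_edge[[which(bank$thetas == 360)]], max(on_edge))
  expect_gt(on_edge[[which(bank$thetas == 360)]],
            on_edge[[which(bank$thetas == 90)]])
})

test_that("maximum-response code images match the 16-kernel loop", {
  bl <- build_mask_bank(0.5, 3.5, "left")
  br <- build_mask_bank(0.5, 3.5, "right")
  const_pair <- make_channel_pairs(make_triple(matrix(0.7, 9, 9)))[[1]]
  expect_equal(max_response_code(const_pair, bl, br)$values, matrix(0, 9, 9))

  set.seed(6)
  for (rep in 1:5) {
    ctr <- matrix(runif(81), 9, 9); nbr <- matrix(runif(81), 9, 9)
    pair <- structure(list(center = ctr, neighbor = nbr, tag = "HS"),
                      class = "channel_pair")
    code <- max_response_code(pair, bl, br)
    expect_equal(code$values, oracle_max_response(ctr, nbr, bl, br))
    expect_true(all(code$values >= 0 & code$values <= 1))

    # scale invariance: doubling both planes leaves the code unchanged
    pair2 <- structure(list(center = 2 * ctr, neighbor = 2 * nbr, tag = "HS"),
                       class = "channel_pair")
    expect_equal(max_response_code(pair2, bl, br)$values, code$values)
  }

  mismatched <- build_mask_bank(0.5, 7, "right")
  expect_error(max_response_code(const_pair, bl, mismatched),
               class = "sdpskin_validation_error")
})

test_that("the DoG kernel and filter behave as defined", {
  # equal sigmas (internal construction) give the identically zero kernel
  expect_equal(sdpskin:::dog_kernel(2, 2), matrix(0, 13, 13))
  # near-zero DC at the default truncation
  expect_lt(abs(sum(sdpskin:::dog_kernel(2, 1))), 1e-6)

  # unit impulse: pre-rescale centre response equals D(0, 0)
  imp <- matrix(0, 15, 15); imp[8, 8] <- 1
  k <- sdpskin:::dog_kernel(1.5, 0.8)
  ctr_val <- sdpskin:::correlate2d(imp, k)[8, 8]
  expect_equal(ctr_val, k[(nrow(k) + 1) / 2, (ncol(k) + 1) / 2])

  code <- structure(list(values = imp, pair_tag = "t"), class = "code_image")
  out <- dog_denoise(code, 1.5, 0.8)
  expect_true(all(out$values >= 0 & out$values <= 1))
  expect_error(dog_denoise(code, 1, 2), class = "sdpskin_validation_error")

  # constant input maps to all zeros after rescaling
  const_code <- structure(list(values = matrix(0.5, 12, 12), pair_tag = "t"),
                          class = "code_image")
  expect_equal(dog_denoise(const_code, 1.5, 0.8)$values, matrix(0, 12, 12))
})

test_that("grid histograms equal the brute-force binning loop", {
  zero <- structure(list(values = matrix(0, 10, 10), pair_tag = "t"),
                    class = "code_image")
  h <- grid_histogram_features(zero, grid = 2, bins = 4)
  expect_equal(h, rep(c(1, 0, 0, 0), 4))
  expect_length(grid_histogram_features(zero, grid = 3, bins = 5), 45)

  set.seed(8)
  for (rep in 1:10) {
    n <- sample(7:15, 1)
    vals <- matrix(runif(n * n), n, n)
    code <- structure(list(values = vals, pair_tag = "t"), class = "code_image")
    g <- sample(2:3, 1); b <- sample(3:8, 1)
    got <- grid_histogram_features(code, g, b)
    expect_equal(got, oracle_grid_hist(vals, g, b))
    # each per-cell block sums to one
    blocks <- matrix(got, nrow = b)
    expect_equal(colSums(blocks), rep(1, g^2))
  }
  expect_error(grid_histogram_features(zero, grid = 20, bins = 4),
               class = "sdpskin_validation_error")
})

test_that("feature vectors have the documented layout and length", {
  set.seed(9)
  img <- rgb_image(array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3)))
  f1 <- extract_sdp(img, sdp_config())
  expect_length(f1, 6 * 16 * 16)
  expect_equal(length(f1), sdp_feature_length(sdp_config()))
  f3 <- extract_sdp(img, sdp_config(spaces = c("RGB", "HSV", "YCbCr"),
                                    grid = 2, bins = 4))
  expect_length(f3, 3 * 6 * 4 * 4)
  layout <- attr(f3, "layout")
  expect_equal(unique(layout$space), c("RGB", "HSV", "YCbCr"))
})

test_that("code images are invariant to illumination offset", {
  set.seed(10)
  c1 <- matrix(runif(144, 0.2, 0.6), 12, 12)
  c2 <- matrix(runif(144, 0.2, 0.6), 12, 12)
  bl <- build_mask_bank(0.5, 3.5, "left"); br <- build_mask_bank(0.5, 3.5, "right")
  pair <- structure(list(center = c1, neighbor = c2, tag = "HS"),
                    class = "channel_pair")
  shifted <- structure(list(center = c1 + 0.1, neighbor = c2 + 0.1, tag = "HS"),
                       class = "channel_pair")
  expect_equal(max_response_code(shifted, bl, br)$values,
               max_response_code(pair, bl, br)$values)

  # and the full feature vector under a global offset of all channels
  tr <- make_triple(c1, c2, matrix(runif(144, 0.2, 0.6), 12, 12))
  tr_off <- make_triple(tr$c1 + 0.1, tr$c2 + 0.1, tr$c3 + 0.1)
  cfg <- sdp_config(grid = 2, bins = 8)
  expect_equal(extract_sdp(tr_off, cfg), extract_sdp(tr, cfg),
               ignore_attr = TRUE)
})

test_that("the alpha = 1 pipeline equals one built from classical Sobel kernels", {
  sobel_x <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  manual_bank <- function(sign) {
    thetas <- c(45, 90, 135, 180, 225, 270, 315, 360)
    kernels <- lapply(thetas, function(th) {
      sdpskin:::rotate_kernel45(sign * 3.5 * sobel_x, (th / 45) %% 8)
    })
    names(kernels) <- paste0("theta", thetas)
    structure(list(alpha = 1, lam = 3.5, side = if (sign > 0) "left" else "right",
                   thetas = thetas, kernels = kernels), class = "mask_bank")
  }
  set.seed(11)
  ctr <- matrix(runif(100), 10, 10); nbr <- matrix(runif(100), 10, 10)
  pair <- structure(list(center = ctr, neighbor = nbr, tag = "HS"),
                    class = "channel_pair")
  built <- max_response_code(pair, build_mask_bank(1, 3.5, "left"),
                             build_mask_bank(1, 3.5, "right"))
  manual <- max_response_code(pair, manual_bank(1), manual_bank(-1))
  expect_identical(built$values, manual$values)
})

test_that("rotating the input permutes the winning orientation", {
  set.seed(4)
  m <- matrix(runif(196), 14, 14)
  bl <- build_mask_bank(0.5, 3.5, "left"); br <- build_mask_bank(0.5, 3.5, "right")
  o1 <- attr(max_response_code(make_channel_pairs(make_triple(m))[[1]], bl, br),
             "orientation")
  rot90 <- function(x) t(x)[, nrow(x):1, drop = FALSE]
  mr <- rot90(m)
  o2 <- attr(max_response_code(make_channel_pairs(make_triple(mr))[[1]], bl, br),
             "orientation")
  n <- nrow(m)
  shifts <- c()
  for (r in 4:(n - 3)) {
    for (cc in 4:(n - 3)) {
      a <- o1[r, cc]; b <- o2[cc, n + 1 - r]   # (r, c) -> (c, n + 1 - r)
      if ((a - 1) %% 2 == (b - 1) %% 2) {      # same mask side
        shifts <- c(shifts, ((b - 1) %/% 2 - (a - 1) %/% 2) %% 8)
      }
    }
  }
  # away from borders a quarter turn advances the compass by two 45-deg steps
  expect_gt(length(shifts), 20)
  expect_true(all(shifts == 2))
})
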