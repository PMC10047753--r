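# The Sobel Directional Pattern (SDP) descriptor: opponent colour-channel
# pairs, maximum response over the oriented fractional Sobel masks, DoG
# denoising of the code image, and grid histograms concatenated into a single
# feature vector.

#' SDP configuration
#'
#' @param spaces colour spaces to pool, subset of `c("RGB","HSV","YCbCr")`.
#' @param alpha fractional order of the Sobel masks.
#' @param lambdas gain values; with more than one, code images are max-pooled
#'   across the scales.
#' @param sigma1,sigma2 DoG standard deviations, `sigma1 > sigma2 > 0`.
#' @param grid cells per side for the grid histograms.
#' @param bins histogram bins per cell.
#' @return parameter list of class `sdp_config`.
#' @export
sdp_config <- function(spaces = "HSV", alpha = 0.5, lambdas = 3.5,
                       sigma1 = 2, sigma2 = 1, grid = 4, bins = 16) {
  if (!all(spaces %in% c("RGB", "HSV", "YCbCr"))) {
    stop_validation("spaces must be drawn from RGB, HSV, YCbCr")
  }
  structure(list(spaces = spaces, alpha = alpha, lambdas = lambdas,
                 sigma1 = sigma1, sigma2 = sigma2, grid = grid, bins = bins),
            class = "sdp_config")
}

#' Expected SDP feature length
#'
#' `n_spaces * 6 * grid^2 * bins` for the configured layout.
#'
#' @param config an [sdp_config()].
#' @return integer length.
#' @export
sdp_feature_length <- function(config = sdp_config()) {
  length(config$spaces) * 6L * config$grid^2 * config$bins
}

#' Form the six opponent channel pairs
#'
#' Centre and neighbour planes for the tags 11, 22, 33, 12, 13, 23 of a
#' channel triple (e.g. HH, SS, VV, HS, HV, SV for HSV): the centre pixel of
#' each 3 x 3 block is drawn from the first channel and its eight neighbours
#' from the second.
#'
#' @param triple a `channel_triple` from [convert_colorspace()].
#' @return list of six `channel_pair` objects (fields `center`, `neighbor`,
#'   `tag`).
#' @export
make_channel_pairs <- function(triple) {
  stopifnot(is_channel_triple(triple))
  chans <- list(triple$c1, triple$c2, triple$c3)
  if (!all(vapply(chans, function(m) identical(dim(m), dim(chans[[1]])),
                  logical(1)))) {
    stop_validation("channel dimensions differ")
  }
  nm <- triple$channel_names
  combos <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  lapply(combos, function(ix) {
    structure(list(center = chans[[ix[1]]], neighbor = chans[[ix[2]]],
                   tag = paste0(nm[ix[1]], nm[ix[2]])),
              class = "channel_pair")
  })
}

is_channel_pair <- function(x) inherits(x, "channel_pair")

#' Response of one oriented mask on a channel pair
#'
#' The response at (c, d) applies the kernel's off-centre weights to the
#' neighbour plane around (c, d) and the centre weight to the centre plane at
#' (c, d), with reflect padding at the borders.
#'
#' @param pair a `channel_pair`.
#' @param kernel a 3 x 3 kernel from a [build_mask_bank()].
#' @return numeric matrix of responses.
#' @export
pair_response <- function(pair, kernel) {
  stopifnot(is_channel_pair(pair))
  if (!identical(dim(pair$center), dim(pair$neighbor))) {
    stop_validation("pair planes have different dimensions")
  }
  if (min(dim(pair$center)) < nrow(kernel)) {
    stop_validation("kernel does not fit inside the image")
  }
  koff <- kernel
  kc <- koff[2, 2]
  koff[2, 2] <- 0
  correlate2d(pair$neighbor, koff) + kc * pair$center
}

#' Maximum-response code image
#'
#' Per pixel, the maximum over the 16 oriented responses (8 orientations of
#' the left bank and 8 of the right); ties are broken by the lowest
#' orientation index with the left side before the right. Negative maxima are
#' clamped to zero and the image is rescaled to `[0, 1]` by its maximum (an
#' all-zero response maps to all zeros). The winning response index is kept as
#' the `"orientation"` attribute.
#'
#' @param pair a `channel_pair`.
#' @param bank_left,bank_right left/right [build_mask_bank()]s sharing
#'   `alpha` and `lam`.
#' @return a `code_image`: list with `values` in `[0, 1]` and `pair_tag`.
#' @export
max_response_code <- function(pair, bank_left, bank_right) {
  stopifnot(is_mask_bank(bank_left), is_mask_bank(bank_right))
  if (bank_left$alpha != bank_right$alpha || bank_left$lam != bank_right$lam) {
    stop_validation("banks must share alpha and lambda")
  }
  d <- dim(pair$center)
  best <- matrix(-Inf, d[1], d[2])
  which_best <- matrix(0L, d[1], d[2])
  idx <- 0L
  for (o in seq_len(8)) {
    for (side in list(bank_left, bank_right)) {
      idx <- idx + 1L
      resp <- pair_response(pair, side$kernels[[o]])
      upd <- resp > best          # strict: ties keep the earlier index
      best[upd] <- resp[upd]
      which_best[upd] <- idx
    }
  }
  best[best < 0] <- 0
  mx <- max(best)
  # responses on constant inputs are pure rounding noise of the DC-free
  # kernels; treat them as an all-zero code image
  vals <- if (mx > 1e-12) best / mx else matrix(0, d[1], d[2])
  structure(list(values = vals, pair_tag = pair$tag),
            class = "code_image", orientation = which_best)
}

is_code_image <- function(x) inherits(x, "code_image")

# truncated difference-of-Gaussians kernel (no argument checks; the public
# entry point validates)
dog_kernel <- function(sigma1, sigma2) {
  rad <- ceiling(3 * sigma1)
  ax <- -rad:rad
  g <- function(s) {
    k <- outer(ax, ax, function(a, b) exp(-(a^2 + b^2) / (2 * s^2)))
    k / sum(k)
  }
  g(sigma1) - g(sigma2)
}

#' Difference-of-Gaussians denoising of a code image
#'
#' Convolves the code image with `D = G(sigma1) - G(sigma2)` (normalized
#' Gaussians truncated at radius `ceiling(3 * sigma1)`, reflect padding) and
#' rescales the result to `[0, 1]` by min-max; a constant result maps to all
#' zeros.
#'
#' @param code a `code_image`.
#' @param sigma1,sigma2 standard deviations with `sigma1 > sigma2 > 0`.
#' @return a `code_image`.
#' @export
dog_denoise <- function(code, sigma1 = 2, sigma2 = 1) {
  stopifnot(is_code_image(code))
  if (!(sigma1 > sigma2 && sigma2 > 0)) {
    stop_validation("require sigma1 > sigma2 > 0")
  }
  f <- correlate2d(code$values, dog_kernel(sigma1, sigma2))
  structure(list(values = rescale01(f), pair_tag = code$pair_tag),
            class = "code_image")
}

#' Grid histogram features of a code image
#'
#' Partitions the image into `grid x grid` cells (remainder pixels joining the
#' last row/column of cells) and histograms each cell into `bins` uniform bins
#' on `[0, 1]` (final bin right-closed), normalized to sum 1, concatenated
#' row-major.
#'
#' @param code a `code_image`.
#' @param grid cells per side, at least 1.
#' @param bins bins per cell, at least 2.
#' @return numeric vector of length `grid^2 * bins`.
#' @export
grid_histogram_features <- function(code, grid = 4, bins = 16) {
  stopifnot(is_code_image(code))
  if (grid < 1) stop_validation("grid must be at least 1")
  if (bins < 2) stop_validation("bins must be at least 2")
  h <- nrow(code$values); w <- ncol(code$values)
  if (h < grid || w < grid) stop_validation("image smaller than the grid")
  cell_edges <- function(n) {
    base <- n %/% grid
    starts <- (seq_len(grid) - 1) * base + 1
    ends <- c(starts[-1] - 1, n)
    list(starts = starts, ends = ends)
  }
  re <- cell_edges(h); ce <- cell_edges(w)
  out <- numeric(0)
  for (i in seq_len(grid)) {
    for (j in seq_len(grid)) {
      v <- code$values[re$starts[i]:re$ends[i], ce$starts[j]:ce$ends[j]]
      bin <- pmin(floor(v * bins) + 1L, bins)
      counts <- tabulate(bin, nbins = bins)
      out <- c(out, counts / sum(counts))
    }
  }
  out
}

#' Extract the SDP feature vector
#'
#' For each configured colour space and each of its six channel pairs:
#' maximum-response coding (max-pooled across the configured lambda scales),
#' DoG denoising, and grid histograms, concatenated in the order
#' spaces > pairs (11, 22, 33, 12, 13, 23) > cells (row-major) > bins.
#'
#' @param x an [rgb_image()], `skin_roi` or `channel_triple`. A channel
#'   triple restricts `config$spaces` to that triple's space.
#' @param config an [sdp_config()].
#' @return numeric feature vector with a `"layout"` attribute (tibble with one
#'   row per histogram block: space, pair, cell, offset).
#' @export
extract_sdp <- function(x, config = sdp_config()) {
  stopifnot(inherits(config, "sdp_config"))
  triples <- if (is_channel_triple(x)) {
    stats::setNames(list(x), x$space)
  } else {
    img <- if (is_skin_roi(x)) x$image else x
    stopifnot(is_rgb_image(img))
    stats::setNames(lapply(config$spaces, function(s) convert_colorspace(img, s)),
                    config$spaces)
  }
  banks <- lapply(config$lambdas, function(l) {
    list(left = build_mask_bank(config$alpha, l, "left"),
         right = build_mask_bank(config$alpha, l, "right"))
  })
  feats <- numeric(0)
  layout <- list()
  for (sp in names(triples)) {
    pairs <- make_channel_pairs(triples[[sp]])
    for (pair in pairs) {
      codes <- lapply(banks, function(b) {
        max_response_code(pair, b$left, b$right)$values
      })
      pooled <- Reduce(pmax, codes)
      code <- structure(list(values = pooled, pair_tag = pair$tag),
                        class = "code_image")
      den <- dog_denoise(code, config$sigma1, config$sigma2)
      block <- grid_histogram_features(den, config$grid, config$bins)
      layout[[length(layout) + 1L]] <-
        tibble::tibble(space = sp, pair = pair$tag,
                       cell = seq_len(config$grid^2), offset = length(feats) +
                         (seq_len(config$grid^2) - 1L) * config$bins + 1L)
      feats <- c(feats, block)
    }
  }
  attr(feats, "layout") <- dplyr::bind_rows(layout)
  feats
}

#' SDP feature matrix for a set of images
#'
#' @param images list of inputs accepted by [extract_sdp()].
#' @param config an [sdp_config()].
#' @return numeric matrix, one row per image.
#' @export
sdp_feature_matrix <- function(images, config = sdp_config()) {
  rows <- lapply(images, function(im) as.numeric(extract_sdp(im, config)))
  do.call(rbind, rows)
}
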