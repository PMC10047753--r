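# Classical lesion segmentation: Otsu threshold on luminance (lesion = darker
# side), opening/closing, border-component rejection, region growing from the
# darkest decile seeds and hole filling. An externally supplied mask can stand
# in for any other segmenter (e.g. a semantic-segmentation network) through
# `lesion_mask()`.

#' Segmentation configuration
#'
#' @param disc_radius radius (px) of the disc used for morphological opening
#'   and closing.
#' @param tolerance region-growing tolerance on normalized luminance.
#' @param min_area minimum lesion area in pixels.
#' @param pad default ROI padding in pixels.
#' @return parameter list.
#' @export
segment_config <- function(disc_radius = 5, tolerance = 0.08, min_area = 200,
                           pad = 10) {
  list(disc_radius = disc_radius, tolerance = tolerance, min_area = min_area,
       pad = pad)
}

#' Construct a lesion mask
#'
#' Validates that the binary mask has exactly one connected component and
#' derives its area and tight bounding box (half-open on the max edges).
#'
#' @param mask binary H x W matrix, 1 = lesion.
#' @param min_area minimum component area.
#' @return a `lesion_mask`: list with `mask`, `area`, `bbox`
#'   `(row_min, col_min, row_max, col_max)`.
#' @export
lesion_mask <- function(mask, min_area = 1) {
  mask <- (mask != 0) * 1L
  if (!any(mask == 1)) stop_validation("empty lesion mask")
  lab <- from_eb(EBImage::bwlabel(as_eb(mask)))
  if (max(lab) != 1) stop_validation("lesion mask must be a single connected component")
  area <- sum(mask)
  if (area < min_area) stop_validation("lesion component smaller than min_area")
  idx <- which(mask == 1, arr.ind = TRUE)
  bbox <- c(row_min = min(idx[, 1]), col_min = min(idx[, 2]),
            row_max = max(idx[, 1]) + 1L, col_max = max(idx[, 2]) + 1L)
  structure(list(mask = mask, area = area, bbox = bbox), class = "lesion_mask")
}

is_lesion_mask <- function(x) inherits(x, "lesion_mask")

# luminance in [0,1]: Y of the BT.601 YCbCr transform
luminance01 <- function(img) convert_colorspace(img, "YCbCr")$c1

#' Segment the lesion
#'
#' Otsu threshold on the luminance channel with the lesion on the darker side,
#' morphological opening then closing with a disc, retention of the largest
#' connected component that does not touch two or more image borders, region
#' growing from the component's darkest-decile seeds with tolerance
#' `config$tolerance`, and hole filling.
#'
#' @param img an [rgb_image()], normally hair-removed.
#' @param config see [segment_config()].
#' @return a [lesion_mask()].
#' @export
segment_lesion <- function(img, config = segment_config()) {
  stopifnot(is_rgb_image(img))
  lum <- luminance01(img)
  if (max(lum) - min(lum) < 1e-9) stop_validation("no lesion found: uniform image")
  thr <- EBImage::otsu(as_eb(lum), range = range(lum))
  dark <- (lum < thr) * 1
  brush <- EBImage::makeBrush(2 * config$disc_radius + 1, shape = "disc")
  dark <- from_eb(EBImage::opening(as_eb(dark), brush))
  dark <- from_eb(EBImage::closing(as_eb(dark), brush))
  lab <- from_eb(EBImage::bwlabel(as_eb(dark)))
  n <- max(lab)
  if (n == 0) stop_validation("no lesion found")
  h <- nrow(lum); w <- ncol(lum)
  borders_touched <- function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    sum(c(any(idx[, 1] == 1), any(idx[, 1] == h),
          any(idx[, 2] == 1), any(idx[, 2] == w)))
  }
  areas <- tabulate(lab[lab > 0], nbins = n)
  ok <- which(vapply(seq_len(n), borders_touched, numeric(1)) < 2)
  ok <- ok[areas[ok] >= config$min_area]
  if (!length(ok)) stop_validation("no lesion found")
  k <- ok[which.max(areas[ok])]
  comp <- lab == k
  # region growing from the darkest decile of the component
  seeds <- comp & (lum <= stats::quantile(lum[comp], 0.1))
  ref <- mean(lum[seeds])
  admissible <- lum <= ref + config$tolerance
  grown <- seeds
  box <- EBImage::makeBrush(3, "box")
  repeat {
    nxt <- (from_eb(EBImage::dilate(as_eb(grown * 1), box)) > 0) & admissible
    if (all(nxt == grown)) break
    grown <- nxt
  }
  grown <- grown | comp
  grown <- from_eb(EBImage::fillHull(as_eb(grown * 1))) > 0
  lab2 <- from_eb(EBImage::bwlabel(as_eb(grown * 1)))
  areas2 <- tabulate(lab2[lab2 > 0], nbins = max(lab2))
  final <- (lab2 == which.max(areas2)) * 1L
  if (sum(final) < config$min_area) stop_validation("no lesion found")
  lesion_mask(final, min_area = config$min_area)
}

#' Extract the region of interest
#'
#' Crops the image to the mask's bounding box expanded by `pad` (clipped to
#' the image) and zeroes every pixel outside the lesion.
#'
#' @param img an [rgb_image()].
#' @param mask a [lesion_mask()] of matching dimensions.
#' @param pad non-negative padding in pixels.
#' @return a `skin_roi`: list with `image` (masked crop), `mask` (cropped
#'   binary mask) and `bbox` (the crop window in full-image coordinates,
#'   half-open max edges).
#' @export
extract_roi <- function(img, mask, pad = 10) {
  stopifnot(is_rgb_image(img), is_lesion_mask(mask))
  if (!identical(dim(mask$mask), c(img$height, img$width))) {
    stop_validation("mask dimensions do not match the image")
  }
  if (pad < 0) stop_validation("pad must be non-negative")
  bb <- mask$bbox
  r0 <- max(1L, bb[["row_min"]] - pad)
  c0 <- max(1L, bb[["col_min"]] - pad)
  r1 <- min(img$height + 1L, bb[["row_max"]] + pad)
  c1 <- min(img$width + 1L, bb[["col_max"]] + pad)
  rows <- r0:(r1 - 1L); cols <- c0:(c1 - 1L)
  sub <- img$pixels[rows, cols, , drop = FALSE]
  msub <- mask$mask[rows, cols, drop = FALSE]
  for (ch in 1:3) sub[, , ch] <- sub[, , ch] * msub
  structure(list(image = rgb_image(sub), mask = msub,
                 bbox = c(row_min = r0, col_min = c0, row_max = r1, col_max = c1)),
            class = "skin_roi")
}

is_skin_roi <- function(x) inherits(x, "skin_roi")
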