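# DullRazor-style hair artifact removal: dark hairs are detected as pixels
# raised by broad grayscale closings with oriented line structuring elements,
# validated as thin elongated components, repaired by interpolation across the
# hair, then smoothed with an adaptive median filter confined to the repair.

#' Hair removal configuration
#'
#' @param closing_length length (odd, >= 3) of the linear structuring elements
#'   used for grayscale closing; default 9 px.
#' @param threshold detection threshold on the closing residual, 8-bit scale.
#' @param max_window largest adaptive-median window (odd).
#' @param min_elongation minimum length/width ratio for a component to count
#'   as hair.
#' @param max_width maximum mean width (px) for a hair component.
#' @return a list of parameters.
#' @export
hair_config <- function(closing_length = 9, threshold = 10, max_window = 7,
                        min_elongation = 5, max_width = 5) {
  list(closing_length = closing_length, threshold = threshold,
       max_window = max_window, min_elongation = min_elongation,
       max_width = max_width)
}

# Oriented linear structuring element: a length-`len` line of ones at 0, 45,
# 90 or 135 degrees embedded in the smallest odd-sided matrix.
line_brush <- function(len, angle) {
  switch(as.character(angle),
         "0" = matrix(1, 1, len),
         "90" = matrix(1, len, 1),
         "45" = { m <- diag(len); m[, len:1] },
         "135" = diag(len),
         stop_validation("angle must be one of 0, 45, 90, 135"))
}

# Per-component shape statistics. A hair is a thin ribbon, for which the
# perimeter is about twice the medial-axis length, so mean width =
# 2 * area / perimeter is robust to curvature (a moment-based major axis is
# not); skeleton length = area / width. The principal-axis angle from image
# moments still gives the local orientation used for inpainting.
component_shape_stats <- function(lab) {
  n <- max(lab)
  if (n == 0) return(NULL)
  # 4-neighbour boundary count as the perimeter estimate
  pad <- matrix(0L, nrow(lab) + 2, ncol(lab) + 2)
  pad[2:(nrow(lab) + 1), 2:(ncol(lab) + 1)] <- lab
  core <- pad[2:(nrow(lab) + 1), 2:(ncol(lab) + 1)]
  boundary <- core > 0 &
    (pad[1:nrow(lab), 2:(ncol(lab) + 1)] != core |
       pad[3:(nrow(lab) + 2), 2:(ncol(lab) + 1)] != core |
       pad[2:(nrow(lab) + 1), 1:ncol(lab)] != core |
       pad[2:(nrow(lab) + 1), 3:(ncol(lab) + 2)] != core)
  perim <- tabulate(lab[boundary], nbins = n)
  idx <- which(lab > 0, arr.ind = TRUE)
  comp <- lab[lab > 0]
  out <- vector("list", n)
  for (k in seq_len(n)) {
    pts <- idx[comp == k, , drop = FALSE]
    area <- nrow(pts)
    mu <- colMeans(pts)
    dr <- pts[, 1] - mu[1]; dc <- pts[, 2] - mu[2]
    crr <- mean(dr^2) + 1 / 12; ccc <- mean(dc^2) + 1 / 12; crc <- mean(dr * dc)
    angle <- 0.5 * atan2(2 * crc, crr - ccc)  # major-axis direction
    width <- 2 * area / max(perim[k], 1)
    len <- area / max(width, 1e-9)
    out[[k]] <- list(area = area, length = len, width = width,
                     elongation = len / max(width, 1e-9), angle = angle,
                     centroid = mu)
  }
  out
}

#' Detect dark hair strokes
#'
#' Applies grayscale morphological closing with linear structuring elements at
#' 0, 45, 90 and 135 degrees to each colour channel, takes the maximum closing
#' residual over orientations and channels, thresholds it, and keeps only
#' connected components validated as thin and extended (elongation at least
#' `min_elongation` and mean width at most `max_width`).
#'
#' @param img an [rgb_image()].
#' @param config see [hair_config()].
#' @return a `hair_mask`: list with binary `mask` (1 = hair) and `coverage`
#'   (flagged fraction).
#' @export
detect_hair_mask <- function(img, config = hair_config()) {
  stopifnot(is_rgb_image(img))
  len <- config$closing_length
  if (len < 3 || len %% 2 == 0) stop_validation("closing_length must be odd and >= 3")
  if (len > min(img$height, img$width)) {
    stop_validation("structuring element larger than the image")
  }
  thr <- config$threshold
  if (thr <= 0 || thr >= 255) stop_validation("threshold must lie in (0, 255)")
  resid <- matrix(0, img$height, img$width)
  for (ch in 1:3) {
    x <- img$pixels[, , ch]
    for (ang in c(0, 45, 90, 135)) {
      se <- line_brush(len, ang)
      closed <- from_eb(EBImage::closing(as_eb(x / 255), se)) * 255
      resid <- pmax(resid, closed - x)
    }
  }
  cand <- resid > thr
  mask <- matrix(0L, img$height, img$width)
  if (any(cand)) {
    lab <- from_eb(EBImage::bwlabel(as_eb(cand * 1)))
    stats <- component_shape_stats(lab)
    keep <- which(vapply(stats, function(s) {
      s$elongation >= config$min_elongation && s$width <= config$max_width
    }, logical(1)))
    if (length(keep)) mask[lab %in% keep] <- 1L
  }
  structure(list(mask = mask, coverage = mean(mask)), class = "hair_mask")
}

is_hair_mask <- function(x) inherits(x, "hair_mask")

#' Inpaint flagged hair pixels
#'
#' Each flagged pixel is replaced by linear interpolation between the nearest
#' unflagged pixels on either side along the minor axis of its connected
#' component (i.e. across, not along, the hair), estimated from image moments.
#' If support exists on only one side the nearest unflagged value is used.
#'
#' @param img an [rgb_image()].
#' @param mask a `hair_mask` matching the image dimensions.
#' @return an `rgb_image` with flagged pixels repaired.
#' @export
inpaint_hair <- function(img, mask) {
  stopifnot(is_rgb_image(img), is_hair_mask(mask))
  m <- mask$mask
  if (!identical(dim(m), c(img$height, img$width))) {
    stop_validation("mask dimensions do not match the image")
  }
  if (all(m == 1)) stop_validation("mask flags every pixel; nothing to interpolate from")
  if (!any(m == 1)) return(img)
  px <- img$pixels
  h <- img$height; w <- img$width
  lab <- from_eb(EBImage::bwlabel(as_eb(m * 1)))
  stats <- component_shape_stats(lab)
  flagged <- which(m == 1, arr.ind = TRUE)
  comp_of <- lab[m == 1]
  max_step <- max(h, w)
  for (n in seq_len(nrow(flagged))) {
    r0 <- flagged[n, 1]; c0 <- flagged[n, 2]
    ang <- stats[[comp_of[n]]]$angle + pi / 2   # minor axis: across the hair
    dr <- cos(ang); dc <- sin(ang)
    hit <- function(sgn) {
      for (t in seq_len(max_step)) {
        rr <- as.integer(round(r0 + sgn * t * dr))
        cc <- as.integer(round(c0 + sgn * t * dc))
        if (rr < 1 || rr > h || cc < 1 || cc > w) return(NULL)
        if (m[rr, cc] == 0) return(list(d = t, r = rr, c = cc))
      }
      NULL
    }
    a <- hit(1); b <- hit(-1)
    for (ch in 1:3) {
      va <- if (!is.null(a)) px[a$r, a$c, ch] else NA_real_
      vb <- if (!is.null(b)) px[b$r, b$c, ch] else NA_real_
      val <- if (!is.null(a) && !is.null(b)) {
        (vb * a$d + va * b$d) / (a$d + b$d)
      } else if (!is.null(a)) va else if (!is.null(b)) vb else {
        # no support along the minor axis: nearest unflagged pixel overall
        free <- which(m == 0, arr.ind = TRUE)
        i <- which.min((free[, 1] - r0)^2 + (free[, 2] - c0)^2)
        px[free[i, 1], free[i, 2], ch]
      }
      px[r0, c0, ch] <- val
    }
  }
  rgb_image(pmin(pmax(px, 0), 255))
}

#' Adaptive median smoothing inside the hair region
#'
#' Only pixels inside the 1-px-dilated mask are filtered. For each such pixel
#' the window grows from 3 up to `max_window` until the window median lies
#' strictly between the window minimum and maximum; the pixel is then replaced
#' by that median (at `max_window`, by the final median regardless).
#'
#' @param img an [rgb_image()].
#' @param mask a `hair_mask`.
#' @param max_window odd window bound, >= 3.
#' @return an `rgb_image`.
#' @export
adaptive_median_smooth <- function(img, mask, max_window = 7) {
  stopifnot(is_rgb_image(img), is_hair_mask(mask))
  if (max_window < 3 || max_window %% 2 == 0) {
    stop_validation("max_window must be odd and >= 3")
  }
  m <- mask$mask
  if (!identical(dim(m), c(img$height, img$width))) {
    stop_validation("mask dimensions do not match the image")
  }
  if (!any(m == 1)) return(img)
  region <- from_eb(EBImage::dilate(as_eb(m * 1), EBImage::makeBrush(3, "box"))) > 0
  px <- img$pixels
  h <- img$height; w <- img$width
  targets <- which(region, arr.ind = TRUE)
  for (ch in 1:3) {
    plane <- px[, , ch]
    out <- plane
    for (n in seq_len(nrow(targets))) {
      r0 <- targets[n, 1]; c0 <- targets[n, 2]
      for (win in seq(3, max_window, by = 2)) {
        rad <- (win - 1) %/% 2
        rs <- max(1, r0 - rad):min(h, r0 + rad)
        cs <- max(1, c0 - rad):min(w, c0 + rad)
        v <- plane[rs, cs]
        med <- stats::median(v)
        if ((med > min(v) && med < max(v)) || win == max_window) {
          out[r0, c0] <- med
          break
        }
      }
    }
    px[, , ch] <- out
  }
  rgb_image(px)
}

#' Remove hair artifacts
#'
#' Composition of [detect_hair_mask()], [inpaint_hair()] and
#' [adaptive_median_smooth()]. No pixel outside the dilated hair mask is
#' altered.
#'
#' @param img an [rgb_image()].
#' @param config see [hair_config()].
#' @param keep_stages if `TRUE`, attach the intermediate mask, inpainted and
#'   smoothed images as the `"stages"` attribute of the result.
#' @return an `rgb_image`.
#' @export
remove_hair <- function(img, config = hair_config(), keep_stages = FALSE) {
  mask <- detect_hair_mask(img, config)
  inpainted <- inpaint_hair(img, mask)
  smoothed <- if (mask$coverage > 0) {
    adaptive_median_smooth(inpainted, mask, config$max_window)
  } else inpainted
  if (keep_stages) {
    attr(smoothed, "stages") <- list(mask = mask, inpainted = inpainted,
                                     smoothed = smoothed)
  }
  smoothed
}
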