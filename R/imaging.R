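# Image containers and colour-space conversions. The package's universal
# carrier is an 8-bit three-channel raster stored as an H x W x 3 double array
# of values in [0, 255], row-major with origin top-left.

#' Construct an RGB image
#'
#' Validates and wraps an `H x W x 3` array of intensities in `[0, 255]`.
#' Grayscale matrices are replicated across the three channels. Images must be
#' at least 3 x 3 pixels because the descriptor operates on 3 x 3 blocks.
#'
#' @param pixels numeric `H x W x 3` array (or `H x W` matrix) in `[0, 255]`.
#' @return an object of class `rgb_image`.
#' @export
rgb_image <- function(pixels) {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop_validation("pixels must be an H x W x 3 array")
  }
  if (!all(is.finite(pixels))) stop_validation("pixel values must be finite")
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop_validation("pixel values must lie in [0, 255]")
  }
  d <- dim(pixels)
  if (d[1] < 3L || d[2] < 3L) {
    stop_validation("image must be at least 3 x 3 pixels")
  }
  structure(list(pixels = pixels, height = d[1], width = d[2]),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d, range [%.1f, %.1f]>\n",
              x$height, x$width, min(x$pixels), max(x$pixels)))
  invisible(x)
}

is_rgb_image <- function(x) inherits(x, "rgb_image")

#' Load a PNG or JPEG image
#'
#' Decodes an 8-bit PNG or JPEG file into an [rgb_image()]. Grayscale sources
#' are replicated to three channels; an alpha channel, if present, is dropped.
#'
#' @param path file path to a `.png`, `.jpg` or `.jpeg` file.
#' @return an `rgb_image`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop_io(paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           jpg = ,
           jpeg = jpeg::readJPEG(path),
           stop_validation(paste0("unsupported image format: ", path))),
    error = function(e) {
      if (inherits(e, "sdpskin_error")) rlang::cnd_signal(e)
      stop_io(paste0("cannot decode image: ", path))
    })
  if (length(raw) == 0) stop_validation(paste0("zero-sized image: ", path))
  if (length(dim(raw)) == 3L && dim(raw)[3] >= 3L) {
    raw <- raw[, , 1:3, drop = FALSE]
  }
  rgb_image(round(raw * 255))
}

#' Save an RGB image as PNG
#'
#' @param img an `rgb_image`.
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  stopifnot(is_rgb_image(img))
  png::writePNG(img$pixels / 255, target = path)
  invisible(path)
}

#' Resize an image with bilinear interpolation
#'
#' Default target is the pipeline's working size of 760 x 570 pixels
#' (width x height).
#'
#' @param img an `rgb_image`.
#' @param width,height target dimensions in pixels, both at least 3.
#' @return an `rgb_image` of exactly the requested size.
#' @export
resize_image <- function(img, width = 760, height = 570) {
  stopifnot(is_rgb_image(img))
  if (width < 3 || height < 3) stop_validation("target dimensions must be >= 3")
  if (width == img$width && height == img$height) return(img)
  out <- array(0, dim = c(height, width, 3L))
  for (ch in 1:3) {
    # rows are EBImage's first (x) axis under this package's conventions
    out[, , ch] <- from_eb(EBImage::resize(as_eb(img$pixels[, , ch] / 255),
                                           w = height, h = width))
  }
  rgb_image(pmin(pmax(out * 255, 0), 255))
}

#' Convert an image to a normalized channel triple
#'
#' Returns the three channels of the requested colour space, each rescaled to
#' `[0, 1]`. RGB returns the normalized input channels; HSV uses the standard
#' hexcone model (hue rescaled linearly from its angle, treated as an ordinary
#' linear channel); YCbCr uses the ITU-R BT.601 full-range transform.
#'
#' @param img an `rgb_image`.
#' @param space one of `"RGB"`, `"HSV"`, `"YCbCr"`.
#' @return a `channel_triple`: list with `space`, channel names, and matrices
#'   `c1`, `c2`, `c3` in `[0, 1]`.
#' @export
convert_colorspace <- function(img, space = c("RGB", "HSV", "YCbCr")) {
  stopifnot(is_rgb_image(img))
  if (!is.character(space) || !space[1] %in% c("RGB", "HSV", "YCbCr")) {
    stop_validation("space must be one of RGB, HSV, YCbCr")
  }
  space <- space[1]
  r <- img$pixels[, , 1]; g <- img$pixels[, , 2]; b <- img$pixels[, , 3]
  h <- img$height; w <- img$width
  shape <- function(v) matrix(v, h, w)
  chans <- switch(space,
    RGB = list(r / 255, g / 255, b / 255),
    HSV = {
      hsv <- grDevices::rgb2hsv(r = as.vector(r), g = as.vector(g),
                                b = as.vector(b), maxColorValue = 255)
      list(shape(hsv[1, ]), shape(hsv[2, ]), shape(hsv[3, ]))
    },
    YCbCr = {
      y  <- 0.299 * r + 0.587 * g + 0.114 * b
      # full-range chroma can reach 255.5 at saturated corners; clamp as the
      # 8-bit transform does
      cb <- pmin(pmax(128 - 0.168736 * r - 0.331264 * g + 0.5 * b, 0), 255)
      cr <- pmin(pmax(128 + 0.5 * r - 0.418688 * g - 0.081312 * b, 0), 255)
      list(y / 255, cb / 255, cr / 255)
    })
  names(chans) <- NULL
  channel_names <- switch(space,
    RGB = c("R", "G", "B"), HSV = c("H", "S", "V"), YCbCr = c("Y", "Cb", "Cr"))
  structure(list(space = space, channel_names = channel_names,
                 c1 = chans[[1]], c2 = chans[[2]], c3 = chans[[3]]),
            class = "channel_triple")
}

is_channel_triple <- function(x) inherits(x, "channel_triple")

#' @export
print.channel_triple <- function(x, ...) {
  cat(sprintf("<channel_triple %s (%s) %d x %d>\n", x$space,
              paste(x$channel_names, collapse = ","),
              nrow(x$c1), ncol(x$c1)))
  invisible(x)
}
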