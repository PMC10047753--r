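# Shared low-level helpers: validation, reflect padding and 2-D correlation.
# All rasters in the package are base matrices/arrays in (row, column) order,
# origin top-left, 0-based offsets in documentation but 1-based R indexing in
# code.

abort_sdp <- function(msg, class) {
  rlang::abort(msg, class = c(class, "sdpskin_error"))
}

stop_validation <- function(msg) abort_sdp(msg, "sdpskin_validation_error")
stop_io <- function(msg) abort_sdp(msg, "sdpskin_io_error")

#' Reflect-pad a matrix
#'
#' Pads by mirroring with edge duplication, i.e. `(b a | a b c | c b)` for a
#' pad of 2, matching the usual image-processing "reflect" convention. The pad
#' may not exceed the matrix extent.
#'
#' @param x numeric matrix.
#' @param pad non-negative integer pad width applied on all four sides.
#' @return the padded matrix.
#' @keywords internal
pad_reflect <- function(x, pad) {
  if (pad == 0) return(x)
  nr <- nrow(x); nc <- ncol(x)
  if (pad > nr || pad > nc) {
    stop_validation("pad exceeds matrix extent; reflect padding undefined")
  }
  ri <- c(pad:1, seq_len(nr), nr:(nr - pad + 1))
  ci <- c(pad:1, seq_len(nc), nc:(nc - pad + 1))
  x[ri, ci, drop = FALSE]
}

#' Reflect-padded 2-D correlation
#'
#' Correlates `x` with an odd-sided kernel (no flipping): the output at (r, c)
#' is `sum_k k(i, j) * x(r + i, c + j)` over kernel offsets, with reflect
#' padding at the borders. Implemented as a shift-and-sum over kernel entries,
#' which is exact and fast for the small kernels used here.
#'
#' @param x numeric matrix.
#' @param kernel odd-sided numeric matrix.
#' @return matrix of the same dimensions as `x`.
#' @keywords internal
correlate2d <- function(x, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  if (kr %% 2 == 0 || kc %% 2 == 0) stop_validation("kernel sides must be odd")
  r <- (kr - 1L) %/% 2L
  p <- pad_reflect(x, r)
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      w <- kernel[i, j]
      if (w == 0) next
      out <- out + w * p[i:(i + nr - 1L), j:(j + nc - 1L)]
    }
  }
  out
}

# Rescale a matrix to [0, 1] by its min-max; a constant matrix maps to zeros.
rescale01 <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(matrix(0, nrow(x), ncol(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

# Dice overlap between two binary masks.
#' Dice overlap between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; returns 1 when both masks are empty.
#'
#' @param a,b binary (0/1 or logical) matrices of equal dimensions.
#' @return scalar in \[0, 1\].
#' @export
dice_overlap <- function(a, b) {
  a <- a != 0; b <- b != 0
  if (!identical(dim(a), dim(b))) stop_validation("mask dimensions differ")
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

# EBImage round-trips: package rasters are (row, col); EBImage indexes (x, y)
# with x along the FIRST dim of the underlying array, so a plain matrix can be
# handed over as-is provided we are consistent in both directions.
as_eb <- function(m) EBImage::Image(m)
from_eb <- function(img) {
  m <- EBImage::imageData(img)
  dim(m) <- dim(m)[1:2]
  m
}
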