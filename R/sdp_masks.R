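# Fractional-order Sobel compass masks. The descriptor's oriented kernels are
# built from a 3 x 3 base kernel: the outer product of the Sobel smoothing
# weights (1, 2, 1) across rows with a 3-term Grunwald-Letnikov (GL)
# derivative stencil across columns, scaled by a gain lambda, rotated through
# eight 45-degree compass steps, and made DC-free by mean subtraction.

#' Grunwald-Letnikov fractional-difference coefficients
#'
#' Returns `w_j = (-1)^j * C(alpha, j)` for `j = 0..n_terms-1`, computed via
#' the stable product form of the generalized binomial coefficient. Order
#' `alpha = 1` reproduces the first difference `(1, -1, 0, ...)`; `w_0` is 1
#' for every order. The unit pixel step absorbs the `1/m^alpha` factor of the
#' continuous operator.
#'
#' @param alpha fractional order in `(0, 1]`.
#' @param n_terms number of series terms, at least 2.
#' @return object of class `gl_coefficients`: list with `alpha` and `terms`.
#' @export
gl_coefficients <- function(alpha, n_terms = 3) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1) {
    stop_validation("alpha must lie in (0, 1]")
  }
  if (n_terms < 2) stop_validation("n_terms must be at least 2")
  j <- seq_len(n_terms) - 1
  binom <- vapply(j, function(jj) {
    if (jj == 0) 1 else prod(alpha - seq_len(jj) + 1) / factorial(jj)
  }, numeric(1))
  structure(list(alpha = alpha, terms = (-1)^j * binom),
            class = "gl_coefficients")
}

#' Orientation-to-offset map
#'
#' The eight compass orientations and their neighbour offsets `(i, j)` in
#' (row, column) order, one per 45-degree step.
#'
#' @return a tibble with columns `theta`, `i`, `j`.
#' @export
orientation_offsets <- function() {
  tibble::tibble(
    theta = c(45, 90, 135, 180, 225, 270, 315, 360),
    i = c(1L, 0L, -1L, -1L, -1L, 0L, 1L, 1L),
    j = c(1L, 1L, 1L, 0L, -1L, -1L, -1L, 0L))
}

# positions of the 8 outer cells of a 3 x 3 kernel, in ring order
ring_positions <- function() {
  cbind(r = c(1, 1, 1, 2, 3, 3, 3, 2), c = c(1, 2, 3, 3, 3, 2, 1, 1))
}

#' Rotate a 3 x 3 kernel by 45-degree steps
#'
#' Moves the eight outer entries `steps` positions along the index ring; the
#' centre entry is unchanged.
#'
#' @param k 3 x 3 matrix.
#' @param steps integer number of 45-degree steps.
#' @return rotated 3 x 3 matrix.
#' @keywords internal
rotate_kernel45 <- function(k, steps = 1) {
  ring <- ring_positions()
  vals <- k[ring]
  steps <- steps %% 8
  out <- k
  out[ring] <- vals[((seq_len(8) - 1 - steps) %% 8) + 1]
  out
}

#' Build a fractional Sobel mask bank
#'
#' The horizontal (theta = 360) base kernel is the outer product of the Sobel
#' smoothing weights (1, 2, 1) across rows with a GL derivative stencil across
#' columns. The three GL weights are assigned leading-to-trailing along the
#' derivative axis: the leading sample gets `w_0 = 1`, the trailing sample
#' `w_1 = -alpha`, and the residual weight `w_2 = alpha(alpha-1)/2` sits at
#' the centre, so `alpha = 1` reproduces the classical central-difference
#' Sobel kernel exactly. The left mask leads to the right (trailing/backward
#' offsets); the right mask is its mirror (leading/forward offsets). The bank
#' holds the eight 45-degree rotations, each multiplied by the gain `lam` and
#' made DC-free by subtracting its mean.
#'
#' @param alpha fractional order in `(0, 1]`.
#' @param lam positive multiplicative gain.
#' @param side `"left"` or `"right"`.
#' @return a `mask_bank`: list with `alpha`, `lam`, `side`, `thetas` and
#'   `kernels` (named list of eight 3 x 3 matrices).
#' @export
build_mask_bank <- function(alpha, lam = 3.5, side = c("left", "right")) {
  side <- match.arg(side)
  if (!is.numeric(lam) || length(lam) != 1 || lam <= 0) {
    stop_validation("lam must be positive")
  }
  w <- gl_coefficients(alpha, 3)$terms
  # derivative stencil over column offsets (-1, 0, +1)
  d <- if (side == "left") c(w[2], w[3], w[1]) else c(w[1], w[3], w[2])
  base <- outer(c(1, 2, 1), d) * lam
  thetas <- c(45, 90, 135, 180, 225, 270, 315, 360)
  kernels <- lapply(thetas, function(th) {
    k <- rotate_kernel45(base, (th / 45) %% 8)
    k - mean(k)
  })
  names(kernels) <- paste0("theta", thetas)
  structure(list(alpha = alpha, lam = lam, side = side, thetas = thetas,
                 kernels = kernels),
            class = "mask_bank")
}

is_mask_bank <- function(x) inherits(x, "mask_bank")

#' @export
print.mask_bank <- function(x, ...) {
  cat(sprintf("<mask_bank alpha=%.3g lambda=%.3g side=%s, 8 orientations>\n",
              x$alpha, x$lam, x$side))
  invisible(x)
}
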