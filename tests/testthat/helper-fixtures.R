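# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately written as plain nested loops, independent of the package's
# vectorized implementations.

# reflect index with edge duplication: 0 -> 1, -1 -> 2, n+1 -> n, ...
refl_index <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# brute-force reflect-padded correlation of an arbitrary odd kernel
oracle_correlate <- function(x, kernel) {
  kr <- (nrow(kernel) - 1) / 2
  kc <- (ncol(kernel) - 1) / 2
  out <- matrix(0, nrow(x), ncol(x))
  for (r in seq_len(nrow(x))) {
    for (c in seq_len(ncol(x))) {
      acc <- 0
      for (i in -kr:kr) {
        for (j in -kc:kc) {
          acc <- acc + kernel[i + kr + 1, j + kc + 1] *
            x[refl_index(r + i, nrow(x)), refl_index(c + j, ncol(x))]
        }
      }
      out[r, c] <- acc
    }
  }
  out
}

# brute-force channel-pair response: off-centre kernel weights hit the
# neighbour plane, the centre weight hits the centre plane
oracle_pair_response <- function(center, neighbor, kernel) {
  out <- matrix(0, nrow(center), ncol(center))
  for (r in seq_len(nrow(center))) {
    for (c in seq_len(ncol(center))) {
      acc <- kernel[2, 2] * center[r, c]
      for (i in -1:1) {
        for (j in -1:1) {
          if (i == 0 && j == 0) next
          acc <- acc + kernel[i + 2, j + 2] *
            neighbor[refl_index(r + i, nrow(center)),
                     refl_index(c + j, ncol(center))]
        }
      }
      out[r, c] <- acc
    }
  }
  out
}

# brute-force maximum response over an explicit 16-kernel loop, with the
# package's clamping and max-normalization applied afterwards
oracle_max_response <- function(center, neighbor, bank_left, bank_right) {
  best <- matrix(-Inf, nrow(center), ncol(center))
  for (o in 1:8) {
    for (bank in list(bank_left, bank_right)) {
      resp <- oracle_pair_response(center, neighbor, bank$kernels[[o]])
      best <- pmax(best, resp)
    }
  }
  best[best < 0] <- 0
  mx <- max(best)
  if (mx > 0) best / mx else matrix(0, nrow(center), ncol(center))
}

# brute-force per-pixel grid histogram binning
oracle_grid_hist <- function(values, grid, bins) {
  h <- nrow(values); w <- ncol(values)
  bh <- h %/% grid; bw <- w %/% grid
  out <- numeric(0)
  for (i in seq_len(grid)) {
    for (j in seq_len(grid)) {
      r0 <- (i - 1) * bh + 1
      r1 <- if (i == grid) h else i * bh
      c0 <- (j - 1) * bw + 1
      c1 <- if (j == grid) w else j * bw
      counts <- numeric(bins)
      for (r in r0:r1) {
        for (c in c0:c1) {
          b <- min(floor(values[r, c] * bins) + 1, bins)
          counts[b] <- counts[b] + 1
        }
      }
      out <- c(out, counts / sum(counts))
    }
  }
  out
}

# scalar-loop RBM energy
oracle_rbm_energy <- function(W, b, cc, v, h) {
  acc <- 0
  for (i in seq_along(v)) {
    for (j in seq_along(h)) acc <- acc - v[i] * W[i, j] * h[j]
  }
  acc - sum(b * v) - sum(cc * h)
}

# brute-force adaptive median rule over every pixel of the dilated region
oracle_adaptive_median <- function(pixels, mask, max_window) {
  h <- nrow(mask); w <- ncol(mask)
  region <- matrix(FALSE, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      for (i in max(1, r - 1):min(h, r + 1)) {
        for (j in max(1, c - 1):min(w, c + 1)) {
          if (mask[i, j] == 1) region[r, c] <- TRUE
        }
      }
    }
  }
  out <- pixels
  for (ch in 1:3) {
    for (r in seq_len(h)) {
      for (c in seq_len(w)) {
        if (!region[r, c]) next
        for (win in seq(3, max_window, by = 2)) {
          rad <- (win - 1) / 2
          v <- pixels[max(1, r - rad):min(h, r + rad),
                      max(1, c - rad):min(w, c + rad), ch]
          med <- median(v)
          if ((med > min(v) && med < max(v)) || win == max_window) {
            out[r, c, ch] <- med
            break
          }
        }
      }
    }
  }
  out
}

# fixture: flat skin-toned image with five drawn dark strokes of width 2
stroke_fixture <- function(seed = 9, n = 120) {
  set.seed(seed)
  px <- array(210, c(n, n, 3))
  gt <- matrix(0L, n, n)
  for (s in 1:5) {
    r0 <- runif(1, 10, n - 10); c0 <- runif(1, 10, n - 10)
    ang <- runif(1, 0, 2 * pi)
    for (t in seq(0, 70, by = 0.5)) {
      rr <- round(r0 + t * cos(ang)); cc <- round(c0 + t * sin(ang))
      for (dr in 0:1) for (dc in 0:1) {
        r <- rr + dr; c <- cc + dc
        if (r >= 1 && r <= n && c >= 1 && c <= n) gt[r, c] <- 1L
      }
    }
  }
  for (ch in 1:3) {
    p <- px[, , ch]
    p[gt == 1] <- 35
    px[, , ch] <- p
  }
  list(img = rgb_image(px), gt = gt)
}

# fixture: constant-channel triple wrapper
make_triple <- function(c1, c2 = c1, c3 = c1, space = "HSV") {
  nm <- switch(space, HSV = c("H", "S", "V"), RGB = c("R", "G", "B"),
               YCbCr = c("Y", "Cb", "Cr"))
  structure(list(space = space, channel_names = nm, c1 = c1, c2 = c2, c3 = c3),
            class = "channel_triple")
}

# fixture: image with a filled dark disc on a bright background
disc_image <- function(n = 100, center = c(50, 50), radius = 20,
                       fg = 40, bg = 220) {
  px <- array(bg, c(n, n, 3))
  rows <- matrix(seq_len(n), n, n); cols <- t(rows)
  disc <- (rows - center[1])^2 + (cols - center[2])^2 <= radius^2
  for (ch in 1:3) {
    p <- px[, , ch]
    p[disc] <- fg
    px[, , ch] <- p
  }
  list(img = rgb_image(px), disc = disc * 1L)
}
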