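# Seeded generator of dermoscopy-like images with exact ground-truth lesion
# and hair masks. The generator parameterizes the clinical ABCD-style cues a
# lesion descriptor should respond to: border irregularity (radial sinusoid
# perturbation of an ellipse), hue multiplicity (number of sub-colours), and
# intra-lesion texture frequency.

#' Lesion class specification
#'
#' @param name class label.
#' @param border_irregularity amplitude of the radial boundary perturbation in
#'   `[0, 1]` (0 = exact ellipse).
#' @param n_hues number of lesion sub-colours, at least 1.
#' @param texture_freq spatial frequency (cycles/px) of the intra-lesion
#'   sinusoidal texture.
#' @param base_palette list of RGB tones (length-3 vectors, 0-255), one per
#'   hue (recycled if shorter than `n_hues`).
#' @param diameter_px mean lesion diameter in pixels, at least 8.
#' @return a `lesion_class_spec`.
#' @export
lesion_class_spec <- function(name, border_irregularity, n_hues, texture_freq,
                              base_palette, diameter_px) {
  if (diameter_px < 8) stop_validation("diameter_px must be at least 8")
  if (n_hues < 1) stop_validation("n_hues must be at least 1")
  structure(list(name = name, border_irregularity = border_irregularity,
                 n_hues = n_hues, texture_freq = texture_freq,
                 base_palette = base_palette, diameter_px = diameter_px),
            class = "lesion_class_spec")
}

#' Built-in three-class presets
#'
#' Specs mirroring the common nevus / atypical nevus / melanoma triad:
#' border irregularity, hue count and texture frequency increase strictly
#' from the nevus-like to the melanoma-like class, and the melanoma-like
#' palette adds dark and blue-grey tones.
#'
#' @return named list of three [lesion_class_spec()]s.
#' @export
ph2like_specs <- function() {
  list(
    `common-nevus-like` = lesion_class_spec(
      "common-nevus-like", border_irregularity = 0.05, n_hues = 1,
      texture_freq = 0.03,
      base_palette = list(c(125, 85, 60)), diameter_px = 48),
    `atypical-like` = lesion_class_spec(
      "atypical-like", border_irregularity = 0.18, n_hues = 2,
      texture_freq = 0.06,
      base_palette = list(c(110, 70, 50), c(160, 115, 85)), diameter_px = 54),
    `melanoma-like` = lesion_class_spec(
      "melanoma-like", border_irregularity = 0.38, n_hues = 4,
      texture_freq = 0.12,
      base_palette = list(c(60, 40, 35), c(105, 60, 45),
                          c(75, 75, 95), c(35, 28, 28)), diameter_px = 60))
}

# radius of an axis-aligned ellipse at polar angle phi
ellipse_radius <- function(rx, ry, phi) {
  rx * ry / sqrt((ry * cos(phi))^2 + (rx * sin(phi))^2)
}

#' Generate one synthetic dermoscopy-like sample
#'
#' Skin background = base tone + low-frequency illumination gradient +
#' Gaussian noise (sd 3 intensity levels). The lesion is a star-convex region
#' whose boundary radius is `r(phi) = R(phi) * (1 + irregularity * sum of
#' low-order sinusoids)` around an ellipse `R(phi)`; it is filled with
#' `n_hues` tones selected by smooth random fields and modulated by a
#' sinusoidal texture at `texture_freq`. Optionally 3-8 thin dark hair
#' strokes (random smooth curves, width 1-3 px) are drawn on top. Fully
#' seeded and reproducible.
#'
#' @param spec a [lesion_class_spec()].
#' @param size `c(H, W)` in pixels, each at least 64.
#' @param with_hair draw hair strokes?
#' @param seed RNG seed.
#' @return a `synthetic_sample`: list with `image` ([rgb_image()]),
#'   `lesion_mask`, `hair_mask`, `label`, `seed`, and `geometry` (drawn
#'   lesion centre and ellipse radii, for oracle checks against the analytic
#'   shape).
#' @export
generate_sample <- function(spec, size = c(128, 128), with_hair = FALSE,
                            seed = 0) {
  stopifnot(inherits(spec, "lesion_class_spec"))
  h <- size[1]; w <- size[2]
  if (h < 64 || w < 64) stop_validation("size must be at least 64 x 64")
  if (spec$diameter_px >= min(h, w)) {
    stop_validation("lesion larger than the image")
  }
  with_local_seed(seed, {
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    # skin background with smooth illumination gradient and noise
    base_tone <- c(225, 185, 165)
    grad_dir <- stats::runif(1, 0, 2 * pi)
    u <- (rows * cos(grad_dir) + cols * sin(grad_dir)) / max(h, w)
    illum <- 12 * u + 6 * sin(2 * pi * (0.7 * u + stats::runif(1)))
    px <- array(0, c(h, w, 3))
    for (ch in 1:3) {
      px[, , ch] <- base_tone[ch] + illum +
        matrix(stats::rnorm(h * w, sd = 3), h, w)
    }
    # lesion geometry
    cy <- h / 2 + stats::runif(1, -h / 16, h / 16)
    cx <- w / 2 + stats::runif(1, -w / 16, w / 16)
    ecc <- stats::runif(1, 0, 0.15)
    rx <- spec$diameter_px / 2 * (1 + ecc)
    ry <- spec$diameter_px / 2 / (1 + ecc)
    n_modes <- 4
    amps <- stats::runif(n_modes)
    amps <- amps / sum(amps)          # sum 1: radius stays positive
    phases <- stats::runif(n_modes, 0, 2 * pi)
    dy <- rows - cy; dx <- cols - cx
    phi <- atan2(dx, dy)
    wobble <- matrix(0, h, w)
    for (m in seq_len(n_modes)) {
      wobble <- wobble + amps[m] * sin((m + 1) * phi + phases[m])
    }
    rb <- ellipse_radius(rx, ry, phi) * (1 + spec$border_irregularity * wobble)
    dist <- sqrt(dy^2 + dx^2)
    lesion <- (dist <= rb) * 1L
    # hue fields and texture
    palette <- rep(spec$base_palette, length.out = spec$n_hues)
    hue_idx <- matrix(1L, h, w)
    if (spec$n_hues > 1) {
      score <- array(0, c(h, w, spec$n_hues))
      for (k in seq_len(spec$n_hues)) {
        th <- stats::runif(1, 0, pi)
        f <- stats::runif(1, 0.01, 0.03)
        score[, , k] <- sin(2 * pi * f * (rows * cos(th) + cols * sin(th)) +
                              stats::runif(1, 0, 2 * pi))
      }
      hue_idx <- apply(score, c(1, 2), which.max)
    }
    tex_th <- stats::runif(1, 0, pi)
    texture <- 1 + 0.18 * sin(2 * pi * spec$texture_freq *
                                (rows * cos(tex_th) + cols * sin(tex_th)) +
                                stats::runif(1, 0, 2 * pi))
    inside <- lesion == 1
    for (ch in 1:3) {
      tone <- matrix(vapply(as.vector(hue_idx), function(k) palette[[k]][ch],
                            numeric(1)), h, w)
      plane <- px[, , ch]
      plane[inside] <- (tone * texture)[inside] +
        stats::rnorm(sum(inside), sd = 3)
      px[, , ch] <- plane
    }
    # hair strokes
    hair <- matrix(0L, h, w)
    if (with_hair) {
      n_strokes <- sample(3:8, 1)
      for (s in seq_len(n_strokes)) {
        r0 <- stats::runif(1, 5, h - 5)
        c0 <- stats::runif(1, 5, w - 5)
        ang <- stats::runif(1, 0, 2 * pi)
        width <- sample(1:3, 1)
        len <- stats::runif(1, 0.5, 0.9) * min(h, w)
        steps <- ceiling(len * 2)
        rad <- width / 2
        for (t in seq_len(steps)) {
          ang <- ang + stats::rnorm(1, sd = 0.03)
          r0 <- r0 + 0.5 * cos(ang)
          c0 <- c0 + 0.5 * sin(ang)
          if (r0 < 1 || r0 > h || c0 < 1 || c0 > w) break
          rr <- max(1, floor(r0 - rad)):min(h, ceiling(r0 + rad))
          ccs <- max(1, floor(c0 - rad)):min(w, ceiling(c0 + rad))
          for (r in rr) for (cc in ccs) {
            if ((r - r0)^2 + (cc - c0)^2 <= rad^2 + 0.25) hair[r, cc] <- 1L
          }
        }
      }
      dark <- c(32, 26, 22)
      for (ch in 1:3) {
        plane <- px[, , ch]
        plane[hair == 1] <- dark[ch] + stats::rnorm(sum(hair), sd = 2)
        px[, , ch] <- plane
      }
    }
    # quantize to 8-bit levels so a PNG round-trip is lossless
    structure(list(image = rgb_image(round(pmin(pmax(px, 0), 255))),
                   lesion_mask = lesion, hair_mask = hair,
                   label = spec$name, seed = seed,
                   geometry = list(center = c(cy, cx), rx = rx, ry = ry)),
              class = "synthetic_sample")
  })
}

#' Generate a labelled synthetic dataset
#'
#' Draws `n_per_class` seeded samples per class spec, assigns hair strokes to
#' a `hair_fraction` of images, and builds a manifest with a stratified
#' train/test split. With `dir` set, images and 1-bit masks are written as
#' PNGs and the manifest as `manifest.csv` (columns path, label, split).
#'
#' @param class_specs named list of [lesion_class_spec()]s; default
#'   [ph2like_specs()].
#' @param n_per_class samples per class.
#' @param size image size `c(H, W)`.
#' @param hair_fraction fraction of images receiving hair strokes.
#' @param seed master seed; per-sample seeds are derived from it.
#' @param dir optional output directory.
#' @return list with `samples` (list of `synthetic_sample`) and `manifest`
#'   (tibble with path, label, split, with_hair, seed).
#' @export
generate_dataset <- function(class_specs = ph2like_specs(), n_per_class = 50,
                             size = c(128, 128), hair_fraction = 0.3,
                             seed = 0, dir = NULL) {
  if (n_per_class < 1) stop_validation("n_per_class must be at least 1")
  n_total <- n_per_class * length(class_specs)
  draws <- with_local_seed(seed, {
    list(seeds = sample.int(.Machine$integer.max - 1, n_total),
         hairy = stats::runif(n_total) < hair_fraction,
         test_pick = lapply(seq_along(class_specs), function(i) {
           sample.int(n_per_class, max(1, round(0.2 * n_per_class)))
         }))
  })
  samples <- vector("list", n_total)
  rows <- list()
  i <- 0L
  for (ci in seq_along(class_specs)) {
    spec <- class_specs[[ci]]
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      samples[[i]] <- generate_sample(spec, size,
                                      with_hair = draws$hairy[i],
                                      seed = draws$seeds[i])
      split <- if (j %in% draws$test_pick[[ci]]) "test" else "train"
      path <- sprintf("%s_%03d.png", gsub("[^a-z0-9]+", "_", spec$name), j)
      rows[[i]] <- tibble::tibble(path = path, label = spec$name,
                                  split = split,
                                  with_hair = draws$hairy[i],
                                  seed = draws$seeds[i])
    }
  }
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
      stop_io(paste0("cannot create output directory: ", dir))
    }
    for (i in seq_len(n_total)) {
      save_image(samples[[i]]$image, file.path(dir, manifest$path[i]))
      png::writePNG(samples[[i]]$lesion_mask * 1.0,
                    file.path(dir, sub("\\.png$", "_lesion_mask.png",
                                       manifest$path[i])))
      png::writePNG(samples[[i]]$hair_mask * 1.0,
                    file.path(dir, sub("\\.png$", "_hair_mask.png",
                                       manifest$path[i])))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(samples = samples, manifest = manifest)
}
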