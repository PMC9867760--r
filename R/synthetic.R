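# Seeded generator of colonoscopy-like frames with exact ground-truth
# masks, so the whole stack can be trained and evaluated without external
# downloads.
#
# A frame is a mucosa-toned textured background inside a circular dark
# vignette (the black border typical of endoscope optics), carrying 0-3
# polyp regions. Each polyp is a deformed ellipse: a circle perturbed by a
# low-order radial Fourier series, which yields the smooth blob-like
# boundaries real polyps show. Polyps get a tone shift (the configured
# contrast), their own texture and a soft specular highlight; the mask is
# the exact indicator of the polyp support.

#' Synthetic dataset configuration
#'
#' @param n number of images
#' @param img_size image side length in pixels
#' @param polyps integer range (min, max) of polyps per image
#' @param radius polyp base radius range as a fraction of the image side,
#'   each value in (0, 0.5)
#' @param boundary_wobble amplitude of the radial Fourier boundary
#'   perturbation (0 = perfect ellipses)
#' @param contrast additive intensity offset of the polyp region over the
#'   local background, in \[0, 1\] units
#' @param texture_sd pixelwise texture noise standard deviation
#' @param vignette strength of the circular border darkening in \[0, 1\]
#' @param seed RNG seed; the generator is fully deterministic given the
#'   seed
#' @return list of class `synth_config`
#' @export
synth_config <- function(n = 16L, img_size = 64L, polyps = c(0L, 3L),
                         radius = c(0.08, 0.22), boundary_wobble = 0.12,
                         contrast = 0.25, texture_sd = 0.03,
                         vignette = 0.6, seed = 1L) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (any(radius <= 0) || any(radius >= 0.5))
    stop("radius fractions must lie in (0, 0.5)", call. = FALSE)
  structure(list(n = as.integer(n), img_size = as.integer(img_size),
                 polyps = as.integer(polyps), radius = radius,
                 boundary_wobble = boundary_wobble, contrast = contrast,
                 texture_sd = texture_sd, vignette = vignette,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Smooth low-frequency noise field: coarse gaussian grid upsampled
# bilinearly to full resolution.
#' @keywords internal
smooth_noise <- function(size, coarse = 8L, sd = 1) {
  g <- array(stats::rnorm(coarse * coarse, 0, sd), c(1L, 1L, coarse, coarse))
  drop(ft_resize(g, size, size))
}

# Render one frame; returns list(image (h,w,3), mask (h,w)).
#' @keywords internal
synth_render_frame <- function(cfg) {
  s <- cfg$img_size
  xs <- matrix(rep(seq_len(s), each = s), s)      # column index per pixel
  ys <- matrix(rep(seq_len(s), times = s), s)     # row index per pixel
  cx <- (s + 1) / 2; cy <- (s + 1) / 2
  # mucosa-toned background with low-frequency mottling
  base <- c(0.72, 0.45, 0.40) + stats::rnorm(3L, 0, 0.03)
  mottle <- smooth_noise(s, sd = 0.06)
  img <- array(0, c(s, s, 3L))
  for (k in 1:3) img[, , k] <- base[k] + mottle + stats::rnorm(s * s, 0, cfg$texture_sd)
  # circular vignette: darken outside ~70% of the half-diagonal
  r_norm <- sqrt((ys - cy)^2 + (xs - cx)^2) / (s / 2)
  vig <- 1 - cfg$vignette * pmin(pmax((r_norm - 0.75) / 0.35, 0), 1)
  for (k in 1:3) img[, , k] <- img[, , k] * vig
  # polyps
  n_p <- sample(seq(cfg$polyps[1L], cfg$polyps[2L]), 1L)
  mask <- matrix(0, s, s)
  if (n_p > 0) for (p in seq_len(n_p)) {
    pcx <- stats::runif(1, 0.3, 0.7) * s
    pcy <- stats::runif(1, 0.3, 0.7) * s
    r0 <- stats::runif(1, cfg$radius[1L], cfg$radius[2L]) * s
    aspect <- stats::runif(1, 0.7, 1.3)
    rot <- stats::runif(1, 0, pi)
    amp <- stats::rnorm(3L, 0, cfg$boundary_wobble / c(1, 1.5, 2))
    phs <- stats::runif(3L, 0, 2 * pi)
    dx <- (xs - pcx) * cos(rot) + (ys - pcy) * sin(rot)
    dy <- -(xs - pcx) * sin(rot) + (ys - pcy) * cos(rot)
    rho <- sqrt((dx / aspect)^2 + (dy * aspect)^2)
    th <- atan2(dy, dx)
    rb <- r0 * (1 + amp[1] * cos(2 * th + phs[1]) + amp[2] * cos(3 * th + phs[2]) +
                  amp[3] * cos(4 * th + phs[3]))
    inside <- rho < rb
    mask[inside] <- 1
    # appearance: tone shift + own texture + soft specular highlight
    tone <- cfg$contrast * c(1.2, 0.9, 0.8) + stats::rnorm(3L, 0, 0.02)
    ptex <- stats::rnorm(sum(inside), 0, cfg$texture_sd)
    hx <- pcx + stats::runif(1, -0.3, 0.3) * r0
    hy <- pcy + stats::runif(1, -0.3, 0.3) * r0
    spec <- 0.25 * exp(-(((xs - hx)^2 + (ys - hy)^2) / (2 * (r0 / 3)^2)))
    for (k in 1:3) {
      ch <- img[, , k]
      ch[inside] <- ch[inside] + tone[k] + ptex
      ch <- ch + spec * mask * (rho < 0.8 * rb)
      img[, , k] <- ch
    }
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n` PNG image/mask pairs plus a `manifest.csv` (dialect of
#' [read_manifest()]) into `out_dir`. Fully deterministic: the same config
#' and seed produce byte-identical files.
#'
#' @param cfg a [synth_config()]
#' @param out_dir output directory (created if missing)
#' @return the manifest data.frame (also written to
#'   `out_dir/manifest.csv`)
#' @export
synth_generate <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create '%s'", out_dir), call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  image <- character(cfg$n); mask <- character(cfg$n)
  for (i in seq_len(cfg$n)) {
    fr <- synth_render_frame(cfg)
    image[i] <- file.path(out_dir, sprintf("img_%03d.png", i))
    mask[i] <- file.path(out_dir, sprintf("msk_%03d.png", i))
    png::writePNG(fr$image, image[i])
    png::writePNG(fr$mask, mask[i])
  }
  manifest <- new_manifest(image, mask, source = "synthetic", split = "train")
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Generate a synthetic dataset in memory
#'
#' Same renderer as [synth_generate()] without touching the filesystem.
#' @param cfg a [synth_config()]
#' @return list with `x` (n, 3, s, s) images in \[0, 1\] and `y`
#'   (n, 1, s, s) binary masks
#' @export
synth_arrays <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  s <- cfg$img_size
  x <- array(0, c(cfg$n, 3L, s, s))
  y <- array(0, c(cfg$n, 1L, s, s))
  for (i in seq_len(cfg$n)) {
    fr <- synth_render_frame(cfg)
    x[i, , , ] <- aperm(fr$image, c(3L, 1L, 2L))
    y[i, 1L, , ] <- fr$mask
  }
  list(x = x, y = y)
}
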