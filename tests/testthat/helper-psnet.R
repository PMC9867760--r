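# Shared fixtures and oracles for the test suite.

# Central-difference gradient of a scalar function of a flat numeric vector.
num_grad <- function(fn, x, eps = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}

# Check a module's analytic input and parameter gradients against central
# differences of sum(forward(x) * dy) with a fixed random dy. Activations
# have kinks, so comparison uses a mixed absolute/relative tolerance.
expect_gradients_match <- function(m, xdim, tol = 1e-4, eps = 1e-5, seed = 42) {
  set.seed(seed)
  set_training(m, TRUE)
  x <- array(rnorm(prod(xdim)), xdim)
  dy <- NULL
  lossfn <- function(xx) {
    y <- m$forward(xx)
    if (is.null(dy)) dy <<- array(rnorm(length(y)), dim(y))
    sum(y * dy)
  }
  invisible(lossfn(x))
  zero_grad(m)
  invisible(m$forward(x))
  dx <- m$backward(dy)
  gx <- num_grad(function(v) lossfn(array(v, xdim)), as.numeric(x), eps)
  scale_x <- max(abs(gx), 1)
  expect_lt(max(abs(as.numeric(dx) - gx)) / scale_x, tol)
  for (nm in names(module_parameters(m))) {
    p <- module_parameters(m)[[nm]]
    fn <- function(v) {
      old <- p$value
      p$value <- if (is.null(dim(old))) v else array(v, dim(old))
      on.exit(p$value <- old)
      lossfn(x)
    }
    gnum <- num_grad(fn, as.numeric(p$value), eps)
    scale_p <- max(abs(gnum), 1)
    expect_lt(max(abs(as.numeric(p$grad) - gnum)) / scale_p, tol,
              label = sprintf("gradient error for %s", nm))
  }
  invisible(TRUE)
}

# Brute-force quadruple-loop dense convolution oracle (stride 1).
loop_conv_oracle <- function(x, w, bias = NULL, pad = c(0, 0), dil = 1) {
  d <- dim(x); dw <- dim(w)
  xp <- array(0, c(d[1], d[2], d[3] + 2 * pad[1], d[4] + 2 * pad[2]))
  xp[, , pad[1] + seq_len(d[3]), pad[2] + seq_len(d[4])] <- x
  oh <- d[3] + 2 * pad[1] - dil * (dw[3] - 1)
  ow <- d[4] + 2 * pad[2] - dil * (dw[4] - 1)
  y <- array(0, c(d[1], dw[1], oh, ow))
  for (b in seq_len(d[1])) for (co in seq_len(dw[1])) for (i in seq_len(oh)) for (j in seq_len(ow)) {
    acc <- if (is.null(bias)) 0 else bias[co]
    for (ci in seq_len(d[2])) for (ki in seq_len(dw[3])) for (kj in seq_len(dw[4]))
      acc <- acc + xp[b, ci, i + (ki - 1) * dil, j + (kj - 1) * dil] * w[co, ci, ki, kj]
    y[b, co, i, j] <- acc
  }
  y
}

# Per-pixel loop oracle for the soft IoU loss on a single image.
loop_iou_loss_oracle <- function(xbar, y, eps = 1e-6) {
  p <- 1 / (1 + exp(-as.numeric(xbar)))
  yv <- as.numeric(y)
  I <- 0; P <- 0; G <- 0
  for (i in seq_along(p)) {
    I <- I + p[i] * yv[i]
    P <- P + p[i]
    G <- G + yv[i]
  }
  1 - (I + eps) / (P + G - I + eps)
}

# Tiny full-model fixture shared by several test files.
tiny_model <- function(variant = "full", seed = 7L) {
  build_variant(psnet_tiny_config(seed = seed), variant)
}

rand_image <- function(b = 1L, size = 64L, seed = 1L) {
  set.seed(seed)
  array(rnorm(b * 3 * size * size), c(b, 3L, size, size))
}
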