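# Low-level array operations for 4-D feature maps.
#
# A feature map is a plain numeric array indexed [batch, channel, height,
# width]. All operations here are pure functions; layer state (weights,
# caches) lives in the nn_* modules built on top (see nn-core.R).
#
# Convolutions are evaluated as matrix products against BLAS: dense
# convolutions through an im2col expansion, depthwise convolutions by
# accumulating shifted slices. Backward passes are exact transposes of the
# forward linear maps and are checked against finite differences in the
# test suite.

#' @keywords internal
ft_check_4d <- function(x, what = "input") {
  if (!is.array(x) || length(dim(x)) != 4L)
    stop(what, " must be a 4-D array (batch, channel, height, width)", call. = FALSE)
  invisible(x)
}

#' Zero-pad the spatial dimensions of a feature map
#' @keywords internal
ft_pad <- function(x, ph, pw) {
  if (ph == 0L && pw == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1L], d[2L], d[3L] + 2L * ph, d[4L] + 2L * pw))
  out[, , (ph + 1L):(ph + d[3L]), (pw + 1L):(pw + d[4L])] <- x
  out
}

#' Output length of a 1-D convolution
#' @keywords internal
conv_out_len <- function(n, k, s = 1L, p = 0L, d = 1L) {
  (n + 2L * p - d * (k - 1L) - 1L) %/% s + 1L
}

#' Dense 2-D convolution (cross-correlation), stride/padding/dilation
#'
#' im2col unfolding (compiled) followed by one BLAS matrix product.
#'
#' @param x feature map (b, cin, h, w)
#' @param w weights (cout, cin, kh, kw)
#' @param bias optional length-cout vector
#' @keywords internal
conv2d_dense <- function(x, w, bias = NULL, stride = 1L, pad = c(0L, 0L), dil = 1L) {
  dx <- dim(x); dw <- dim(w)
  if (dx[2L] != dw[2L])
    stop(sprintf("channel mismatch: input has shape (%s) but weights expect %d input channels (weight shape %s)",
                 paste(dx, collapse = ","), dw[2L], paste(dw, collapse = ",")), call. = FALSE)
  oh <- conv_out_len(dx[3L], dw[3L], stride, pad[1L], dil)
  ow <- conv_out_len(dx[4L], dw[4L], stride, pad[2L], dil)
  if (oh < 1L || ow < 1L)
    stop(sprintf("convolution output would be empty: input (%s), kernel (%d,%d), dilation %d",
                 paste(dx, collapse = ","), dw[3L], dw[4L], dil), call. = FALSE)
  M <- cpp_im2col(x, dim(x), dw[3L], dw[4L], stride, pad[1L], pad[2L], dil)
  Wm <- matrix(w, dw[1L])                       # (cout, cin*kh*kw)
  Y <- M %*% t(Wm)
  if (!is.null(bias)) Y <- sweep(Y, 2L, bias, "+")
  aperm(array(Y, c(dx[1L], oh, ow, dw[1L])), c(1L, 4L, 2L, 3L))
}

# Backward pass of conv2d_dense. Returns list(dx, dw, db).
#' @keywords internal
conv2d_dense_bwd <- function(dy, x, w, stride = 1L, pad = c(0L, 0L), dil = 1L) {
  dx_ <- dim(x); dw_ <- dim(w); dyd <- dim(dy)
  oh <- dyd[3L]; ow <- dyd[4L]; b <- dx_[1L]
  M <- cpp_im2col(x, dim(x), dw_[3L], dw_[4L], stride, pad[1L], pad[2L], dil)
  dYm <- matrix(aperm(dy, c(1L, 3L, 4L, 2L)), b * oh * ow, dw_[1L])
  dW <- array(t(dYm) %*% M, dw_)
  db <- colSums(dYm)
  Wm <- matrix(w, dw_[1L])
  dM <- dYm %*% Wm                              # (b*oh*ow, cin*kh*kw)
  dx <- cpp_col2im(dM, dim(x), dw_[3L], dw_[4L], stride, pad[1L], pad[2L], dil)
  list(dx = dx, dw = dW, db = db)
}

#' Depthwise 2-D convolution (one filter per channel)
#'
#' @param x feature map (b, c, h, w)
#' @param w weights (c, kh, kw)
#' @keywords internal
conv2d_dw <- function(x, w, bias = NULL, stride = 1L, pad = c(0L, 0L), dil = 1L) {
  dx <- dim(x); dw <- dim(w)
  if (dx[2L] != dw[1L])
    stop(sprintf("channel mismatch: input has shape (%s) but depthwise weights cover %d channels (weight shape %s)",
                 paste(dx, collapse = ","), dw[1L], paste(dw, collapse = ",")), call. = FALSE)
  cpp_conv_dw_fwd(x, dim(x), w, dim(w),
                  if (is.null(bias)) numeric(0) else bias,
                  stride, pad[1L], pad[2L], dil)
}

#' @keywords internal
conv2d_dw_bwd <- function(dy, x, w, stride = 1L, pad = c(0L, 0L), dil = 1L) {
  cpp_conv_dw_bwd(dy, x, dim(x), w, dim(w), stride, pad[1L], pad[2L], dil)
}

#' 2x2 max-pooling with stride 2
#' @return list(y, masks) where masks route gradients to the (first) argmax
#' @keywords internal
maxpool2_fwd <- function(x) {
  d <- dim(x)
  if (d[3L] %% 2L || d[4L] %% 2L)
    stop(sprintf("maxpool2 requires even spatial dims, got (%d, %d)", d[3L], d[4L]), call. = FALSE)
  r1 <- seq(1L, d[3L], by = 2L); r2 <- r1 + 1L
  c1 <- seq(1L, d[4L], by = 2L); c2 <- c1 + 1L
  a <- x[, , r1, c1, drop = FALSE]; b2 <- x[, , r1, c2, drop = FALSE]
  c3 <- x[, , r2, c1, drop = FALSE]; d4 <- x[, , r2, c2, drop = FALSE]
  m <- pmax(a, b2, c3, d4)
  m1 <- a == m
  m2 <- (b2 == m) & !m1
  m3 <- (c3 == m) & !m1 & !m2
  m4 <- !m1 & !m2 & !m3
  list(y = m, masks = list(m1, m2, m3, m4))
}

#' @keywords internal
maxpool2_bwd <- function(dy, masks, in_dim) {
  dx <- array(0, in_dim)
  r1 <- seq(1L, in_dim[3L], by = 2L); r2 <- r1 + 1L
  c1 <- seq(1L, in_dim[4L], by = 2L); c2 <- c1 + 1L
  dx[, , r1, c1] <- dy * masks[[1L]]
  dx[, , r1, c2] <- dy * masks[[2L]]
  dx[, , r2, c1] <- dy * masks[[3L]]
  dx[, , r2, c2] <- dy * masks[[4L]]
  dx
}

# --- Interpolation ----------------------------------------------------------

# Row-interpolation matrix mapping a length n_in axis to n_out samples.
# Half-pixel centre convention (the torch/opencv align_corners = FALSE
# default): src = (i + 0.5) * n_in/n_out - 0.5.
#' @keywords internal
interp_matrix <- function(n_in, n_out, method = c("bilinear", "bicubic")) {
  method <- match.arg(method)
  A <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  clamp <- function(i) pmin(pmax(i, 0L), n_in - 1L)
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale - 0.5
    i0 <- floor(src); t <- src - i0
    if (method == "bilinear") {
      taps <- clamp(c(i0, i0 + 1)); wts <- c(1 - t, t)
    } else {
      # Keys cubic kernel, a = -0.75 (the common bicubic choice)
      a <- -0.75
      cub <- function(s) {
        s <- abs(s)
        ifelse(s <= 1, (a + 2) * s^3 - (a + 3) * s^2 + 1,
               ifelse(s < 2, a * s^3 - 5 * a * s^2 + 8 * a * s - 4 * a, 0))
      }
      taps <- clamp(c(i0 - 1, i0, i0 + 1, i0 + 2))
      wts <- cub(c(-1 - t, -t, 1 - t, 2 - t))
    }
    for (j in seq_along(taps)) A[i, taps[j] + 1L] <- A[i, taps[j] + 1L] + wts[j]
  }
  A
}

# Apply separable resampling out = A %*% X %*% t(B) over the spatial dims of
# a (b, c, h, w) array, for interpolation matrices A (oh x h), B (ow x w).
#' @keywords internal
ft_apply_interp <- function(x, A, B) {
  d <- dim(x); b <- d[1L]; cc <- d[2L]; h <- d[3L]; w <- d[4L]
  oh <- nrow(A); ow <- nrow(B)
  xr <- aperm(x, c(3L, 1L, 2L, 4L)); dim(xr) <- c(h, b * cc * w)
  y1 <- A %*% xr; dim(y1) <- c(oh, b, cc, w)
  yc <- aperm(y1, c(4L, 1L, 2L, 3L)); dim(yc) <- c(w, oh * b * cc)
  y2 <- B %*% yc; dim(y2) <- c(ow, oh, b, cc)
  aperm(y2, c(3L, 4L, 2L, 1L))
}

#' Bilinear (or bicubic) spatial resize of a feature map
#' @keywords internal
ft_resize <- function(x, oh, ow, method = "bilinear") {
  d <- dim(x)
  if (d[3L] == oh && d[4L] == ow) return(x)
  ft_apply_interp(x, interp_matrix(d[3L], oh, method), interp_matrix(d[4L], ow, method))
}

# Gradient of ft_resize w.r.t. its input: the transposed linear map.
#' @keywords internal
ft_resize_bwd <- function(dy, h, w, method = "bilinear") {
  d <- dim(dy)
  if (d[3L] == h && d[4L] == w) return(dy)
  ft_apply_interp(dy, t(interp_matrix(h, d[3L], method)), t(interp_matrix(w, d[4L], method)))
}

#' Nearest-neighbour spatial resize (used for masks)
#' @keywords internal
ft_resize_nearest <- function(x, oh, ow) {
  d <- dim(x)
  if (d[3L] == oh && d[4L] == ow) return(x)
  ri <- pmin(floor((seq_len(oh) - 1L) * d[3L] / oh) + 1L, d[3L])
  ci <- pmin(floor((seq_len(ow) - 1L) * d[4L] / ow) + 1L, d[4L])
  x[, , ri, ci, drop = FALSE]
}

#' Global average pool (b,c,h,w) -> (b,c,1,1)
#' @keywords internal
ft_gap <- function(x) {
  d <- dim(x)
  array(rowMeans(matrix(x, d[1L] * d[2L], d[3L] * d[4L])), c(d[1L], d[2L], 1L, 1L))
}

#' @keywords internal
ft_gap_bwd <- function(dy, in_dim) {
  n <- in_dim[3L] * in_dim[4L]
  array(rep(as.vector(dy), n) / n, in_dim)
}

# Per-channel reduction: sum over batch and spatial dims -> length-c vector.
#' @keywords internal
ft_channel_sum <- function(x) cpp_channel_sum(x, dim(x))

# Broadcast a per-channel vector over a (b,c,h,w) array layout.
#' @keywords internal
ft_bc_channel <- function(v, b) rep(v, each = b)
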