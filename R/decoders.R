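# The transformer-branch decoder and the CNN (PS) decoder.
#
# Partial decoder: a pointwise linear map from embed dim d to mu tissue
#   logits, followed by a row-major rearrangement of the N tokens into a
#   (sqrt(N), sqrt(N)) spatial grid at 1/16 resolution. Each of the mu
#   channels can be read as a logit for one tissue condition.
# Enhanced dilated transformer decoder: upsampling + double standard
#   convolution, upsampling + double dilated convolution (rate 3), then two
#   pointwise convolutions down to a single-channel full-resolution
#   candidate map. The two bilinear upsamplings each use factor 4
#   (1/16 -> 1/4 -> 1/1).
# PS decoder: four upsample+LFE stages mirroring the encoder, with U-Net
#   style channel concatenation of encoder skips, wSq attention after
#   stages 2 and 3, SCSE after stage 4, and a final pointwise convolution to
#   one channel.

#' Partial decoder: tokens to a mu-channel logit grid
#'
#' @param d_model embedding dimension of the incoming tokens
#' @param mu number of tissue logits (channels of the output grid)
#' @return an `nn_module`; forward maps (b, N, d) to (b, mu, sqrt(N), sqrt(N))
#' @export
nn_partial_decoder <- function(d_model, mu = 64L) {
  if (mu < 1L) stop("mu must be >= 1", call. = FALSE)
  children <- list(proj = nn_linear(d_model, mu))
  cache <- NULL
  forward <- function(tok) {
    d <- dim(tok)
    g <- as.integer(round(sqrt(d[2L])))
    if (g * g != d[2L])
      stop(sprintf("token count %d is not a perfect square; cannot form a spatial grid", d[2L]),
           call. = FALSE)
    z <- children$proj$forward(tok)            # (b, N, mu)
    if (training) cache <<- c(b = d[1L], g = g)
    dim(z) <- c(d[1L], g, g, mu)               # (b, j, i, mu): tokens are j-fastest
    aperm(z, c(1L, 4L, 3L, 2L))                # (b, mu, i, j)
  }
  backward <- function(dy) {
    b <- cache[["b"]]; g <- cache[["g"]]
    z <- aperm(dy, c(1L, 4L, 3L, 2L))
    dim(z) <- c(b, g * g, mu)
    children$proj$backward(z)
  }
  nn_finish_module(environment(), "nn_partial_decoder")
}

#' Rearrange a (b, N, mu) token matrix into a (b, mu, g, g) grid
#'
#' The row-major token-to-grid rearrangement used by the partial decoder,
#' exposed for round-trip testing.
#' @export
tokens_to_grid <- function(z) {
  d <- dim(z)
  g <- as.integer(round(sqrt(d[2L])))
  if (g * g != d[2L]) stop("token count is not a perfect square", call. = FALSE)
  dim(z) <- c(d[1L], g, g, d[3L])
  aperm(z, c(1L, 4L, 3L, 2L))
}

#' Inverse of [tokens_to_grid()]
#' @export
grid_to_tokens <- function(gr) {
  d <- dim(gr)
  z <- aperm(gr, c(1L, 4L, 3L, 2L))
  dim(z) <- c(d[1L], d[3L] * d[4L], d[2L])
  z
}

# conv + BN + SiLU used by the enhanced decoder (dense convolutions).
#' @keywords internal
conv_bn_silu <- function(in_ch, out_ch, k = 3L, dil = 1L) {
  pad <- dil * (k - 1L) %/% 2L
  nn_sequential(list(conv = nn_conv2d(in_ch, out_ch, k, pad = pad, dil = dil),
                     bn = nn_batchnorm2d(out_ch),
                     act = nn_silu()))
}

#' Enhanced dilated transformer decoder
#'
#' Maps the partial-decoder grid at 1/16 resolution to a single-channel
#' full-resolution candidate segmentation map.
#'
#' @param mu channel count of the incoming logit grid
#' @param width internal channel width (64)
#' @param dil dilation rate of the dilated pair (3)
#' @param up_factors the two bilinear upsampling factors; they must multiply
#'   to 16
#' @return an `nn_module`
#' @export
nn_enhanced_decoder <- function(mu = 64L, width = 64L, dil = 3L, up_factors = c(4L, 4L)) {
  if (prod(up_factors) != 16L)
    stop("enhanced decoder upsampling factors must multiply to 16", call. = FALSE)
  body <- nn_sequential(list(
    up1 = nn_upsample(up_factors[1L]),
    conv1 = conv_bn_silu(mu, width, 3L),
    conv2 = conv_bn_silu(width, width, 3L),
    up2 = nn_upsample(up_factors[2L]),
    dconv1 = conv_bn_silu(width, width, 3L, dil = dil),
    dconv2 = conv_bn_silu(width, width, 3L, dil = dil),
    pw1 = conv_bn_silu(width, width %/% 2L, 1L),
    pw2 = nn_conv2d(width %/% 2L, 1L, 1L)
  ))
  children <- list(body = body)
  forward <- function(x) body$forward(x)
  backward <- function(dy) body$backward(dy)
  nn_finish_module(environment(), "nn_enhanced_decoder")
}

# --- Attention modules of the PS decoder ------------------------------------

#' Configuration of the weighted squeeze-and-excitation (wSq) pooling
#'
#' The weighted average pooling (WAP) is a size-preserving average pool
#' whose zero padding is included in the averaging denominator, so border
#' positions are down-weighted; kernel/stride/padding are exposed because
#' larger kernels/paddings widen the region of focus.
#'
#' @param kernel WAP kernel size
#' @param stride WAP stride (1 preserves size)
#' @param pad WAP padding; `pad = (kernel-1)/2` preserves size
#' @param ratio channel reduction ratio of the two pointwise convolutions
#' @export
wsq_config <- function(kernel = 7L, stride = 1L, pad = 3L, ratio = 2L) {
  if (kernel < 1L || pad >= kernel || ratio < 1L)
    stop("invalid wSq geometry: need kernel >= 1, padding < kernel, ratio >= 1", call. = FALSE)
  list(kernel = as.integer(kernel), stride = as.integer(stride),
       pad = as.integer(pad), ratio = as.integer(ratio))
}

# Weighted average pooling: depthwise average with constant kernel 1/k^2 and
# zeros included in the denominator (fixed, non-learnable).
#' @keywords internal
wap_fwd <- function(x, k, stride, pad) {
  w <- array(1 / (k * k), c(dim(x)[2L], k, k))
  conv2d_dw(x, w, NULL, stride, c(pad, pad), 1L)
}

#' @keywords internal
wap_bwd <- function(dy, x, k, stride, pad) {
  w <- array(1 / (k * k), c(dim(x)[2L], k, k))
  conv2d_dw_bwd(dy, x, w, stride, c(pad, pad), 1L)$dx
}

# Broadcast a (b,1,h,w) gate over c channels.
#' @keywords internal
bc_spatial <- function(g, cc) g[, rep(1L, cc), , , drop = FALSE]

# Broadcast a (b,c,1,1) gate over h x w.
#' @keywords internal
bc_channel <- function(g, h, w) g[, , rep(1L, h), rep(1L, w), drop = FALSE]

#' Weighted squeeze-and-excitation module (wSq)
#'
#' Two concurrent gates: a WAP branch, `gateA = sigmoid(PW2(PW1(WAP(x))))`,
#' giving a per-pixel per-channel gate, and a single-channel pointwise
#' branch, `gateB = sigmoid(PW(x))`, broadcast over channels. The output is
#' `x * gateA + x * gateB`. (In the source architecture's naming the two
#' branches are labelled cSE/sSE inconsistently with the SCSE convention;
#' this implementation follows the structure: WAP branch vs. 1-channel
#' pointwise branch.)
#'
#' @param ch channel count (must be >= ratio so the reduction keeps at least
#'   one channel)
#' @param cfg a [wsq_config()]
#' @return an `nn_module`; output shape equals input shape
#' @export
nn_wsq <- function(ch, cfg = wsq_config()) {
  red <- ch %/% cfg$ratio
  if (red < 1L)
    stop(sprintf("wSq reduction ratio %d collapses %d channels to zero", cfg$ratio, ch), call. = FALSE)
  children <- list(
    pw_a1 = nn_conv2d(ch, red, 1L),
    pw_a2 = nn_conv2d(red, ch, 1L),
    pw_b = nn_conv2d(ch, 1L, 1L)
  )
  cache <- NULL
  forward <- function(x) {
    d <- dim(x)
    if (d[2L] < 2L) stop("wSq requires at least 2 channels", call. = FALSE)
    wapx <- wap_fwd(x, cfg$kernel, cfg$stride, cfg$pad)
    za <- children$pw_a2$forward(children$pw_a1$forward(wapx))
    ga <- sigmoid(za)
    zb <- children$pw_b$forward(x)
    gb <- sigmoid(zb)
    gbb <- bc_spatial(gb, d[2L])
    if (training) cache <<- list(x = x, ga = ga, gb = gb, gbb = gbb, d = d)
    x * ga + x * gbb
  }
  backward <- function(dy) {
    x <- cache$x; ga <- cache$ga; gb <- cache$gb; gbb <- cache$gbb; d <- cache$d
    dx <- dy * (ga + gbb)
    dga <- dy * x
    dza <- dga * ga * (1 - ga)
    dwap <- children$pw_a1$backward(children$pw_a2$backward(dza))
    dx <- dx + wap_bwd(dwap, x, cfg$kernel, cfg$stride, cfg$pad)
    dgb <- array(rowSums(matrix(aperm(dy * x, c(1L, 3L, 4L, 2L)), ncol = d[2L])),
                 c(d[1L], 1L, d[3L], d[4L]))
    dzb <- dgb * gb * (1 - gb)
    dx + children$pw_b$backward(dzb)
  }
  nn_finish_module(environment(), "nn_wsq")
}

#' Concurrent spatial and channel squeeze-and-excitation (SCSE)
#'
#' Channel excitation: global average pool, bottleneck (pointwise, ReLU,
#' pointwise), sigmoid, per-channel scale. Spatial excitation: one-channel
#' pointwise convolution, sigmoid, per-pixel scale. Combined additively:
#' `y = x * cSE(x) + x * sSE(x)`.
#'
#' @param ch channel count
#' @param ratio bottleneck reduction ratio
#' @return an `nn_module`; output shape equals input shape
#' @export
nn_scse <- function(ch, ratio = 2L) {
  red <- ch %/% ratio
  if (red < 1L)
    stop(sprintf("SCSE reduction ratio %d collapses %d channels to zero", ratio, ch), call. = FALSE)
  children <- list(
    pw_c1 = nn_conv2d(ch, red, 1L),
    pw_c2 = nn_conv2d(red, ch, 1L),
    pw_s = nn_conv2d(ch, 1L, 1L)
  )
  cache <- NULL
  forward <- function(x) {
    d <- dim(x)
    p <- ft_gap(x)
    h1 <- children$pw_c1$forward(p)
    r1 <- pmax(h1, 0)
    zc <- children$pw_c2$forward(r1)
    gc_ <- sigmoid(zc)                          # (b, ch, 1, 1)
    gcb <- bc_channel(gc_, d[3L], d[4L])
    zs <- children$pw_s$forward(x)
    gs <- sigmoid(zs)                           # (b, 1, h, w)
    gsb <- bc_spatial(gs, d[2L])
    if (training) cache <<- list(x = x, h1 = h1, gc_ = gc_, gcb = gcb,
                                 gs = gs, gsb = gsb, d = d)
    x * gcb + x * gsb
  }
  backward <- function(dy) {
    x <- cache$x; d <- cache$d
    dx <- dy * (cache$gcb + cache$gsb)
    # channel gate path
    dgc <- array(rowMeans(matrix(dy * x, d[1L] * d[2L], d[3L] * d[4L])) * (d[3L] * d[4L]),
                 c(d[1L], d[2L], 1L, 1L))
    dzc <- dgc * cache$gc_ * (1 - cache$gc_)
    dr1 <- children$pw_c2$backward(dzc)
    dh1 <- dr1 * (cache$h1 > 0)
    dp <- children$pw_c1$backward(dh1)
    dx <- dx + ft_gap_bwd(dp, d)
    # spatial gate path
    dgs <- array(rowSums(matrix(aperm(dy * x, c(1L, 3L, 4L, 2L)), ncol = d[2L])),
                 c(d[1L], 1L, d[3L], d[4L]))
    dzs <- dgs * cache$gs * (1 - cache$gs)
    dx + children$pw_s$backward(dzs)
  }
  nn_finish_module(environment(), "nn_scse")
}

# --- PS decoder -------------------------------------------------------------

#' The CNN-branch (PS) decoder
#'
#' Four bilinear x2 upsample + LFE stages consuming the encoder pyramid
#' (skips concatenated channelwise for stages 1-3; the full-resolution stage
#' has no skip), wSq attention after stages 2 and 3, SCSE after stage 4, and
#' a final pointwise convolution to a single-channel candidate map.
#'
#' @param enc_channels encoder channel schedule, shallowest first
#'   (default c(64, 128, 256, 512))
#' @param dec_channels decoder channel schedule (default c(256, 128, 64, 32))
#' @param wsq_cfg a [wsq_config()]
#' @param use_ccm passed through to the LFE modules
#' @param attention placement of attention modules per stage: character
#'   vector of length 4 from {"none", "wsq", "scse"}
#' @return an `nn_module`; `$forward(pyramid)` takes the list of 4 encoder
#'   maps and returns a (b, 1, H, W) pre-activation map; `$backward(dy)`
#'   returns the list of gradients w.r.t. the 4 pyramid maps
#' @export
nn_ps_decoder <- function(enc_channels = c(64L, 128L, 256L, 512L),
                          dec_channels = c(256L, 128L, 64L, 32L),
                          wsq_cfg = wsq_config(), use_ccm = TRUE,
                          attention = c("none", "wsq", "wsq", "scse")) {
  stopifnot(length(enc_channels) == 4L, length(dec_channels) == 4L,
            length(attention) == 4L)
  in_chs <- c(enc_channels[4L] + enc_channels[3L],
              dec_channels[1L] + enc_channels[2L],
              dec_channels[2L] + enc_channels[1L],
              dec_channels[3L])
  children <- list()
  for (i in 1:4) {
    children[[sprintf("up%d", i)]] <- nn_upsample(2L)
    children[[sprintf("lfe%d", i)]] <- nn_lfe(in_chs[i], dec_channels[i], use_ccm = use_ccm)
    children[[sprintf("att%d", i)]] <- switch(attention[i],
      none = nn_identity(),
      wsq = nn_wsq(dec_channels[i], wsq_cfg),
      scse = nn_scse(dec_channels[i]),
      stop(sprintf("unknown attention '%s'", attention[i]), call. = FALSE))
  }
  children$head <- nn_conv2d(dec_channels[4L], 1L, 1L)
  cache <- NULL
  forward <- function(pyramid) {
    if (length(pyramid) != 4L)
      stop("PS decoder expects a 4-level feature pyramid", call. = FALSE)
    if (dim(pyramid[[4L]])[2L] != enc_channels[4L])
      stop(sprintf("pyramid/config mismatch: deepest map has %d channels, configured %d",
                   dim(pyramid[[4L]])[2L], enc_channels[4L]), call. = FALSE)
    skip_ch <- integer(3L)
    x <- pyramid[[4L]]
    for (i in 1:4) {
      x <- children[[sprintf("up%d", i)]]$forward(x)
      if (i <= 3L) {
        skip <- pyramid[[4L - i]]
        if (!all(dim(skip)[3:4] == dim(x)[3:4]))
          stop(sprintf("skip connection scale mismatch at stage %d: decoder (%s) vs encoder (%s)",
                       i, paste(dim(x), collapse = ","), paste(dim(skip), collapse = ",")),
               call. = FALSE)
        skip_ch[i] <- dim(skip)[2L]
        d <- dim(x)
        xc <- array(0, c(d[1L], d[2L] + dim(skip)[2L], d[3L], d[4L]))
        xc[, seq_len(d[2L]), , ] <- x
        xc[, d[2L] + seq_len(dim(skip)[2L]), , ] <- skip
        x <- xc
      }
      x <- children[[sprintf("lfe%d", i)]]$forward(x)
      x <- children[[sprintf("att%d", i)]]$forward(x)
    }
    if (training) cache <<- skip_ch
    children$head$forward(x)
  }
  backward <- function(dy) {
    skip_ch <- cache
    dskips <- vector("list", 4L)
    dy <- children$head$backward(dy)
    for (i in 4:1) {
      dy <- children[[sprintf("att%d", i)]]$backward(dy)
      dy <- children[[sprintf("lfe%d", i)]]$backward(dy)
      if (i <= 3L) {
        d <- dim(dy)
        own <- d[2L] - skip_ch[i]
        dskips[[4L - i]] <- dy[, own + seq_len(skip_ch[i]), , , drop = FALSE]
        dy <- dy[, seq_len(own), , , drop = FALSE]
      }
      dy <- children[[sprintf("up%d", i)]]$backward(dy)
    }
    dskips[[4L]] <- dy
    dskips
  }
  nn_finish_module(environment(), "nn_ps_decoder")
}
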