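# Convolutional building blocks of the PS branch.
#
# DWSC: depthwise separable standard convolution -- a per-channel spatial
#   convolution followed by a pointwise (1x1) channel-mixing convolution,
#   with batch normalization and an activation at the end of the pair.
# CCM:  "complex convolutional module" -- two passes of depthwise asymmetric
#   convolution (1xk then kx1) followed by a depthwise dilated kxk
#   convolution. The first pass uses k = 3, dilation 2; the second k = 5,
#   dilation 3. Batch normalization follows every convolution; one
#   activation closes each pass (PReLU after the k = 3 set, ReLU6 after the
#   k = 5 set). All layers are channel-preserving and size-preserving.
# LFE:  local feature extraction -- two DWSC (each BN + SiLU) followed by a
#   CCM. The first DWSC carries the channel change, the second preserves it.

#' Depthwise separable convolution block
#'
#' Per-channel spatial convolution followed by a pointwise projection, with
#' optional batch normalization and activation applied after the pair.
#'
#' @param in_ch,out_ch input/output channel counts
#' @param k spatial kernel size (scalar or length 2)
#' @param stride,pad,dil convolution geometry; defaults preserve spatial size
#'   for k = 3
#' @param norm apply batch normalization after the pointwise convolution
#' @param act activation name: "silu", "prelu", "relu6" or "none"
#' @return an `nn_module` with `$forward(x)` / `$backward(dy)`
#' @export
nn_dwsc <- function(in_ch, out_ch, k = 3L, stride = 1L, pad = 1L, dil = 1L,
                    norm = TRUE, act = "silu") {
  children <- list(
    dw = nn_conv2d(in_ch, in_ch, k, stride, pad, dil, depthwise = TRUE),
    pw = nn_conv2d(in_ch, out_ch, 1L, bias = TRUE)
  )
  if (norm) children$bn <- nn_batchnorm2d(out_ch)
  children$act <- make_activation(act)
  seq_ <- nn_sequential(children)
  children <- list(body = seq_)
  forward <- function(x) seq_$forward(x)
  backward <- function(dy) seq_$backward(dy)
  nn_finish_module(environment(), "nn_dwsc")
}

# One depthwise convolution + BN used inside the CCM.
#' @keywords internal
ccm_layer <- function(ch, kh, kw, dil) {
  if ((dil * (kh - 1L)) %% 2L || (dil * (kw - 1L)) %% 2L)
    stop(sprintf("CCM layer with kernel (%d,%d), dilation %d has an even effective extent; cannot pad to preserve size",
                 kh, kw, dil), call. = FALSE)
  pad <- c(dil * (kh - 1L) %/% 2L, dil * (kw - 1L) %/% 2L)
  nn_sequential(list(
    conv = nn_conv2d(ch, ch, c(kh, kw), pad = pad, dil = dil, depthwise = TRUE),
    bn = nn_batchnorm2d(ch)
  ))
}

#' Complex convolutional module (CCM)
#'
#' Two passes of depthwise asymmetric + dilated convolutions: 1xk, kx1, kxk
#' with k = 3 (dilation 2) then k = 5 (dilation 3). Every convolution is
#' followed by batch normalization; a PReLU closes the first pass and a
#' ReLU6 the second. Channel count and spatial size are preserved.
#'
#' @param ch channel count (preserved)
#' @param ks kernel sizes of the two passes
#' @param dils dilation rates of the two passes
#' @return an `nn_module`
#' @export
nn_ccm <- function(ch, ks = c(3L, 5L), dils = c(2L, 3L)) {
  mods <- list()
  for (i in seq_along(ks)) {
    k <- ks[i]; dl <- dils[i]
    mods[[sprintf("aconv_1x%d_g%d", k, i)]] <- ccm_layer(ch, 1L, k, dl)
    mods[[sprintf("aconv_%dx1_g%d", k, i)]] <- ccm_layer(ch, k, 1L, dl)
    mods[[sprintf("dconv_%dx%d_g%d", k, k, i)]] <- ccm_layer(ch, k, k, dl)
    mods[[sprintf("act_g%d", i)]] <- if (i == 1L) nn_prelu() else nn_relu6()
  }
  body <- nn_sequential(mods)
  children <- list(body = body)
  forward <- function(x) body$forward(x)
  backward <- function(dy) body$backward(dy)
  nn_finish_module(environment(), "nn_ccm")
}

#' Local feature extraction module (LFE)
#'
#' Dual DWSC (each with BN + SiLU; the first changes the channel count) then
#' a CCM. Spatial size is preserved throughout.
#'
#' @param in_ch,out_ch channel counts
#' @param use_ccm replace the CCM with identity when FALSE (the "without
#'   CCM" ablation)
#' @return an `nn_module`
#' @export
nn_lfe <- function(in_ch, out_ch, use_ccm = TRUE) {
  body <- nn_sequential(list(
    dwsc1 = nn_dwsc(in_ch, out_ch, k = 3L, stride = 1L, pad = 1L, act = "silu"),
    dwsc2 = nn_dwsc(out_ch, out_ch, k = 3L, stride = 1L, pad = 1L, act = "silu"),
    ccm = if (use_ccm) nn_ccm(out_ch) else nn_identity()
  ))
  children <- list(body = body)
  forward <- function(x) body$forward(x)
  backward <- function(dy) body$backward(dy)
  nn_finish_module(environment(), "nn_lfe")
}

#' Functional depthwise separable convolution
#'
#' Applies a freshly constructed (or supplied) DWSC block to a feature map.
#' Mostly a convenience for tests and exploration; model code composes the
#' `nn_dwsc` module directly.
#'
#' @param x feature map array (b, c, h, w)
#' @param spec list with elements `out_channels`, and optionally `k`,
#'   `stride`, `pad`, `dil`, `norm`, `act`
#' @param module optional pre-built `nn_dwsc` to apply instead
#' @return feature map array
#' @export
depthwise_separable_conv <- function(x, spec = list(), module = NULL) {
  ft_check_4d(x)
  if (is.null(module)) {
    module <- nn_dwsc(dim(x)[2L],
                      out_ch = spec$out_channels %||% dim(x)[2L],
                      k = spec$k %||% 3L,
                      stride = spec$stride %||% 1L,
                      pad = spec$pad %||% 1L,
                      dil = spec$dil %||% 1L,
                      norm = spec$norm %||% TRUE,
                      act = spec$act %||% "silu")
  }
  module$forward(x)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
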