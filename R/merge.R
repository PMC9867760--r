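# Merge modules: fuse a PS-encoder stage feature map with the
# partial-decoder logit grid at one of the scales 1/2, 1/4, 1/8, 1/16 and
# emit a full-resolution single-channel candidate segmentation map.
#
# Pipeline: resize the grid bilinearly to the PS scale, concatenate along
# channels, project to the constant internal width of 64 channels, two
# (maxpool + double DWSC) stages down, two (bilinear x2 + double DWSC)
# stages up (returning to the entry scale), one final bilinear upsample to
# full resolution and a pointwise reduction to 1 channel. Every convolution
# carries BN + SiLU.

#' One merge module at a fixed pyramid scale
#'
#' @param ps_ch channels of the PS-encoder feature at this scale (0 when the
#'   CNN branch is ablated away)
#' @param grid_ch channels of the transformer logit grid (mu; 0 when the
#'   transformer branch is ablated away)
#' @param scale_div the scale denominator s in {2, 4, 8, 16}: features enter
#'   at 1/s of the input resolution
#' @param width internal channel width (64)
#' @return an `nn_module`; `$forward(ps_feat, grid)` returns a (b, 1, H, W)
#'   map; `$backward(dy)` returns `list(d_ps, d_grid)` (NULL for absent
#'   inputs). Internal feature maps after the entry projection are recorded
#'   in `$last_widths` for introspection.
#' @export
nn_merge <- function(ps_ch, grid_ch, scale_div, width = 64L) {
  if (ps_ch + grid_ch < 1L) stop("merge module needs at least one input branch", call. = FALSE)
  if (!scale_div %in% c(2L, 4L, 8L, 16L)) stop("scale_div must be 2, 4, 8 or 16", call. = FALSE)
  dbl_dwsc <- function() nn_sequential(list(
    a = nn_dwsc(width, width, act = "silu"),
    b = nn_dwsc(width, width, act = "silu")))
  children <- list(
    proj = nn_sequential(list(conv = nn_conv2d(ps_ch + grid_ch, width, 1L),
                              bn = nn_batchnorm2d(width), act = nn_silu())),
    pool1 = nn_maxpool2(), conv_d1 = dbl_dwsc(),
    pool2 = nn_maxpool2(), conv_d2 = dbl_dwsc(),
    up1 = nn_upsample(2L), conv_u1 = dbl_dwsc(),
    up2 = nn_upsample(2L), conv_u2 = dbl_dwsc(),
    up_full = nn_upsample(scale_div),
    head = nn_conv2d(width, 1L, 1L)
  )
  last_widths <- integer()
  cache <- NULL
  forward <- function(ps_feat, grid) {
    if (ps_ch > 0L) {
      d <- dim(ps_feat)
      if (d[2L] != ps_ch)
        stop(sprintf("merge at 1/%d: PS feature has %d channels, expected %d",
                     scale_div, d[2L], ps_ch), call. = FALSE)
      target <- d[3:4]
    } else {
      d <- dim(grid)
      target <- d[3:4] * (16L %/% scale_div)
    }
    if (grid_ch > 0L) {
      gin_dim <- dim(grid)
      gr <- ft_resize(grid, target[1L], target[2L])
      x <- if (ps_ch > 0L) {
        xc <- array(0, c(dim(gr)[1L], ps_ch + grid_ch, target[1L], target[2L]))
        xc[, seq_len(ps_ch), , ] <- ps_feat
        xc[, ps_ch + seq_len(grid_ch), , ] <- gr
        xc
      } else gr
    } else {
      gin_dim <- NULL
      x <- ps_feat
    }
    if (training) cache <<- list(gin_dim = gin_dim)
    x <- children$proj$forward(x)
    widths <- dim(x)[2L]
    for (nm in c("pool1", "conv_d1", "pool2", "conv_d2", "up1", "conv_u1", "up2", "conv_u2")) {
      x <- children[[nm]]$forward(x)
      widths <- c(widths, dim(x)[2L])
    }
    last_widths <<- widths
    x <- children$up_full$forward(x)
    children$head$forward(x)
  }
  backward <- function(dy) {
    dy <- children$head$backward(dy)
    dy <- children$up_full$backward(dy)
    for (nm in rev(c("pool1", "conv_d1", "pool2", "conv_d2", "up1", "conv_u1", "up2", "conv_u2")))
      dy <- children[[nm]]$backward(dy)
    dy <- children$proj$backward(dy)
    d_ps <- NULL; d_grid <- NULL
    if (ps_ch > 0L) d_ps <- dy[, seq_len(ps_ch), , , drop = FALSE]
    if (grid_ch > 0L) {
      dgr <- dy[, ps_ch + seq_len(grid_ch), , , drop = FALSE]
      d_grid <- ft_resize_bwd(dgr, cache$gin_dim[3L], cache$gin_dim[4L])
    }
    list(d_ps = d_ps, d_grid = d_grid)
  }
  nn_finish_module(environment(), "nn_merge")
}
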