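# The CNN-branch (PS) encoder: four identical maxpool -> LFE stages
# producing a feature pyramid at 1/2, 1/4, 1/8 and 1/16 of the input
# resolution. Every stage output is exposed: the merge modules and the PS
# decoder skip connections both tap the pyramid.

#' The PS encoder
#'
#' @param in_ch input channels (3 for RGB)
#' @param channels channel schedule of the four stages, shallowest first
#'   (default 64, 128, 256, 512)
#' @param use_ccm passed to the LFE modules
#' @return an `nn_module`; `$forward(x)` maps a (b, in_ch, H, W) image with
#'   H, W divisible by 16 to a list of four feature maps at (H/2, H/4, H/8,
#'   H/16); `$backward(dys)` accepts a list of four gradients (NULL entries
#'   allowed) and returns the gradient w.r.t. the image
#' @export
nn_ps_encoder <- function(in_ch = 3L, channels = c(64L, 128L, 256L, 512L),
                          use_ccm = TRUE) {
  stopifnot(length(channels) == 4L)
  chs <- c(in_ch, channels)
  children <- list()
  for (i in 1:4) {
    children[[sprintf("pool%d", i)]] <- nn_maxpool2()
    children[[sprintf("lfe%d", i)]] <- nn_lfe(chs[i], chs[i + 1L], use_ccm = use_ccm)
  }
  forward <- function(x) {
    ft_check_4d(x)
    d <- dim(x)
    if (d[2L] != in_ch)
      stop(sprintf("channel mismatch: input shape (%s), encoder expects %d channels",
                   paste(d, collapse = ","), in_ch), call. = FALSE)
    if (d[3L] %% 16L || d[4L] %% 16L)
      stop(sprintf("input spatial dims (%d, %d) must be divisible by 16", d[3L], d[4L]),
           call. = FALSE)
    out <- vector("list", 4L)
    for (i in 1:4) {
      x <- children[[sprintf("pool%d", i)]]$forward(x)
      x <- children[[sprintf("lfe%d", i)]]$forward(x)
      out[[i]] <- x
    }
    out
  }
  backward <- function(dys) {
    dx <- NULL
    for (i in 4:1) {
      g <- dys[[i]]
      if (!is.null(dx)) g <- if (is.null(g)) dx else g + dx
      g <- children[[sprintf("lfe%d", i)]]$backward(g)
      dx <- children[[sprintf("pool%d", i)]]$backward(g)
    }
    dx
  }
  nn_finish_module(environment(), "nn_ps_encoder")
}

#' Encode an image into the four-scale PS feature pyramid
#'
#' Convenience wrapper around the module: `ps_encode(x, enc)` equals
#' `enc$forward(x)`.
#' @param x image array (b, c, H, W), H and W divisible by 16
#' @param encoder module from [nn_ps_encoder()]
#' @return list of four feature maps, shallowest (1/2 scale) first
#' @export
ps_encode <- function(x, encoder) encoder$forward(x)
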