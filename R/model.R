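# Full PSNet assembly: dual encoder (PS + ViT), dual decoder (PS decoder;
# partial + enhanced dilated transformer decoder), four merge modules, and
# deep supervision by averaging the six candidate segmentation streams
# before a single sigmoid:
#
#   xbar = (x^T + x^C + x^(1/16) + x^(1/8) + x^(1/4) + x^(1/2)) / 6
#   prob = sigmoid(xbar)
#
# Ablation switches remove branches; the average always renormalizes over
# the streams actually present.

#' Full model configuration
#'
#' @param img_size input side length; divisible by 16 and by the ViT patch
#'   size
#' @param enc_channels PS-encoder channel schedule (shallowest first)
#' @param dec_channels PS-decoder channel schedule
#' @param vit a [vit_config()]; its `img_size` must match
#' @param mu number of tissue logits produced by the partial decoder
#' @param wsq a [wsq_config()]
#' @param variant one of "full", "no_transformer", "no_dual_decoder",
#'   "no_merge", "no_ps_encoder", "no_ccm"
#' @param seed seed used by [init_weights()] when the model is built
#' @return a list of class `psnet_config`
#' @export
psnet_config <- function(img_size = 512L,
                         enc_channels = c(64L, 128L, 256L, 512L),
                         dec_channels = c(256L, 128L, 64L, 32L),
                         vit = vit_config(img_size = img_size),
                         mu = 64L,
                         wsq = wsq_config(),
                         variant = "full",
                         seed = 1L) {
  img_size <- as.integer(img_size)
  if (img_size %% 16L)
    stop(sprintf("image size %d must be divisible by 16", img_size), call. = FALSE)
  if (vit$img_size != img_size)
    stop(sprintf("ViT config image size %d does not match model image size %d",
                 vit$img_size, img_size), call. = FALSE)
  if (mu < 1L) stop("mu must be >= 1", call. = FALSE)
  variant <- match.arg(variant, psnet_variants())
  structure(list(img_size = img_size,
                 enc_channels = as.integer(enc_channels),
                 dec_channels = as.integer(dec_channels),
                 vit = vit, mu = as.integer(mu), wsq = wsq,
                 variant = variant, seed = as.integer(seed)),
            class = "psnet_config")
}

#' The recognised model variants (full model plus the ablations)
#' @export
psnet_variants <- function() {
  c("full", "no_transformer", "no_dual_decoder", "no_merge",
    "no_ps_encoder", "no_ccm")
}

#' Small test-scale configuration
#'
#' 64 x 64 input, default channel schedules, a 2-block / 64-dim / 4-head
#' ViT. Used throughout the test suite; forward passes run in seconds on a
#' CPU.
#' @param img_size input side length
#' @param ... passed on to [psnet_config()]
#' @export
psnet_tiny_config <- function(img_size = 64L, ...) {
  psnet_config(img_size = img_size,
               vit = vit_config(img_size = img_size, patch = 16L, depth = 2L,
                                dim = 64L, heads = 4L),
               ...)
}

#' Build a PSNet model
#'
#' @param cfg a [psnet_config()]
#' @return an `nn_module` of class `psnet_model`; use [psnet_forward()] to
#'   run it
#' @export
psnet <- function(cfg) {
  stopifnot(inherits(cfg, "psnet_config"))
  v <- cfg$variant
  has_ps <- v != "no_ps_encoder"
  has_vit <- v != "no_transformer"
  has_dual_dec <- v != "no_dual_decoder"
  has_merge <- v != "no_merge"
  use_ccm <- v != "no_ccm"

  children <- list()
  if (has_ps)
    children$ps_encoder <- nn_ps_encoder(3L, cfg$enc_channels, use_ccm = use_ccm)
  if (has_vit) {
    children$vit <- nn_vit(cfg$vit)
    children$partial <- nn_partial_decoder(cfg$vit$dim, cfg$mu)
  }
  if (has_dual_dec) {
    if (has_vit) children$enhanced <- nn_enhanced_decoder(cfg$mu)
    if (has_ps)
      children$ps_decoder <- nn_ps_decoder(cfg$enc_channels, cfg$dec_channels,
                                           wsq_cfg = cfg$wsq, use_ccm = use_ccm)
  } else {
    in_ch <- (if (has_ps) cfg$enc_channels[4L] else 0L) + (if (has_vit) cfg$mu else 0L)
    children$simple_head <- nn_conv2d(in_ch, 1L, 1L)
    children$simple_up <- nn_upsample(16L)
  }
  if (has_merge) {
    for (i in 1:4) {
      children[[sprintf("merge%d", i)]] <- nn_merge(
        ps_ch = if (has_ps) cfg$enc_channels[i] else 0L,
        grid_ch = if (has_vit) cfg$mu else 0L,
        scale_div = 2L^i)
    }
  }

  config <- cfg
  cache <- NULL

  forward <- function(x) {
    ft_check_4d(x)
    d <- dim(x)
    if (d[3L] != cfg$img_size || d[4L] != cfg$img_size)
      stop(sprintf("input (%s) does not match configured image size %d",
                   paste(d, collapse = ","), cfg$img_size), call. = FALSE)
    pyr <- if (has_ps) children$ps_encoder$forward(x) else NULL
    grid <- NULL
    if (has_vit) {
      tok <- children$vit$forward(x)
      grid <- children$partial$forward(tok)
    }
    streams <- list()
    simple_in <- NULL
    if (has_dual_dec) {
      if (has_vit) streams$t <- children$enhanced$forward(grid)
      if (has_ps) streams$c <- children$ps_decoder$forward(pyr)
    } else {
      parts <- list()
      if (has_ps) parts <- c(parts, list(pyr[[4L]]))
      if (has_vit) parts <- c(parts, list(grid))
      simple_in <- if (length(parts) == 1L) parts[[1L]] else {
        dd <- dim(parts[[1L]])
        xc <- array(0, c(dd[1L], dd[2L] + dim(parts[[2L]])[2L], dd[3L], dd[4L]))
        xc[, seq_len(dd[2L]), , ] <- parts[[1L]]
        xc[, dd[2L] + seq_len(dim(parts[[2L]])[2L]), , ] <- parts[[2L]]
        xc
      }
      streams$t <- children$simple_up$forward(children$simple_head$forward(simple_in))
    }
    if (has_merge) {
      for (i in 1:4) {
        streams[[sprintf("m%d", 2L^i)]] <- children[[sprintf("merge%d", i)]]$forward(
          if (has_ps) pyr[[i]] else NULL, grid)
      }
    }
    n_str <- length(streams)
    xbar <- Reduce(`+`, streams) / n_str
    if (training) cache <<- list(n_str = n_str)
    list(streams = streams, xbar = xbar, prob = sigmoid(xbar))
  }

  backward <- function(d_xbar) {
    ds <- d_xbar / cache$n_str
    d_pyr <- vector("list", 4L)
    d_grid <- NULL
    add_grid <- function(g) d_grid <<- if (is.null(d_grid)) g else d_grid + g
    add_pyr <- function(i, g) {
      if (is.null(g)) return(invisible(NULL))
      d_pyr[[i]] <<- if (is.null(d_pyr[[i]])) g else d_pyr[[i]] + g
    }
    if (has_merge) {
      for (i in 4:1) {
        r <- children[[sprintf("merge%d", i)]]$backward(ds)
        add_pyr(i, r$d_ps)
        if (!is.null(r$d_grid)) add_grid(r$d_grid)
      }
    }
    if (has_dual_dec) {
      if (has_ps) {
        dskips <- children$ps_decoder$backward(ds)
        for (i in 1:4) add_pyr(i, dskips[[i]])
      }
      if (has_vit) add_grid(children$enhanced$backward(ds))
    } else {
      dsim <- children$simple_head$backward(children$simple_up$backward(ds))
      if (has_ps && has_vit) {
        nc <- cfg$enc_channels[4L]
        add_pyr(4L, dsim[, seq_len(nc), , , drop = FALSE])
        add_grid(dsim[, nc + seq_len(cfg$mu), , , drop = FALSE])
      } else if (has_ps) add_pyr(4L, dsim) else add_grid(dsim)
    }
    dx <- NULL
    if (has_vit && !is.null(d_grid)) {
      dtok <- children$partial$backward(d_grid)
      dx <- children$vit$backward(dtok)
    }
    if (has_ps) {
      dps <- children$ps_encoder$backward(d_pyr)
      dx <- if (is.null(dx)) dps else dx + dps
    }
    dx
  }
  nn_finish_module(environment(), c("psnet_model"))
}

#' Run a PSNet forward pass
#'
#' @param model a model from [psnet()] or [build_variant()]
#' @param x image array (b, 3, H, W), values typically normalized to
#'   \[-1, 1\]
#' @return list with `streams` (named list of (b,1,H,W) pre-activation
#'   candidate maps), `xbar` (their mean) and `prob` (`sigmoid(xbar)`)
#' @export
psnet_forward <- function(model, x) model$forward(x)

#' Build a model variant by name
#'
#' The ablation axes: `no_transformer` drops the ViT together with the
#' partial and enhanced decoders and routes only PS features into the merge
#' modules; `no_dual_decoder` replaces both decoders with a pointwise
#' convolution over the concatenated dual-encoder output followed by
#' bilinear upsampling; `no_merge` drops the four merge streams;
#' `no_ps_encoder` drops the CNN branch and its decoder; `no_ccm` replaces
#' every LFE's CCM with identity. The candidate-map average renormalizes
#' over the streams present.
#'
#' @param cfg a [psnet_config()] (its own `variant` field is overridden)
#' @param variant one of [psnet_variants()]
#' @export
build_variant <- function(cfg, variant = "full") {
  variant <- match.arg(variant, psnet_variants())
  cfg$variant <- variant
  m <- psnet(cfg)
  init_weights(m, cfg$seed)
  m
}

# --- Loss and metrics -------------------------------------------------------

#' @keywords internal
check_binary_mask <- function(y) {
  if (!all(y == 0 | y == 1))
    stop("mask must be strictly binary (values 0/1)", call. = FALSE)
  invisible(y)
}

#' Soft IoU loss
#'
#' `loss = 1 - (sum(p*y) + eps) / (sum(p) + sum(y) - sum(p*y) + eps)` with
#' `p = sigmoid(xbar)`, computed per image and averaged over the batch. The
#' complement (1 - soft IoU) is taken so that minimizing the loss maximizes
#' overlap. With the epsilon convention an empty mask predicted empty gives
#' a loss near zero.
#'
#' @param xbar pre-activation map (b, 1, h, w): the averaged candidate map
#' @param y binary ground-truth mask of the same shape
#' @param eps stabilizer (1e-6)
#' @return scalar loss in \[0, 1\]
#' @export
iou_loss <- function(xbar, y, eps = 1e-6) {
  if (!all(dim(xbar) == dim(y)))
    stop(sprintf("shape mismatch: prediction (%s) vs mask (%s)",
                 paste(dim(xbar), collapse = ","), paste(dim(y), collapse = ",")),
         call. = FALSE)
  check_binary_mask(y)
  b <- dim(xbar)[1L]
  p <- sigmoid(xbar)
  pm <- matrix(p, b); ym <- matrix(y, b)
  I <- rowSums(pm * ym)
  U <- rowSums(pm) + rowSums(ym) - I
  mean(1 - (I + eps) / (U + eps))
}

#' Gradient of [iou_loss()] with respect to the pre-activation map
#' @keywords internal
iou_loss_grad <- function(xbar, y, eps = 1e-6) {
  b <- dim(xbar)[1L]
  p <- sigmoid(xbar)
  pm <- matrix(p, b); ym <- matrix(y, b)
  I <- rowSums(pm * ym)
  U <- rowSums(pm) + rowSums(ym) - I
  # d loss_i / d p = -( y (U+eps) - (I+eps)(1-y) ) / (U+eps)^2
  dP <- -(ym * (U + eps) - (I + eps) * (1 - ym)) / (U + eps)^2
  dxbar <- array(dP * pm * (1 - pm), dim(xbar)) / b
  dxbar
}

#' Dice and IoU of a binary prediction against a binary ground truth
#'
#' `dice = 2|P∩G| / (|P| + |G|)`, `iou = |P∩G| / |P∪G|`; two empty masks
#' score (1, 1) by convention.
#'
#' @param pred,gt binary arrays of identical shape
#' @return named numeric vector `c(dice = , iou = )`
#' @export
dice_iou <- function(pred, gt) {
  if (length(pred) != length(gt) ||
      (!is.null(dim(pred)) && !is.null(dim(gt)) && !all(dim(pred) == dim(gt))))
    stop(sprintf("shape mismatch: prediction (%s) vs ground truth (%s)",
                 paste(dim(pred), collapse = ","), paste(dim(gt), collapse = ",")),
         call. = FALSE)
  check_binary_mask(pred); check_binary_mask(gt)
  inter <- sum(pred * gt)
  np <- sum(pred); ng <- sum(gt)
  if (np + ng == 0) return(c(dice = 1, iou = 1))
  c(dice = 2 * inter / (np + ng), iou = inter / (np + ng - inter))
}

#' Binarize a probability map at a threshold
#' @param prob array of probabilities
#' @param threshold decision threshold (0.5)
#' @export
binarize <- function(prob, threshold = 0.5) {
  out <- array(0, dim(prob))
  out[prob > threshold] <- 1
  out
}

# --- Checkpointing ----------------------------------------------------------

#' Save a model (configuration + all tensors) to a file
#' @param model a `psnet_model` (or any `nn_module` with a `config` field)
#' @param path output `.rds` path
#' @export
psnet_save <- function(model, path) {
  saveRDS(list(config = model$config, state = state_dict(model)), path)
  invisible(path)
}

#' Restore a model saved by [psnet_save()]
#' @param path checkpoint path
#' @return a rebuilt `psnet_model` with the saved tensors loaded
#' @export
psnet_load <- function(path) {
  obj <- tryCatch(suppressWarnings(readRDS(path)), error = function(e)
    stop(sprintf("cannot read checkpoint '%s': %s", path, conditionMessage(e)), call. = FALSE))
  if (!is.list(obj) || is.null(obj$config) || is.null(obj$state))
    stop(sprintf("'%s' is not a PSNet checkpoint", path), call. = FALSE)
  m <- psnet(obj$config)
  load_state_dict(m, obj$state)
  m
}
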