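# A minimal neural-network layer system.
#
# A module is an environment of class "nn_module" created by a constructor
# function: every local variable of the constructor (parameters, children,
# forward/backward closures, caches) becomes a field. Reference semantics of
# environments give us in-place gradient accumulation and mutable caches
# without a heavyweight class system -- the same pattern R6 uses underneath.
#
# Conventions every module follows:
#   * params   : named list of nn_parameter objects owned directly
#   * children : named list of sub-modules
#   * training : logical; set recursively with set_training(). In training
#                mode forward() caches what backward() needs; in inference
#                mode nothing is cached and backward() is unavailable.
#   * forward(x): returns the output array
#   * backward(dy): accumulates parameter gradients (param$grad) and returns
#                the gradient w.r.t. the module input
#
# Parameter "kind" tags (conv_weight, linear_weight, bias, norm_weight,
# norm_bias, prelu, pos_embed) drive weight initialisation (init_weights).

#' Create a learnable parameter
#'
#' @param value numeric array/vector holding the initial value
#' @param kind tag used by [init_weights()] to pick the initialiser
#' @keywords internal
nn_parameter <- function(value, kind = "weight") {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$kind <- kind
  class(p) <- "nn_parameter"
  p
}

#' @keywords internal
nn_finish_module <- function(env, classname) {
  if (is.null(env$params)) env$params <- list()
  if (is.null(env$children)) env$children <- list()
  env$training <- FALSE
  class(env) <- c(classname, "nn_module")
  env
}

#' Collect all parameters of a module tree
#'
#' @param m an nn_module
#' @return named list of nn_parameter objects, names are dotted paths
#' @export
module_parameters <- function(m, prefix = "") {
  out <- m$params
  if (length(out) && nzchar(prefix)) names(out) <- paste0(prefix, names(out))
  for (nm in names(m$children)) {
    child <- m$children[[nm]]
    out <- c(out, module_parameters(child, paste0(prefix, nm, ".")))
  }
  out
}

#' Collect non-learnable buffers (running statistics) of a module tree
#' @keywords internal
module_buffers <- function(m, prefix = "") {
  out <- if (is.null(m$buffers)) list() else m$buffers
  if (length(out) && nzchar(prefix)) names(out) <- paste0(prefix, names(out))
  for (nm in names(m$children)) {
    out <- c(out, module_buffers(m$children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

#' Total number of scalar learnable parameters in a module tree
#' @export
n_parameters <- function(m) {
  sum(vapply(module_parameters(m), function(p) length(p$value), numeric(1)))
}

#' Switch a module tree between training and inference mode
#' @export
set_training <- function(m, mode = TRUE) {
  m$training <- mode
  for (child in m$children) set_training(child, mode)
  invisible(m)
}

#' Zero all accumulated gradients in a module tree
#' @export
zero_grad <- function(m) {
  for (p in module_parameters(m)) p$grad <- NULL
  invisible(m)
}

#' @keywords internal
acc_grad <- function(p, g) {
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(p)
}

#' Extract a flat named list of parameter and buffer values
#' @export
state_dict <- function(m) {
  c(lapply(module_parameters(m), function(p) p$value),
    lapply(module_buffers(m), function(b) b$value))
}

#' Load values into a module tree from a named list
#'
#' Shapes must match exactly; names not present in the module are ignored by
#' the caller's choice (see [load_pretrained()] for the reporting loader).
#' @export
load_state_dict <- function(m, sd) {
  slots <- c(module_parameters(m), module_buffers(m))
  for (nm in names(sd)) {
    if (nm %in% names(slots)) {
      tgt <- slots[[nm]]
      if (!identical(dim(tgt$value), dim(sd[[nm]])) ||
          length(tgt$value) != length(sd[[nm]]))
        stop(sprintf("shape mismatch for '%s'", nm), call. = FALSE)
      tgt$value <- sd[[nm]]
    }
  }
  invisible(m)
}

# --- Elementwise activations ------------------------------------------------

#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

#' SiLU activation module: x * sigmoid(x)
#' @export
nn_silu <- function() {
  cache <- NULL
  forward <- function(x) {
    s <- sigmoid(x)
    if (training) cache <<- list(x = x, s = s)
    x * s
  }
  backward <- function(dy) dy * (cache$s * (1 + cache$x * (1 - cache$s)))
  nn_finish_module(environment(), "nn_silu")
}

#' ReLU6 activation module: min(max(x, 0), 6)
#' @export
nn_relu6 <- function() {
  cache <- NULL
  forward <- function(x) {
    if (training) cache <<- (x > 0) & (x < 6)
    pmin(pmax(x, 0), 6)
  }
  backward <- function(dy) dy * cache
  nn_finish_module(environment(), "nn_relu6")
}

#' PReLU with a single learnable slope
#' @export
nn_prelu <- function(init_slope = 0.25) {
  slope <- nn_parameter(init_slope, kind = "prelu")
  params <- list(slope = slope)
  cache <- NULL
  forward <- function(x) {
    if (training) cache <<- x
    out <- x
    neg <- x < 0
    out[neg] <- as.numeric(slope$value) * x[neg]
    out
  }
  backward <- function(dy) {
    x <- cache
    neg <- x < 0
    acc_grad(slope, sum(dy[neg] * x[neg]))
    dx <- dy
    dx[neg] <- dy[neg] * as.numeric(slope$value)
    dx
  }
  nn_finish_module(environment(), "nn_prelu")
}

#' Identity module (used by ablations)
#' @export
nn_identity <- function() {
  forward <- function(x) x
  backward <- function(dy) dy
  nn_finish_module(environment(), "nn_identity")
}

#' @keywords internal
make_activation <- function(name) {
  switch(name,
         silu = nn_silu(),
         relu6 = nn_relu6(),
         prelu = nn_prelu(),
         none = nn_identity(),
         stop(sprintf("unknown activation '%s'", name), call. = FALSE))
}

# --- Convolution module -----------------------------------------------------

#' 2-D convolution layer
#'
#' @param in_ch,out_ch channel counts (out_ch must equal in_ch when
#'   depthwise)
#' @param k kernel size, scalar or (kh, kw)
#' @param pad padding, scalar or (ph, pw)
#' @param depthwise logical; one filter per channel
#' @export
nn_conv2d <- function(in_ch, out_ch, k, stride = 1L, pad = 0L, dil = 1L,
                      depthwise = FALSE, bias = TRUE) {
  k <- as.integer(rep(k, length.out = 2L))
  pad <- as.integer(rep(pad, length.out = 2L))
  if (any(k < 1L) || dil < 1L || stride < 1L || any(pad < 0L))
    stop("invalid convolution geometry", call. = FALSE)
  if (depthwise && in_ch != out_ch)
    stop("depthwise convolution must preserve channel count", call. = FALSE)
  wdim <- if (depthwise) c(out_ch, k) else c(out_ch, in_ch, k)
  weight <- nn_parameter(array(stats::rnorm(prod(wdim), 0, 0.02), wdim), kind = "conv_weight")
  params <- list(weight = weight)
  if (bias) {
    bias_p <- nn_parameter(numeric(out_ch), kind = "bias")
    params$bias <- bias_p
  } else bias_p <- NULL
  cache <- NULL
  forward <- function(x) {
    ft_check_4d(x)
    if (dim(x)[2L] != in_ch)
      stop(sprintf("channel mismatch: input shape (%s) but layer expects %d channels",
                   paste(dim(x), collapse = ","), in_ch), call. = FALSE)
    if (training) cache <<- x
    bv <- if (is.null(bias_p)) NULL else bias_p$value
    if (depthwise) conv2d_dw(x, weight$value, bv, stride, pad, dil)
    else conv2d_dense(x, weight$value, bv, stride, pad, dil)
  }
  backward <- function(dy) {
    g <- if (depthwise) conv2d_dw_bwd(dy, cache, weight$value, stride, pad, dil)
         else conv2d_dense_bwd(dy, cache, weight$value, stride, pad, dil)
    acc_grad(weight, g$dw)
    if (!is.null(bias_p)) acc_grad(bias_p, g$db)
    g$dx
  }
  nn_finish_module(environment(), "nn_conv2d")
}

# --- Batch normalization ----------------------------------------------------

#' 2-D batch normalization
#'
#' Training mode normalizes with batch statistics and updates running
#' statistics (momentum 0.1, unbiased running variance); inference mode uses
#' the running statistics.
#' @export
nn_batchnorm2d <- function(ch, eps = 1e-5, momentum = 0.1) {
  weight <- nn_parameter(rep(1, ch), kind = "norm_weight")
  bias <- nn_parameter(rep(0, ch), kind = "norm_bias")
  params <- list(weight = weight, bias = bias)
  run_mean <- new.env(parent = emptyenv()); run_mean$value <- rep(0, ch)
  run_var <- new.env(parent = emptyenv()); run_var$value <- rep(1, ch)
  buffers <- list(running_mean = run_mean, running_var = run_var)
  cache <- NULL
  forward <- function(x) {
    d <- dim(x); b <- d[1L]
    if (d[2L] != ch)
      stop(sprintf("channel mismatch: input shape (%s) but batchnorm has %d channels",
                   paste(d, collapse = ","), ch), call. = FALSE)
    n <- b * d[3L] * d[4L]
    if (training) {
      mu <- ft_channel_sum(x) / n
      xc <- x - ft_bc_channel(mu, b)
      var_b <- ft_channel_sum(xc * xc) / n
      inv <- 1 / sqrt(var_b + eps)
      xhat <- xc * ft_bc_channel(inv, b)
      if (n > 1) {
        run_mean$value <<- (1 - momentum) * run_mean$value + momentum * mu
        run_var$value <<- (1 - momentum) * run_var$value + momentum * var_b * n / (n - 1)
      }
      cache <<- list(xhat = xhat, inv = inv, n = n, b = b)
      xhat * ft_bc_channel(weight$value, b) + ft_bc_channel(bias$value, b)
    } else {
      inv <- 1 / sqrt(run_var$value + eps)
      (x - ft_bc_channel(run_mean$value, b)) * ft_bc_channel(inv * weight$value, b) +
        ft_bc_channel(bias$value, b)
    }
  }
  backward <- function(dy) {
    ch_ <- ch
    xhat <- cache$xhat; inv <- cache$inv; n <- cache$n; b <- cache$b
    dgamma <- ft_channel_sum(dy * xhat)
    dbeta <- ft_channel_sum(dy)
    acc_grad(weight, dgamma)
    acc_grad(bias, dbeta)
    dxhat <- dy * ft_bc_channel(weight$value, b)
    s1 <- ft_channel_sum(dxhat)
    s2 <- ft_channel_sum(dxhat * xhat)
    (dxhat - ft_bc_channel(s1 / n, b) - xhat * ft_bc_channel(s2 / n, b)) *
      ft_bc_channel(inv, b)
  }
  nn_finish_module(environment(), "nn_batchnorm2d")
}

# --- Linear / LayerNorm (token tensors, (b, n, d)) --------------------------

#' Fully-connected layer applied to the last axis of a (b, n, d) array
#' @export
nn_linear <- function(in_f, out_f, bias = TRUE) {
  weight <- nn_parameter(array(stats::rnorm(out_f * in_f, 0, 0.02), c(out_f, in_f)),
                         kind = "linear_weight")
  params <- list(weight = weight)
  if (bias) {
    bias_p <- nn_parameter(numeric(out_f), kind = "bias")
    params$bias <- bias_p
  } else bias_p <- NULL
  cache <- NULL
  forward <- function(x) {
    d <- dim(x)
    if (d[length(d)] != in_f)
      stop(sprintf("feature mismatch: input shape (%s) but linear expects %d features",
                   paste(d, collapse = ","), in_f), call. = FALSE)
    xm <- matrix(x, prod(d[-length(d)]), in_f)
    if (training) cache <<- list(xm = xm, d = d)
    y <- xm %*% t(weight$value)
    if (!is.null(bias_p)) y <- sweep(y, 2L, bias_p$value, "+")
    array(y, c(d[-length(d)], out_f))
  }
  backward <- function(dy) {
    d <- cache$d
    dym <- matrix(dy, nrow(cache$xm), out_f)
    acc_grad(weight, t(dym) %*% cache$xm)
    if (!is.null(bias_p)) acc_grad(bias_p, colSums(dym))
    array(dym %*% weight$value, d)
  }
  nn_finish_module(environment(), "nn_linear")
}

#' Layer normalization over the last axis
#' @export
nn_layernorm <- function(d_model, eps = 1e-6) {
  weight <- nn_parameter(rep(1, d_model), kind = "norm_weight")
  bias <- nn_parameter(rep(0, d_model), kind = "norm_bias")
  params <- list(weight = weight, bias = bias)
  cache <- NULL
  forward <- function(x) {
    d <- dim(x)
    xm <- matrix(x, prod(d[-length(d)]), d_model)
    mu <- rowMeans(xm)
    xc <- xm - mu
    v <- rowMeans(xc * xc)
    inv <- 1 / sqrt(v + eps)
    xhat <- xc * inv
    if (training) cache <<- list(xhat = xhat, inv = inv, d = d)
    array(sweep(sweep(xhat, 2L, weight$value, "*"), 2L, bias$value, "+"), d)
  }
  backward <- function(dy) {
    d <- cache$d
    dym <- matrix(dy, nrow(cache$xhat), d_model)
    acc_grad(weight, colSums(dym * cache$xhat))
    acc_grad(bias, colSums(dym))
    dxhat <- sweep(dym, 2L, weight$value, "*")
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * cache$xhat)
    array((dxhat - m1 - cache$xhat * m2) * cache$inv, d)
  }
  nn_finish_module(environment(), "nn_layernorm")
}

# --- Composition helpers ----------------------------------------------------

#' Chain a list of modules sequentially
#' @export
nn_sequential <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && is.list(mods[[1L]]) && !inherits(mods[[1L]], "nn_module"))
    mods <- mods[[1L]]
  if (is.null(names(mods)) || any(!nzchar(names(mods))))
    names(mods) <- sprintf("m%02d", seq_along(mods))
  children <- mods
  forward <- function(x) {
    for (m in children) x <- m$forward(x)
    x
  }
  backward <- function(dy) {
    for (m in rev(children)) dy <- m$backward(dy)
    dy
  }
  nn_finish_module(environment(), "nn_sequential")
}

#' 2x2 max-pool module
#' @export
nn_maxpool2 <- function() {
  cache <- NULL
  forward <- function(x) {
    r <- maxpool2_fwd(x)
    if (training) cache <<- list(masks = r$masks, in_dim = dim(x))
    r$y
  }
  backward <- function(dy) maxpool2_bwd(dy, cache$masks, cache$in_dim)
  nn_finish_module(environment(), "nn_maxpool2")
}

#' Bilinear up/down-sampling module to a fixed scale factor
#' @export
nn_upsample <- function(factor) {
  cache <- NULL
  forward <- function(x) {
    d <- dim(x)
    if (training) cache <<- d
    ft_resize(x, as.integer(round(d[3L] * factor)), as.integer(round(d[4L] * factor)))
  }
  backward <- function(dy) ft_resize_bwd(dy, cache[3L], cache[4L])
  nn_finish_module(environment(), "nn_upsample")
}
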