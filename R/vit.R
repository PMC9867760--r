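# Transformer (ViT) encoder branch.
#
# The image is cut into non-overlapping P x P patches, flattened, linearly
# embedded and summed with a learnable positional embedding; L pre-norm
# transformer blocks (multi-headed self-attention + MLP) follow, then a
# final layer norm. No class token is kept: the decoder consumes exactly the
# N = (H/P)(W/P) patch tokens. Token order is row-major over the patch grid.

#' Transformer encoder configuration
#'
#' Defaults are the ViT-B/16 variant (embed dim 768, depth 12, 12 heads,
#' MLP ratio 4) at 512 x 512 input. The "tiny" preset used throughout the
#' test suite is `vit_config(img_size = 64, depth = 2, dim = 64, heads = 4)`.
#'
#' @param img_size input image side length (multiple of `patch`)
#' @param patch patch size P
#' @param depth number of transformer blocks L
#' @param dim embedding dimension d (divisible by `heads`)
#' @param heads number of attention heads
#' @param mlp_ratio MLP hidden width as a multiple of `dim`
#' @return a list of class `vit_config`
#' @export
vit_config <- function(img_size = 512L, patch = 16L, depth = 12L, dim = 768L,
                       heads = 12L, mlp_ratio = 4L) {
  if (img_size %% patch != 0L)
    stop(sprintf("image size %d is not divisible by patch size %d", img_size, patch), call. = FALSE)
  if (dim %% heads != 0L)
    stop(sprintf("embed dim %d is not divisible by %d heads", dim, heads), call. = FALSE)
  structure(list(img_size = as.integer(img_size), patch = as.integer(patch),
                 depth = as.integer(depth), dim = as.integer(dim),
                 heads = as.integer(heads), mlp_ratio = mlp_ratio),
            class = "vit_config")
}

#' Cut an image into flattened non-overlapping patches
#'
#' @param x image array (b, c, H, W); P must divide H and W
#' @param patch patch side length P
#' @return token array (b, N, P*P*c), tokens ordered row-major over the
#'   patch grid
#' @export
patchify <- function(x, patch) {
  ft_check_4d(x)
  d <- dim(x)
  if (d[3L] %% patch || d[4L] %% patch)
    stop(sprintf("spatial dims (%d, %d) not divisible by patch size %d",
                 d[3L], d[4L], patch), call. = FALSE)
  gh <- d[3L] %/% patch; gw <- d[4L] %/% patch
  dim(x) <- c(d[1L], d[2L], patch, gh, patch, gw)
  x <- aperm(x, c(1L, 6L, 4L, 3L, 5L, 2L))   # (b, j, i, pi, pj, c)
  dim(x) <- c(d[1L], gw * gh, patch * patch * d[2L])
  x
}

#' Inverse of [patchify()]
#'
#' @param tok token array (b, N, P*P*c)
#' @param patch patch side P
#' @param channels channel count c of the original image
#' @export
unpatchify <- function(tok, patch, channels) {
  d <- dim(tok)
  g <- as.integer(round(sqrt(d[2L])))
  if (g * g != d[2L]) stop("token count is not a perfect square", call. = FALSE)
  dim(tok) <- c(d[1L], g, g, patch, patch, channels)
  tok <- aperm(tok, c(1L, 6L, 4L, 3L, 5L, 2L))
  dim(tok) <- c(d[1L], channels, g * patch, g * patch)
  tok
}

# GELU (exact, via the normal CDF).
#' @keywords internal
nn_gelu <- function() {
  cache <- NULL
  forward <- function(x) {
    if (training) cache <<- x
    x * stats::pnorm(x)
  }
  backward <- function(dy) {
    x <- cache
    dy * (stats::pnorm(x) + x * stats::dnorm(x))
  }
  nn_finish_module(environment(), "nn_gelu")
}

#' Multi-headed scaled dot-product self-attention
#' @keywords internal
nn_attention <- function(d_model, heads) {
  dh <- d_model %/% heads
  children <- list(qkv = nn_linear(d_model, 3L * d_model),
                   proj = nn_linear(d_model, d_model))
  cache <- NULL
  forward <- function(x) {
    dd <- dim(x); b <- dd[1L]; n <- dd[2L]
    qkv <- children$qkv$forward(x)            # (b, n, 3d)
    O <- array(0, c(b, n, d_model))
    ca <- if (training) vector("list", b * heads) else NULL
    for (bi in seq_len(b)) {
      for (hd in seq_len(heads)) {
        idx <- (hd - 1L) * dh + seq_len(dh)
        Q <- matrix(qkv[bi, , idx], n, dh)
        K <- matrix(qkv[bi, , d_model + idx], n, dh)
        V <- matrix(qkv[bi, , 2L * d_model + idx], n, dh)
        S <- (Q %*% t(K)) / sqrt(dh)
        S <- S - apply(S, 1L, max)
        A <- exp(S); A <- A / rowSums(A)
        O[bi, , idx] <- A %*% V
        if (training) ca[[(bi - 1L) * heads + hd]] <- list(Q = Q, K = K, V = V, A = A)
      }
    }
    if (training) cache <<- list(ca = ca, b = b, n = n)
    children$proj$forward(O)
  }
  backward <- function(dy) {
    dO <- children$proj$backward(dy)
    b <- cache$b; n <- cache$n
    dqkv <- array(0, c(b, n, 3L * d_model))
    for (bi in seq_len(b)) {
      for (hd in seq_len(heads)) {
        idx <- (hd - 1L) * dh + seq_len(dh)
        cc <- cache$ca[[(bi - 1L) * heads + hd]]
        dOh <- matrix(dO[bi, , idx], n, dh)
        dV <- t(cc$A) %*% dOh
        dA <- dOh %*% t(cc$V)
        dS <- cc$A * (dA - rowSums(dA * cc$A))
        dS <- dS / sqrt(dh)
        dqkv[bi, , idx] <- dS %*% cc$K
        dqkv[bi, , d_model + idx] <- t(dS) %*% cc$Q
        dqkv[bi, , 2L * d_model + idx] <- dV
      }
    }
    children$qkv$backward(dqkv)
  }
  # expose attention maps for diagnostics/tests
  attention_maps <- function() lapply(cache$ca, `[[`, "A")
  nn_finish_module(environment(), "nn_attention")
}

#' One pre-norm transformer block: x + MSA(LN(x)); x + MLP(LN(x))
#' @keywords internal
nn_vit_block <- function(d_model, heads, mlp_ratio = 4L) {
  children <- list(
    ln1 = nn_layernorm(d_model),
    attn = nn_attention(d_model, heads),
    ln2 = nn_layernorm(d_model),
    mlp = nn_sequential(list(fc1 = nn_linear(d_model, as.integer(d_model * mlp_ratio)),
                             gelu = nn_gelu(),
                             fc2 = nn_linear(as.integer(d_model * mlp_ratio), d_model)))
  )
  forward <- function(x) {
    x <- x + children$attn$forward(children$ln1$forward(x))
    x + children$mlp$forward(children$ln2$forward(x))
  }
  backward <- function(dy) {
    dy <- dy + children$ln2$backward(children$mlp$backward(dy))
    dy + children$ln1$backward(children$attn$backward(dy))
  }
  nn_finish_module(environment(), "nn_vit_block")
}

#' Build a ViT encoder module
#'
#' @param cfg a [vit_config()]
#' @return an `nn_module` whose forward maps an image (b, 3, H, W) to a
#'   token sequence (b, N, dim)
#' @export
nn_vit <- function(cfg) {
  stopifnot(inherits(cfg, "vit_config"))
  g <- cfg$img_size %/% cfg$patch
  n_tok <- g * g
  pos_embed <- nn_parameter(
    array(stats::rnorm(n_tok * cfg$dim, 0, 0.02), c(n_tok, cfg$dim)),
    kind = "pos_embed")
  params <- list(pos_embed = pos_embed)
  blocks <- lapply(seq_len(cfg$depth), function(i) nn_vit_block(cfg$dim, cfg$heads, cfg$mlp_ratio))
  names(blocks) <- sprintf("block%02d", seq_len(cfg$depth))
  children <- c(list(patch_embed = nn_linear(cfg$patch^2 * 3L, cfg$dim)),
                blocks,
                list(norm = nn_layernorm(cfg$dim)))
  config <- cfg
  forward <- function(x) {
    d <- dim(x)
    if (d[3L] != cfg$img_size || d[4L] != cfg$img_size)
      stop(sprintf("input (%s) does not match configured image size %d",
                   paste(d, collapse = ","), cfg$img_size), call. = FALSE)
    tok <- children$patch_embed$forward(patchify(x, cfg$patch))
    tok <- tok + aperm(array(pos_embed$value, c(n_tok, cfg$dim, d[1L])), c(3L, 1L, 2L))
    for (i in seq_len(cfg$depth)) tok <- children[[sprintf("block%02d", i)]]$forward(tok)
    children$norm$forward(tok)
  }
  backward <- function(dy) {
    dy <- children$norm$backward(dy)
    for (i in rev(seq_len(cfg$depth))) dy <- children[[sprintf("block%02d", i)]]$backward(dy)
    b <- dim(dy)[1L]
    acc_grad(pos_embed, matrix(colSums(matrix(dy, b, n_tok * cfg$dim)), n_tok, cfg$dim))
    dtok <- children$patch_embed$backward(dy)
    unpatchify(dtok, cfg$patch, 3L)
  }
  nn_finish_module(environment(), "nn_vit")
}

#' Encode an image with a ViT module
#'
#' Convenience wrapper: `vit_encode(x, vit)` equals `vit$forward(x)`.
#' @param x image array (b, 3, H, W)
#' @param vit module from [nn_vit()]
#' @return token array (b, N, dim)
#' @export
vit_encode <- function(x, vit) vit$forward(x)

#' Embed an image into patch tokens (patch embedding + positional embedding)
#'
#' The first stage of the transformer branch on its own: patchify, linear
#' embedding, positional embedding. No transformer blocks are applied.
#' @param x image array (b, 3, H, W)
#' @param vit module from [nn_vit()]
#' @export
patchify_embed <- function(x, vit) {
  tok <- vit$children$patch_embed$forward(patchify(x, vit$config$patch))
  np <- nrow(vit$params$pos_embed$value)
  tok + aperm(array(vit$params$pos_embed$value, c(np, dim(tok)[3L], dim(x)[1L])), c(3L, 1L, 2L))
}

#' Load pretrained weights into a module with a report
#'
#' Reads a serialized tensor dictionary (an `.rds` file holding a named list
#' of numeric arrays; names follow this package's dotted `state_dict()`
#' paths) and assigns every tensor whose name and shape match. Positional
#' embeddings whose token grid differs from the model's are interpolated
#' bicubically to the model grid. Nothing fails silently: the returned
#' report lists loaded, skipped (shape mismatch) and missing tensors.
#'
#' @param model an `nn_module` (typically the ViT encoder)
#' @param checkpoint path to an `.rds` tensor dictionary
#' @return a list of class `psnet_load_report` with elements `loaded`,
#'   `skipped`, `missing`
#' @export
load_pretrained <- function(model, checkpoint) {
  sd <- tryCatch(suppressWarnings(readRDS(checkpoint)), error = function(e)
    stop(sprintf("cannot read checkpoint '%s': %s", checkpoint, conditionMessage(e)), call. = FALSE))
  if (!is.list(sd) || is.null(names(sd)))
    stop(sprintf("checkpoint '%s' is not a named tensor dictionary", checkpoint), call. = FALSE)
  slots <- c(module_parameters(model), module_buffers(model))
  loaded <- character(); skipped <- character()
  for (nm in names(sd)) {
    if (!nm %in% names(slots)) { skipped <- c(skipped, nm); next }
    src <- sd[[nm]]; tgt <- slots[[nm]]
    if (grepl("pos_embed", nm) && !is.null(dim(src)) && length(dim(src)) == 2L &&
        !identical(dim(src), dim(tgt$value)) && ncol(src) == ncol(tgt$value)) {
      g0 <- as.integer(round(sqrt(nrow(src)))); g1 <- as.integer(round(sqrt(nrow(tgt$value))))
      if (g0 * g0 == nrow(src) && g1 * g1 == nrow(tgt$value)) {
        # (N0, d) -> (1, d, g0, g0) -> bicubic -> (N1, d)
        dd <- ncol(src)
        grid <- aperm(array(src, c(g0, g0, dd)), c(3L, 2L, 1L))  # (d, i, j); rows of src are j-fastest
        dim(grid) <- c(1L, dd, g0, g0)
        grid <- ft_resize(grid, g1, g1, method = "bicubic")
        out <- aperm(array(grid[1L, , , ], c(dd, g1, g1)), c(3L, 2L, 1L))
        tgt$value <- matrix(out, g1 * g1, dd)
        loaded <- c(loaded, nm)
        next
      }
    }
    same_shape <- if (is.null(dim(tgt$value))) length(src) == length(tgt$value) &&
                    is.null(dim(src)) else identical(dim(src), dim(tgt$value))
    if (!same_shape) { skipped <- c(skipped, nm); next }
    tgt$value <- src
    loaded <- c(loaded, nm)
  }
  missing <- setdiff(names(slots), names(sd))
  structure(list(loaded = loaded, skipped = skipped, missing = missing),
            class = "psnet_load_report")
}

#' @export
print.psnet_load_report <- function(x, ...) {
  cat(sprintf("checkpoint load: %d loaded, %d skipped, %d missing\n",
              length(x$loaded), length(x$skipped), length(x$missing)))
  if (length(x$skipped)) cat("  skipped:", paste(x$skipped, collapse = ", "), "\n")
  if (length(x$missing)) cat("  missing:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}
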