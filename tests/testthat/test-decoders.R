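# Partial decoder, enhanced dilated decoder, wSq/SCSE and the PS decoder.

test_that("partial decoder maps tokens to a mu-channel grid", {
  set.seed(40)
  pd <- nn_partial_decoder(16L, 8L)
  tok <- array(rnorm(2 * 16 * 16), c(2, 16, 16))
  g <- pd$forward(tok)
  expect_equal(dim(g), c(2, 8, 4, 4))
  pd1 <- nn_partial_decoder(16L, 1L)
  expect_equal(dim(pd1$forward(tok)), c(2, 1, 4, 4))
  expect_error(pd$forward(array(0, c(1, 5, 16))), "perfect square")
})

test_that("token-grid rearrangement round-trips exactly", {
  set.seed(41)
  z <- array(rnorm(2 * 9 * 5), c(2, 9, 5))
  expect_identical(grid_to_tokens(tokens_to_grid(z)), z)
})

test_that("partial decoder is linear in its input when the bias is zero", {
  set.seed(42)
  pd <- nn_partial_decoder(6L, 4L)
  pd$children$proj$params$bias$value <- numeric(4L)
  tok <- array(rnorm(1 * 4 * 6), c(1, 4, 6))
  expect_equal(pd$forward(3.7 * tok), 3.7 * pd$forward(tok), tolerance = 1e-12)
})

test_that("enhanced decoder emits a full-resolution single-channel map", {
  ed <- nn_enhanced_decoder(8L)
  g <- array(rnorm(1 * 8 * 4 * 4), c(1, 8, 4, 4))
  y <- ed$forward(g)
  expect_equal(dim(y), c(1, 1, 64, 64))      # 16x the input scale
  expect_error(nn_enhanced_decoder(8L, up_factors = c(2L, 4L)), "multiply to 16")
})

test_that("enhanced decoder with all parameters zeroed emits a zero map", {
  ed <- nn_enhanced_decoder(4L)
  for (p in module_parameters(ed)) p$value <- p$value * 0
  y <- ed$forward(array(rnorm(1 * 4 * 2 * 2), c(1, 4, 2, 2)))
  expect_true(all(y == 0))
})

test_that("wSq with gates forced to 1 doubles the input, forced to 0 zeroes it", {
  set.seed(43)
  m <- nn_wsq(4L, wsq_config(kernel = 3L, pad = 1L))
  x <- array(rnorm(1 * 4 * 6 * 6), c(1, 4, 6, 6))
  for (bias_val in c(30, -30)) {
    m$children$pw_a2$params$weight$value <- m$children$pw_a2$params$weight$value * 0
    m$children$pw_a2$params$bias$value <- rep(bias_val, 4L)
    m$children$pw_b$params$weight$value <- m$children$pw_b$params$weight$value * 0
    m$children$pw_b$params$bias$value <- bias_val
    y <- m$forward(x)
    if (bias_val > 0) expect_equal(y, 2 * x, tolerance = 1e-10)
    else expect_equal(y, x * 0, tolerance = 1e-10)
  }
})

test_that("wSq equals the stepwise gate-composition oracle", {
  set.seed(44)
  cfgw <- wsq_config()                        # kernel 7, stride 1, pad 3
  m <- nn_wsq(8L, cfgw)
  x <- array(rnorm(1 * 8 * 16 * 16), c(1, 8, 16, 16))
  got <- m$forward(x)
  # oracle: WAP (zero-padded average including pad in the denominator),
  # two pointwise convs, sigmoid; plus 1-channel pointwise gate; Eq sum
  sig <- function(z) 1 / (1 + exp(-z))
  wap <- psnet:::wap_fwd(x, cfgw$kernel, cfgw$stride, cfgw$pad)
  ga <- sig(m$children$pw_a2$forward(m$children$pw_a1$forward(wap)))
  gb <- sig(m$children$pw_b$forward(x))
  want <- x * ga + x * psnet:::bc_spatial(gb, 8L)
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("WAP down-weights borders by including padding in the denominator", {
  x <- array(1, c(1, 2, 9, 9))
  p <- psnet:::wap_fwd(x, 3L, 1L, 1L)
  expect_equal(p[1, 1, 5, 5], 1)              # interior: full window
  expect_equal(p[1, 1, 1, 1], 4 / 9)          # corner: 4 of 9 taps inside
})

test_that("wSq and SCSE reject configurations that collapse channels", {
  expect_error(nn_wsq(2L, wsq_config(ratio = 3L)), "collapses")
  expect_error(nn_scse(2L, ratio = 3L), "collapses")
})

test_that("SCSE output is spatially constant for spatially constant input", {
  set.seed(45)
  m <- nn_scse(4L)
  x <- array(rep(rnorm(4), each = 1), c(1, 4, 1, 1))[, , rep(1, 6), rep(1, 6), drop = FALSE]
  y <- m$forward(x)
  for (c in 1:4) expect_lt(diff(range(y[1, c, , ])), 1e-12)
})

test_that("SCSE with gates forced to 1 doubles the input", {
  set.seed(46)
  m <- nn_scse(4L)
  x <- array(rnorm(1 * 4 * 5 * 5), c(1, 4, 5, 5))
  m$children$pw_c2$params$weight$value <- m$children$pw_c2$params$weight$value * 0
  m$children$pw_c2$params$bias$value <- rep(30, 4L)
  m$children$pw_s$params$weight$value <- m$children$pw_s$params$weight$value * 0
  m$children$pw_s$params$bias$value <- 30
  expect_equal(m$forward(x), 2 * x, tolerance = 1e-10)
})

test_that("SCSE equals its stepwise composition oracle", {
  set.seed(47)
  m <- nn_scse(6L)
  x <- array(rnorm(2 * 6 * 7 * 7), c(2, 6, 7, 7))
  sig <- function(z) 1 / (1 + exp(-z))
  p <- psnet:::ft_gap(x)
  gc_ <- sig(m$children$pw_c2$forward(pmax(m$children$pw_c1$forward(p), 0)))
  gs <- sig(m$children$pw_s$forward(x))
  want <- x * psnet:::bc_channel(gc_, 7L, 7L) + x * psnet:::bc_spatial(gs, 6L)
  expect_lt(max(abs(m$forward(x) - want)), 1e-6)
})

test_that("PS decoder maps a tiny pyramid to a full-resolution map", {
  set.seed(48)
  dec <- nn_ps_decoder()
  pyr <- list(array(rnorm(1 * 64 * 32 * 32), c(1, 64, 32, 32)),
              array(rnorm(1 * 128 * 16 * 16), c(1, 128, 16, 16)),
              array(rnorm(1 * 256 * 8 * 8), c(1, 256, 8, 8)),
              array(rnorm(1 * 512 * 4 * 4), c(1, 512, 4, 4)))
  y <- dec$forward(pyr)
  expect_equal(dim(y), c(1, 1, 64, 64))
})

test_that("PS decoder rejects a pyramid that disagrees with its configuration", {
  dec <- nn_ps_decoder()
  pyr <- list(array(0, c(1, 64, 32, 32)), array(0, c(1, 128, 16, 16)),
              array(0, c(1, 256, 8, 8)), array(0, c(1, 100, 4, 4)))
  expect_error(dec$forward(pyr), "pyramid/config mismatch")
})

test_that("zeroing a skip connection changes the PS decoder output", {
  set.seed(49)
  dec <- nn_ps_decoder()
  # training mode: batch statistics renormalize each stage, so the probe
  # signal survives the depth (fresh running stats in inference mode let
  # small-weight activations decay below double precision)
  set_training(dec, TRUE)
  pyr <- list(array(rnorm(1 * 64 * 32 * 32), c(1, 64, 32, 32)),
              array(rnorm(1 * 128 * 16 * 16), c(1, 128, 16, 16)),
              array(rnorm(1 * 256 * 8 * 8), c(1, 256, 8, 8)),
              array(rnorm(1 * 512 * 4 * 4), c(1, 512, 4, 4)))
  y0 <- dec$forward(pyr)
  pyr2 <- pyr
  pyr2[[2]] <- pyr2[[2]] * 0
  expect_gt(max(abs(dec$forward(pyr2) - y0)), 1e-8)
})

test_that("wSq and SCSE preserve input shape exactly", {
  x <- array(rnorm(2 * 8 * 6 * 6), c(2, 8, 6, 6))
  expect_equal(dim(nn_wsq(8L, wsq_config(kernel = 3L, pad = 1L))$forward(x)), dim(x))
  expect_equal(dim(nn_scse(8L)$forward(x)), dim(x))
})
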