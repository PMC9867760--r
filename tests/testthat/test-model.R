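# Full model assembly, candidate averaging, loss, metrics, variants,
# checkpointing.

test_that("PS encoder produces the four-scale pyramid with the configured channels", {
  enc <- nn_ps_encoder()
  x <- rand_image(size = 64L)
  pyr <- ps_encode(x, enc)
  expect_length(pyr, 4)
  for (i in 1:4) expect_equal(dim(pyr[[i]]),
                              c(1, c(64, 128, 256, 512)[i], 64 / 2^i, 64 / 2^i))
  expect_error(enc$forward(array(0, c(1, 3, 50, 50))), "divisible by 16")
})

test_that("averaging six constant streams 0..5 gives 2.5 everywhere", {
  streams <- lapply(0:5, function(v) array(v, c(1, 1, 4, 4)))
  xbar <- Reduce(`+`, streams) / 6
  expect_true(all(xbar == 2.5))
})

test_that("tiny full model emits six streams whose mean is xbar", {
  m <- tiny_model()
  out <- psnet_forward(m, rand_image(seed = 60))
  expect_named(out$streams, c("t", "c", "m2", "m4", "m8", "m16"))
  for (s in out$streams) expect_equal(dim(s), c(1, 1, 64, 64))
  expect_equal(out$xbar, Reduce(`+`, out$streams) / 6, tolerance = 1e-12)
  expect_equal(out$prob, 1 / (1 + exp(-out$xbar)), tolerance = 1e-12)
})

test_that("inference is deterministic for a fixed model and input", {
  m <- tiny_model()
  x <- rand_image(seed = 61)
  expect_identical(psnet_forward(m, x)$xbar, psnet_forward(m, x)$xbar)
})

test_that("model rejects inputs at the wrong size", {
  m <- tiny_model()
  expect_error(psnet_forward(m, array(0, c(1, 3, 32, 32))), "image size")
})

test_that("every variant builds, runs, and has strictly fewer parameters than full", {
  np_full <- n_parameters(tiny_model())
  x <- rand_image(seed = 62)
  for (v in setdiff(psnet_variants(), "full")) {
    m <- tiny_model(variant = v)
    expect_lt(n_parameters(m), np_full)
    out <- psnet_forward(m, x)
    n_expect <- switch(v, no_merge = 2L, no_ccm = 6L, 5L)
    expect_length(out$streams, n_expect)
    expect_equal(out$xbar, Reduce(`+`, out$streams) / n_expect, tolerance = 1e-12)
  }
})

test_that("the no_transformer variant has no ViT tensors", {
  m <- tiny_model(variant = "no_transformer")
  expect_false(any(grepl("^vit\\.", names(module_parameters(m)))))
})

test_that("without CCM the LFE forward equals the dual-DWSC-only chain", {
  set.seed(63)
  lfe <- nn_lfe(3L, 6L, use_ccm = FALSE)
  x <- array(rnorm(1 * 3 * 8 * 8), c(1, 3, 8, 8))
  ch <- lfe$children$body$children
  want <- ch$dwsc2$forward(ch$dwsc1$forward(x))
  expect_identical(lfe$forward(x), want)
})

test_that("soft IoU loss satisfies its limit and hand-computed cases", {
  y <- array(0, c(1, 1, 4, 4)); y[1, 1, 1:2, 1:2] <- 1
  perfect <- array(-20, c(1, 1, 4, 4)); perfect[1, 1, 1:2, 1:2] <- 20
  expect_lt(iou_loss(perfect, y), 1e-6)
  # all-empty mask with confident empty prediction: near zero by the epsilon
  # convention (exactly 1 - eps/(sum(p) + eps), small because sum(p) -> 0)
  expect_lt(iou_loss(array(-20, c(1, 1, 4, 4)), array(0, c(1, 1, 4, 4))), 0.05)
  # 2x2 case: sigma = 0.5 everywhere, one positive pixel
  # soft-I = 0.5, soft-U = 2 + 1 - 0.5 = 2.5, loss = 1 - 0.2 = 0.8
  y2 <- array(c(1, 0, 0, 0), c(1, 1, 2, 2))
  expect_equal(iou_loss(array(0, c(1, 1, 2, 2)), y2), 0.8, tolerance = 1e-6)
  expect_error(iou_loss(array(0, c(1, 1, 2, 2)), array(0.5, c(1, 1, 2, 2))),
               "binary")
  expect_error(iou_loss(array(0, c(1, 1, 2, 2)), array(0, c(1, 1, 3, 3))),
               "shape mismatch")
})

test_that("loss decreases monotonically toward 0 as logit confidence grows", {
  y <- array(0, c(1, 1, 4, 4)); y[1, 1, 1:2, ] <- 1
  losses <- vapply(c(1, 2, 5, 10, 20), function(a) {
    xb <- array(-a, dim(y)); xb[y == 1] <- a
    iou_loss(xb, y)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_lt(losses[length(losses)], 1e-6)
})

test_that("dice and IoU satisfy their identities and counted cases", {
  a <- array(1, c(1, 1, 2, 2))
  expect_equal(dice_iou(a, a), c(dice = 1, iou = 1))
  b <- array(0, c(1, 1, 2, 2))
  expect_equal(dice_iou(b, b), c(dice = 1, iou = 1))   # empty-vs-empty convention
  d <- array(c(1, 1, 0, 0), c(1, 1, 2, 2))
  e <- array(c(0, 0, 1, 1), c(1, 1, 2, 2))
  expect_equal(dice_iou(d, e), c(dice = 0, iou = 0))
  # |P| = 4, |G| = 4, |P ∩ G| = 2  ->  dice 0.5, iou 1/3
  p <- array(0, c(1, 1, 3, 3)); p[1, 1, 1, ] <- 1; p[1, 1, 2, 1] <- 1
  g <- array(0, c(1, 1, 3, 3)); g[1, 1, 1, 1:2] <- 1; g[1, 1, 3, 1:2] <- 1
  expect_equal(sum(p), 4); expect_equal(sum(g), 4); expect_equal(sum(p * g), 2)
  expect_equal(dice_iou(p, g), c(dice = 0.5, iou = 1 / 3))
  expect_error(dice_iou(p, array(0, c(1, 1, 2, 2))), "shape mismatch")
})

test_that("dice = 2 iou / (1 + iou) on random binary masks", {
  set.seed(64)
  for (i in 1:50) {
    p <- array(rbinom(64, 1, runif(1, 0.2, 0.8)), c(1, 1, 8, 8))
    g <- array(rbinom(64, 1, runif(1, 0.2, 0.8)), c(1, 1, 8, 8))
    m <- dice_iou(p, g)
    expect_equal(m[["dice"]], 2 * m[["iou"]] / (1 + m[["iou"]]), tolerance = 1e-12)
    expect_gte(m[["dice"]], m[["iou"]])
  }
})

test_that("checkpoint save/load round-trips the model exactly", {
  m <- tiny_model(seed = 11L)
  x <- rand_image(seed = 65)
  y0 <- psnet_forward(m, x)$xbar
  path <- tempfile(fileext = ".rds")
  psnet_save(m, path)
  m2 <- psnet_load(path)
  expect_identical(psnet_forward(m2, x)$xbar, y0)
  expect_error(psnet_load(tempfile()), "cannot read")
})

test_that("unknown variants are rejected", {
  expect_error(build_variant(psnet_tiny_config(), "no_everything"), "arg")
})
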