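# Scheduler, initialisation, training loop mechanics and reporting.

test_that("learning-rate schedule hits its anchor points", {
  cfg <- train_config(epochs = 400L, warmup = 20L,
                      initial_lr = 2.1052e-5, peak_lr = 2.1052e-4)
  expect_identical(lr_at(0, cfg), 2.1052e-5)
  expect_identical(lr_at(cfg$warmup, cfg), cfg$peak_lr)
  # last epoch: peak * (1/(E - w))^0.98
  expect_equal(lr_at(399, cfg), cfg$peak_lr * (1 / 380)^0.98, tolerance = 1e-12)
  expect_error(lr_at(400, cfg), "outside")
  expect_error(lr_at(-1, cfg), "outside")
})

test_that("schedule is continuous at warmup and strictly decreasing after", {
  cfg <- train_config(epochs = 50L, warmup = 10L)
  lrs <- vapply(0:49, lr_at, numeric(1), cfg = cfg)
  expect_equal(lrs[10 + 1], cfg$peak_lr)
  # ramp approaches the peak from below
  expect_lt(abs(lrs[10] - (cfg$initial_lr + (cfg$peak_lr - cfg$initial_lr) * 9 / 10)), 1e-15)
  expect_true(all(diff(lrs[(10 + 1):50]) < 0))
  expect_error(train_config(epochs = 10L, warmup = 10L), "warmup")
})

test_that("init_weights draws conv weights from Normal(0, 0.02)", {
  # pool >= 1e5 conv weights from a model large enough to test the moments
  m <- nn_sequential(list(a = nn_conv2d(64L, 64L, 3L, pad = 1L),
                          b = nn_conv2d(64L, 64L, 3L, pad = 1L),
                          c = nn_conv2d(64L, 64L, 3L, pad = 1L)))
  init_weights(m, seed = 123L)
  w <- unlist(lapply(module_parameters(m), function(p)
    if (p$kind == "conv_weight") as.numeric(p$value)))
  expect_gte(length(w), 1e5)
  expect_lt(abs(mean(w)), 3 * 0.02 / sqrt(length(w)))
  expect_lt(abs(sd(w) - 0.02) / 0.02, 0.02)
})

test_that("init_weights sets norm layers to exactly 1 and 0 and is deterministic", {
  m <- tiny_model(seed = 5L)
  init_weights(m, seed = 99L)
  ps <- module_parameters(m)
  for (nm in names(ps)) {
    p <- ps[[nm]]
    if (p$kind == "norm_weight") expect_identical(unique(as.numeric(p$value)), 1)
    if (p$kind == "norm_bias") expect_identical(unique(as.numeric(p$value)), 0)
    if (p$kind == "bias") expect_true(all(p$value == 0))
    if (p$kind == "prelu") expect_identical(as.numeric(p$value), 0.25)
  }
  s1 <- state_dict(m)
  init_weights(m, seed = 99L)
  expect_identical(state_dict(m), s1)
})

test_that("one optimizer step moves parameters in every active module", {
  m <- tiny_model(seed = 3L)
  syn <- synth_arrays(synth_config(n = 2L, img_size = 64L, polyps = c(1L, 2L), seed = 2L))
  syn$x <- (syn$x - 0.5) / 0.5
  before <- lapply(state_dict(m), identity)
  cfg <- train_config(epochs = 2L, warmup = 1L, batch_size = 2L,
                      initial_lr = 1e-3, peak_lr = 1e-3, seed = 1L)
  res <- psnet_train(m, syn, cfg)
  after <- state_dict(m)
  moved <- vapply(names(module_parameters(m)),
                  function(nm) any(before[[nm]] != after[[nm]]), logical(1))
  # group by top-level module: every one must contain moved parameters
  top <- vapply(strsplit(names(moved), ".", fixed = TRUE), `[[`, character(1), 1)
  for (grp in unique(top)) expect_true(any(moved[top == grp]), label = grp)
  expect_equal(nrow(res$history), 2)
})

test_that("training is deterministic under a fixed seed", {
  syn <- synth_arrays(synth_config(n = 4L, img_size = 64L, polyps = c(1L, 2L), seed = 8L))
  syn$x <- (syn$x - 0.5) / 0.5
  cfg <- train_config(epochs = 3L, warmup = 1L, batch_size = 2L,
                      initial_lr = 1e-3, peak_lr = 1e-3, seed = 21L)
  run <- function() {
    m <- tiny_model(seed = 13L)
    psnet_train(m, syn, cfg)$history$loss
  }
  expect_identical(run(), run())
})

test_that("evaluate reports per-source means and their unweighted average", {
  m <- tiny_model(seed = 2L)
  syn <- synth_arrays(synth_config(n = 4L, img_size = 64L, polyps = c(1L, 2L), seed = 6L))
  syn$x <- (syn$x - 0.5) / 0.5
  syn$source <- c("a", "a", "b", "b")
  ev <- psnet_evaluate(m, syn)
  expect_equal(nrow(ev$per_source), 2)
  expect_equal(ev$mean_dice, mean(ev$per_source$mdice))
  # invariant to sample order
  perm <- c(3, 1, 4, 2)
  syn2 <- list(x = syn$x[perm, , , , drop = FALSE], y = syn$y[perm, , , , drop = FALSE],
               source = syn$source[perm])
  ev2 <- psnet_evaluate(m, syn2)
  expect_equal(ev2$per_source, ev$per_source, tolerance = 1e-12)
  # single dataset: mean equals its own score
  syn$source <- rep("only", 4)
  ev3 <- psnet_evaluate(m, syn)
  expect_equal(ev3$mean_dice, ev3$per_source$mdice[1])
  expect_error(psnet_evaluate(m, list(x = syn$x[0, , , , drop = FALSE],
                                      y = syn$y[0, , , , drop = FALSE])),
               "empty")
})

test_that("cross-dataset mean and ablation deltas reproduce the reporting arithmetic", {
  expect_equal(round(cross_dataset_mean(c(0.929, 0.928, 0.795, 0.877, 0.787)), 3), 0.863)
  expect_equal(report_ablation_delta(0.929, 0.662), 28.7)
  expect_equal(report_ablation_delta(0.879, 0.544), 38.1)
  expect_equal(report_ablation_delta(0.5, 0.5), 0)
})

test_that("training aborts with a diagnostic on divergence", {
  m <- tiny_model(seed = 3L)
  syn <- synth_arrays(synth_config(n = 2L, img_size = 64L, polyps = c(1L, 1L), seed = 2L))
  # poison the final head so the candidate map (and hence the loss) is NaN
  p0 <- module_parameters(m)[["ps_decoder.head.weight"]]
  p0$value[] <- NaN
  cfg <- train_config(epochs = 2L, warmup = 1L, batch_size = 2L, seed = 1L)
  expect_error(psnet_train(m, syn, cfg), "diverged|non-finite|missing value")
})
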