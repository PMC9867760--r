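# psnet

Dual encoder–decoder deep networks for binary polyp segmentation of
colonoscopy frames, in R.

Colorectal polyps are found and delineated during colonoscopy; automated
pixel-level segmentation has to capture both fine boundary detail and
global context across widely varying polyp sizes, textures and colours.
`psnet` implements the PSNet architecture for this problem: a CNN branch
(the *PS encoder/decoder*, built from depthwise separable, asymmetric and
dilated convolutions with squeeze-and-excitation attention) runs alongside
a vision-transformer branch (ViT encoder, partial decoder, enhanced dilated
decoder), and four merge modules fuse the two branches at 1/2 … 1/16
scale. Six full-resolution candidate maps `x^T, x^C, x^(1/16), x^(1/8),
x^(1/4), x^(1/2)` are combined under deep supervision,

```
xbar = (x^T + x^C + x^(1/16) + x^(1/8) + x^(1/4) + x^(1/2)) / 6,
p    = sigmoid(xbar),
```

and trained with the soft-IoU loss
`L = 1 − (Σ p·y + ε) / (Σ p + Σ y − Σ p·y + ε)`. Evaluation reports mDice
`2|P∩G|/(|P|+|G|)` and mIoU `|P∩G|/|P∪G|` per image, averaged per dataset.

Every layer carries an explicit reverse-mode `backward()`; the memory-bound
inner loops are compiled C++ (`src/`), channel mixing goes through BLAS,
and all gradients are validated against finite differences in the test
suite. No deep-learning framework is required.

The package also provides dataset manifests with the two published split
protocols (standard Kvasir+ClinicDB training and the merged five-dataset
protocol), a seeded synthetic colonoscopy-frame generator with exact
masks (so everything runs with no downloads), ablation variants
(`no_transformer`, `no_dual_decoder`, `no_merge`, `no_ps_encoder`,
`no_ccm`), checkpointing, and a CLI (`inst/cli/psnet.R`) with
`synth / train / eval / predict / ablate / report` subcommands.

## Worked example

Generate a small synthetic dataset, train the test-scale model to overfit
it, and evaluate:

```r
library(psnet)

syn <- synth_arrays(synth_config(n = 8, img_size = 64, polyps = c(1, 3), seed = 11))
syn$x <- (syn$x - 0.5) / 0.5            # the [-1, 1] normalization the loader applies

model <- build_variant(psnet_tiny_config(seed = 7), "full")
n_parameters(model)
#> [1] 1570623

cfg <- train_config(epochs = 50, batch_size = 2, warmup = 5,
                    initial_lr = 6e-4, peak_lr = 6e-3, seed = 3)
res <- psnet_train(model, syn, cfg)     # 200 optimizer steps
round(tail(res$history$loss, 1), 4)
#> [1] 0.0694
psnet_evaluate(model, syn)
#>  source n  mdice   miou
#>     all 8 0.9817 0.9642
#> cross-dataset mean: mDice 0.982  mIoU 0.964
```

An mDice near 1 on the training frames says the
optimizer can drive the full dual-branch assembly to memorise the fixture
— the standard smoke test that forward, backward and optimizer are wired
correctly. It says nothing about generalisation to real colonoscopy data.

The split protocols reproduce the published bookkeeping exactly:

```r
kvasir <- new_manifest(sprintf("k%04d.png", 1:1000), sprintf("m%04d.png", 1:1000), "kvasir")
clinic <- new_manifest(sprintf("c%03d.png", 1:612), sprintf("n%03d.png", 1:612), "clinicdb")
split_standard(kvasir, clinic, seed = 1)$n_train_pool
#> [1] 1450
```

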