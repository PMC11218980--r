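# mrivit

Four-class brain-tumor MRI slice classification (glioma, meningioma,
pituitary, tumor-free) for image-analysis researchers who want the full
method — enhancement, model, data handling, evaluation — as inspectable,
dependency-light R.

Clinical MRI slices are low-contrast, unevenly illuminated and noisy, and
open brain-tumor collections are small. The package addresses both problems
the way the underlying method does:

1. **Enhancement pipeline.** Homomorphic filtering — the
   illumination–reflectance model $f = i \cdot r$, log-transformed and
   filtered in the frequency domain by
   $H(u,v) = (\gamma_H-\gamma_L)\{1-e^{-cD^2(u,v)/D_0^2}\}+\gamma_L$
   ($\gamma_H{=}1.5$, $\gamma_L{=}0.5$, $c{=}1$, $D_0{=}40$) — followed by
   contrast-limited adaptive histogram equalization (per-tile clip and
   iterative uniform redistribution of the excess, bilinear blending) and
   unsharp masking. The composite both preprocesses and *doubles* the
   dataset (one enhanced copy per original); gray-level Shannon entropy
   scores the detail gain.
2. **Modified ViT-B/16.** Multi-head self-attention with clipped 2-D
   relative position encoding — per-bucket learnable logit bias and
   query/key/value vectors indexed by
   $\mathrm{clip}(\Delta,k)=\max(-k,\min(k,\Delta))$ per axis, one reserved
   class-token bucket — so
   $e_{ij} = [(q_i+p^Q)(k_j+p^K)^\top + b]/\sqrt{d_z}$ and
   $z_i = \sum_j \alpha_{ij}(v_j+p^V)$; feed-forward blocks carry an inner
   residual shortcut $F(x)+x$; the head is adaptive average pooling →
   linear → tanh → linear. Forward *and* backward passes are written in
   plain R matrix algebra and verified against finite differences and a
   literal double-loop implementation of the defining equations.
3. **Data handling and evaluation.** Class-folder manifests, stratified
   80/20 split with round-half-up training counts, Adam training
   (lr 0.001, batch 8, 30 epochs), confusion-matrix metrics
   (per-class accuracy, one-vs-rest precision/recall/F1, macro averages),
   PR curves, normal-approximation 95% accuracy intervals, and per-block
   attention-map extraction.
4. **Phantom generator.** Seeded MRI-like head phantoms with
   class-dependent lesions, low-contrast texture, illumination gradients
   and noise, so every claim above is testable offline.

## Worked example

```r
library(mrivit)

# a low-contrast phantom with a glioma-like lesion, and its enhancement
ph  <- generate_phantom(phantom_spec(class_id = 0L, seed = 42))
information_entropy(ph)                  # 6.390 bits
enh <- combined_enhance(ph)
information_entropy(enh)                 # 6.865 bits  (detail enriched)

homomorphic_gain(0)                      # 0.5     = gamma_L, illumination damped
homomorphic_gain(40)                     # 1.1321  = 0.5 + (1 - exp(-1)), at D0

# the published dataset arithmetic, from per-class counts alone
manifest_from_counts(c(glioma = 1621, meningioma = 1645,
                       pituitary = 1757, no_tumor = 2000)) |>
  augment_manifest() |>                  # 7023 -> 14046 records
  stratified_split(seed = 1) |>
  split_counts()
#>   label       test train total
#> 1 glioma       648  2594  3242
#> 2 meningioma   658  2632  3290
#> 3 no_tumor     800  3200  4000
#> 4 pituitary    703  2811  3514

# desk-scale end-to-end run: 200 phantoms, reduced model, published recipe
generate_dataset(50, "phantoms", seed = 7)
man <- build_manifest("phantoms") |> stratified_split(seed = 7)
fit <- fit_vit(vit_model(vit_config_tiny(), seed = 7), man,
               train_config(seed = 7))   # Adam 0.001, batch 8, 30 epochs
glance(fit)                              # best held-out accuracy >= 0.90
cm <- evaluate_model(fit, fit$test_data$x, fit$test_data$y)
metric_report(cm)                        # per-class + overall + macro rows
autoplot(fit)                            # training curves
plot_attention_maps(attention_maps(fit$model, fit$test_data$x[1, , ]))
```

The entropy values are what the code above prints; the split table matches
the published per-class train/test counts exactly, and the tiny training
run reaches 95% held-out accuracy under seed 7 (about five CPU-minutes).

A thin CLI over the same functions lives at `inst/cli/mrivit.R`
(subcommands `synth`, `enhance`, `split`, `train`, `evaluate`, `attend`).

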