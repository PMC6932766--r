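# amypet

Binary classification of 2D amyloid-PET brain slices with a classical
two-stage pipeline:

1. **Image preparation** — automatic cropping of the black frame, bilinear
   resize to a 200×200 grid, and **APPN** (Average Pixel Per Node) feature
   reduction: the grid is split into 10×10-pixel blocks and each block's
   mean gray value, normalized to [0, 1], becomes one of 400 network
   inputs.
2. **A from-scratch back-propagation neural network** — one hidden layer
   (400–45–2 by default), logistic-sigmoid activations, bias weights, and
   online gradient descent with momentum:

   δ_k = (t_k − o_k)·σ′(z_k),  Δw(t) = η·δ·a + α·Δw(t−1)

   with η = 0.00079, α = 0.90, stopping when the epoch-end RMS output error
   √( Σ_p Σ_k (t_pk − o_pk)² / (P·K) ) reaches 0.003.

Evaluation uses a stratified hold-out protocol: 30% of each class trains
the network, the remaining 70% measure sensitivity, specificity and
accuracy, with the disease group (AD, LMCI, EMCI or SMC) as positive class
and normal controls (NC) as negative class.

Because clinical amyloid-PET datasets are access-controlled, the package
includes a **synthetic phantom generator**: elliptical brain slices on a
black frame with a bright white-matter core and a cortical rim whose
uptake rises with disease stage, Gaussian-smoothed (8 px FWHM) and
noise-corrupted. The whole pipeline, including its acceptance tests, runs
self-contained on phantoms.

## Worked example

```r
library(amypet)

# 20 synthetic phantoms per class, default graded rim-uptake effect sizes
ph    <- phantom_config(n_per_class = 20L, seed = 42L)
feats <- phantom_features(ph, classes = c("NC", "AD"))   # 40 x 402 table

cfg <- network_config(seed = 1L, max_epochs = 5000L)     # 400-45-2 net
res <- run_experiment(feats, c("NC", "AD"), cfg, split_seed = 17L)
print(res)
#> <evaluation_report> NC/AD (positive = disease group)
#>   tp=14 tn=13 fp=1 fn=0
#>   sensitivity 100.0%  specificity 92.9%  accuracy 96.4%
#>   training accuracy 100.0%  (stopped after 5000 epochs, RMS 0.04581)
```

The split held out 14 phantoms per class (70% of 20); the network labeled
all 14 AD phantoms and 13 of 14 NC phantoms correctly. Training accuracy
is 100% even though the RMS stopping threshold (0.003) was not yet reached
at the 5,000-epoch cap — classification saturates long before the RMS
tail ends. With a zero rim effect the same experiment hovers at chance
(~50%), and accuracy rises monotonically with the rim effect size.

The same workflow is scriptable end to end (simulate → prepare → train →
evaluate → run-all), with YAML configs and JSON reports:

```sh
CLI=$(Rscript -e 'cat(system.file("scripts/amypet", package = "amypet"))')
Rscript $CLI simulate --out data/ --n-per-class 100 --seed 7 \
    --effect-sizes SMC=0.05,EMCI=0.12,LMCI=0.30,AD=0.60 --noise 0.08
Rscript $CLI prepare --manifest data/manifest.csv --out features.csv
Rscript $CLI evaluate --features features.csv --experiment NC/AD \
    --split-seed 17 --report report.json
```

Real data enter through the same door: a CSV manifest
(`source_id,path,label`) pointing at PNG/TIFF files or NIfTI volumes (one
axial slice is extracted per volume; labels NC, SMC, EMCI, LMCI, AD).

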