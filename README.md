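# spectrareg

Near-infrared hyperspectral regression for non-destructive fruit quality
prediction, with wavelength-importance saliency.

Refractometry and pH probes measure the internal quality of fruit —
soluble solid content (SSC, °Brix) and pH — but destroy the sample.
NIR hyperspectral imaging (here 224 bands, 900–1700 nm) predicts both
from the mean reflectance spectrum of each fruit. `spectrareg` is a
complete, tested implementation of that workflow for R users in
chemometrics and horticultural phenotyping:

* **Cube I/O and calibration** — ENVI header+binary reader/writer
  (BIL/BIP/BSQ), white/dark reflectance correction
  `R = (I − D) / (W − D)`, noisy-edge band trimming (224 → 209 bands).
* **Spectra pipeline** — threshold/connected-component ROI segmentation,
  per-fruit mean spectra, multiplicative scatter correction (MSC),
  Tukey box-plot outlier screening, and a PLSR-screened 3:1:1
  calibration/validation/prediction split.
* **Seven calibration models** — PLSR (NIPALS-family PLS1 with CV-chosen
  1–21 latent variables), SVR (linear/polynomial/Gaussian kernels,
  γ ∈ 10⁻⁴…10⁵), and five deep models compiled from scratch in
  RcppArmadillo with hand-derived gradients: 1-D CNN, LSTM, CNN-LSTM,
  Transformer encoder, and the **CNN-Transformer** hybrid (two conv
  layers feeding a 6-layer, 4-head encoder, d_model = 256, sequence
  length 209), trained with AdamW, MSE loss, batch 10.
* **Evaluation** — R², RMSE and RPD per split part
  (`RPD = SD/RMSEP`; > 2.0 "high reliability"), assembled into the
  standard model-comparison table.
* **Grad-CAM saliency** — per-wavelength importance profiles from the
  final conv feature map, aggregated over 50 samples with a variance
  envelope, plus a band-mass localisation score.
* **Synthetic generator** — truncated-normal targets
  (SSC ~ N(6.90, 1.41²) on [4.20, 10.20]; pH ~ N(4.20, 0.20²) on
  [3.77, 4.78]), Beer–Lambert-style spectra with known informative
  bands (SSC at 1450/1550 nm, pH at 1000/1200 nm), per-sample scatter
  and noise, and full scene cubes with ground-truth masks — so the
  entire pipeline, including saliency localisation, is testable without
  instrument data.

## Worked example

```r
library(spectrareg)

# synthetic 357-fruit study with known informative bands
ssc <- generate_targets(357, 6.90, 1.41, 4.20, 10.20, seed = 101)
ph  <- generate_targets(357, 4.20, 0.20, 3.77, 4.78, seed = 102)
gen <- generate_spectra(ssc, ph, synthetic_config(n_samples = 357, seed = 103))

# preprocess: MSC, then drop the 15 noisy leading bands
X <- crop_bands(msc_fit_apply(gen$spectra)$corrected)
dim(X)
#> [1] 357 209

# 3:1:1 split and a CNN-Transformer for the sugar target
idx  <- withr::with_seed(104, sample.int(357))
val  <- sort(idx[1:71]); pred <- sort(idx[72:142]); cal <- sort(idx[143:357])
fit <- train_model(build_model(cnn_transformer_spec(), 209, seed = 1),
                   X$values[cal, ], ssc[cal], X$values[val, ], ssc[val],
                   train_config(max_epochs = 14, patience = 8, seed = 1))

r_squared(ssc[pred], predict(fit, X$values[pred, ]))
#> [1] 0.860891
rpd(ssc[pred], predict(fit, X$values[pred, ]))
#> [1] 2.700241

# where does the model look? (truth: 1450/1550 nm)
prof <- aggregate_profiles(fit, X, n = 50, seed = 131)
band_mass_fraction(prof, 1380, 1650)
#> [1] 0.5021544
```

The prediction-set R² of 0.86 says the model recovers most of the
target variance the generator encoded; an RPD above 2 marks a
calibration conventionally considered reliable for quantitative use.
The band-mass fraction of 0.50 against the window's 0.36 share of
bands shows the Grad-CAM profile leaning toward the wavelengths that
actually carry the sugar signal (see the methods vignette for why this
channel-pooled profile localises only partially).

A command-line interface over the same functions is installed at
`inst/cli/spectrareg.R` (subcommands `simulate`, `calibrate`,
`extract`, `preprocess`, `split`, `train`, `evaluate`, `explain`).

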