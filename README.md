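# piezodenoise

Denoising of throat-attached piezoelectric (PVDF) vibration signals with an
Adam-optimized deep belief network.

Flexible PVDF films taped over the thyroid cartilage convert vocal-fold
vibration into charge (Q = d·F) and give a microphone-free view of speech
that ignores airborne background sound — but the voltage traces they produce
are contaminated by high-frequency perturbations and slow baseline drift.
This package implements a complete reconstruction pipeline for such 1-D
vibration recordings, for researchers working on wearable physiological
sensing and silent-speech interfaces:

1. **Trajectory embedding** — the signal `x[1..T]` is embedded into the
   `L × (T−L+1)` Hankel matrix with column `j = x[j..j+L−1]`, and each
   column is normalized to zero mean and unit (population) standard
   deviation. Diagonal averaging — the mean over anti-diagonals
   `i + j = t + 1`, with counts `n_t = min(t, min(L,K), L+K−t)` — is the
   exact inverse and maps per-window reconstructions back to one signal.
2. **Time–frequency analysis** — short-time Fourier transform
   `X[m,k] = Σ_n x[n+mH]·w[n]·e^(−j2πkn/N)` with the Hanning window
   `w[n] = 1/2 − 1/2·cos(2πn/(N−1))`, an optional per-bin soft magnitude
   mask against a quantile noise floor, and squared-window overlap-add
   inverse.
3. **DBN reconstructor** — three stacked restricted Boltzmann machines
   (Gauss–Bernoulli energy
   `E(v,h) = Σ(v_i−a_i)²/2σ_i² − Σb_j h_j − ΣΣ(v_i/σ_i)W_ij h_j` at the
   continuous input, Bernoulli above), pre-trained layer by layer with
   contrastive divergence (plain SGD), then fine-tuned end to end with a
   from-scratch Adam optimizer (bias-corrected first/second moments) under
   the joint loss `L = λ₁·MSE(x, x̂) + λ₂·‖|X_f| − |X̂_f|‖₁` with
   λ₁ = 0.7, λ₂ = 0.3 and a learning-rate schedule of 5×10⁻³ halved to
   2.5×10⁻³ at epoch 90.
4. **Evaluation** — spectral flatness (geometric/arithmetic PSD mean ratio),
   Pearson correlation (PPMCC), local noise energy (mean per-frame
   variance), energy ratio, and the weighted composite score
   `100·[W₁ρ + W₂(1 − min(1, SF/0.1)) + W₃(1 − min(1, LNE/0.1))]`
   with weights (0.4, 0.3, 0.3).
5. **Comparator and data** — a one-dimensional convolutional
   encoder–decoder baseline (conv 15/64 → pool → conv 11/128 → pool →
   conv 7/256 → sigmoid attention → deconv 5/128 → deconv 7/64 → skip 3)
   trained with the same loss, optimizer and rounds; and a seeded generator
   of vocal-fold-like signals (harmonic pulse train, voiced/unvoiced
   envelope, white noise + 2 Hz drift, two-channel superposition
   `y = y_CH1 + y_CH2`) standing in for live recordings.

## Worked example

```r
library(piezodenoise)

cfg <- pipeline_config()                       # L = 64, 100 epochs, seed 42
fit <- train_pipeline(cfg)                     # CD pre-training + Adam fine-tuning
tail(fit$history, 3)
#>     epoch train_loss  val_loss learning_rate
#> 98     98 0.08178693 0.1641069        0.0025
#> 99     99 0.07987731 0.1644456        0.0025
#> 100   100 0.07953753 0.1654924        0.0025

rec <- synthesize_recording(synthetic_config(seed = 777))   # held-out recording
before <- evaluate_denoising(rec$clean, rec$noisy)
after  <- evaluate_denoising(rec$clean, denoise(fit$model, rec$noisy))
print(comparison_table(list(Noisy = before, `Adam-DBNs` = after)),
      row.names = FALSE)
#>           Parameter    Noisy Adam-DBNs
#>   Spectral Flatness 0.289333  0.000054
#>               PPMCC   0.7140    0.8611
#>  Local Noise Energy 0.078353  0.030504
#>     Composite Score    35.06     85.28
```

Training drives the joint loss from ≈0.9 down to ≈0.08 over 100 epochs.
On the held-out recording the reconstruction removes almost the entire
broadband noise floor (spectral flatness 0.29 → 5×10⁻⁵), raises the
waveform similarity to the clean reference from 0.71 to 0.86, more than
halves the local noise energy, and lifts the composite score from 35 to 85.
`compare_denoisers()` runs the same protocol for the DBN and the CNN
baseline side by side.

A command-line interface wraps the same functions
(`simulate`, `train`, `denoise`, `evaluate`, `compare`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli/piezodenoise", package = "piezodenoise"))')
Rscript "$CLI" simulate --out-prefix demo --duration 1 --seed 7
Rscript "$CLI" train --noisy demo_noisy.wav --clean demo_clean.wav --out model.rds
Rscript "$CLI" denoise --model model.rds --input demo_noisy.wav --output demo_den.wav
Rscript "$CLI" evaluate --original demo_clean.wav --denoised demo_den.wav
```

Signals are WAV (PCM16 or IEEE float32, one or two channels) or one/two
column CSV; configuration files are YAML overriding the
`pipeline_config()` defaults.

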