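# rt4dcbct

Real-time four-dimensional cone-beam CT (4D-CBCT) estimation from
single-angle projection sequences, for researchers in image-guided
radiotherapy who need a fully reproducible, self-contained implementation of
PCA-motion-model + ConvLSTM volumetric imaging — including a synthetic 4D
thorax phantom, so every stage runs without clinical data.

## The method

During lung SBRT the anatomy moves with respiration, but a kV imager can
acquire only one projection at a time. The package estimates the full moving
volume from a short sequence of projections at one fixed gantry angle:

1. **Motion model.** Deformation vector fields (DVFs) between the 0% phase
   and every other phase of a planning 4D-CT are flattened and decomposed by
   mean-centered PCA:

   `DVF(i) ≈ d̄ + Σ_{j≤k} q_j(i) p_j`,

   with orthonormal eigen-fields `p_j` and per-phase coefficients `q_j`. The
   first `k = 3` components typically carry ~97% of the motion information,
   so the entire breathing state reduces to three numbers.
2. **Projection simulation.** Candidate coefficient sets (the per-phase
   trajectory, scaled ±15% and jittered) synthesize DVFs that deform the
   reference volume; a Siddon ray tracer renders each deformed volume into a
   digitally reconstructed radiograph (DRR) at the fixed angle, and quantum
   noise `I = Poisson(I₀ e^{-p_n}) + N(0, σ_e²)` (I₀ = 10⁵, σ_e² = 10) makes
   the DRRs resemble measured projections.
3. **Spatiotemporal regression.** A convolutional LSTM — gate equations with
   3×3 convolutions, two stacked cell layers, a convolutional-pooling
   regression head — maps each window of `T = 4` consecutive DRRs to the PCA
   coefficients of the final frame. The loss
   `1/N Σ ‖w ∘ (y − ŷ)‖²` with `w = (2/6, 1/6, 1/6)` concentrates accuracy
   on the dominant first coefficient.
4. **Reconstruction.** Predicted coefficients synthesize a DVF that warps
   the reference volume into the phased CBCT; a sliding causal window over
   the online projection stream yields the whole respiratory cycle.

Fidelity is quantified with MAE, NCC, SSIM, PSNR, RMSE and MAPE on
coefficients, mid-plane slices and volumes.

The methods vignette (`vignettes/motion-estimation-methods.Rmd`) documents
the model assumptions, the synthetic phantom, all numerical choices and the
known limitations.

## Worked example

A desk-scale end-to-end run (32³ phantom, 60 noisy 32×32 DRR sequences,
6 training epochs — about a minute on one CPU; the full-scale configuration
is `desk_experiment_config()`):

```r
library(rt4dcbct)

cfg <- experiment_config(
  grid_dims = c(32, 32, 32), spacing = rep(8, 3),
  n_sequences = 60,
  geometry = cone_beam_geometry(detector_size = c(32, 32), pixel_pitch = 12),
  net = network_config(hidden_channels = 4, input_dim = c(32, 32),
                       pool_channels = 2, fc_dim = 64),
  train = training_config(epochs = 6),
  seed = 42)
report <- run_experiment(cfg)

round(report$information$cumulative_percent, 2)
#> [1]  73.98  89.25  97.35  98.29  99.19  99.58  99.89 100.00
round(unlist(report$summary), 4)
#>        mean_ncc       mean_ssim       mean_psnr       mean_rmse       mean_mape
#>          0.9700          0.8603         19.8822          0.0027          0.2442
#> q1_relative_mae
#>          0.2669
head(report$phase_metrics, 3)
#>   phase       ncc      ssim     psnr        rmse      mape         mae
#> 1     0 0.9724196 0.8621438 19.01860 0.003179675 0.1931909 0.001338185
#> 2     1 0.9828234 0.9061349 22.14501 0.002343530 0.1754707 0.000963545
#> 3     2 0.9791474 0.8653512 20.96624 0.002684164 0.2253368 0.001136934
```

Reading the output: the information curve shows the phantom's motion is
dominated by three PCA modes (97.4% at three components) and closes at 100%
at full rank, as mean-centering guarantees. `mean_ncc`/`mean_ssim` compare
each reconstructed phase volume (mid-coronal slice for SSIM) against the
ground-truth phase volume; `q1_relative_mae` is the held-out error of the
dominant coefficient relative to its range across the cycle. This
one-minute toy run visibly underfits (q1 error ~27% of range); the full
desk-scale configuration — `run_experiment(desk_experiment_config(seed = 1))`,
64³ phantom, 300 sequences, 8 hidden channels, 15 epochs, ~10 min — reaches
mean NCC 0.997, mean SSIM 0.963 and q1 relative MAE 0.007.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/rt4dcbct.R phantom --out phantom_dir --grid 64 --seed 1
Rscript inst/cli/rt4dcbct.R run --sequences 300 --epochs 15 --seed 1 --out report.json
```

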