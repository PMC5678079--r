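# cvep — spatiotemporal beamformer decoding of code-modulated VEPs

`cvep` is an R toolkit for decoding **code-modulated visual evoked
potentials** (cVEPs), the EEG responses evoked when the targets of a
brain-computer interface (BCI) flicker with circularly lagged copies of a
pseudorandom binary code. Identifying which target a user gazes at reduces
to identifying the lag of the code imprinted on the occipital EEG. The
package is aimed at BCI researchers who want an offline, fully scriptable
pipeline — from raw recordings (BrainVision or EDF+) or simulated sessions
to cross-validated accuracy and information-transfer-rate reports.

## The method in brief

Targets are encoded with a 63-bit m-sequence (shipped as `CVEP_CODE63`;
balanced, circular autocorrelation 63 at lag 0 and −1 elsewhere), each
target lagged by a multiple of two display frames. After re-referencing to
the mastoids, 4–31 Hz zero-phase Butterworth filtering, epoching (5.25 s)
and decimation to the analysis rate, every epoch is cut into segments of
one code presentation (105 samples at either presentation rate). For each
target *i*, the **activation pattern** `A_i` (channels × samples) is the
mean of its training segments, and the decoder is a linearly-constrained
minimum-variance (LCMV) spatiotemporal beamformer

```
w_i = Σ⁺ a_i / (a_iᵀ Σ⁺ a_i)       subject to  a_iᵀ w_i = 1 ,
```

where `a_i` is the flattened pattern and `Σ⁺` the Moore–Penrose
pseudoinverse of the covariance of all flattened training segments. A
segment is scored by the weighted sum `y_i = s · w_i`; per-target decision
thresholds come from an inner 4-fold ROC analysis (median of the
accuracy-maximising thresholds), and an epoch is classified by averaging
its first `n` segments, scoring with all beamformers, and taking the
highest above-threshold score (highest overall if none passes). Evaluation
is a stratified 5-fold cross-validation (one epoch per target per fold)
reporting accuracy and Wolpaw ITR per repetition count; a greedy forward
channel selection and a Wilcoxon signed-rank harness round out the
analysis tools. A synthetic session generator (lag-coded evoked responses
+ 1/f, alpha and sensor noise) makes the whole pipeline testable without
recorded data.

## Worked example

Simulate a clean fast-presentation session (120 Hz, 32 targets × 5
trials), preprocess it, and evaluate the decoder:

```r
library(cvep)

mont <- c("PO7", "PO3", "O1", "Oz", "O2", "Iz", "TP9", "TP10")
sim <- sim_config("120", montage = mont, acquisition_rate = 1000,
                  noise_sd = 6, alpha_amp_uv = 20, pink_amp_uv = 20,
                  seed = 7)
cfg <- run_config("120")
epochs <- simulate_epochs(sim, cfg)
ev <- stratified_cv(epochs, cfg, repetitions = c(1, 2, 4))
ev
#> <cvep_evaluation> 5 folds, channels: PO7 PO3 O1 Oz O2 Iz TP9 TP10
#>  repetitions accuracy itr_bits_min
#>            1   0.8812       227.47
#>            2   0.9812       184.75
#>            4   0.9938       113.41
```

Reading the output: at one repetition (0.525 s of stimulation + 0.5 s gaze
shift) the decoder identifies 88.1% of the 160 held-out epochs correctly,
worth 227 bits/min; averaging more code presentations raises accuracy
towards 1 while the ITR declines because each selection takes longer —
the accuracy-vs-time trade-off that the ITR is designed to arbitrate.

The same pipeline runs from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/cvep.R", package = "cvep"))')
Rscript $CLI simulate  --config sim.yaml --out session.vhdr
Rscript $CLI preprocess --in session.vhdr --config run.yaml --out epochs.rds
Rscript $CLI evaluate  --epochs epochs.rds --config run.yaml --out report.json
Rscript $CLI channels  --epochs epochs.rds --config run.yaml
```

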