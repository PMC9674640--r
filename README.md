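# motifembed

Unsupervised segmentation of animal behavior from pose-estimation time
series, for behavioral neuroscientists and computational ethologists who
have marker trajectories (e.g. DeepLabCut CSV exports of a freely moving
rodent) and want discrete, hierarchically organized behavioral motifs
without hand annotation.

## What it does

1. **Align & clean.** Allocentric marker coordinates are egocentrically
   aligned (translate to the nose–tailbase midpoint, rotate the body axis
   onto +x), confidence-masked, IQR-deoutliered, linearly interpolated,
   Savitzky–Golay smoothed and z-scored, giving a series
   `X ∈ R^(N×m)`.
2. **Embed.** Trajectory windows `x_i ∈ R^(m×w)` are embedded by a
   variational autoencoder built from bidirectional GRUs: a 2-layer
   biGRU encoder maps each window to a diagonal-Gaussian posterior over
   `z_i ∈ R^d` (`z = μ + σ ⊙ ε`), a biGRU decoder reconstructs the
   window and a second biGRU decoder predicts the following `v` frames,
   regularizing the latent space toward dynamics. The objective is the
   evidence lower bound
   `L = L_reconstruction + L_prediction + KL(q(z|x) ‖ N(0, I))`,
   minimized with Adam (learning rate 0.0005). Forward pass and
   analytic gradients are hand-written in RcppArmadillo and verified
   against finite differences.
3. **Segment.** Sliding the window (stride 1) and emitting posterior
   means gives `Z ∈ R^(d×(N−w))`; a Gaussian-emission hidden Markov
   model (EM + Viterbi, restart-selected; k-means as the fast
   alternative) yields motif labels and usages `U_i`. The motif count
   can be chosen by probing with many states and keeping those used
   >1% of frames.
4. **Structure & scoring.** Transition matrices `T_lk = P(b_k | b_l)`,
   a binary merge tree built by repeatedly joining the pair minimizing
   `(U_i + U_j)/(T_ij + T_ji)`, dendrogram-style community cuts, usage
   ratios between groups, and Purity / NMI / Homogeneity against
   reference annotations.

A synthetic pose simulator (Markov-switching behavioral regimes, limb
oscillators with gait-like phases, heading rotation, arena-bounded
drift, marker noise and likelihood dropouts) provides ground-truthed
recordings, so the entire pipeline is testable without animal data.

## Worked example

```r
library(motifembed)

# a ground-truthed synthetic recording: 3 behavioral regimes,
# 4 markers, 3000 frames at 60 fps
ds  <- reference_dataset("tiny", seed = 1)
raw <- confidence_mask(ds$track, pose_confidence = 0.9)
s   <- preprocess_series(raw, anchor_front = 1, anchor_back = 4,
                         frame_rate = 60)

cfg <- vae_config(num_features = ncol(s$values), zdims = 8,
                  time_window = 30, prediction_window = 15,
                  hidden_size = 64, max_epochs = 30,
                  batches_per_epoch = 100, seed = 1)
model <- motif_vae(s, config = cfg)     # ~5 min on one CPU core
model
#> motif_vae: fitted (d=8, m=6, w=30, v=15, hidden=64, 137244 parameters)
#>   best epoch 21/30: test loss 0.2127 (rec 0.0997, pred 0.1368, kl 8.0208)

latents <- infer_latents(model, s)      # d x (N - w) latent series
hmm     <- fit_hmm(latents, K = 3, seed = 1)
motifs  <- decode_states(hmm, latents)

# score against the planted labels at the window centers
truth <- ds$labels[floor(latents$window_centers) + 1]
score_report(truth, motifs$labels)
#> score_report (2970 frames): purity 0.9293, NMI 0.7792, homogeneity 0.7727
```

Purity 0.93 says each inferred motif is dominated by one planted
regime; NMI 0.78 and homogeneity 0.77 quantify how much of the planted
structure the unsupervised pipeline recovered. From here,
`transition_matrix()`, `build_tree()` and `cut_tree()` give the motif
hierarchy, `generate()` samples new trajectories per motif, and
`run_pipeline()` drives the same steps as on-disk project stages
(`init_project()` scaffolds the folder layout). A thin command-line
front end lives in `inst/cli/motifembed.R`.

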