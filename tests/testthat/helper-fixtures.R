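# Shared fixture builders (all generated in code at test time).

# small synthetic recording (walking regime, signal-rich tracks)
make_pose_fixture <- function(n = 100L, seed = 7L, dropout = 0) {
  regimes <- motifembed:::.tiny_regimes()
  simulate_pose(rep(1L, n), regimes, dropout_rate = dropout, seed = seed)
}

# Gaussian HMM parameters with 4 heavy, tight regimes plus one diffuse
# low-usage background state (the long usage tail the 1% rule assumes)
heavy_regime_hmm <- function() {
  means <- rbind(c(5, 5, 0), c(-5, 5, 0), c(-5, -5, 0), c(5, -5, 0),
                 c(0, 0, 0))
  covars <- rbind(matrix(0.3^2, 4, 3), rep(20^2, 3))
  A <- matrix(0, 5, 5)
  for (i in 1:4) { A[i, ] <- 0.022 / 3; A[i, i] <- 0.97; A[i, 5] <- 0.008 }
  A[5, ] <- c(rep(0.025, 4), 0.9)
  list(initial = rep(0.2, 5), transition = A, means = means,
       covars = covars, covariance = "diag")
}

# well-separated sticky 2-state Gaussian HMM
two_regime_hmm <- function(sep = 4) {
  list(initial = c(0.5, 0.5),
       transition = matrix(c(0.95, 0.05, 0.05, 0.95), 2, byrow = TRUE),
       means = rbind(rep(-sep / 2, 3), rep(sep / 2, 3)),
       covars = matrix(1, 2, 3),
       covariance = "diag")
}

# a quickly trainable model on a short synthetic series
quick_model_and_series <- function(n = 400L, epochs = 3L, seed = 11L) {
  ds <- reference_dataset("tiny", seed = seed)
  s <- preprocess_series(confidence_mask(ds$track, 0.9),
                         anchor_front = 1, anchor_back = 4)
  s$values <- s$values[seq_len(n), , drop = FALSE]
  s <- zscore(marker_series(s$values))
  cfg <- vae_config(num_features = ncol(s$values), zdims = 4,
                    time_window = 20, prediction_window = 10,
                    hidden_size = 16, max_epochs = epochs,
                    batch_size = 16, batches_per_epoch = 5, seed = seed)
  list(model = motif_vae(s, config = cfg), series = s)
}
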