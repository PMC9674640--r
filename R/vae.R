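#' Model configuration for the recurrent variational autoencoder
#'
#' @param num_features m, number of egocentric coordinate features.
#' @param zdims d, latent dimension (default 30); must satisfy
#'   `d < m * w`.
#' @param time_window w, input trajectory length in frames (default 30,
#'   i.e. 500 ms at 60 fps).
#' @param prediction_window v, number of future frames the prediction
#'   decoder forecasts (default 15).
#' @param hidden_size GRU hidden width for encoder and decoders
#'   (default 256).
#' @param encoder_layers number of encoder biGRU layers (fixed at 2).
#' @param learning_rate Adam learning rate (default 0.0005).
#' @param max_epochs training epoch budget (default 100).
#' @param patience epochs without test-loss improvement before stopping
#'   (default 50).
#' @param batch_size windows per gradient step (default 64).
#' @param batches_per_epoch gradient steps per epoch (default 25).
#' @param kl_anneal linearly anneal the KL weight from 0 to 1 over the
#'   first `anneal_frac` of `max_epochs` (default `TRUE`); set `FALSE`
#'   for a constant weight of 1 (the strict evidence lower bound).
#' @param anneal_frac fraction of `max_epochs` over which to anneal
#'   (default 0.25).
#' @param seed RNG seed controlling initialization, window sampling and
#'   the reparameterization noise (default 42).
#' @return a `vae_config` list.
#' @export
vae_config <- function(num_features, zdims = 30L, time_window = 30L,
                       prediction_window = 15L, hidden_size = 256L,
                       encoder_layers = 2L, learning_rate = 5e-4,
                       max_epochs = 100L, patience = 50L, batch_size = 64L,
                       batches_per_epoch = 25L, kl_anneal = TRUE,
                       anneal_frac = 0.25, seed = 42L) {
  stopifnot(num_features >= 1L, zdims >= 1L, time_window >= 2L,
            prediction_window >= 1L, hidden_size >= 1L,
            learning_rate >= 0, max_epochs >= 1L, patience >= 1L)
  if (encoder_layers != 2L)
    stop("the encoder is a 2-layer bidirectional GRU; encoder_layers must be 2")
  if (zdims >= num_features * time_window)
    stop("zdims must be smaller than num_features * time_window (d < m*w)")
  structure(list(num_features = as.integer(num_features),
                 zdims = as.integer(zdims),
                 time_window = as.integer(time_window),
                 prediction_window = as.integer(prediction_window),
                 hidden_size = as.integer(hidden_size),
                 encoder_layers = 2L,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 batches_per_epoch = as.integer(batches_per_epoch),
                 kl_anneal = isTRUE(kl_anneal),
                 anneal_frac = anneal_frac,
                 seed = as.integer(seed)),
            class = "vae_config")
}

# uniform(-1/sqrt(h), 1/sqrt(h)) initialization, one GRU block
.init_gru <- function(input, hidden) {
  k <- 1 / sqrt(hidden)
  list(Wi = matrix(stats::runif(3L * hidden * input, -k, k), 3L * hidden),
       Wh = matrix(stats::runif(3L * hidden * hidden, -k, k), 3L * hidden),
       bi = stats::runif(3L * hidden, -k, k),
       bh = stats::runif(3L * hidden, -k, k))
}

.init_linear <- function(out, input) {
  k <- 1 / sqrt(input)
  list(W = matrix(stats::runif(out * input, -k, k), out),
       b = stats::runif(out, -k, k))
}

#' Build an untrained model from a configuration
#'
#' Instantiates all parameter matrices (seeded): a 2-layer bidirectional
#' GRU encoder whose two directions are summed within layers and whose
#' final forward/backward states are concatenated, two linear heads for
#' the posterior mean and log-variance, and two bidirectional GRU decoders
#' (reconstruction over `w` frames, prediction over `v` frames) that
#' receive the latent vector as input at every timestep.
#'
#' @param config a [vae_config()].
#' @return an object of class `motif_vae` (untrained; `fitted = FALSE`).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "vae_config"))
  m <- config$num_features; h <- config$hidden_size; d <- config$zdims
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(config$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  p <- list()
  add_gru <- function(p, pre, input) {
    g <- .init_gru(input, h)
    p[[paste0(pre, ".Wi")]] <- g$Wi; p[[paste0(pre, ".Wh")]] <- g$Wh
    p[[paste0(pre, ".bi")]] <- g$bi; p[[paste0(pre, ".bh")]] <- g$bh
    p
  }
  p <- add_gru(p, "enc1f", m); p <- add_gru(p, "enc1b", m)
  p <- add_gru(p, "enc2f", h); p <- add_gru(p, "enc2b", h)
  p <- add_gru(p, "decrf", d); p <- add_gru(p, "decrb", d)
  p <- add_gru(p, "decpf", d); p <- add_gru(p, "decpb", d)
  mu <- .init_linear(d, 2L * h); lv <- .init_linear(d, 2L * h)
  p[["mu.W"]] <- mu$W; p[["mu.b"]] <- mu$b
  p[["lv.W"]] <- lv$W; p[["lv.b"]] <- lv$b
  or <- .init_linear(m, h); op <- .init_linear(m, h)
  p[["decr.Wo"]] <- or$W; p[["decr.bo"]] <- or$b
  p[["decp.Wo"]] <- op$W; p[["decp.bo"]] <- op$b
  structure(list(params = p, config = config, history = NULL,
                 best_epoch = NA_integer_, scale_stats = NULL,
                 fitted = FALSE),
            class = "motif_vae")
}

#' Number of free parameters of a model
#' @param object a `motif_vae`.
#' @return integer parameter count.
#' @export
n_parameters <- function(object) {
  sum(vapply(object$params, length, integer(1)))
}

#' Reparameterization trick
#'
#' Draws a latent sample `z = mu + exp(log_variance / 2) * eps`
#' elementwise, turning the stochastic sampling of the posterior into a
#' differentiable transform of auxiliary noise.
#'
#' @param mu,log_variance numeric vectors/matrices of matching shape.
#' @param eps auxiliary standard-normal noise of the same shape.
#' @return the latent sample, same shape as `mu`.
#' @export
reparameterize <- function(mu, log_variance, eps) {
  stopifnot(length(mu) == length(log_variance), length(mu) == length(eps))
  mu + exp(log_variance / 2) * eps
}

#' KL divergence to the standard-normal prior
#'
#' Closed form for a diagonal Gaussian `N(mu, diag(exp(log_variance)))`
#' against `N(0, I)`: `0.5 * sum(exp(lv) + mu^2 - 1 - lv)`.
#'
#' @inheritParams reparameterize
#' @return non-negative scalar.
#' @export
kl_divergence <- function(mu, log_variance) {
  stopifnot(length(mu) == length(log_variance))
  0.5 * sum(exp(log_variance) + mu^2 - 1 - log_variance)
}

#' Loss decomposition
#'
#' Computes the three training-loss terms from model outputs: mean squared
#' error of the reconstruction against the input windows, mean squared
#' error of the prediction against the future windows, and the KL term
#' (batch mean), with `total = reconstruction + prediction +
#' kl_weight * kl`.
#'
#' @param batch a `window_batch` (targets).
#' @param outputs list with `recon` (m x w x B) and `pred` (m x v x B)
#'   arrays.
#' @param latents list with `mu` and `log_variance` (d x B matrices).
#' @param kl_weight weight on the KL term (default 1).
#' @return list with `reconstruction`, `prediction`, `kl`, `total`.
#' @export
loss_terms <- function(batch, outputs, latents, kl_weight = 1) {
  if (!all(dim(outputs$recon) == dim(batch$inputs)))
    stop("reconstruction output shape does not match input windows")
  if (!all(dim(outputs$pred) == dim(batch$futures)))
    stop("prediction output shape does not match future windows")
  B <- dim(batch$inputs)[3L]
  rec <- mean((outputs$recon - batch$inputs)^2)
  pred <- mean((outputs$pred - batch$futures)^2)
  kl <- kl_divergence(latents$mu, latents$log_variance) / B
  list(reconstruction = rec, prediction = pred, kl = kl,
       total = rec + pred + kl_weight * kl)
}

# one Adam step over the flat parameter list (in place on copies)
.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# draw windows using the current RNG stream (internal; sample_windows is
# the seeded public entry point)
.draw_windows <- function(series, w, v, n) {
  lens <- vapply(series, function(s) nrow(s$values), integer(1))
  ok <- which(lens >= w + v)
  if (!length(ok)) stop("no series long enough for w + v frames")
  m <- ncol(series[[ok[1L]]]$values)
  sid <- ok[sample.int(length(ok), n, replace = TRUE)]
  inputs <- array(NA_real_, c(m, w, n))
  futures <- array(NA_real_, c(m, v, n))
  starts <- integer(n)
  for (k in seq_len(n)) {
    s <- series[[sid[k]]]$values
    st <- sample.int(lens[sid[k]] - w - v + 1L, 1L)
    starts[k] <- st
    inputs[, , k] <- t(s[st:(st + w - 1L), , drop = FALSE])
    futures[, , k] <- t(s[(st + w):(st + w + v - 1L), , drop = FALSE])
  }
  structure(list(inputs = inputs, futures = futures,
                 origin = data.frame(series = sid, start = starts - 1L)),
            class = "window_batch")
}

#' Fit the variational recurrent autoencoder
#'
#' Trains the embedding model on egocentrically aligned, cleaned and
#' z-scored marker series: random trajectory windows are encoded by a
#' 2-layer bidirectional GRU into a Gaussian posterior over a
#' d-dimensional latent vector, which a reconstruction decoder maps back
#' onto the window and a prediction decoder maps onto the following
#' frames. The optimizer is Adam at a fixed learning rate; training stops
#' at the epoch budget or once the test loss has not improved for
#' `patience` epochs, and the parameters of the best test epoch are kept.
#'
#' Test loss is monitored on windows from a held-out contiguous tail of
#' each series, evaluated deterministically (posterior mean, KL weight 1)
#' so early stopping is reproducible.
#'
#' @param x a z-scored [marker_series()] or list of them.
#' @param config a [vae_config()]; if `NULL` one is built from `...`.
#' @param ... arguments passed to [vae_config()] when `config` is `NULL`
#'   (e.g. `zdims`, `hidden_size`, `max_epochs`).
#' @param test_fraction fraction of frames held out for the test loss
#'   (default 0.1).
#' @param verbose print per-epoch losses.
#' @return a fitted `motif_vae` object with elements `params`, `config`,
#'   `history` (per-epoch loss breakdown), `best_epoch`, `scale_stats`.
#' @seealso [infer_latents()], [generate()], [evaluate()]
#' @export
motif_vae <- function(x, config = NULL, ..., test_fraction = 0.1,
                      verbose = FALSE) {
  if (inherits(x, "marker_series")) x <- list(x)
  m <- ncol(x[[1L]]$values)
  if (is.null(config)) config <- vae_config(num_features = m, ...)
  if (config$num_features != m)
    stop("config num_features (", config$num_features,
         ") does not match the data (", m, ")")
  model <- build_model(config)
  model$scale_stats <- x[[1L]]$scale_stats
  sp <- split_train_test(x, test_fraction)
  w <- config$time_window; v <- config$prediction_window
  d <- config$zdims

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(config$seed + 1L)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  n_test <- min(512L, config$batch_size * config$batches_per_epoch)
  test_batch <- .draw_windows(sp$test, w, v, n_test)
  eps0 <- matrix(0, d, n_test)
  # the optimized objective follows the evidence lower bound with the
  # reconstruction/prediction errors summed over window elements; relative
  # to per-element means this scales the KL term by 1/(m*w) and the
  # prediction term by v/w (Adam is invariant to the overall constant)
  kl_scale <- 1 / (m * w)
  pred_weight <- v / w

  params <- model$params
  state <- list(t = 0L,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  anneal_epochs <- max(1, ceiling(config$anneal_frac * config$max_epochs))
  hist <- vector("list", config$max_epochs)
  best <- list(loss = Inf, params = params, epoch = 0L)
  stall <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    klw <- if (config$kl_anneal) min(1, epoch / anneal_epochs) else 1
    tr <- c(reconstruction = 0, prediction = 0, kl = 0, total = 0)
    for (b in seq_len(config$batches_per_epoch)) {
      batch <- .draw_windows(sp$train, w, v, config$batch_size)
      eps <- matrix(stats::rnorm(d * config$batch_size), d)
      res <- cpp_vae_grad(params, batch$inputs, batch$futures, eps,
                          klw * kl_scale, pred_weight, TRUE)
      if (!is.finite(res$total))
        stop("training diverged at epoch ", epoch, " (non-finite loss); ",
             "reduce the learning rate or check the input scaling")
      upd <- .adam_step(params, res$grads, state, config$learning_rate)
      params <- upd$params; state <- upd$state
      tr <- tr + c(res$reconstruction, res$prediction, res$kl, res$total)
    }
    tr <- tr / config$batches_per_epoch
    te <- cpp_vae_grad(params, test_batch$inputs, test_batch$futures,
                       eps0, kl_scale, pred_weight, FALSE)
    hist[[epoch]] <- data.frame(
      epoch = epoch, kl_weight = klw,
      train_reconstruction = tr[1L], train_prediction = tr[2L],
      train_kl = tr[3L], train_total = tr[4L],
      test_reconstruction = te$reconstruction,
      test_prediction = te$prediction, test_kl = te$kl,
      test_total = te$total)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  test %.4f (kl w %.2f)",
                      epoch, tr[4L], te$total, klw))
    if (te$total < best$loss) {
      best <- list(loss = te$total, params = params, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  model$params <- best$params
  model$best_epoch <- best$epoch
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  rownames(model$history) <- NULL
  model$fitted <- TRUE
  model
}

#' @export
print.motif_vae <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "motif_vae: %s (d=%d, m=%d, w=%d, v=%d, hidden=%d, %d parameters)\n",
    if (x$fitted) "fitted" else "untrained",
    cfg$zdims, cfg$num_features, cfg$time_window, cfg$prediction_window,
    cfg$hidden_size, n_parameters(x)))
  if (x$fitted) {
    h <- x$history[x$best_epoch, ]
    cat(sprintf("  best epoch %d/%d: test loss %.4f (rec %.4f, pred %.4f, kl %.4f)\n",
                x$best_epoch, nrow(x$history), h$test_total,
                h$test_reconstruction, h$test_prediction, h$test_kl))
  }
  invisible(x)
}

#' @export
summary.motif_vae <- function(object, ...) {
  print(object)
  if (object$fitted) {
    cat("\nLoss history (last 5 epochs):\n")
    print(utils::tail(object$history[, c("epoch", "train_total",
                                         "test_total", "kl_weight")], 5L),
          row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.motif_vae <- function(object, ...) object$params

#' @export
plot.motif_vae <- function(x, ...) {
  if (!x$fitted) stop("model is not fitted")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_total, h$test_total),
                    type = "l", lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "test"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Latent series inference
#'
#' Slides a `w`-frame window with stride 1 over the series and emits the
#' posterior mean of every window as one latent column, giving a
#' `d x (N - w)` latent series. Using the mean (not a random draw) makes
#' the downstream segmentation deterministic.
#'
#' @param model a fitted `motif_vae`.
#' @param series a z-scored [marker_series()] (same scaling as training).
#' @param batch_size windows encoded per chunk.
#' @return a `latent_series`: list with `Z` (d x (N-w) matrix),
#'   `window_centers` (0-based frame index of each window center,
#'   `start + w/2`) and `w`.
#' @export
infer_latents <- function(model, series, batch_size = 256L) {
  w <- model$config$time_window
  vals <- series$values
  n <- nrow(vals)
  if (n < w) stop("series shorter than the time window (", w, " frames)")
  n_win <- n - w
  d <- model$config$zdims
  Z <- matrix(NA_real_, d, max(n_win, 0L))
  if (n_win > 0L) {
    tv <- t(vals)
    for (lo in seq(1L, n_win, by = batch_size)) {
      hi <- min(lo + batch_size - 1L, n_win)
      X <- array(NA_real_, c(ncol(vals), w, hi - lo + 1L))
      for (k in lo:hi) X[, , k - lo + 1L] <- tv[, k:(k + w - 1L)]
      Z[, lo:hi] <- cpp_vae_encode(model$params, X)$mu
    }
  }
  structure(list(Z = Z,
                 window_centers = (seq_len(n_win) - 1L) + w / 2,
                 w = w),
            class = "latent_series")
}

#' @export
print.latent_series <- function(x, ...) {
  cat(sprintf("latent_series: %d dims x %d windows (w = %d)\n",
              nrow(x$Z), ncol(x$Z), x$w))
  invisible(x)
}

#' @export
predict.motif_vae <- function(object, newdata,
                              type = c("latent", "reconstruction",
                                       "prediction"), ...) {
  type <- match.arg(type)
  if (type == "latent") return(infer_latents(object, newdata, ...))
  if (inherits(newdata, "marker_series")) {
    lat <- infer_latents(object, newdata)
    z <- lat$Z
  } else if (inherits(newdata, "window_batch")) {
    z <- cpp_vae_encode(object$params, newdata$inputs)$mu
  } else stop("newdata must be a marker_series or window_batch")
  Tlen <- if (type == "reconstruction") object$config$time_window
          else object$config$prediction_window
  cpp_vae_decode(object$params, z, Tlen, type == "prediction")
}

#' @export
residuals.motif_vae <- function(object, newdata, ...) {
  if (!inherits(newdata, "window_batch"))
    stop("newdata must be a window_batch")
  recon <- predict(object, newdata, type = "reconstruction")
  recon - newdata$inputs
}

#' Evaluate a fitted model on held-out data
#'
#' Reports reconstruction and prediction errors on windows sampled from
#' the given series, both in z-units and (when z-scoring statistics are
#' available) converted back to pixels: the per-feature root-mean-square
#' error in z-units times the feature's standard deviation, averaged over
#' features.
#'
#' @param model a fitted `motif_vae`.
#' @param series a z-scored [marker_series()] or list of them (typically
#'   the held-out test block).
#' @param n_windows number of evaluation windows (default 256).
#' @param seed RNG seed for window sampling.
#' @return list with `reconstruction_error_z`, `prediction_error_z`,
#'   `reconstruction_error_px`, `prediction_error_px` (NA without scale
#'   stats) and the loss `history`.
#' @export
evaluate <- function(model, series, n_windows = 256L, seed = 1L) {
  UseMethod("evaluate")
}

#' @rdname evaluate
#' @export
evaluate.motif_vae <- function(model, series, n_windows = 256L, seed = 1L) {
  if (!model$fitted) stop("model is not fitted")
  if (inherits(series, "marker_series")) series <- list(series)
  cfg <- model$config
  batch <- sample_windows(series, cfg$time_window, cfg$prediction_window,
                          n_windows, seed = seed)
  enc <- cpp_vae_encode(model$params, batch$inputs)
  recon <- cpp_vae_decode(model$params, enc$mu, cfg$time_window, FALSE)
  pred <- cpp_vae_decode(model$params, enc$mu, cfg$prediction_window, TRUE)
  per_feature_rmse <- function(err) sqrt(apply(err^2, 1L, mean))
  rec_z <- per_feature_rmse(recon - batch$inputs)
  prd_z <- per_feature_rmse(pred - batch$futures)
  ss <- model$scale_stats
  list(reconstruction_error_z = mean(rec_z),
       prediction_error_z = mean(prd_z),
       reconstruction_error_px =
         if (is.null(ss)) NA_real_ else mean(rec_z * ss$sd),
       prediction_error_px =
         if (is.null(ss)) NA_real_ else mean(prd_z * ss$sd),
       n_windows = n_windows,
       history = model$history)
}

#' Generative sampling from a fitted model
#'
#' Three modes: `"reconstruction"` encodes and decodes real windows;
#' `"sampling"` decodes latent vectors drawn from the standard-normal
#' prior; `"motifs"` decodes draws from a diagonal Gaussian fitted to the
#' latent columns assigned to each motif (all motifs, or only
#' `motif_num`).
#'
#' @param model a fitted `motif_vae`.
#' @param mode one of `"reconstruction"`, `"sampling"`, `"motifs"`.
#' @param windows a `window_batch` (reconstruction mode).
#' @param latents a `latent_series` (motifs mode).
#' @param motifs a `motif_series` (motifs mode).
#' @param motif_num single motif id (0-based) or `NULL` for all motifs.
#' @param count samples per motif / total samples (default 10).
#' @param seed RNG seed.
#' @return `reconstruction`/`sampling`: an m x w x count array; `motifs`:
#'   a named list of such arrays, one per motif.
#' @export
generate <- function(model, mode = c("reconstruction", "sampling", "motifs"),
                     windows = NULL, latents = NULL, motifs = NULL,
                     motif_num = NULL, count = 10L, seed = 42L) {
  mode <- match.arg(mode)
  if (!model$fitted) stop("model is not fitted")
  w <- model$config$time_window; d <- model$config$zdims
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  if (mode == "reconstruction") {
    if (is.null(windows)) stop("reconstruction mode needs a window_batch")
    z <- cpp_vae_encode(model$params, windows$inputs)$mu
    return(cpp_vae_decode(model$params, z, w, FALSE))
  }
  if (mode == "sampling") {
    z <- matrix(stats::rnorm(d * count), d)
    return(cpp_vae_decode(model$params, z, w, FALSE))
  }
  if (is.null(latents) || is.null(motifs))
    stop("motifs mode needs latents and a motif_series")
  ids <- if (is.null(motif_num)) sort(unique(motifs$labels)) else motif_num
  out <- list()
  for (k in ids) {
    cols <- which(motifs$labels == k)
    if (length(cols) < 2L)
      stop("motif ", k, " has fewer than 2 latent columns")
    zk <- latents$Z[, cols, drop = FALSE]
    mu <- rowMeans(zk)
    sd <- apply(zk, 1L, stats::sd)
    z <- mu + sd * matrix(stats::rnorm(d * count), d)
    out[[as.character(k)]] <- cpp_vae_decode(model$params, z, w, FALSE)
  }
  if (!is.null(motif_num) && length(ids) == 1L) out[[1L]] else out
}

#' @export
simulate.motif_vae <- function(object, nsim = 10L, seed = 42L, ...) {
  generate(object, mode = "sampling", count = nsim, seed = seed)
}
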