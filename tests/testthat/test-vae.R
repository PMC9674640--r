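test_that("reparameterization is the deterministic transform of the noise", {
  mu <- c(1, -2, 0.5); lv <- c(0, 0.4, -1)
  expect_equal(reparameterize(mu, lv, c(0, 0, 0)), mu)
  expect_equal(reparameterize(mu, 0 * lv, c(1, 1, 1)), mu + 1)
  set.seed(10)
  n <- 1e5
  eps <- matrix(rnorm(3 * n), 3)
  z <- reparameterize(matrix(mu, 3, n), matrix(lv, 3, n), eps)
  se_mean <- sqrt(exp(lv) / n)
  expect_true(all(abs(rowMeans(z) - mu) < 3 * se_mean))
  se_var <- exp(lv) * sqrt(2 / (n - 1))
  expect_true(all(abs(apply(z, 1, var) - exp(lv)) < 3 * se_var))
})

test_that("KL closed form matches trivial cases and quadrature", {
  expect_equal(kl_divergence(c(0, 0), c(0, 0)), 0)
  expect_equal(kl_divergence(c(1, 0), c(0, 0)), 0.5)
  set.seed(20)
  for (i in 1:5) {
    mu <- rnorm(4); lv <- rnorm(4, sd = 0.8)
    expect_equal(kl_divergence(mu, lv), oracle_kl_quadrature(mu, lv),
                 tolerance = 1e-6)
  }
  expect_gte(kl_divergence(rnorm(10), rnorm(10)), 0)
})

test_that("loss decomposition matches an elementwise oracle and sums exactly", {
  set.seed(30)
  m <- 3L; w <- 6L; v <- 4L; B <- 5L; d <- 2L
  batch <- structure(list(inputs = array(rnorm(m * w * B), c(m, w, B)),
                          futures = array(rnorm(m * v * B), c(m, v, B))),
                     class = "window_batch")
  outputs <- list(recon = array(rnorm(m * w * B), c(m, w, B)),
                  pred = array(rnorm(m * v * B), c(m, v, B)))
  latents <- list(mu = matrix(rnorm(d * B), d),
                  log_variance = matrix(rnorm(d * B), d))
  lt <- loss_terms(batch, outputs, latents, kl_weight = 0.3)
  # hand-rolled loops
  rec <- 0
  for (i in 1:m) for (t in 1:w) for (b in 1:B)
    rec <- rec + (outputs$recon[i, t, b] - batch$inputs[i, t, b])^2
  expect_equal(lt$reconstruction, rec / (m * w * B), tolerance = 1e-12)
  kl <- 0
  for (j in 1:d) for (b in 1:B)
    kl <- kl + 0.5 * (exp(latents$log_variance[j, b]) + latents$mu[j, b]^2 -
                        1 - latents$log_variance[j, b])
  expect_equal(lt$kl, kl / B, tolerance = 1e-12)
  expect_identical(lt$total,
                   lt$reconstruction + lt$prediction + 0.3 * lt$kl)

  # perfect outputs and prior-matching posterior give zero loss
  perfect <- list(recon = batch$inputs, pred = batch$futures)
  zero_lat <- list(mu = matrix(0, d, B), log_variance = matrix(0, d, B))
  expect_equal(loss_terms(batch, perfect, zero_lat)$total, 0)
  # constant offset of 1 gives MSE exactly 1
  off <- list(recon = batch$inputs + 1, pred = batch$futures)
  expect_equal(loss_terms(batch, off, zero_lat)$reconstruction, 1)
})

test_that("the C++ forward pass agrees with the R loss decomposition", {
  set.seed(31)
  cfg <- vae_config(num_features = 3, zdims = 2, time_window = 5,
                    prediction_window = 3, hidden_size = 4, seed = 2)
  mod <- build_model(cfg)
  B <- 4L
  batch <- structure(list(inputs = array(rnorm(3 * 5 * B), c(3, 5, B)),
                          futures = array(rnorm(3 * 3 * B), c(3, 3, B))),
                     class = "window_batch")
  eps <- matrix(rnorm(2 * B), 2)
  res <- motifembed:::cpp_vae_grad(mod$params, batch$inputs, batch$futures,
                                   eps, 0.7, 1, TRUE)
  lt <- loss_terms(batch, list(recon = res$recon, pred = res$pred),
                   list(mu = res$mu, log_variance = res$log_variance),
                   kl_weight = 0.7)
  expect_equal(res$reconstruction, lt$reconstruction, tolerance = 1e-12)
  expect_equal(res$prediction, lt$prediction, tolerance = 1e-12)
  expect_equal(res$kl, lt$kl, tolerance = 1e-12)
  expect_equal(res$total, lt$total, tolerance = 1e-12)
  # reparameterization inside the graph matches the exported op
  expect_equal(res$z, reparameterize(res$mu, res$log_variance, eps),
               tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  set.seed(7)
  cfg <- vae_config(num_features = 3, zdims = 2, time_window = 4,
                    prediction_window = 2, hidden_size = 3, seed = 1)
  p <- build_model(cfg)$params
  B <- 2L
  X <- array(rnorm(3 * 4 * B), c(3, 4, B))
  Y <- array(rnorm(3 * 2 * B), c(3, 2, B))
  eps <- matrix(rnorm(2 * B), 2)
  klw <- 0.7; pw <- 0.5
  res <- motifembed:::cpp_vae_grad(p, X, Y, eps, klw, pw, TRUE)
  h <- 1e-5
  for (nm in names(p)) {
    set.seed(match(nm, names(p)))
    for (idx in sample(length(p[[nm]]), min(3L, length(p[[nm]])))) {
      pp <- p; pp[[nm]][idx] <- pp[[nm]][idx] + h
      up <- motifembed:::cpp_vae_grad(pp, X, Y, eps, klw, pw, FALSE)$total
      pm <- p; pm[[nm]][idx] <- pm[[nm]][idx] - h
      dn <- motifembed:::cpp_vae_grad(pm, X, Y, eps, klw, pw, FALSE)$total
      num <- (up - dn) / (2 * h)
      ana <- res$grads[[nm]][idx]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("model construction is seeded and dimensionally consistent", {
  cfg <- vae_config(num_features = 10, zdims = 12, time_window = 30,
                    hidden_size = 8, seed = 3)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)
  enc <- motifembed:::cpp_vae_encode(m1$params,
                                     array(rnorm(10 * 30 * 2), c(10, 30, 2)))
  expect_equal(dim(enc$mu), c(12L, 2L))

  # closed-form parameter count: 8 GRUs + 2 latent heads + 2 output layers
  count_gru <- function(input, h) 3 * h * input + 3 * h * h + 6 * h
  m <- 10; h <- 8; d <- 12
  expected <- 2 * count_gru(m, h) + 2 * count_gru(h, h) +
    4 * count_gru(d, h) + 2 * (d * 2 * h + d) + 2 * (m * h + m)
  expect_equal(n_parameters(m1), expected)

  expect_error(vae_config(num_features = 2, zdims = 60, time_window = 30),
               "d < m\\*w")
})

test_that("latent inference emits exactly N - w columns with stride 1", {
  qs <- quick_model_and_series()
  mod <- qs$model; s <- qs$series
  w <- mod$config$time_window
  lat <- infer_latents(mod, s)
  expect_equal(ncol(lat$Z), nrow(s$values) - w)
  expect_equal(lat$window_centers[1], w / 2)

  # N = w gives a valid empty result
  short <- marker_series(s$values[seq_len(w), , drop = FALSE])
  expect_equal(ncol(infer_latents(mod, short)$Z), 0L)
  expect_error(infer_latents(mod, marker_series(s$values[1:5, ])), "shorter")

  # shifting the series by one frame shifts the latent columns by one
  shifted <- marker_series(s$values[-1, , drop = FALSE])
  lat2 <- infer_latents(mod, shifted)
  expect_equal(lat2$Z, lat$Z[, -1L], tolerance = 1e-12)
})

test_that("training improves the held-out loss and is reproducible", {
  ds <- reference_dataset("tiny", seed = 17L)
  s <- preprocess_series(confidence_mask(ds$track, 0.9), 1L, 4L)
  s$values <- s$values[1:800, ]
  s <- zscore(marker_series(s$values))
  cfg <- vae_config(num_features = 6, zdims = 4, time_window = 20,
                    prediction_window = 10, hidden_size = 24,
                    max_epochs = 8, batch_size = 32, batches_per_epoch = 10,
                    seed = 5)
  mod <- motif_vae(s, config = cfg)
  h <- mod$history
  expect_lt(h$test_total[mod$best_epoch], h$test_total[1])
  expect_equal(nrow(h), 8L)
  mod2 <- motif_vae(s, config = cfg)
  expect_identical(mod$history, mod2$history)
  expect_identical(mod$params, mod2$params)
})

test_that("the patience rule stops training once the test loss stalls", {
  ds <- reference_dataset("tiny", seed = 23L)
  s <- preprocess_series(confidence_mask(ds$track, 0.9), 1L, 4L)
  s <- zscore(marker_series(s$values[1:500, ]))
  cfg <- vae_config(num_features = 6, zdims = 4, time_window = 20,
                    prediction_window = 10, hidden_size = 8,
                    max_epochs = 50, patience = 1, batch_size = 8,
                    batches_per_epoch = 2, learning_rate = 0, seed = 6)
  mod <- motif_vae(s, config = cfg)
  expect_equal(nrow(mod$history), 2L)   # epoch 1 best, epoch 2 stalls
  expect_equal(mod$best_epoch, 1L)
})

test_that("evaluation converts errors between z-units and pixels", {
  qs <- quick_model_and_series()
  ev <- evaluate(qs$model, qs$series, n_windows = 64L, seed = 2L)
  expect_true(ev$reconstruction_error_z > 0)
  expect_true(is.finite(ev$reconstruction_error_px))
  # pixel error is the per-feature z-RMSE scaled by the feature sd
  sd_range <- range(qs$series$scale_stats$sd)
  expect_gte(ev$reconstruction_error_px,
             ev$reconstruction_error_z * sd_range[1] * 0.999)
  expect_lte(ev$reconstruction_error_px,
             ev$reconstruction_error_z * sd_range[2] * 1.001)
})

test_that("generative modes are seeded and mutually consistent", {
  qs <- quick_model_and_series()
  mod <- qs$model
  s1 <- generate(mod, "sampling", count = 5L, seed = 9L)
  s2 <- generate(mod, "sampling", count = 5L, seed = 9L)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(6L, mod$config$time_window, 5L))
  expect_identical(simulate(mod, nsim = 5L, seed = 9L), s1)

  b <- sample_windows(qs$series, mod$config$time_window,
                      mod$config$prediction_window, 16L, seed = 4L)
  rec <- generate(mod, "reconstruction", windows = b)
  expect_equal(dim(rec), dim(b$inputs))
  expect_equal(rec, predict(mod, b, type = "reconstruction"))
  res <- residuals(mod, b)
  expect_equal(res, rec - b$inputs)

  lat <- infer_latents(mod, qs$series)
  labs <- motif_series(rep(0:1, length.out = ncol(lat$Z)), 2L)
  g <- generate(mod, "motifs", latents = lat, motifs = labs, count = 3L,
                seed = 1L)
  expect_named(g, c("0", "1"))
  expect_equal(dim(g[["0"]])[3], 3L)
  one_frame <- motif_series(c(rep(0L, ncol(lat$Z) - 1L), 1L), 2L)
  expect_error(generate(mod, "motifs", latents = lat, motifs = one_frame),
               "fewer than 2")
})
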