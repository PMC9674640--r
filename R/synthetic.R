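#' Behavioral regime specification for the pose simulator
#'
#' One planted behavioral regime: a posture (per-marker baseline offsets
#' in the body frame), limb oscillators (amplitude, frequency, phase
#' offset per marker, mimicking gait), a locomotion speed, and a marker
#' noise level. Regimes differing in frequency, amplitude, posture and
#' speed are what make trajectory windows discriminative.
#'
#' @param id regime id (0-based).
#' @param offsets M x 2 matrix of baseline marker positions in the body
#'   frame (pixels); rows ordered like the marker list, with the front
#'   anchor (nose) first and the back anchor (tailbase) last.
#' @param amplitude oscillation amplitude per marker (pixels).
#' @param frequency oscillation frequency per marker (Hz).
#' @param phase oscillation phase offset per marker (radians); offset
#'   paw phases imitate alternating gait.
#' @param speed forward body speed (pixels/frame).
#' @param noise_sd additive Gaussian marker noise (pixels).
#' @return an object of class `regime_spec`.
#' @export
regime_spec <- function(id, offsets, amplitude, frequency, phase = NULL,
                        speed = 0, noise_sd = 0.5) {
  offsets <- as.matrix(offsets)
  M <- nrow(offsets)
  if (length(amplitude) == 1L) amplitude <- rep(amplitude, M)
  if (length(frequency) == 1L) frequency <- rep(frequency, M)
  if (is.null(phase)) phase <- rep(0, M)
  stopifnot(length(amplitude) == M, length(frequency) == M,
            length(phase) == M, all(frequency >= 0), noise_sd >= 0)
  structure(list(id = as.integer(id), offsets = offsets,
                 amplitude = amplitude, frequency = frequency,
                 phase = phase, speed = speed, noise_sd = noise_sd),
            class = "regime_spec")
}

#' Simulate a Markov regime-switching label sequence
#'
#' @param switch_matrix K x K row-stochastic regime transition matrix.
#' @param initial initial distribution (default uniform).
#' @param N sequence length (frames).
#' @param seed RNG seed.
#' @return integer vector of 0-based regime labels, length N.
#' @export
simulate_regime_sequence <- function(switch_matrix, N,
                                     initial = NULL, seed = 42L) {
  switch_matrix <- as.matrix(switch_matrix)
  K <- nrow(switch_matrix)
  if (ncol(switch_matrix) != K ||
      any(abs(rowSums(switch_matrix) - 1) > 1e-8) || any(switch_matrix < 0))
    stop("switch_matrix must be row-stochastic")
  if (is.null(initial)) initial <- rep(1 / K, K)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  labels <- integer(N)
  labels[1L] <- sample.int(K, 1L, prob = initial)
  for (t in seq_len(N - 1L))
    labels[t + 1L] <- sample.int(K, 1L, prob = switch_matrix[labels[t], ])
  labels - 1L
}

#' Simulate an allocentric pose recording with planted regimes
#'
#' Builds a multi-marker 2D trajectory of a freely moving animal: the
#' body frame is assembled from each frame's regime posture plus limb
#' oscillators (phase accumulates continuously across regime switches),
#' rotated by a smoothly varying heading (AR(1) angular velocity),
#' translated along a speed-driven walk bounded by a circular arena, and
#' corrupted by additive Gaussian noise. The likelihood column is 1
#' except on seeded dropout frames, where it drops to 0.1 and the marker
#' coordinates are perturbed — so the confidence-mask path is genuinely
#' exercised.
#'
#' @param labels 0-based regime label sequence (one per frame).
#' @param regimes list of [regime_spec()], one per regime id.
#' @param frame_rate frames/second (default 60).
#' @param arena_radius bounding radius of the walk (pixels, default 250).
#' @param turning_sd innovation sd of the angular velocity
#'   (radians/frame, default 0.02).
#' @param dropout_rate per frame-marker probability of a low-confidence
#'   dropout (default 0).
#' @param markers marker names (defaults to nose/paws/tailbase naming).
#' @param seed RNG seed.
#' @return an object of class `synthetic_dataset`: list with `track`
#'   (a [pose_track()]), `labels`, `heading`, `position`, `frame_rate`
#'   and the generator `config`.
#' @export
simulate_pose <- function(labels, regimes, frame_rate = 60,
                          arena_radius = 250, turning_sd = 0.02,
                          dropout_rate = 0, markers = NULL, seed = 42L) {
  if (!length(regimes)) stop("empty regime list")
  N <- length(labels)
  r1 <- labels + 1L
  if (max(r1) > length(regimes))
    stop("label ", max(labels), " has no regime_spec")
  M <- nrow(regimes[[1L]]$offsets)
  if (is.null(markers)) {
    markers <- if (M == 6L) {
      c("nose", "forepaw_l", "forepaw_r", "hindpaw_l", "hindpaw_r",
        "tailbase")
    } else {
      c("nose", paste0("paw", seq_len(max(M - 2L, 0L))), "tailbase")[1:M]
    }
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  # per-frame regime parameter lookups
  amp <- t(vapply(regimes, `[[`, numeric(M), "amplitude"))[r1, , drop = FALSE]
  freq <- t(vapply(regimes, `[[`, numeric(M), "frequency"))[r1, , drop = FALSE]
  ph0 <- t(vapply(regimes, `[[`, numeric(M), "phase"))[r1, , drop = FALSE]
  noise <- vapply(regimes, `[[`, numeric(1), "noise_sd")[r1]
  speed <- vapply(regimes, `[[`, numeric(1), "speed")[r1]
  offx <- t(vapply(regimes, function(r) r$offsets[, 1L], numeric(M)))[r1, ,
                                                                     drop = FALSE]
  offy <- t(vapply(regimes, function(r) r$offsets[, 2L], numeric(M)))[r1, ,
                                                                     drop = FALSE]
  # continuous oscillator phase per marker
  phi <- apply(2 * pi * freq / frame_rate, 2L, cumsum) + ph0
  bx <- offx + amp * sin(phi)
  by <- offy + 0.3 * amp * cos(phi)

  # heading (AR(1) angular velocity) and bounded walk
  omega <- as.numeric(stats::filter(stats::rnorm(N, 0, turning_sd), 0.95,
                                    method = "recursive"))
  theta <- numeric(N)
  px <- numeric(N); py <- numeric(N)
  for (t in 2:N) {
    theta[t] <- theta[t - 1L] + omega[t]
    nx <- px[t - 1L] + speed[t] * cos(theta[t])
    ny <- py[t - 1L] + speed[t] * sin(theta[t])
    rr <- sqrt(nx^2 + ny^2)
    if (rr > arena_radius) {      # reflect back into the arena
      nx <- nx * arena_radius / rr
      ny <- ny * arena_radius / rr
      theta[t] <- theta[t] + pi / 2
    }
    px[t] <- nx; py[t] <- ny
  }
  ct <- cos(theta); st <- sin(theta)
  X <- (bx * ct - by * st) + px +
    matrix(stats::rnorm(N * M), N) * noise
  Y <- (bx * st + by * ct) + py +
    matrix(stats::rnorm(N * M), N) * noise
  lik <- matrix(1, N, M)
  if (dropout_rate > 0) {
    drop <- matrix(stats::runif(N * M) < dropout_rate, N, M)
    lik[drop] <- 0.1
    X[drop] <- X[drop] + stats::runif(sum(drop), 20, 60) *
      sample(c(-1, 1), sum(drop), replace = TRUE)
    Y[drop] <- Y[drop] + stats::runif(sum(drop), 20, 60) *
      sample(c(-1, 1), sum(drop), replace = TRUE)
  }
  structure(list(track = pose_track(X, Y, lik, markers = markers),
                 labels = as.integer(labels),
                 heading = theta, position = cbind(px, py),
                 frame_rate = frame_rate,
                 config = list(regimes = regimes, seed = seed,
                               frame_rate = frame_rate,
                               arena_radius = arena_radius,
                               turning_sd = turning_sd,
                               dropout_rate = dropout_rate)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d frames, %d markers, %d regimes\n",
              nrow(x$track$x), length(x$track$markers),
              length(x$config$regimes)))
  invisible(x)
}

# tiny 4-marker body plan; postures differ between regimes
.tiny_regimes <- function() {
  base <- rbind(nose = c(20, 0), forepaw = c(8, -6),
                hindpaw = c(-8, 6), tailbase = c(-20, 0))
  stretched <- rbind(nose = c(26, 0), forepaw = c(10, -7),
                     hindpaw = c(-10, 7), tailbase = c(-26, 0))
  list(
    regime_spec(0L, base, amplitude = c(0, 0.5, 0.5, 0), frequency = 1,
                phase = c(0, 0, pi, 0), speed = 0, noise_sd = 0.5),
    regime_spec(1L, base, amplitude = c(0, 4, 6, 0), frequency = 5,
                phase = c(0, 0, pi, 0), speed = 3, noise_sd = 0.5),
    regime_spec(2L, stretched, amplitude = c(0, 2, 3, 0), frequency = 2.5,
                phase = c(0, 0, pi, 0), speed = 1, noise_sd = 0.5)
  )
}

# 6-marker body plan with alternating-gait paw phases
.standard_regimes <- function() {
  base <- rbind(nose = c(22, 0),
                forepaw_l = c(8, 7), forepaw_r = c(8, -7),
                hindpaw_l = c(-8, 8), hindpaw_r = c(-8, -8),
                tailbase = c(-22, 0))
  crouched <- base * 0.8
  gait <- c(0, 0, pi, pi, 0, 0)
  list(
    regime_spec(0L, base, amplitude = c(0, 0.5, 0.5, 0.5, 0.5, 0),
                frequency = 1, phase = gait, speed = 0, noise_sd = 0.5),
    regime_spec(1L, base, amplitude = c(0, 4, 4, 6, 6, 0),
                frequency = 5, phase = gait, speed = 3, noise_sd = 0.5),
    regime_spec(2L, base, amplitude = c(0, 2, 2, 3, 3, 0),
                frequency = 2.5, phase = gait, speed = 1, noise_sd = 0.5),
    regime_spec(3L, crouched, amplitude = c(1, 1, 1, 1, 1, 1),
                frequency = 7, phase = gait, speed = 0.3, noise_sd = 0.5)
  )
}

#' Reference synthetic datasets
#'
#' Two fixed study conditions: `"tiny"` (3 regimes, 4 markers — two limb
#' markers plus the nose/tailbase anchors — 3,000 frames; sized so the
#' full pipeline runs in continuous-integration time) and `"standard"`
#' (4 regimes, 6 markers, 30,000 frames, mirroring a typical ~25-minute
#' single-video recording). Regime switching is sticky
#' (self-probability 0.995, mean bout length about 3.3 s at 60 fps,
#' typical of coarse pause/walk/explore bouts) so that 30-frame
#' trajectory windows are predominantly regime-pure, and a 0.5% marker
#' dropout rate exercises the confidence mask.
#'
#' @param preset `"tiny"` or `"standard"`.
#' @param seed RNG seed; the same seed always reproduces the same
#'   dataset.
#' @return a `synthetic_dataset` (see [simulate_pose()]).
#' @export
reference_dataset <- function(preset = c("tiny", "standard"), seed = 42L) {
  preset <- match.arg(preset)
  regimes <- if (preset == "tiny") .tiny_regimes() else .standard_regimes()
  K <- length(regimes)
  N <- if (preset == "tiny") 3000L else 30000L
  sw <- matrix(0.005 / (K - 1), K, K)
  diag(sw) <- 0.995
  labels <- simulate_regime_sequence(sw, N, seed = seed)
  simulate_pose(labels, regimes, frame_rate = 60, dropout_rate = 0.005,
                seed = seed + 1L)
}
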