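#' Motif label series
#'
#' Discrete per-window motif labels (0-based, matching the latent columns
#' they segment) with the motif usage vector: the fraction of frames
#' assigned to each motif.
#'
#' @param labels integer vector of labels in `0..K-1`.
#' @param K motif count (defaults to `max(labels) + 1`).
#' @return an object of class `motif_series` with fields `labels`, `K`,
#'   `usage`.
#' @export
motif_series <- function(labels, K = NULL) {
  labels <- as.integer(labels)
  if (is.null(K)) K <- max(labels) + 1L
  if (length(labels) && (min(labels) < 0L || max(labels) >= K))
    stop("labels must lie in 0..K-1")
  usage <- tabulate(labels + 1L, nbins = K) / max(length(labels), 1L)
  structure(list(labels = labels, K = as.integer(K), usage = usage),
            class = "motif_series")
}

#' @export
print.motif_series <- function(x, ...) {
  cat(sprintf("motif_series: %d frames, K = %d motifs\n",
              length(x$labels), x$K))
  cat("usage:", paste(sprintf("%.3f", x$usage), collapse = " "), "\n")
  invisible(x)
}

# ---- internal helpers -------------------------------------------------

# accept latent_series / list thereof / matrix (d x T) / list of matrices;
# return list(X = T_total x d observation matrix, lengths)
.pool_latents <- function(latents) {
  as_mat <- function(l) {
    if (inherits(l, "latent_series")) t(l$Z)
    else if (is.matrix(l)) t(l)
    else stop("latents must be latent_series objects or d x T matrices")
  }
  if (inherits(latents, "latent_series") || is.matrix(latents))
    latents <- list(latents)
  mats <- lapply(latents, as_mat)
  list(X = do.call(rbind, mats),
       lengths = vapply(mats, nrow, integer(1)))
}

# per-observation per-state Gaussian log density, X: T x d
.emission_loglik <- function(X, means, covars, covariance) {
  Tn <- nrow(X); K <- nrow(means); d <- ncol(X)
  ll <- matrix(NA_real_, Tn, K)
  if (covariance == "diag") {
    for (k in seq_len(K)) {
      sd_k <- sqrt(covars[k, ])
      zz <- sweep(sweep(X, 2L, means[k, ]), 2L, sd_k, "/")
      ll[, k] <- -0.5 * rowSums(zz^2) - sum(log(sd_k)) - d / 2 * log(2 * pi)
    }
  } else {
    for (k in seq_len(K)) {
      ch <- chol(covars[, , k])
      zz <- backsolve(ch, t(sweep(X, 2L, means[k, ])), transpose = TRUE)
      ll[, k] <- -0.5 * colSums(zz^2) - sum(log(diag(ch))) -
        d / 2 * log(2 * pi)
    }
  }
  ll
}

# scaled forward-backward for one sequence; returns gamma, xi_sum, loglik
.forward_backward <- function(ll, initial, transition) {
  Tn <- nrow(ll); K <- ncol(ll)
  mx <- apply(ll, 1L, max)
  b <- exp(ll - mx)
  alpha <- matrix(NA_real_, Tn, K)
  cs <- numeric(Tn)
  a <- initial * b[1L, ]
  cs[1L] <- sum(a)
  alpha[1L, ] <- a / cs[1L]
  for (t in 2L:Tn) {
    a <- as.vector(alpha[t - 1L, ] %*% transition) * b[t, ]
    cs[t] <- sum(a)
    alpha[t, ] <- a / cs[t]
  }
  beta <- matrix(NA_real_, Tn, K)
  beta[Tn, ] <- 1
  xi_sum <- matrix(0, K, K)
  for (t in (Tn - 1L):1L) {
    bb <- b[t + 1L, ] * beta[t + 1L, ]
    xi_sum <- xi_sum +
      transition * (alpha[t, ] %o% bb) / cs[t + 1L]
    beta[t, ] <- as.vector(transition %*% bb) / cs[t + 1L]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(gamma = gamma, xi_sum = xi_sum, loglik = sum(log(cs) + mx))
}

.hmm_em_once <- function(X, lengths, K, seed, covariance, n_iter, tol,
                         min_covar) {
  d <- ncol(X); Tn <- nrow(X)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  km <- stats::kmeans(X, centers = K, nstart = 1L, iter.max = 50L)
  means <- km$centers
  gvar <- apply(X, 2L, stats::var)
  covars <- if (covariance == "diag") {
    matrix(rep(gvar, each = K), K) + min_covar
  } else {
    array(diag(gvar + min_covar, d), c(d, d, K))
  }
  initial <- rep(1 / K, K)
  transition <- matrix(1 / K, K, K)
  starts <- cumsum(c(1L, lengths[-length(lengths)]))
  ends <- cumsum(lengths)
  prev_ll <- -Inf
  iters <- 0L
  for (it in seq_len(n_iter)) {
    iters <- it
    ll <- .emission_loglik(X, means, covars, covariance)
    gammas <- matrix(NA_real_, Tn, K)
    xi_sum <- matrix(0, K, K)
    init_acc <- numeric(K)
    total_ll <- 0
    for (s in seq_along(lengths)) {
      idx <- starts[s]:ends[s]
      fb <- .forward_backward(ll[idx, , drop = FALSE], initial, transition)
      gammas[idx, ] <- fb$gamma
      xi_sum <- xi_sum + fb$xi_sum
      init_acc <- init_acc + fb$gamma[1L, ]
      total_ll <- total_ll + fb$loglik
    }
    wk <- colSums(gammas)
    if (any(wk < 1e-8))
      return(list(degenerate = TRUE))
    initial <- init_acc / sum(init_acc)
    rs <- rowSums(xi_sum)
    transition <- xi_sum / ifelse(rs > 0, rs, 1)
    transition[rs == 0, ] <- 1 / K
    means <- sweep(t(gammas) %*% X, 1L, wk, "/")
    if (covariance == "diag") {
      for (k in seq_len(K)) {
        ctr <- sweep(X, 2L, means[k, ])
        covars[k, ] <- colSums(gammas[, k] * ctr^2) / wk[k] + min_covar
      }
    } else {
      for (k in seq_len(K)) {
        ctr <- sweep(X, 2L, means[k, ])
        covars[, , k] <- crossprod(ctr * gammas[, k], ctr) / wk[k] +
          diag(min_covar, d)
      }
    }
    if (abs(total_ll - prev_ll) < tol * abs(prev_ll + 1e-10) ||
        abs(total_ll - prev_ll) < tol) break
    prev_ll <- total_ll
  }
  list(degenerate = FALSE, initial = initial, transition = transition,
       means = means, covars = covars, loglik = prev_ll, n_iter = iters)
}

#' Fit a Gaussian-emission hidden Markov model to latent series
#'
#' Expectation-maximization fit of a K-state HMM with Gaussian emissions
#' on pooled latent columns. Multiple animals are pooled with
#' sequence-boundary bookkeeping, so no transition is counted across
#' animal boundaries. Emission means are initialized by seeded k-means,
#' covariances from the pooled variance, and start/transition
#' probabilities uniformly. If EM starves a state (a degenerate empty
#' component) the fit is retried once with the next seed.
#'
#' @param latents a `latent_series`, d x T matrix, or list of either
#'   (one per animal).
#' @param K number of hidden states (motifs).
#' @param seed RNG seed for initialization.
#' @param covariance `"diag"` (default) or `"full"` emission covariance.
#' @param n_iter maximum EM iterations (default 100).
#' @param tol relative log-likelihood convergence tolerance.
#' @param min_covar floor added to covariance diagonals for stability.
#' @param n_restarts number of EM restarts from different k-means
#'   initializations; the fit with the highest log-likelihood is kept
#'   (default 3). Restarts guard against the local optima EM is prone
#'   to on multimodal latent distributions.
#' @return an object of class `motif_hmm` with fields `K`, `initial`,
#'   `transition`, `means` (K x d), `covars`, `covariance`, `loglik`.
#' @export
fit_hmm <- function(latents, K, seed = 42L, covariance = c("diag", "full"),
                    n_iter = 100L, tol = 1e-4, min_covar = 1e-3,
                    n_restarts = 3L) {
  covariance <- match.arg(covariance)
  pl <- .pool_latents(latents)
  if (nrow(pl$X) < 10L * K)
    stop("need at least 10 * K pooled latent columns to fit ", K, " states")
  fit <- NULL
  tried <- 0L
  for (r in seq_len(n_restarts)) {
    cand <- .hmm_em_once(pl$X, pl$lengths, K, seed + r - 1L, covariance,
                         n_iter, tol, min_covar)
    if (isTRUE(cand$degenerate)) {
      # degenerate (empty) state: re-seed once beyond the restart range
      tried <- tried + 1L
      cand <- .hmm_em_once(pl$X, pl$lengths, K, seed + n_restarts + tried,
                           covariance, n_iter, tol, min_covar)
      if (isTRUE(cand$degenerate)) next
    }
    if (is.null(fit) || cand$loglik > fit$loglik) fit <- cand
  }
  if (is.null(fit))
    stop("EM produced a degenerate (empty) state in every restart; reduce K")
  structure(list(K = as.integer(K), d = ncol(pl$X),
                 initial = fit$initial, transition = fit$transition,
                 means = fit$means, covars = fit$covars,
                 covariance = covariance, loglik = fit$loglik,
                 n_iter = fit$n_iter),
            class = "motif_hmm")
}

#' @export
print.motif_hmm <- function(x, ...) {
  cat(sprintf("motif_hmm: %d states, %d-dim %s-covariance Gaussian emissions\n",
              x$K, x$d, x$covariance))
  cat(sprintf("  log-likelihood %.2f after %d EM iterations\n",
              x$loglik, x$n_iter))
  invisible(x)
}

# log-space Viterbi for one sequence
.viterbi <- function(ll, initial, transition) {
  Tn <- nrow(ll); K <- ncol(ll)
  lA <- log(transition)
  delta <- log(initial) + ll[1L, ]
  psi <- matrix(NA_integer_, Tn, K)
  for (t in 2L:Tn) {
    cand <- delta + lA               # K x K: from row, to col
    psi[t, ] <- max.col(t(cand), ties.method = "first")
    delta <- cand[cbind(psi[t, ], seq_len(K))] + ll[t, ]
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta)
  for (t in (Tn - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  path - 1L
}

#' Decode motif labels from latent series
#'
#' Runs Viterbi decoding (most probable state path; the default) or
#' posterior-argmax decoding per animal and assembles motif label series
#' with per-animal and pooled usage.
#'
#' @param hmm a fitted [fit_hmm()] model.
#' @param latents a `latent_series`/matrix or list of them (per animal).
#' @param method `"viterbi"` (default) or `"posterior"`.
#' @return for a single series, a [motif_series()]; for a list, a list of
#'   [motif_series()] with the pooled usage in attribute `"pooled_usage"`.
#' @export
decode_states <- function(hmm, latents, method = c("viterbi", "posterior")) {
  method <- match.arg(method)
  single <- inherits(latents, "latent_series") || is.matrix(latents)
  if (single) latents <- list(latents)
  out <- lapply(latents, function(l) {
    X <- if (inherits(l, "latent_series")) t(l$Z) else t(l)
    if (ncol(X) != hmm$d)
      stop("latent dimension ", ncol(X), " does not match emission dimension ",
           hmm$d)
    ll <- .emission_loglik(X, hmm$means, hmm$covars, hmm$covariance)
    labels <- if (nrow(X) == 1L) {
      which.max(log(hmm$initial) + ll[1L, ]) - 1L
    } else if (method == "viterbi") {
      .viterbi(ll, hmm$initial, hmm$transition)
    } else {
      fb <- .forward_backward(ll, hmm$initial, hmm$transition)
      max.col(fb$gamma, ties.method = "first") - 1L
    }
    motif_series(labels, hmm$K)
  })
  if (single) return(out[[1L]])
  pooled <- tabulate(unlist(lapply(out, `[[`, "labels")) + 1L,
                     nbins = hmm$K)
  attr(out, "pooled_usage") <- pooled / sum(pooled)
  out
}

#' Segment latent series by k-means
#'
#' The simpler, faster alternative to the HMM: seeded k-means on the
#' latent columns, ignoring temporal structure.
#'
#' @inheritParams decode_states
#' @param K number of clusters.
#' @param seed RNG seed.
#' @return a [motif_series()] (single input) or list of them.
#' @export
fit_kmeans <- function(latents, K, seed = 42L) {
  single <- inherits(latents, "latent_series") || is.matrix(latents)
  pl <- .pool_latents(latents)
  if (K > nrow(pl$X)) stop("K exceeds the number of latent columns")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  km <- stats::kmeans(pl$X, centers = K, nstart = 5L, iter.max = 100L)
  labels <- km$cluster - 1L
  if (single) return(motif_series(labels, K))
  ends <- cumsum(pl$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  mapply(function(s, e) motif_series(labels[s:e], K),
         starts, ends, SIMPLIFY = FALSE)
}

#' Select the motif count by the usage-threshold rule
#'
#' Fits an HMM with a deliberately generous number of states
#' (`probe_K`, default 100), decodes the data, and counts the states
#' whose usage exceeds `threshold` (default 1%). The returned count is
#' the suggested motif number; refit at that K for the final
#' segmentation.
#'
#' @inheritParams fit_hmm
#' @param probe_K number of probe states (default 100).
#' @param threshold usage fraction below which a state is discarded
#'   (default 0.01).
#' @return integer: the number of states with usage above the threshold.
#' @export
select_motif_count <- function(latents, probe_K = 100L, threshold = 0.01,
                               seed = 42L, covariance = "diag",
                               n_iter = 100L, n_restarts = 1L) {
  hmm <- fit_hmm(latents, probe_K, seed = seed, covariance = covariance,
                 n_iter = n_iter, n_restarts = n_restarts)
  dec <- decode_states(hmm, latents)
  usage <- if (inherits(dec, "motif_series")) dec$usage
           else attr(dec, "pooled_usage")
  k <- sum(usage > threshold)
  if (k == 0L) stop("no state exceeds the usage threshold")
  k
}

#' Simulate a sequence from HMM parameters
#'
#' Draws a hidden state path and Gaussian emissions; used for generative
#' checks and synthetic segmentation benchmarks.
#'
#' @param hmm a `motif_hmm` (or list with `initial`, `transition`,
#'   `means`, `covars`, `covariance`).
#' @param n sequence length.
#' @param seed RNG seed.
#' @return list with `states` (0-based integer path) and `X` (n x d
#'   emission matrix).
#' @export
simulate_hmm <- function(hmm, n, seed = 42L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  K <- length(hmm$initial)
  d <- ncol(hmm$means)
  states <- integer(n)
  states[1L] <- sample.int(K, 1L, prob = hmm$initial)
  for (t in seq_len(n - 1L))
    states[t + 1L] <- sample.int(K, 1L, prob = hmm$transition[states[t], ])
  X <- matrix(NA_real_, n, d)
  diag_cov <- !identical(hmm$covariance, "full")
  for (t in seq_len(n)) {
    k <- states[t]
    X[t, ] <- if (diag_cov) {
      stats::rnorm(d, hmm$means[k, ], sqrt(hmm$covars[k, ]))
    } else {
      hmm$means[k, ] + as.vector(t(chol(hmm$covars[, , k])) %*%
                                   stats::rnorm(d))
    }
  }
  list(states = states - 1L, X = X)
}
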