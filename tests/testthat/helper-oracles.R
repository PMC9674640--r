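# Independent brute-force oracles used to cross-check the package
# implementations. These are deliberately written as plain double loops /
# direct definitions and share no code with the package internals.

# contingency by explicit double loop
oracle_contingency <- function(u, v) {
  uu <- sort(unique(u)); vv <- sort(unique(v))
  ct <- matrix(0L, length(uu), length(vv), dimnames = list(uu, vv))
  for (i in seq_along(u))
    ct[match(u[i], uu), match(v[i], vv)] <- ct[match(u[i], uu), match(v[i], vv)] + 1L
  ct
}

oracle_purity <- function(u, v) {
  vv <- unique(v)
  s <- 0
  for (cl in vv) {
    members <- u[v == cl]
    s <- s + max(table(members))
  }
  s / length(u)
}

oracle_entropy <- function(u) {
  h <- 0
  for (cl in unique(u)) {
    p <- sum(u == cl) / length(u)
    h <- h - p * log(p)
  }
  h
}

oracle_mi <- function(u, v) {
  n <- length(u)
  mi <- 0
  for (a in unique(u)) for (b in unique(v)) {
    nab <- sum(u == a & v == b)
    if (nab > 0)
      mi <- mi + nab / n * log(n * nab / (sum(u == a) * sum(v == b)))
  }
  mi
}

oracle_nmi <- function(u, v) {
  hu <- oracle_entropy(u); hv <- oracle_entropy(v)
  if (hu + hv == 0) return(0)
  oracle_mi(u, v) / ((hu + hv) / 2)
}

oracle_homogeneity <- function(u, v) {
  hu <- oracle_entropy(u)
  if (hu == 0) return(1)
  hugv <- 0
  n <- length(u)
  for (b in unique(v)) {
    nb <- sum(v == b)
    for (a in unique(u)) {
      nab <- sum(u == a & v == b)
      if (nab > 0) hugv <- hugv - nab / n * log(nab / nb)
    }
  }
  1 - hugv / hu
}

# KL(N(mu, diag(exp(lv))) || N(0, I)) by numerical quadrature, one
# dimension at a time (the KL of a diagonal Gaussian factorizes)
oracle_kl_quadrature <- function(mu, lv) {
  total <- 0
  for (i in seq_along(mu)) {
    s <- sqrt(exp(lv[i]))
    f <- function(x) {
      lq <- stats::dnorm(x, mu[i], s, log = TRUE)
      lp <- stats::dnorm(x, 0, 1, log = TRUE)
      exp(lq) * (lq - lp)
    }
    total <- total + stats::integrate(f, mu[i] - 12 * s, mu[i] + 12 * s,
                                      rel.tol = 1e-10)$value
  }
  total
}

# exhaustive most-probable-path search for a Gaussian HMM (tiny T, K)
oracle_viterbi_enumerate <- function(X, initial, transition, means, sds) {
  Tn <- nrow(X); K <- length(initial)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  best <- -Inf; best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    lp <- log(initial[p[1]])
    for (t in seq_len(Tn)) {
      lp <- lp + sum(stats::dnorm(X[t, ], means[p[t], ], sds[p[t], ],
                                  log = TRUE))
      if (t > 1) lp <- lp + log(transition[p[t - 1], p[t]])
    }
    if (lp > best) { best <- lp; best_path <- p }
  }
  list(path = unname(best_path) - 1L, logprob = best)
}

# one exhaustive merge step of the hierarchical tree: re-derives the
# probabilities from counts and scans every pair
oracle_best_merge <- function(counts, usage) {
  n <- length(usage)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    rs <- sum(counts[i, ])
    P[i, ] <- if (rs > 0) counts[i, ] / rs else rep(1 / n, n)
  }
  best <- NULL; best_cost <- Inf; connected <- FALSE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tt <- P[i, j] + P[j, i]
    if (tt > 0) {
      cost <- (usage[i] + usage[j]) / tt
      if (!connected || cost < best_cost - 1e-15) {
        best_cost <- cost; best <- c(i, j); connected <- TRUE
      }
    } else if (!connected) {
      cost <- usage[i] + usage[j]
      if (cost < best_cost - 1e-15) { best_cost <- cost; best <- c(i, j) }
    }
  }
  best
}

# accuracy of a labeling against truth maximized over label permutations
perm_accuracy <- function(truth, labels, K) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  best <- 0
  for (p in perms(0:(K - 1)))
    best <- max(best, mean(p[labels + 1] == truth))
  best
}
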