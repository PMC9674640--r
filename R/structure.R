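#' Motif transition matrix
#'
#' Counts first-order transitions between consecutive motif labels
#' (self-transitions included) and row-normalizes them into the empirical
#' transition probability matrix `T[l, k] = P(motif k | motif l)`.
#' States with no outgoing transitions get a uniform row (with a warning)
#' by default, or a self-absorbing row with `zero_rows = "self"`.
#'
#' @param labels a [motif_series()] or integer vector of 0-based labels.
#' @param K motif count (defaults to the series' K).
#' @param zero_rows `"uniform"` (default) or `"self"`.
#' @return an object of class `transition_matrix`: list with `T` (K x K
#'   row-stochastic), `counts` (K x K integer) and `K`.
#' @export
transition_matrix <- function(labels, K = NULL,
                              zero_rows = c("uniform", "self")) {
  zero_rows <- match.arg(zero_rows)
  if (inherits(labels, "motif_series")) {
    if (is.null(K)) K <- labels$K
    labels <- labels$labels
  }
  labels <- as.integer(labels)
  if (is.null(K)) K <- max(labels) + 1L
  if (length(labels) < 2L) stop("need at least 2 labels")
  if (min(labels) < 0L || max(labels) >= K)
    stop("labels outside 0..K-1")
  from <- labels[-length(labels)] + 1L
  to <- labels[-1L] + 1L
  counts <- matrix(0L, K, K)
  for (i in seq_along(from))
    counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
  P <- matrix(0, K, K)
  rs <- rowSums(counts)
  zero <- rs == 0L
  if (any(zero)) {
    warning(sum(zero), " state(s) with no outgoing transitions; using ",
            zero_rows, " rows")
  }
  P[!zero, ] <- counts[!zero, , drop = FALSE] / rs[!zero]
  if (any(zero)) {
    if (zero_rows == "uniform") P[zero, ] <- 1 / K
    else P[cbind(which(zero), which(zero))] <- 1
  }
  structure(list(T = P, counts = counts, K = as.integer(K)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("transition_matrix: %d motifs, %d transitions\n",
              x$K, sum(x$counts)))
  print(round(x$T, 3))
  invisible(x)
}

#' Difference of two transition matrices
#'
#' Elementwise `T_a - T_b`; positive entries mark transitions more
#' pronounced in group a, negative entries transitions more pronounced in
#' group b.
#'
#' @param T_a,T_b `transition_matrix` objects or plain K x K matrices of
#'   equal size.
#' @return a K x K numeric matrix.
#' @export
subtraction_matrix <- function(T_a, T_b) {
  a <- if (inherits(T_a, "transition_matrix")) T_a$T else as.matrix(T_a)
  b <- if (inherits(T_b, "transition_matrix")) T_b$T else as.matrix(T_b)
  if (!all(dim(a) == dim(b))) stop("transition matrices differ in shape")
  a - b
}

#' Hierarchical binary merge tree over motifs
#'
#' Iteratively merges the pair of motifs `(i, j)` minimizing the cost
#' `(U_i + U_j) / (T_ij + T_ji)` — the most strongly inter-connected,
#' least used pair first — until a single root remains. After each merge
#' the transition *counts* of the merged pair are summed (rows and
#' columns) and re-normalized, and the merged node's usage is
#' `U_i + U_j`. Pairs with zero bidirectional transition probability have
#' infinite cost and are deferred until only such pairs remain, which are
#' then merged by smallest combined usage; all ties break toward the
#' lowest index pair, making the tree deterministic.
#'
#' @param T a [transition_matrix()] (its `counts` drive the recomputation).
#' @param U usage vector of length K summing to 1 (e.g. from a
#'   [motif_series()]).
#' @return an object of class `motif_tree`: list with `K`, `merges` (data
#'   frame with `step`, `left`, `right` node ids, `cost`, `usage`; leaves
#'   are `0..K-1`, internal nodes `K..2K-2` in merge order) and `root`.
#' @export
build_tree <- function(T, U) {
  stopifnot(inherits(T, "transition_matrix"))
  K <- T$K
  if (K < 2L) stop("need at least 2 motifs to build a tree")
  if (abs(sum(U) - 1) > 1e-8) stop("usage vector must sum to 1")
  counts <- matrix(as.numeric(T$counts), K, K)
  u <- as.numeric(U)
  ids <- 0:(K - 1L)
  merges <- vector("list", K - 1L)
  next_id <- K
  for (step in seq_len(K - 1L)) {
    n <- length(u)
    rs <- rowSums(counts)
    P <- counts / ifelse(rs > 0, rs, 1)
    P[rs == 0, ] <- 1 / n
    best <- NULL
    best_cost <- Inf
    # finite-cost pass
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      tt <- P[i, j] + P[j, i]
      if (tt <= 0) next
      cost <- (u[i] + u[j]) / tt
      if (cost < best_cost - 1e-15) {
        best_cost <- cost; best <- c(i, j)
      }
    }
    if (is.null(best)) {
      # only disconnected pairs remain: merge by smallest combined usage
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        cost <- u[i] + u[j]
        if (cost < best_cost - 1e-15) {
          best_cost <- cost; best <- c(i, j)
        }
      }
      merge_cost <- Inf
    } else {
      merge_cost <- best_cost
    }
    i <- best[1L]; j <- best[2L]
    merges[[step]] <- data.frame(step = step, left = ids[i], right = ids[j],
                                 cost = merge_cost, usage = u[i] + u[j])
    # merge j into i: sum counts rows/columns (diagonal collects the
    # within-pair transitions), sum usage
    counts[i, ] <- counts[i, ] + counts[j, ]
    counts[, i] <- counts[, i] + counts[, j]
    counts <- counts[-j, -j, drop = FALSE]
    u[i] <- u[i] + u[j]
    u <- u[-j]
    ids[i] <- next_id
    ids <- ids[-j]
    next_id <- next_id + 1L
  }
  structure(list(K = K, merges = do.call(rbind, merges),
                 root = next_id - 1L),
            class = "motif_tree")
}

#' @export
print.motif_tree <- function(x, ...) {
  cat(sprintf("motif_tree: %d motifs, %d merges, root node %d\n",
              x$K, nrow(x$merges), x$root))
  invisible(x)
}

# leaves under each internal node id
.tree_leaves <- function(tree) {
  children <- list()
  for (s in seq_len(nrow(tree$merges))) {
    node <- tree$K + s - 1L
    children[[as.character(node)]] <-
      c(tree$merges$left[s], tree$merges$right[s])
  }
  leaves_of <- function(node) {
    if (node < tree$K) return(node)
    ch <- children[[as.character(node)]]
    c(leaves_of(ch[1L]), leaves_of(ch[2L]))
  }
  list(children = children, leaves_of = leaves_of)
}

#' Cut the merge tree into communities
#'
#' Undoes the last `n_communities - 1` merges; the leaves of each
#' remaining subtree form one community, mirroring how dendrograms are
#' cut into clusters. Communities are numbered 0-based in order of their
#' smallest motif id.
#'
#' @param tree a [build_tree()] result.
#' @param n_communities number of communities, in `1..K`.
#' @return an object of class `community_assignment`: list with
#'   `community` (integer per motif, 0-based) and `n_communities`.
#' @export
cut_tree <- function(tree, n_communities) {
  K <- tree$K
  if (n_communities < 1L || n_communities > K)
    stop("n_communities must lie in 1..K")
  parent <- seq_len(K) - 1L          # union-find over motif ids
  find <- function(i) { while (parent[i + 1L] != i) i <- parent[i + 1L]; i }
  lv <- .tree_leaves(tree)
  n_apply <- K - n_communities
  for (s in seq_len(n_apply)) {
    l <- tree$merges$left[s]; r <- tree$merges$right[s]
    ll <- min(lv$leaves_of(l)); rr <- min(lv$leaves_of(r))
    a <- find(ll); b <- find(rr)
    parent[max(a, b) + 1L] <- min(a, b)
  }
  roots <- vapply(0:(K - 1L), find, integer(1))
  comm <- match(roots, sort(unique(roots))) - 1L
  structure(list(community = comm,
                 n_communities = as.integer(n_communities)),
            class = "community_assignment")
}

#' @export
print.community_assignment <- function(x, ...) {
  cat(sprintf("community_assignment: %d motifs in %d communities\n",
              length(x$community), x$n_communities))
  for (c in 0:(x$n_communities - 1L))
    cat(sprintf("  community %d: motifs %s\n", c,
                paste(which(x$community == c) - 1L, collapse = ", ")))
  invisible(x)
}

#' Per-motif usage ratio between groups
#'
#' `ratio_k = mean_a(U_k) / mean_b(U_k)`: values above 1 flag motifs
#' upregulated in group a relative to the reference group b. Motifs
#' unused in the reference group yield `NaN` (undefined, flagged with a
#' warning rather than an error).
#'
#' @param usage_a,usage_b usage vectors, or matrices with one row per
#'   animal and one column per motif.
#' @return numeric vector of per-motif ratios.
#' @export
usage_ratio <- function(usage_a, usage_b) {
  ma <- if (is.matrix(usage_a)) colMeans(usage_a) else as.numeric(usage_a)
  mb <- if (is.matrix(usage_b)) colMeans(usage_b) else as.numeric(usage_b)
  if (length(ma) != length(mb)) stop("usage vectors differ in length")
  if (any(mb == 0))
    warning("motif(s) ", paste(which(mb == 0) - 1L, collapse = ", "),
            " unused in the reference group; ratio undefined (NaN)")
  r <- ma / mb
  r[mb == 0] <- NaN
  r
}

#' Community-level label series and transitions
#'
#' Relabels a motif series at the community level and recomputes the
#' transition matrix on the coarse labels.
#'
#' @param labels a [motif_series()].
#' @param assignment a [cut_tree()] result covering all motifs.
#' @param zero_rows passed to [transition_matrix()].
#' @return list with `series` (a community-level [motif_series()]) and
#'   `transition` (community-level [transition_matrix()]).
#' @export
community_series <- function(labels, assignment, zero_rows = "uniform") {
  stopifnot(inherits(labels, "motif_series"),
            inherits(assignment, "community_assignment"))
  if (length(assignment$community) < labels$K)
    stop("assignment does not cover all motifs")
  comm <- assignment$community[labels$labels + 1L]
  if (anyNA(comm)) stop("unassigned motif in label series")
  cs <- motif_series(comm, assignment$n_communities)
  list(series = cs,
       transition = transition_matrix(cs, zero_rows = zero_rows))
}

#' Newick serialization of a motif tree
#'
#' Leaves are named `m<motif id>`; internal node labels carry the merge
#' step. Infinite merge costs (disconnected pairs) are written without a
#' branch length.
#'
#' @param tree a [build_tree()] result.
#' @return a single Newick string (terminated by `;`).
#' @export
as_newick <- function(tree) {
  lv <- .tree_leaves(tree)
  fmt <- function(node) {
    if (node < tree$K) return(paste0("m", node))
    s <- node - tree$K + 1L
    cost <- tree$merges$cost[s]
    lab <- if (is.finite(cost)) sprintf("s%d:%g", s, cost) else
      sprintf("s%d", s)
    ch <- lv$children[[as.character(node)]]
    sprintf("(%s,%s)%s", fmt(ch[1L]), fmt(ch[2L]), lab)
  }
  paste0(fmt(tree$root), ";")
}
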