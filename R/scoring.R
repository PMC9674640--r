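#' Contingency table between two label sequences
#'
#' Frame-count table with one row per reference class and one column per
#' candidate cluster; cell `(u, v)` counts the frames carrying both
#' labels.
#'
#' @param reference,candidate equal-length label vectors (any atomic
#'   type).
#' @return an integer matrix with dimnames set to the label alphabets.
#' @export
contingency <- function(reference, candidate) {
  if (length(reference) != length(candidate))
    stop("label sequences differ in length")
  if (!length(reference)) stop("empty label sequences")
  as.matrix(table(reference, candidate))
}

#' Purity of a clustering against reference labels
#'
#' Conventional (frame-weighted) purity: each candidate cluster is
#' credited with its best-matching reference class,
#' `(1/N) * sum_v max_u |u intersect v|`. The `"inverse"` direction
#' instead sums over reference classes taking the best candidate cluster;
#' the two coincide on symmetric cases but the conventional direction is
#' the one that grows as the candidate partition is refined.
#'
#' @inheritParams contingency
#' @param direction `"conventional"` (default) or `"inverse"`.
#' @return purity in `[0, 1]`.
#' @export
purity <- function(reference, candidate,
                   direction = c("conventional", "inverse")) {
  direction <- match.arg(direction)
  ct <- contingency(reference, candidate)
  n <- sum(ct)
  if (direction == "conventional") sum(apply(ct, 2L, max)) / n
  else sum(apply(ct, 1L, max)) / n
}

#' Shannon entropy of a label sequence
#'
#' `-sum p log p` over class frame fractions, natural log, with
#' `0 log 0 = 0`.
#'
#' @param labels a label vector.
#' @return non-negative entropy in nats.
#' @export
entropy <- function(labels) {
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Mutual information between two label sequences
#'
#' `sum_{u,v} (n_uv/N) log(N n_uv / (n_u n_v))` over the contingency
#' table; empty cells contribute zero. Natural log.
#'
#' @inheritParams contingency
#' @return non-negative mutual information in nats.
#' @export
mutual_information <- function(reference, candidate) {
  ct <- contingency(reference, candidate)
  n <- sum(ct)
  ru <- rowSums(ct); cv <- colSums(ct)
  mi <- 0
  for (i in seq_along(ru)) for (j in seq_along(cv)) {
    if (ct[i, j] > 0)
      mi <- mi + ct[i, j] / n * log(n * ct[i, j] / (ru[i] * cv[j]))
  }
  max(mi, 0)
}

#' Normalized mutual information
#'
#' Mutual information normalized by the arithmetic mean of the two
#' entropies; defined as 0 when either sequence is constant (the 0/0
#' convention).
#'
#' @inheritParams contingency
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(reference, candidate) {
  hu <- entropy(reference); hv <- entropy(candidate)
  denom <- (hu + hv) / 2
  if (denom == 0) return(0)
  mi <- mutual_information(reference, candidate)
  min(mi / denom, 1)
}

#' Homogeneity of a clustering
#'
#' `1 - H(U|V) / H(U)`: 1 when every candidate cluster contains members
#' of a single reference class, 0 when clustering carries no information
#' about the reference; 1 by convention when the reference is constant.
#'
#' @inheritParams contingency
#' @return homogeneity in `[0, 1]`.
#' @export
homogeneity <- function(reference, candidate) {
  hu <- entropy(reference)
  if (hu == 0) return(1)
  ct <- contingency(reference, candidate)
  n <- sum(ct)
  cv <- colSums(ct)
  hcond <- 0
  for (j in seq_along(cv)) for (i in seq_len(nrow(ct))) {
    if (ct[i, j] > 0)
      hcond <- hcond - ct[i, j] / n * log(ct[i, j] / cv[j])
  }
  unname(1 - hcond / hu)
}

#' Score a candidate segmentation against reference labels
#'
#' Bundles the three clustering-agreement measures and the contingency
#' table into one report.
#'
#' @inheritParams contingency
#' @return an object of class `score_report`: list with `purity`, `nmi`,
#'   `homogeneity`, `contingency`, `n`.
#' @export
score_report <- function(reference, candidate) {
  structure(list(purity = purity(reference, candidate),
                 nmi = nmi(reference, candidate),
                 homogeneity = homogeneity(reference, candidate),
                 contingency = contingency(reference, candidate),
                 n = length(reference)),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("score_report (%d frames): purity %.4f, NMI %.4f, homogeneity %.4f\n",
              x$n, x$purity, x$nmi, x$homogeneity))
  invisible(x)
}

#' Map atomic labels to coarse labels
#'
#' Relabels a sequence through a total mapping table, e.g. collapsing
#' fine-grained annotated behaviors (walk-and-sniff, wall-rear, ...) into
#' coarse classes (walk, rear, ...). Mapping composition commutes with
#' application.
#'
#' @param labels a label vector.
#' @param mapping a named vector (`names` = atomic labels, values =
#'   coarse labels) or a two-column data frame `(from, to)`.
#' @return the relabeled vector.
#' @export
map_labels <- function(labels, mapping) {
  if (is.data.frame(mapping)) {
    mp <- as.character(mapping[[2L]])
    names(mp) <- as.character(mapping[[1L]])
  } else {
    mp <- mapping
  }
  key <- as.character(labels)
  missing <- setdiff(unique(key), names(mp))
  if (length(missing))
    stop("unmapped label(s): ", paste(missing, collapse = ", "))
  unname(mp[key])
}

#' Annotator agreement per model motif
#'
#' Classifies every frame by agreement across two or more annotators
#' (`full`: all identical; `none`: all pairwise distinct; `partial`:
#' anything in between) and reports, per model motif, the fraction of its
#' frames with full annotator agreement. Motifs absent from the scored
#' segment are reported with `NA` fractions (empty columns).
#'
#' @param model_labels the model's motif labels (vector or
#'   [motif_series()]).
#' @param annotations list of two or more equal-length annotator label
#'   vectors.
#' @param K number of model motifs (defaults to the series' K or
#'   `max + 1`).
#' @return list with `frame_class` (factor full/partial/none per frame),
#'   `summary` (named fractions summing to 1) and `per_motif` (data frame
#'   with `motif`, `n_frames`, `full_agreement`).
#' @export
agreement_per_motif <- function(model_labels, annotations, K = NULL) {
  if (inherits(model_labels, "motif_series")) {
    if (is.null(K)) K <- model_labels$K
    model_labels <- model_labels$labels
  }
  if (length(annotations) < 2L) stop("need at least two annotators")
  n <- length(model_labels)
  if (any(vapply(annotations, length, integer(1)) != n))
    stop("annotator label lengths do not match the model labels")
  if (is.null(K)) K <- max(model_labels) + 1L
  A <- do.call(cbind, lapply(annotations, as.character))
  n_distinct <- apply(A, 1L, function(r) length(unique(r)))
  cls <- ifelse(n_distinct == 1L, "full",
                ifelse(n_distinct == ncol(A), "none", "partial"))
  # with two annotators "all pairwise distinct" and "not all equal"
  # coincide; everything disagreeing is "none"
  frame_class <- factor(cls, levels = c("full", "partial", "none"))
  summary <- table(frame_class) / n
  per <- data.frame(motif = 0:(K - 1L), n_frames = 0L,
                    full_agreement = NA_real_)
  for (k in 0:(K - 1L)) {
    idx <- model_labels == k
    per$n_frames[k + 1L] <- sum(idx)
    if (any(idx))
      per$full_agreement[k + 1L] <- mean(frame_class[idx] == "full")
  }
  list(frame_class = frame_class,
       summary = c(full = unname(summary["full"]),
                   partial = unname(summary["partial"]),
                   none = unname(summary["none"])),
       per_motif = per)
}
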