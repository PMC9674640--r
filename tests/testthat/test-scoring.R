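random_pair <- function(n = 200L, ku = 4L, kv = 6L) {
  list(u = sample.int(ku, n, replace = TRUE) - 1L,
       v = sample.int(kv, n, replace = TRUE) - 1L)
}

test_that("contingency tables count joint label frequencies", {
  ct <- contingency(c(0, 0, 1), c(0, 0, 1))
  expect_equal(unname(as.matrix(ct)), matrix(c(2L, 0L, 0L, 1L), 2))
  set.seed(1)
  p <- random_pair()
  ct <- contingency(p$u, p$v)
  expect_equal(sum(ct), 200L)
  expect_equal(unname(ct), unname(oracle_contingency(p$u, p$v)))
  expect_error(contingency(1:3, 1:4), "length")
  expect_error(contingency(integer(), integer()), "empty")
})

test_that("purity behaves on closed-form cases and both directions", {
  expect_equal(purity(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  # one model cluster: purity equals the majority class fraction
  u <- c(rep(0, 7), rep(1, 3))
  expect_equal(purity(u, rep(0, 10)), 0.7)
  # paper-literal (inverse) direction sums over reference classes
  expect_equal(purity(u, rep(0, 10), direction = "inverse"), 1)
  set.seed(2)
  p <- random_pair()
  expect_equal(purity(p$u, p$v), oracle_purity(p$u, p$v),
               tolerance = 1e-14)
})

test_that("purity never decreases when the candidate partition is refined", {
  set.seed(3)
  for (rep in 1:10) {
    p <- random_pair(300L, 3L, 4L)
    base <- purity(p$u, p$v)
    v2 <- p$v
    split <- p$v == 0L
    v2[split] <- ifelse(seq_along(v2)[split] %% 2 == 0, 0L, 9L)
    expect_gte(purity(p$u, v2) + 1e-12, base)
  }
})

test_that("entropy matches closed forms", {
  expect_equal(entropy(rep(1, 10)), 0)
  expect_equal(entropy(rep(c(0, 1), 10)), log(2))
  set.seed(4)
  u <- sample.int(5, 100, replace = TRUE)
  expect_equal(entropy(u), oracle_entropy(u), tolerance = 1e-14)
})

test_that("mutual information: identity, independence and hand example", {
  u <- c(rep(0, 50), rep(1, 50))
  expect_equal(mutual_information(u, u), entropy(u), tolerance = 1e-12)
  set.seed(5)
  a <- sample.int(2, 20000, replace = TRUE)
  b <- sample.int(2, 20000, replace = TRUE)
  expect_lt(mutual_information(a, b), 0.001)  # independent, near zero
  # hand 2x2: perfectly dependent halves
  u <- c(0, 0, 1, 1); v <- c(1, 1, 0, 0)
  expect_equal(mutual_information(u, v), log(2), tolerance = 1e-12)
})

test_that("NMI is normalized, symmetric in degenerate cases", {
  u <- c(0, 0, 1, 1, 2, 2)
  expect_equal(nmi(u, u), 1)
  expect_equal(nmi(u, rep(0, 6)), 0)
  expect_equal(nmi(rep(0, 6), u), 0)
  expect_equal(nmi(rep(0, 6), rep(1, 6)), 0)
  set.seed(6)
  p <- random_pair()
  expect_equal(nmi(p$u, p$v), oracle_nmi(p$u, p$v), tolerance = 1e-12)
})

test_that("homogeneity is 1 iff clusters are pure", {
  u <- c(0, 0, 1, 1)
  expect_equal(homogeneity(u, c(0, 0, 1, 1)), 1)
  expect_equal(homogeneity(u, c(0, 1, 2, 3)), 1)   # refinement stays pure
  expect_equal(homogeneity(u, rep(0, 4)), 0)
  expect_equal(homogeneity(rep(0, 4), c(0, 1, 0, 1)), 1)  # constant reference
  set.seed(7)
  p <- random_pair()
  expect_equal(homogeneity(p$u, p$v), oracle_homogeneity(p$u, p$v),
               tolerance = 1e-12)
})

test_that("all scores are invariant under relabeling permutations", {
  set.seed(8)
  p <- random_pair(150L, 3L, 3L)
  perm_u <- c(2L, 0L, 1L)[p$u + 1L]
  perm_v <- c(1L, 2L, 0L)[p$v + 1L]
  for (f in list(purity, nmi, homogeneity, mutual_information)) {
    expect_equal(f(p$u, p$v), f(perm_u, perm_v), tolerance = 1e-12)
  }
})

test_that("label mapping is total, composable and validated", {
  labs <- c("walk", "walk_sniff", "rear", "groom")
  mp <- c(walk = "Walk", walk_sniff = "Walk", rear = "Rear", groom = "Groom")
  expect_equal(map_labels(labs, mp), c("Walk", "Walk", "Rear", "Groom"))
  ident <- setNames(labs, labs)
  expect_equal(map_labels(labs, ident), labs)
  # composition of mappings equals mapping of the composition
  mp2 <- c(Walk = "Active", Rear = "Active", Groom = "Maintenance")
  expect_equal(map_labels(map_labels(labs, mp), mp2),
               map_labels(labs, setNames(mp2[mp], names(mp))))
  expect_error(map_labels(c("walk", "dig"), mp), "dig")
  # data frame interface and alphabet reduction
  set.seed(9)
  atomic <- sample(0:9, 500, replace = TRUE)
  tab <- data.frame(from = 0:9, to = rep(0:4, each = 2))
  coarse <- map_labels(atomic, tab)
  expect_equal(sort(unique(coarse)), as.character(0:4))
})

test_that("annotator agreement is classified per frame and per motif", {
  ann <- list(rep(0, 10), rep(0, 10), rep(0, 10))
  res <- agreement_per_motif(rep(0L, 10), ann)
  expect_equal(unname(res$summary["full"]), 1)
  expect_equal(res$per_motif$full_agreement, 1)

  # constructed 10-frame example: 6 unanimous, 3 two-way, 1 all-distinct
  a1 <- c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1)
  a2 <- c(1, 1, 1, 1, 1, 1, 2, 2, 2, 2)
  a3 <- c(1, 1, 1, 1, 1, 1, 2, 2, 2, 3)
  model <- c(rep(0L, 5L), rep(1L, 5L))
  res <- agreement_per_motif(model, list(a1, a2, a3))
  expect_equal(unname(res$summary["full"]), 0.6)
  expect_equal(unname(res$summary["partial"]), 0.3)
  expect_equal(unname(res$summary["none"]), 0.1)
  expect_equal(sum(res$summary), 1)
  expect_equal(res$per_motif$full_agreement, c(1, 0.2))

  # absent motifs are reported as empty columns
  res <- agreement_per_motif(rep(0L, 10), list(a1, a2), K = 3L)
  expect_true(is.na(res$per_motif$full_agreement[3]))
  expect_error(agreement_per_motif(model, list(a1)), "two annotators")
  expect_error(agreement_per_motif(model, list(a1, a2[1:5])), "length")
})

test_that("score reports bundle the three measures consistently", {
  set.seed(10)
  p <- random_pair()
  rep <- score_report(p$u, p$v)
  expect_equal(rep$purity, purity(p$u, p$v))
  expect_equal(rep$nmi, nmi(p$u, p$v))
  expect_equal(rep$homogeneity, homogeneity(p$u, p$v))
  expect_equal(sum(rep$contingency), rep$n)
})
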