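raw_from_values <- function(values) {
  structure(list(values = values, mask = is.na(values), markers = NULL),
            class = "raw_series")
}

test_that("egocentric alignment centers, rotates and drops constant columns", {
  # front=(1,0), back=(-1,0), third marker (0,1): already aligned
  vals <- matrix(c(1, 0, -1, 0, 0, 1), 1, 6)
  s <- egocentric_align(raw_from_values(vals), 1L, 2L)
  expect_equal(ncol(s$values), 4L)
  expect_equal(unname(s$values[1, ]), c(1, -1, 0, 1), tolerance = 1e-12)

  # identity case over many frames: output equals input minus dropped cols
  set.seed(1)
  n <- 50L
  third <- cbind(rnorm(n), rnorm(n))
  vals <- cbind(2, 0, -2, 0, third)
  s <- egocentric_align(raw_from_values(vals), 1L, 2L)
  expect_equal(unname(s$values), unname(cbind(2, -2, third)),
               tolerance = 1e-12)
})

test_that("alignment is equivariant under global rigid transforms", {
  ds <- make_pose_fixture(150L, seed = 21L)
  rs <- confidence_mask(ds$track, 0.9)
  base <- egocentric_align(rs, 1L, 4L)
  ang <- 37 * pi / 180
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  moved <- rs
  for (j in seq_len(4L)) {
    xy <- cbind(rs$values[, 2 * j - 1], rs$values[, 2 * j]) %*% t(R)
    moved$values[, 2 * j - 1] <- xy[, 1] + 5
    moved$values[, 2 * j] <- xy[, 2] - 3
  }
  out <- egocentric_align(moved, 1L, 4L)
  expect_lt(max(abs(out$values - base$values)), 1e-9)
})

test_that("alignment validates anchors and masks degenerate frames", {
  vals <- matrix(rnorm(12), 2, 6)
  expect_error(egocentric_align(raw_from_values(vals), 2L, 2L), "differ")
  vals[1, 1:4] <- c(1, 1, 1, 1)   # coincident anchors in frame 1
  expect_warning(s <- egocentric_align(raw_from_values(vals), 1L, 2L),
                 "coincident")
  expect_true(all(is.nan(s$values[1, ])))
  expect_false(anyNA(s$values[2, ]))
})

test_that("IQR rule masks exactly the injected outliers", {
  set.seed(4)
  x <- rnorm(500)
  x[c(50, 200, 400)] <- c(50, -50, 50)
  s <- iqr_clean(marker_series(cbind(x, rnorm(500))), iqr_factor = 4)
  expect_equal(which(is.nan(s$values[, 1])), c(50L, 200L, 400L))
  expect_equal(sum(is.nan(s$values[, 2])), 0L)
})

test_that("IQR rule edge cases: constant feature, huge factor, bad factor", {
  s <- marker_series(cbind(rep(1, 10), rnorm(10)))
  expect_equal(sum(is.nan(iqr_clean(s, 4)$values[, 1])), 0L)
  expect_equal(sum(is.nan(iqr_clean(s, 1e12)$values)), 0L)
  expect_error(iqr_clean(s, -1), "positive")
  expect_error(iqr_clean(marker_series(matrix(1, 2, 1)), 4), "4 frames")
})

test_that("linear interpolation fills interior and edge gaps", {
  s <- marker_series(matrix(c(1, NaN, 3), 3, 1))
  expect_equal(interpolate_nan(s)$values[, 1], c(1, 2, 3))
  s <- marker_series(matrix(c(NaN, 5, 5, NaN), 4, 1))
  expect_equal(interpolate_nan(s)$values[, 1], rep(5, 4))

  # random mask on a linear ramp is recovered exactly
  set.seed(8)
  ramp <- seq(0, 10, length.out = 200)
  masked <- ramp
  masked[sample(2:199, 60)] <- NaN
  out <- interpolate_nan(marker_series(matrix(masked, ncol = 1)))
  expect_lt(max(abs(out$values[, 1] - ramp)), 1e-12)

  expect_error(interpolate_nan(marker_series(matrix(NaN, 5, 1))),
               "fully masked")
})

test_that("Savitzky-Golay reproduces polynomials and damps noise", {
  t <- seq(-1, 1, length.out = 101)
  cubic <- 2 + t - 3 * t^2 + 0.5 * t^3
  sm <- savgol_smooth(marker_series(matrix(cubic, ncol = 1)), 7L, 3L)
  expect_lt(max(abs(sm$values[, 1] - cubic)), 1e-10)

  const <- marker_series(matrix(5, 50, 1))
  expect_equal(savgol_smooth(const, 5L, 2L)$values[, 1], rep(5, 50))

  set.seed(2)
  noise <- matrix(rnorm(500), ncol = 1)
  sm <- savgol_smooth(marker_series(noise), 15L, 2L)
  expect_lt(var(sm$values[, 1]), var(noise[, 1]))

  expect_error(savgol_smooth(const, 4L, 2L), "odd")
  expect_error(savgol_smooth(const, 5L, 5L), "order")
})

test_that("z-scoring is exact, invertible and scale-invariant", {
  set.seed(3)
  v <- matrix(rnorm(200, 5, 3), 50, 4)
  s <- zscore(marker_series(v))
  expect_lt(max(abs(colMeans(s$values))), 1e-10)
  expect_lt(max(abs(apply(s$values, 2, sd) - 1)), 1e-10)
  expect_lt(max(abs(inverse_zscore(s$values, s$scale_stats) - v)), 1e-10)
  s2 <- zscore(marker_series(2 * v))
  expect_equal(s2$values, s$values, tolerance = 1e-12)
  expect_error(zscore(marker_series(cbind(v, 1))), "zero-variance")
})

test_that("train/test split holds out a contiguous tail block", {
  s <- marker_series(matrix(seq_len(1000), 1000, 1))
  sp <- split_train_test(s, 0.1)
  expect_equal(nrow(sp$test[[1]]$values), 100L)
  expect_equal(nrow(sp$train[[1]]$values), 900L)
  expect_equal(c(sp$train[[1]]$values, sp$test[[1]]$values),
               as.numeric(1:1000))   # disjoint partition, order kept
  sp <- split_train_test(marker_series(matrix(1:3, 3, 1)), 0.5)
  expect_equal(nrow(sp$train[[1]]$values), 2L)
  expect_error(split_train_test(s, 0), "strictly between")
  expect_error(split_train_test(marker_series(matrix(1:5, 5, 1)), 0.1),
               "empty split")
})

test_that("window sampling respects bounds, futures and determinism", {
  s <- marker_series(matrix(seq_len(300), 100, 3))
  b <- sample_windows(s, w = 30L, v = 15L, n_samples = 500L, seed = 1L)
  expect_true(all(b$origin$start >= 0L & b$origin$start <= 55L))
  expect_true(any(b$origin$start == 55L))  # the last feasible start is drawn
  # futures are the frames immediately after each window
  k <- 17L
  st <- b$origin$start[k] + 1L
  expect_equal(b$inputs[, , k], t(s$values[st:(st + 29L), ]))
  expect_equal(b$futures[, , k], t(s$values[(st + 30L):(st + 44L), ]))

  b2 <- sample_windows(s, 30L, 15L, 500L, seed = 1L)
  expect_identical(b$inputs, b2$inputs)

  s45 <- marker_series(matrix(rnorm(45), 45, 1))
  b1 <- sample_windows(s45, 30L, 15L, 1L, seed = 5L)
  expect_equal(b1$origin$start, 0L)
  expect_error(sample_windows(marker_series(matrix(1:10, 10, 1)),
                              30L, 15L, 1L), "shorter")
})

test_that("the full preprocessing chain preserves N and m", {
  ds <- make_pose_fixture(300L, seed = 13L, dropout = 0.02)
  s <- preprocess_series(confidence_mask(ds$track, 0.9), 1L, 4L)
  expect_equal(dim(s$values), c(300L, 6L))
  expect_false(anyNA(s$values))
  expect_false(is.null(s$scale_stats))
})
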