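#' Egocentric marker series container
#'
#' An N x m real matrix of egocentrically aligned marker coordinates
#' (features are x/y coordinates per marker, minus the coordinates rendered
#' constant by the alignment), together with optional frame-rate metadata
#' and the z-scoring statistics once [zscore()] has been applied.
#'
#' @param values numeric N x m matrix.
#' @param frame_rate frames per second (metadata only).
#' @param scale_stats list with `mean` and `sd` per feature, set by
#'   [zscore()].
#' @return an object of class `marker_series`.
#' @export
marker_series <- function(values, frame_rate = NULL, scale_stats = NULL) {
  values <- as.matrix(values)
  structure(list(values = values, frame_rate = frame_rate,
                 scale_stats = scale_stats),
            class = "marker_series")
}

#' @export
print.marker_series <- function(x, ...) {
  cat(sprintf("marker_series: %d frames x %d features%s%s\n",
              nrow(x$values), ncol(x$values),
              if (!is.null(x$frame_rate))
                sprintf(", %g fps", x$frame_rate) else "",
              if (!is.null(x$scale_stats)) ", z-scored" else ""))
  invisible(x)
}

#' @export
dim.marker_series <- function(x) dim(x$values)

#' Egocentric alignment about the body axis
#'
#' Translates every frame so that the midpoint between the two anchor
#' markers (e.g. nose and tailbase) is the origin, then rotates it so that
#' the back-to-front body axis lies along +x (animal oriented left to
#' right). The anchor coordinates that become exactly constant under this
#' transform carry no behavioral information and are dropped: under a pure
#' rotation these are the two coordinates perpendicular to the body axis
#' (`drop = "perpendicular"`, the default, which is what the geometry
#' dictates); `drop = "axis"` instead drops the along-axis anchor
#' coordinates for compatibility with conventions that treat those as the
#' fixed ones. For 6 markers this reduces 12 coordinates to 10.
#'
#' Frames in which either anchor is masked (or the anchors coincide) yield
#' fully masked rows, to be linearly interpolated downstream.
#'
#' @param raw a `raw_series` from [confidence_mask()] / [csv_to_series()].
#' @param anchor_front,anchor_back 1-based marker indices of the front
#'   (nose) and back (tailbase) anchors.
#' @param drop which constant anchor coordinates to remove.
#' @param frame_rate optional frames/second carried into the result.
#' @return a [marker_series()] with `m = 2 * n_markers - 2` features.
#' @export
egocentric_align <- function(raw, anchor_front, anchor_back,
                             drop = c("perpendicular", "axis"),
                             frame_rate = NULL) {
  drop <- match.arg(drop)
  values <- raw$values
  n <- nrow(values); m2 <- ncol(values); m <- m2 %/% 2L
  if (n < 1L) stop("empty series")
  if (anchor_front == anchor_back)
    stop("anchor_front and anchor_back must differ")
  stopifnot(anchor_front >= 1L, anchor_front <= m,
            anchor_back >= 1L, anchor_back <= m)
  xi <- seq(1L, by = 2L, length.out = m)
  fx <- values[, xi[anchor_front]]; fy <- values[, xi[anchor_front] + 1L]
  bx <- values[, xi[anchor_back]];  by <- values[, xi[anchor_back] + 1L]
  if (all(is.na(fx)) || all(is.na(bx)))
    stop("an anchor marker is never tracked")
  midx <- (fx + bx) / 2; midy <- (fy + by) / 2
  dx <- fx - bx; dy <- fy - by
  degen <- !is.na(dx) & !is.na(dy) & dx == 0 & dy == 0
  if (any(degen))
    warning(sum(degen), " frame(s) with coincident anchors masked")
  ang <- atan2(dy, dx)
  ca <- cos(ang); sa <- sin(ang)
  out <- matrix(NaN, n, m2)
  for (j in seq_len(m)) {
    rx <- values[, xi[j]] - midx
    ry <- values[, xi[j] + 1L] - midy
    out[, xi[j]]      <-  ca * rx + sa * ry
    out[, xi[j] + 1L] <- -sa * rx + ca * ry
  }
  bad <- is.na(fx) | is.na(fy) | is.na(bx) | is.na(by) | degen
  out[bad, ] <- NaN
  drop_cols <- if (drop == "perpendicular") {
    c(xi[anchor_front] + 1L, xi[anchor_back] + 1L)   # y of both anchors == 0
  } else {
    c(xi[anchor_front], xi[anchor_back])
  }
  keep <- setdiff(seq_len(m2), drop_cols)
  vals <- out[, keep, drop = FALSE]
  if (!is.null(colnames(values))) colnames(vals) <- colnames(values)[keep]
  marker_series(vals, frame_rate = frame_rate)
}

#' Robust outlier removal by the interquartile-range rule
#'
#' Per feature, values outside `median +/- iqr_factor * IQR` are set to
#' `NaN` (to be interpolated). Features with zero IQR (constant signals)
#' are left untouched.
#'
#' @param series a [marker_series()].
#' @param iqr_factor positive multiplier of the IQR (default 4).
#' @return the cleaned [marker_series()].
#' @export
iqr_clean <- function(series, iqr_factor = 4) {
  if (!is.numeric(iqr_factor) || iqr_factor <= 0)
    stop("iqr_factor must be positive")
  v <- series$values
  if (nrow(v) < 4L) stop("need at least 4 frames for quartiles")
  for (j in seq_len(ncol(v))) {
    q <- stats::quantile(v[, j], c(0.25, 0.5, 0.75), na.rm = TRUE,
                         names = FALSE)
    iqr <- q[3L] - q[1L]
    if (!is.finite(iqr) || iqr == 0) next
    out <- !is.na(v[, j]) & abs(v[, j] - q[2L]) > iqr_factor * iqr
    v[out, j] <- NaN
  }
  series$values <- v
  series
}

#' Linear interpolation of masked cells
#'
#' Replaces `NaN` cells feature-by-feature with linear interpolation
#' between the nearest observed values; leading and trailing runs are
#' filled with the nearest observed value.
#'
#' @param series a [marker_series()].
#' @return a [marker_series()] with no masked cells.
#' @export
interpolate_nan <- function(series) {
  v <- series$values
  n <- nrow(v)
  for (j in seq_len(ncol(v))) {
    known <- which(!is.na(v[, j]))
    if (length(known) == 0L)
      stop("feature ", j,
           if (!is.null(colnames(v))) paste0(" (", colnames(v)[j], ")") else "",
           " is fully masked and cannot be interpolated")
    if (length(known) == n) next
    if (length(known) == 1L) {
      v[, j] <- v[known, j]
    } else {
      v[, j] <- stats::approx(known, v[known, j], xout = seq_len(n),
                              rule = 2)$y
    }
  }
  series$values <- v
  series
}

#' Savitzky-Golay smoothing
#'
#' Applies a Savitzky-Golay filter (local least-squares polynomial fit)
#' of the given window length and polynomial order to every feature.
#'
#' @param series a [marker_series()] without masked cells.
#' @param length odd filter window length (frames), default 5.
#' @param order polynomial order `< length`, default 2.
#' @return the smoothed [marker_series()].
#' @export
savgol_smooth <- function(series, length = 5L, order = 2L) {
  if (length %% 2L == 0L) stop("savgol_length must be odd")
  if (order < 0L || order >= length)
    stop("savgol_order must be non-negative and smaller than savgol_length")
  v <- series$values
  if (length > nrow(v)) stop("filter length exceeds series length")
  if (anyNA(v)) stop("series contains masked cells; interpolate first")
  series$values <- apply(v, 2L, signal::sgolayfilt, p = order, n = length)
  series
}

#' Z-score a marker series
#'
#' Centers and scales every feature to mean 0 and standard deviation 1,
#' recording the statistics in `scale_stats` so results can be mapped back
#' to pixel units with [inverse_zscore()]. Scaling the whole dataset to a
#' common scale is what makes embeddings comparable across animals.
#'
#' @param series a [marker_series()].
#' @return the z-scored [marker_series()] with `scale_stats` set.
#' @export
zscore <- function(series) {
  v <- series$values
  mu <- colMeans(v)
  sd <- apply(v, 2L, stats::sd)
  if (any(!is.finite(sd)) || any(sd == 0))
    stop("zero-variance feature(s): ",
         paste(which(!is.finite(sd) | sd == 0), collapse = ", "))
  series$values <- sweep(sweep(v, 2L, mu), 2L, sd, "/")
  series$scale_stats <- list(mean = mu, sd = sd)
  series
}

#' @rdname zscore
#' @param values numeric matrix in z-units.
#' @param scale_stats the `scale_stats` recorded by [zscore()].
#' @export
inverse_zscore <- function(values, scale_stats) {
  sweep(sweep(values, 2L, scale_stats$sd, "*"), 2L, scale_stats$mean, "+")
}

#' Train/test split by contiguous tail block
#'
#' Holds out the final `floor(test_fraction * N)` frames of every series as
#' the test set. A contiguous block (rather than random frames) keeps
#' trajectory windows from straddling the split.
#'
#' @param series a [marker_series()] or list of them.
#' @param test_fraction fraction of frames held out, in (0, 1); default 0.1.
#' @return list with elements `train` and `test`, each a list of
#'   [marker_series()].
#' @export
split_train_test <- function(series, test_fraction = 0.1) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie strictly between 0 and 1")
  if (inherits(series, "marker_series")) series <- list(series)
  out <- lapply(series, function(s) {
    n <- nrow(s$values)
    n_test <- floor(test_fraction * n)
    if (n_test < 1L || n_test >= n)
      stop("test_fraction ", test_fraction, " yields an empty split for a ",
           n, "-frame series")
    tr <- s; te <- s
    tr$values <- s$values[seq_len(n - n_test), , drop = FALSE]
    te$values <- s$values[(n - n_test + 1L):n, , drop = FALSE]
    list(train = tr, test = te)
  })
  list(train = lapply(out, `[[`, "train"), test = lapply(out, `[[`, "test"))
}

#' Sample trajectory windows and their futures
#'
#' Draws `n_samples` window start positions uniformly with replacement
#' (across and within series) such that both the `w`-frame input window and
#' the `v` frames immediately following it fit inside the source series.
#'
#' @param series a [marker_series()] or list of them.
#' @param w input window length (frames), default 30.
#' @param v prediction window length (frames), default 15.
#' @param n_samples number of windows to draw.
#' @param seed RNG seed (default 42).
#' @return a `window_batch`: list with `inputs` (m x w x n array),
#'   `futures` (m x v x n array) and `origin` (data frame with 1-based
#'   `series` id and 0-based `start` frame per window).
#' @export
sample_windows <- function(series, w = 30L, v = 15L, n_samples, seed = 42L) {
  if (inherits(series, "marker_series")) series <- list(series)
  stopifnot(n_samples >= 1L)
  lens <- vapply(series, function(s) nrow(s$values), integer(1))
  short <- which(lens < w + v)
  if (length(short))
    stop("series ", paste(short, collapse = ", "),
         " shorter than w + v = ", w + v, " frames")
  m <- ncol(series[[1L]]$values)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  sid <- sample.int(length(series), n_samples, replace = TRUE)
  starts <- vapply(sid, function(i) {
    sample.int(lens[i] - w - v + 1L, 1L)
  }, integer(1))
  inputs <- array(NA_real_, c(m, w, n_samples))
  futures <- array(NA_real_, c(m, v, n_samples))
  for (k in seq_len(n_samples)) {
    s <- series[[sid[k]]]$values
    inputs[, , k] <- t(s[starts[k]:(starts[k] + w - 1L), , drop = FALSE])
    futures[, , k] <- t(s[(starts[k] + w):(starts[k] + w + v - 1L),
                          , drop = FALSE])
  }
  structure(list(inputs = inputs, futures = futures,
                 origin = data.frame(series = sid, start = starts - 1L)),
            class = "window_batch")
}

#' @export
print.window_batch <- function(x, ...) {
  d <- dim(x$inputs)
  cat(sprintf("window_batch: %d windows of %d features x %d frames (+%d future)\n",
              d[3L], d[1L], d[2L], dim(x$futures)[2L]))
  invisible(x)
}

#' Full preprocessing chain
#'
#' Convenience wrapper running the fixed pipeline order: confidence mask
#' (already applied in `raw`) -> egocentric alignment (skipped when
#' `egocentric_data = TRUE`) -> IQR outlier masking -> linear interpolation
#' -> Savitzky-Golay smoothing -> z-scoring.
#'
#' @param raw a `raw_series`.
#' @param anchor_front,anchor_back anchor marker indices (ignored when
#'   `egocentric_data = TRUE`).
#' @param egocentric_data if `TRUE` the data is egocentric by design and no
#'   alignment is performed.
#' @param robust apply the IQR rule (default `TRUE`).
#' @param iqr_factor IQR multiplier (default 4).
#' @param savgol_filter apply Savitzky-Golay smoothing (default `TRUE`).
#' @param savgol_length,savgol_order filter parameters (defaults 5, 2).
#' @param scale z-score at the end (default `TRUE`).
#' @param frame_rate optional frames/second metadata.
#' @return a cleaned [marker_series()].
#' @export
preprocess_series <- function(raw, anchor_front = 1L, anchor_back = 2L,
                              egocentric_data = FALSE, robust = TRUE,
                              iqr_factor = 4, savgol_filter = TRUE,
                              savgol_length = 5L, savgol_order = 2L,
                              scale = TRUE, frame_rate = NULL) {
  s <- if (egocentric_data) {
    marker_series(raw$values, frame_rate = frame_rate)
  } else {
    egocentric_align(raw, anchor_front, anchor_back, frame_rate = frame_rate)
  }
  if (robust) s <- iqr_clean(s, iqr_factor)
  s <- interpolate_nan(s)
  if (savgol_filter) s <- savgol_smooth(s, savgol_length, savgol_order)
  if (scale) s <- zscore(s)
  s
}
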