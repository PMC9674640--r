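#' Pose track container
#'
#' Holds per-frame allocentric marker coordinates and pose-estimation
#' likelihoods as read from a marker CSV. Frames are indexed 0-based to match
#' the video frame convention of pose-estimation tools.
#'
#' @param x,y numeric N x M matrices of marker coordinates (pixels).
#' @param likelihood numeric N x M matrix of per-marker confidences in
#'   `[0, 1]`, or `NA` where the source file carries none.
#' @param markers character vector of M marker names (file-header order).
#' @param frame_index integer vector of 0-based frame indices.
#' @return an object of class `pose_track`.
#' @export
pose_track <- function(x, y, likelihood = NULL, markers = NULL,
                       frame_index = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(all(dim(x) == dim(y)))
  n <- nrow(x); m <- ncol(x)
  if (is.null(likelihood)) likelihood <- matrix(NA_real_, n, m)
  likelihood <- as.matrix(likelihood)
  stopifnot(all(dim(likelihood) == dim(x)))
  bad <- likelihood[!is.na(likelihood)]
  if (any(bad < 0 | bad > 1))
    stop("likelihood values must lie in [0, 1]")
  if (is.null(markers)) markers <- paste0("marker", seq_len(m))
  if (is.null(frame_index)) frame_index <- seq_len(n) - 1L
  structure(list(x = x, y = y, likelihood = likelihood,
                 markers = as.character(markers),
                 frame_index = as.integer(frame_index)),
            class = "pose_track")
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("pose_track: %d frames, %d markers (%s)\n",
              nrow(x$x), length(x$markers),
              paste(x$markers, collapse = ", ")))
  invisible(x)
}

#' @export
dim.pose_track <- function(x) c(nrow(x$x), length(x$markers))

#' Read a pose-estimation marker CSV
#'
#' Supports the DeepLabCut-style export with three header rows
#' (scorer / bodyparts / coords) and a leading frame-index column, where each
#' body part contributes an `(x, y, likelihood)` column triplet, and a plain
#' dialect with a single header row of `(x, y)` column pairs and no
#' likelihoods.
#'
#' @param path CSV file path.
#' @param dialect `"dlc"` (three header rows) or `"plain"`.
#' @return a [pose_track()].
#' @export
read_pose_csv <- function(path, dialect = c("dlc", "plain")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = ",", blank.lines.skip = FALSE)
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1L)
    stop("ragged CSV: row ", which(nf != nf[1L])[1L],
         " has ", nf[which(nf != nf[1L])[1L]], " fields, expected ", nf[1L])
  if (dialect == "dlc") {
    raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
    if (nrow(raw) < 3L)
      stop("malformed DLC header: need scorer/bodyparts/coords rows")
    coords_row <- tolower(unlist(raw[3L, -1L], use.names = FALSE))
    if (nrow(raw) >= 3L && !all(coords_row %in% c("x", "y", "likelihood")))
      stop("malformed DLC header: third row must name x/y/likelihood coords")
    if ((ncol(raw) - 1L) %% 3L != 0L)
      stop("malformed DLC header: columns after the index must come in ",
           "(x, y, likelihood) triplets")
    if (nrow(raw) == 3L) stop("parse error: empty data section")
    bodyparts <- unlist(raw[2L, -1L], use.names = FALSE)
    markers <- bodyparts[seq(1L, length(bodyparts), by = 3L)]
    dat <- raw[-(1:3), , drop = FALSE]
    num <- suppressWarnings(
      matrix(as.numeric(as.matrix(dat[, -1L, drop = FALSE])),
             nrow = nrow(dat)))
    frame_index <- suppressWarnings(as.integer(dat[[1L]]))
    m <- length(markers)
    xi <- seq(1L, by = 3L, length.out = m)
    pose_track(x = num[, xi, drop = FALSE],
               y = num[, xi + 1L, drop = FALSE],
               likelihood = num[, xi + 2L, drop = FALSE],
               markers = markers, frame_index = frame_index)
  } else {
    dat <- utils::read.csv(path, header = TRUE)
    if (nrow(dat) == 0L) stop("parse error: empty data section")
    if (ncol(dat) %% 2L != 0L)
      stop("plain dialect expects (x, y) column pairs")
    num <- as.matrix(dat)
    m <- ncol(num) %/% 2L
    xi <- seq(1L, by = 2L, length.out = m)
    markers <- sub("_?[xX]$", "", colnames(num)[xi])
    pose_track(x = num[, xi, drop = FALSE], y = num[, xi + 1L, drop = FALSE],
               markers = markers)
  }
}

#' Write a pose track to CSV
#'
#' @param track a [pose_track()].
#' @param path output path.
#' @param dialect `"dlc"` or `"plain"`; the DLC dialect writes the standard
#'   three header rows and a frame-index column.
#' @param scorer scorer name placed in the first DLC header row.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(track, path, dialect = c("dlc", "plain"),
                           scorer = "motifembed") {
  dialect <- match.arg(dialect)
  m <- length(track$markers)
  if (dialect == "dlc") {
    lik <- track$likelihood
    dat <- matrix(NA_real_, nrow(track$x), 3L * m)
    dat[, seq(1L, by = 3L, length.out = m)] <- track$x
    dat[, seq(2L, by = 3L, length.out = m)] <- track$y
    dat[, seq(3L, by = 3L, length.out = m)] <- lik
    hdr1 <- c("scorer", rep(scorer, 3L * m))
    hdr2 <- c("bodyparts", rep(track$markers, each = 3L))
    hdr3 <- c("coords", rep(c("x", "y", "likelihood"), m))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(hdr1, collapse = ","), con)
    writeLines(paste(hdr2, collapse = ","), con)
    writeLines(paste(hdr3, collapse = ","), con)
    body <- cbind(track$frame_index, dat)
    utils::write.table(body, con, sep = ",", col.names = FALSE,
                       row.names = FALSE, na = "")
  } else {
    dat <- matrix(NA_real_, nrow(track$x), 2L * m)
    dat[, seq(1L, by = 2L, length.out = m)] <- track$x
    dat[, seq(2L, by = 2L, length.out = m)] <- track$y
    colnames(dat) <- as.vector(rbind(paste0(track$markers, "_x"),
                                     paste0(track$markers, "_y")))
    utils::write.csv(as.data.frame(dat), path, row.names = FALSE)
  }
  invisible(path)
}

#' Apply the pose-confidence mask
#'
#' Coordinates whose pose-estimation likelihood falls below
#' `pose_confidence` are replaced by `NaN` (both x and y of the marker), to
#' be linearly interpolated later in the preprocessing chain. Cells without
#' a likelihood are kept.
#'
#' @param track a [pose_track()].
#' @param pose_confidence minimum accepted likelihood, in `[0, 1]`
#'   (default 0.9).
#' @return a `raw_series`: list with `values` (N x 2M matrix, x/y
#'   interleaved per marker), logical `mask` of the same shape (`TRUE` =
#'   missing/low confidence), and `markers`.
#' @export
confidence_mask <- function(track, pose_confidence = 0.9) {
  if (!is.numeric(pose_confidence) || length(pose_confidence) != 1L ||
      is.na(pose_confidence) || pose_confidence < 0 || pose_confidence > 1)
    stop("pose_confidence must be a probability in [0, 1]")
  n <- nrow(track$x); m <- length(track$markers)
  values <- matrix(NA_real_, n, 2L * m)
  xi <- seq(1L, by = 2L, length.out = m)
  values[, xi] <- track$x
  values[, xi + 1L] <- track$y
  low <- !is.na(track$likelihood) & track$likelihood < pose_confidence
  mask <- matrix(FALSE, n, 2L * m)
  mask[, xi] <- low
  mask[, xi + 1L] <- low
  mask <- mask | is.na(values) | is.nan(values)
  values[mask] <- NaN
  colnames(values) <- as.vector(rbind(paste0(track$markers, "_x"),
                                      paste0(track$markers, "_y")))
  structure(list(values = values, mask = mask, markers = track$markers),
            class = "raw_series")
}

#' @export
print.raw_series <- function(x, ...) {
  cat(sprintf("raw_series: %d frames x %d coordinates (%d masked cells)\n",
              nrow(x$values), ncol(x$values), sum(x$mask)))
  invisible(x)
}

#' Convert a pose track directly to a model-ready series
#'
#' For data that is already in egocentric coordinates (head-fixed setups and
#' the like) this is the whole import step: confidence masking without
#' alignment. The result can be persisted with [write_series_npy()].
#'
#' @inheritParams confidence_mask
#' @return a `raw_series`.
#' @export
csv_to_series <- function(track, pose_confidence = 0.9) {
  if (nrow(track$x) == 0L) stop("empty pose track")
  confidence_mask(track, pose_confidence)
}

#' Persist a series as an NPY array
#'
#' Writes the `values` matrix of a `raw_series` or [marker_series()] (frames
#' x features, masked cells as NaN) to NumPy format, matching the
#' `<video>-PE-seq.npy` artifact convention of the workflow.
#'
#' @param series a `raw_series` or `marker_series`.
#' @param path output `.npy` path.
#' @return `path`, invisibly.
#' @export
write_series_npy <- function(series, path) {
  npy_save(unclass(series)$values, path)
}

#' @rdname write_series_npy
#' @export
read_series_npy <- function(path) {
  values <- npy_load(path)
  structure(list(values = values, mask = is.na(values) | is.nan(values),
                 markers = NULL),
            class = "raw_series")
}
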