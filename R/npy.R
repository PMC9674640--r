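#' Minimal NPY array serialization
#'
#' Reads and writes NumPy `.npy` files (format version 1.0) for numeric
#' vectors and matrices, so pipeline artifacts interoperate with the Python
#' scientific stack. Doubles are stored as little-endian `<f8`, integers as
#' `<i8`; matrices are written in C (row-major) order.
#'
#' @param x numeric or integer vector/matrix.
#' @param path file path ending in `.npy`.
#' @return `npy_save` returns `path` invisibly; `npy_load` returns a vector
#'   or matrix matching the stored shape.
#' @examples
#' f <- tempfile(fileext = ".npy")
#' npy_save(matrix(1:6, 2, 3), f)
#' npy_load(f)
#' @export
npy_save <- function(x, path) {
  if (!(is.numeric(x) || is.integer(x)))
    stop("npy_save() handles numeric and integer arrays only")
  dims <- if (is.matrix(x)) dim(x) else length(x)
  descr <- if (is.integer(x)) "<i8" else "<f8"
  shape <- if (length(dims) == 1L) sprintf("(%d,)", dims) else
    sprintf("(%d, %d)", dims[1L], dims[2L])
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                    descr, shape)
  # pad so magic(6) + version(2) + hlen(2) + header is a multiple of 64
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59, 0x01, 0x00)), con)
  writeBin(as.raw(c(nchar(header) %% 256L, nchar(header) %/% 256L)), con)
  writeChar(header, con, eos = NULL)
  dat <- if (is.matrix(x)) as.vector(t(x)) else as.vector(x)  # C order
  if (is.integer(x)) {
    # emit int64 as interleaved 32-bit halves (R integers are 32-bit)
    out <- integer(2L * length(dat))
    out[seq(1L, by = 2L, length.out = length(dat))] <- dat
    out[seq(2L, by = 2L, length.out = length(dat))] <-
      ifelse(dat < 0L, -1L, 0L)
    writeBin(out, con, size = 4L, endian = "little")
  } else {
    writeBin(as.double(dat), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' @rdname npy_save
#' @export
npy_load <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 6L)
  if (!identical(magic, as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59))))
    stop("not an NPY file: ", path)
  ver <- readBin(con, "raw", n = 2L)
  hlen <- if (as.integer(ver[1L]) >= 2L) {
    readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  } else {
    sum(as.integer(readBin(con, "raw", n = 2L)) * c(1L, 256L))
  }
  header <- readChar(con, hlen, useBytes = TRUE)
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_s <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1L]])
  if (length(shape) == 0L) shape <- integer(0)
  n <- prod(c(shape, 1L))
  dat <- switch(descr,
    "<f8" = readBin(con, "double", n = n, size = 8L, endian = "little"),
    "<f4" = readBin(con, "double", n = n, size = 4L, endian = "little"),
    "<i8" = read_int64(con, n),
    "<i4" = readBin(con, "integer", n = n, size = 4L, endian = "little"),
    "|b1" = as.integer(readBin(con, "raw", n = n)),
    stop("unsupported NPY dtype: ", descr)
  )
  if (length(shape) <= 1L) return(dat)
  if (length(shape) != 2L) stop("only 1-D and 2-D arrays supported")
  if (fortran) matrix(dat, shape[1L], shape[2L])
  else matrix(dat, shape[1L], shape[2L], byrow = TRUE)
}

# R has no native int64; reassemble from 32-bit halves. Exact while |x| < 2^53.
read_int64 <- function(con, n) {
  lo_hi <- readBin(con, "integer", n = 2L * n, size = 4L, endian = "little")
  lo <- lo_hi[seq(1L, by = 2L, length.out = n)]
  hi <- lo_hi[seq(2L, by = 2L, length.out = n)]
  lo_u <- ifelse(lo < 0, lo + 2^32, lo)
  hi * 2^32 + lo_u
}
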