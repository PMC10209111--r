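#' Read a one-dimensional NPY array
#'
#' Minimal reader for NumPy `.npy` files (format version 1.0/2.0,
#' little-endian, C order) restricted to one-dimensional numeric arrays --
#' the shape Phy/Kilosort uses for `spike_times.npy` and
#' `spike_clusters.npy`. Unsigned/signed 64-bit integers are returned as
#' doubles; values are exact up to 2^53, far beyond any realistic sample
#' index.
#'
#' @param path Path to a `.npy` file.
#' @return A numeric vector.
#' @export
read_npy <- function(path) {
  if (!file.exists(path)) {
    stop("NPY file not found: ", path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 6L)
  if (length(magic) < 6L ||
      !identical(magic, as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59)))) {
    stop("Not an NPY file (bad magic): ", path, call. = FALSE)
  }
  ver <- readBin(con, "raw", n = 2L)
  if (as.integer(ver[1L]) == 1L) {
    hlen <- readBin(con, "integer", n = 1L, size = 2L, signed = FALSE,
                    endian = "little")
  } else {
    hlen <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  }
  header <- rawToChar(readBin(con, "raw", n = hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  if (grepl("'fortran_order':\\s*True", header)) {
    stop("Fortran-ordered NPY arrays are not supported: ", path,
         call. = FALSE)
  }
  shape <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  dims <- as.numeric(strsplit(gsub("\\s", "", shape), ",")[[1]])
  dims <- dims[!is.na(dims)]
  if (length(dims) == 0L) dims <- 1
  if (sum(dims > 1) > 1L) {
    stop("Only one-dimensional NPY arrays are supported (shape (",
         shape, ")): ", path, call. = FALSE)
  }
  n <- prod(dims)
  out <- switch(descr,
    "<f8" = readBin(con, "double", n = n, size = 8L, endian = "little"),
    "<f4" = readBin(con, "double", n = n, size = 4L, endian = "little"),
    "<i4" = as.numeric(readBin(con, "integer", n = n, size = 4L,
                               endian = "little")),
    "<i2" = as.numeric(readBin(con, "integer", n = n, size = 2L,
                               endian = "little")),
    "<u4" = {
      lo <- readBin(con, "integer", n = n, size = 4L, endian = "little")
      ifelse(lo < 0, lo + 2^32, as.numeric(lo))
    },
    "<i8" = ,
    "<u8" = {
      raw8 <- readBin(con, "raw", n = n * 8L)
      m <- matrix(as.numeric(raw8), nrow = 8L)
      v <- as.numeric(crossprod(m, 256^(0:7)))
      if (descr == "<i8") v <- ifelse(v >= 2^63, v - 2^64, v)
      v
    },
    stop("Unsupported NPY dtype '", descr, "': ", path, call. = FALSE)
  )
  if (length(out) != n) {
    stop("Truncated NPY file (expected ", n, " values, read ",
         length(out), "): ", path, call. = FALSE)
  }
  out
}

#' Write a one-dimensional NPY array
#'
#' Companion writer to [read_npy()]; used to emit Phy-style
#' `spike_times.npy` / `spike_clusters.npy` files from the synthetic-data
#' module and from tests.
#'
#' @param x Numeric vector.
#' @param path Output path.
#' @param dtype One of `"<f8"` (double), `"<i4"` (32-bit int) or `"<u8"`
#'   (unsigned 64-bit, e.g. sample indices); values must be representable.
#' @return `path`, invisibly.
#' @export
write_npy <- function(x, path, dtype = c("<f8", "<i4", "<u8")) {
  dtype <- match.arg(dtype)
  n <- length(x)
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': (%d,), }",
                    dtype, n)
  # pad so that magic(6) + version(2) + hlen(2) + header is a multiple of 64
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  if (pad == 64L) pad <- 0L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59, 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeBin(charToRaw(header), con)
  if (dtype == "<f8") {
    writeBin(as.double(x), con, size = 8L, endian = "little")
  } else if (dtype == "<i4") {
    if (any(abs(x) >= 2^31)) stop("values out of range for <i4", call. = FALSE)
    writeBin(as.integer(round(x)), con, size = 4L, endian = "little")
  } else {
    if (any(x < 0) || any(x >= 2^53)) {
      stop("values out of range for <u8 writer", call. = FALSE)
    }
    v <- round(x)
    bytes <- raw(8L * n)
    rem <- v
    for (k in 1:8) {
      b <- rem %% 256
      bytes[seq(k, by = 8L, length.out = n)] <- as.raw(b)
      rem <- (rem - b) / 256
    }
    writeBin(bytes, con)
  }
  invisible(path)
}
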