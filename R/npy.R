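# Minimal NumPy container IO: NPY v1.0 read/write for 1-3 dimensional
# arrays (dtypes <f8, <f4, <i8, <i4) and NPZ archives as stored (method 0)
# ZIP files. int64 payloads are carried through R doubles, which is exact
# for the integer magnitudes that occur here (atomic numbers, indices).

# C-order flattening of an R (column-major) array
.cOrder <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 1L) return(as.vector(x))
  as.vector(aperm(x, rev(seq_along(d))))
}

.fromCOrder <- function(v, shape) {
  if (length(shape) <= 1L) return(v)
  aperm(array(v, dim = rev(shape)), rev(seq_along(shape)))
}

.writeInt64 <- function(con, v) {
  v <- as.double(v)
  neg <- v < 0
  v[neg] <- v[neg] + 2^64
  hi <- floor(v / 2^32)
  lo <- v - hi * 2^32
  toSigned <- function(u) { u[u >= 2^31] <- u[u >= 2^31] - 2^32; as.integer(u) }
  inter <- integer(2L * length(v))
  inter[seq(1L, by = 2L, length.out = length(v))] <- toSigned(lo)
  inter[seq(2L, by = 2L, length.out = length(v))] <- toSigned(hi)
  writeBin(inter, con, size = 4L, endian = "little")
}

.readInt64 <- function(con, n) {
  ints <- readBin(con, "integer", n = 2L * n, size = 4L, endian = "little")
  lo <- as.double(ints[seq(1L, by = 2L, length.out = n)])
  lo[lo < 0] <- lo[lo < 0] + 2^32
  hi <- as.double(ints[seq(2L, by = 2L, length.out = n)])
  hi * 2^32 + lo
}

# serialize one array as NPY into a raw vector
.npyRaw <- function(x, dtype = NULL) {
  if (is.null(dtype)) dtype <- if (is.integer(x)) "<i8" else "<f8"
  shape <- dim(x)
  if (is.null(shape)) shape <- length(x)
  shapeStr <- if (length(shape) == 1L) sprintf("(%d,)", shape) else
    sprintf("(%s)", paste(shape, collapse = ", "))
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                    dtype, shapeStr)
  totLen <- 10L + nchar(header) + 1L
  pad <- (64L - totLen %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(c(0x93, utf8ToInt("N"), utf8ToInt("U"), utf8ToInt("M"),
                    utf8ToInt("P"), utf8ToInt("Y"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeChar(header, con, eos = NULL)
  v <- .cOrder(x)
  switch(dtype,
         "<f8" = writeBin(as.double(v), con, size = 8L, endian = "little"),
         "<f4" = writeBin(as.double(v), con, size = 4L, endian = "little"),
         "<i4" = writeBin(as.integer(v), con, size = 4L, endian = "little"),
         "<i8" = .writeInt64(con, v),
         stop("unsupported NPY dtype: ", dtype))
  rawConnectionValue(con)
}

#' Read and write NumPy NPY files
#'
#' Supports NPY format 1.0 with dtypes `<f8`, `<f4`, `<i8`, `<i4` and
#' C-contiguous layout, for arrays of up to three dimensions. int64 values
#' are returned as doubles (exact for |x| < 2^53).
#'
#' @param path file path.
#' @return `readNpy`: the array (vector for 1-D).
#' @export
readNpy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  .readNpyCon(con)
}

.readNpyCon <- function(con) {
  magic <- readBin(con, "raw", n = 8L)
  if (length(magic) < 8L || any(magic[1:6] != as.raw(c(0x93, utf8ToInt("N"), utf8ToInt("U"),
                                                       utf8ToInt("M"), utf8ToInt("P"), utf8ToInt("Y"))))) {
    stop("not an NPY file")
  }
  major <- as.integer(magic[7L])
  hlen <- if (major >= 2L) readBin(con, "integer", size = 4L, endian = "little")
          else readBin(con, "integer", size = 2L, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", n = hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shapeStr <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s|,$", "", shapeStr), ",")[[1]])
  if (length(shape) == 0L || any(is.na(shape))) shape <- integer(0)
  n <- if (length(shape)) prod(shape) else 1L
  v <- switch(descr,
              "<f8" = readBin(con, "double", n = n, size = 8L, endian = "little"),
              "<f4" = readBin(con, "double", n = n, size = 4L, endian = "little"),
              "<i4" = readBin(con, "integer", n = n, size = 4L, endian = "little"),
              "<i8" = .readInt64(con, n),
              stop("unsupported NPY dtype: ", descr))
  if (length(shape) <= 1L) return(v)
  if (fortran) array(v, dim = shape) else .fromCOrder(v, shape)
}

#' @rdname readNpy
#' @param x numeric/integer vector or array (up to 3-D).
#' @param dtype NumPy dtype string; default `<i8` for integer storage mode,
#'   `<f8` otherwise.
#' @export
writeNpy <- function(x, path, dtype = NULL) {
  writeBin(.npyRaw(x, dtype), path)
  invisible(path)
}

.crcTable <- local({
  tab <- integer(256L)
  poly <- -306674912L # 0xEDB88320
  for (n in 0:255) {
    cc <- n
    for (k in 1:8) {
      cc <- if (bitwAnd(cc, 1L)) bitwXor(poly, bitwShiftR(cc, 1L)) else bitwShiftR(cc, 1L)
    }
    tab[n + 1L] <- cc
  }
  tab
})

.crc32 <- function(bytes) {
  cc <- -1L
  b <- as.integer(bytes)
  tab <- .crcTable
  for (x in b) {
    cc <- bitwXor(tab[bitwAnd(bitwXor(cc, x), 255L) + 1L], bitwShiftR(cc, 8L))
  }
  bitwXor(cc, -1L)
}

#' Read and write NumPy NPZ archives
#'
#' `writeNpz` emits a stored (uncompressed) ZIP of NPY members; `readNpz`
#' accepts stored or deflated archives.
#'
#' @param arrays named list of arrays.
#' @param path file path.
#' @return `readNpz`: a named list of arrays.
#' @export
writeNpz <- function(arrays, path) {
  stopifnot(is.list(arrays), !is.null(names(arrays)), all(nzchar(names(arrays))))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w32u <- function(x) { # accepts doubles up to 2^32-1
    x <- as.double(x); if (x >= 2^31) x <- x - 2^32
    writeBin(as.integer(x), con, size = 4L, endian = "little")
  }
  offsets <- integer(0); crcs <- integer(0); sizes <- double(0); fnames <- character(0)
  offset <- 0
  for (nm in names(arrays)) {
    payload <- .npyRaw(arrays[[nm]])
    fname <- paste0(nm, ".npy")
    crc <- .crc32(payload)
    offsets <- c(offsets, offset); crcs <- c(crcs, crc)
    sizes <- c(sizes, length(payload)); fnames <- c(fnames, fname)
    w32(67324752L)                     # local header 0x04034b50
    w16(20L); w16(0L); w16(0L)           # version, flags, method=store
    w16(0L); w16(33L)                    # dos time/date (1980-01-01)
    writeBin(as.integer(crc), con, size = 4L, endian = "little")
    w32u(length(payload)); w32u(length(payload))
    w16(nchar(fname)); w16(0L)
    writeChar(fname, con, eos = NULL)
    writeBin(payload, con)
    offset <- offset + 30 + nchar(fname) + length(payload)
  }
  cdStart <- offset
  for (k in seq_along(fnames)) {
    w32(33639248L)                     # central header 0x02014b50
    w16(20L); w16(20L); w16(0L); w16(0L)
    w16(0L); w16(33L)
    writeBin(as.integer(crcs[k]), con, size = 4L, endian = "little")
    w32u(sizes[k]); w32u(sizes[k])
    w16(nchar(fnames[k])); w16(0L); w16(0L)
    w16(0L); w16(0L); w32(0L)
    w32u(offsets[k])
    writeChar(fnames[k], con, eos = NULL)
    offset <- offset + 46 + nchar(fnames[k])
  }
  w32(101010256L)                       # EOCD 0x06054b50
  w16(0L); w16(0L)
  w16(length(fnames)); w16(length(fnames))
  w32u(offset - cdStart); w32u(cdStart)
  w16(0L)
  invisible(path)
}

#' @rdname writeNpz
#' @export
readNpz <- function(path) {
  exdir <- tempfile("npz")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  files <- utils::unzip(path, exdir = exdir)
  out <- lapply(files, readNpy)
  names(out) <- sub("\\.npy$", "", basename(files))
  out
}
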