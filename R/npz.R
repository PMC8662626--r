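# Minimal NumPy .npy / .npz support. No installed R package reads these, and
# the segmentation stage upstream of this package dumps its cropped label
# arrays as .npz, so a small reader/writer is provided: .npy format 1.0 with
# the common little-endian dtypes, and the stored (uncompressed) ZIP dialect
# for writing; reading goes through R's internal unzip, which also handles
# deflated archives.

.crcTable <- local({
  tab <- integer(256L)
  for (n in 0:255) {
    c <- n
    for (k in 1:8)
      c <- if (bitwAnd(c, 1L) == 1L)
        bitwXor(bitwShiftR(c, 1L), -306674912L) else bitwShiftR(c, 1L)
    tab[n + 1L] <- c
  }
  tab
})

# CRC-32 of a raw vector, returned as a double in [0, 2^32)
.crc32 <- function(bytes) {
  crc <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b))
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   .crcTable[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L])
  crc <- bitwXor(crc, -1L)
  if (crc < 0) crc + 2^32 else as.numeric(crc)
}

.packU16 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))
.packU32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

# serialize an integer 3D array (column-major / Fortran order) as .npy bytes
.npyBytes <- function(data) {
  shape <- dim(data)
  header <- sprintf("{'descr': '<i4', 'fortran_order': True, 'shape': (%s), }",
                    paste(shape, collapse = ", "))
  # pad with spaces so that 10 + header length is a multiple of 64; newline last
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  if (pad == 64L) pad <- 0L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59, 0x01, 0x00)), con)
  writeBin(.packU16(nchar(header)), con)
  writeBin(charToRaw(header), con)
  writeBin(as.integer(data), con, size = 4L, endian = "little")
  rawConnectionValue(con)
}

# parse .npy bytes -> numeric/integer array (always returned column-major)
.parseNpy <- function(bytes) {
  if (length(bytes) < 10L ||
      !identical(bytes[1:6], as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59))))
    stop("not a .npy file (bad magic)", call. = FALSE)
  major <- as.integer(bytes[7])
  if (major == 1L) {
    hlen <- as.integer(bytes[9]) + 256L * as.integer(bytes[10])
    hstart <- 11L
  } else {
    hlen <- sum(as.integer(bytes[9:12]) * c(1, 256, 65536, 16777216))
    hstart <- 13L
  }
  header <- rawToChar(bytes[hstart:(hstart + hlen - 1L)])
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shapeStr <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shapeStr), ",")[[1]])
  payload <- bytes[(hstart + hlen):length(bytes)]
  n <- prod(shape)
  vec <- switch(descr,
    "|b1" = , "|u1" = as.integer(payload[seq_len(n)]),
    "|i1" = readBin(payload, "integer", n, size = 1L, signed = TRUE),
    "<i2" = readBin(payload, "integer", n, size = 2L, signed = TRUE,
                    endian = "little"),
    "<u2" = readBin(payload, "integer", n, size = 2L, signed = FALSE,
                    endian = "little"),
    "<i4" = readBin(payload, "integer", n, size = 4L, endian = "little"),
    "<i8" = {
      u <- readBin(payload, "integer", 2L * n, size = 4L, endian = "little")
      lo <- u[seq(1L, 2L * n, by = 2L)]
      hi <- u[seq(2L, 2L * n, by = 2L)]
      lo <- ifelse(lo < 0, lo + 2^32, lo)
      lo + hi * 2^32
    },
    "<f4" = readBin(payload, "numeric", n, size = 4L, endian = "little"),
    "<f8" = readBin(payload, "numeric", n, size = 8L, endian = "little"),
    stop("unsupported .npy dtype: ", descr, call. = FALSE))
  arr <- if (fortran || length(shape) == 1L) array(vec, shape)
         else aperm(array(vec, rev(shape)), rev(seq_along(shape)))
  arr
}

# write named raw payloads as a stored (method 0) ZIP archive
.writeStoredZip <- function(path, entries) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(entries))
  crcs <- numeric(length(entries))
  pos <- 0
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    offsets[i] <- pos
    crcs[i] <- .crc32(data)
    hdr <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), .packU16(20L), .packU16(0L),
             .packU16(0L), .packU16(0L), .packU16(33L), .packU32(crcs[i]),
             .packU32(length(data)), .packU32(length(data)),
             .packU16(length(name)), .packU16(0L))
    writeBin(hdr, con); writeBin(name, con); writeBin(data, con)
    pos <- pos + length(hdr) + length(name) + length(data)
  }
  cdStart <- pos
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    cd <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)), .packU16(20L), .packU16(20L),
            .packU16(0L), .packU16(0L), .packU16(0L), .packU16(33L),
            .packU32(crcs[i]), .packU32(length(data)),
            .packU32(length(data)), .packU16(length(name)), .packU16(0L),
            .packU16(0L), .packU16(0L), .packU16(0L), .packU32(0L),
            .packU32(offsets[i]))
    writeBin(cd, con); writeBin(name, con)
    pos <- pos + length(cd) + length(name)
  }
  eocd <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), .packU16(0L), .packU16(0L),
            .packU16(length(entries)), .packU16(length(entries)),
            .packU32(pos - cdStart), .packU32(cdStart), .packU16(0L))
  writeBin(eocd, con)
  invisible(path)
}

# read one array from an .npz archive: prefer the entry named "vol",
# fall back to the first array in the archive
.readNpz <- function(path) {
  tmp <- tempfile("npz")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  files <- utils::unzip(path, exdir = tmp, unzip = "internal")
  if (length(files) == 0L)
    stop("empty or unreadable .npz archive: ", path, call. = FALSE)
  pick <- files[basename(files) == "vol.npy"]
  if (length(pick) == 0L) pick <- files[1L]
  .parseNpy(readBin(pick[1L], "raw", file.size(pick[1L])))
}
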