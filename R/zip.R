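# Minimal deterministic ZIP writer plus thin readers over utils::unzip.
#
# Archives are write-once: all entries are collected in memory and the file
# is emitted in one pass (local headers + central directory + end record).
# Every entry is DEFLATE-compressed; the raw deflate stream is obtained by
# stripping the 2-byte zlib header and 4-byte Adler trailer from
# memCompress() output. Timestamps are fixed so identical content yields a
# byte-identical archive. No ZIP64: entries and totals stay far below 4 GB.

.ZIP_DOSTIME <- c(0x00, 0x00)            # 00:00:00
.ZIP_DOSDATE <- u16_le((2022 - 1980) * 512 + 1 * 32 + 1)  # 2022-01-01

# raw DEFLATE stream for ZIP entries
deflate_raw <- function(bytes) {
  z <- memCompress(bytes, type = "gzip")  # zlib-framed despite the name
  z[3:(length(z) - 4)]
}

#' Write a ZIP archive from named raw entries
#'
#' @param path Output file path.
#' @param entries Named list of raw vectors; names are entry paths inside the
#'   archive (forward slashes).
#' @return `path`, invisibly.
#' @export
zip_write <- function(path, entries) {
  stopifnot(is.list(entries), !is.null(names(entries)), all(nzchar(names(entries))))
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(entries))
  locals <- vector("list", length(entries))
  centrals <- vector("list", length(entries))
  pos <- 0
  for (i in seq_along(entries)) {
    nm <- names(entries)[i]
    body <- entries[[i]]
    stopifnot(is.raw(body))
    comp <- deflate_raw(body)
    crc <- crc32(body)
    name_raw <- charToRaw(nm)
    common <- c(u16_le(20),                     # version needed
                u16_le(0),                      # flags
                u16_le(8),                      # method: deflate
                as.raw(.ZIP_DOSTIME), .ZIP_DOSDATE,
                u32_le(crc),
                u32_le(length(comp)),
                u32_le(length(body)),
                u16_le(length(name_raw)),
                u16_le(0))                      # extra length
    locals[[i]] <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), common, name_raw, comp)
    centrals[[i]] <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)),
                       u16_le(20),              # version made by
                       common,
                       u16_le(0), u16_le(0), u16_le(0),  # comment/disk/int attrs
                       u32_le(0),               # external attrs
                       u32_le(pos),             # local header offset
                       name_raw)
    offsets[i] <- pos
    pos <- pos + length(locals[[i]])
  }
  cd <- do.call(c, centrals)
  eocd <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)),
            u16_le(0), u16_le(0),
            u16_le(length(entries)), u16_le(length(entries)),
            u32_le(length(cd)), u32_le(pos),
            u16_le(0))
  writeBin(do.call(c, c(locals, list(cd, eocd))), con)
  invisible(path)
}

#' List entry paths in a ZIP archive
#' @param path Archive path.
#' @return Character vector of entry names.
#' @export
zip_entries <- function(path) {
  if (!file.exists(path)) stop(sprintf("archive not found: %s", path), call. = FALSE)
  utils::unzip(path, list = TRUE)$Name
}

#' Read entries from a ZIP archive as raw vectors
#' @param path Archive path.
#' @param name Entry path inside the archive.
#' @return `zip_read()`: raw vector of the entry's uncompressed bytes;
#'   `zip_read_many()`: named list of raw vectors.
#' @export
zip_read <- function(path, name) {
  zip_read_many(path, name)[[name]]
}

#' @rdname zip_read
#' @param names Character vector of entry paths.
#' @export
zip_read_many <- function(path, names) {
  td <- tempfile("zipx")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  tryCatch(
    utils::unzip(path, files = names, exdir = td),
    warning = function(w) stop(sprintf("corrupt or missing archive entry in %s (%s)",
                                       path, conditionMessage(w)), call. = FALSE)
  )
  out <- lapply(names, function(nm) {
    f <- file.path(td, nm)
    if (!file.exists(f)) stop(sprintf("corrupt or missing archive entry: %s", nm), call. = FALSE)
    readBin(f, "raw", n = file.size(f))
  })
  stats::setNames(out, names)
}
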