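# Low-level byte helpers shared by the integer codec and the ZIP layer.
#
# All unsigned 32-bit quantities are carried as R doubles (exact below 2^53);
# R's native integer is signed 32-bit and cannot hold codes >= 2^31.

#' @noRd
u16_le <- function(x) {
  stopifnot(x >= 0, x < 65536)
  as.raw(c(x %% 256, x %/% 256))
}

#' @noRd
u32_le <- function(x) {
  stopifnot(x >= 0, x < 2^32)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

#' @noRd
rd_u32_le <- function(bytes, at = 1L) {
  b <- as.double(bytes[at:(at + 3L)])
  b[1] + b[2] * 256 + b[3] * 65536 + b[4] * 16777216
}

# CRC-32 (reflected, poly 0xEDB88320), as used by ZIP/gzip. The running value
# is kept in a signed 32-bit integer; bitwXor/bitwAnd act on the bit pattern
# and bitwShiftR is a logical shift, so the arithmetic is exact.
.crc_env <- new.env(parent = emptyenv())

#' @noRd
crc32_table <- function() {
  if (!is.null(.crc_env$tab)) return(.crc_env$tab)
  poly <- -306674912L  # 0xEDB88320 as a signed 32-bit pattern
  tab <- integer(256)
  for (i in 0:255) {
    c <- as.integer(i)
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(bitwShiftR(c, 1L), poly) else bitwShiftR(c, 1L)
    }
    tab[i + 1L] <- c
  }
  .crc_env$tab <- tab
  tab
}

#' @noRd
crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L  # 0xFFFFFFFF
  n <- length(bytes)
  if (n > 0L) {
    ints <- as.integer(bytes)
    for (i in seq_len(n)) {
      idx <- bitwAnd(bitwXor(crc, ints[i]), 255L)
      crc <- bitwXor(bitwShiftR(crc, 8L), tab[idx + 1L])
    }
  }
  crc <- bitwXor(crc, -1L)
  # return as unsigned double
  if (crc < 0) crc + 2^32 else as.double(crc)
}

# LEB128 varint (base-128, little-endian, continuation bit), used by the
# long-variant record stream.

#' @noRd
varint_encode <- function(x) {
  stopifnot(x >= 0, x < 2^32)
  out <- integer(0)
  repeat {
    b <- x %% 128
    x <- x %/% 128
    if (x > 0) {
      out <- c(out, b + 128)
    } else {
      out <- c(out, b)
      break
    }
  }
  as.raw(out)
}

#' Decode one varint starting at position `at`; returns list(value, next_at).
#' @noRd
varint_decode <- function(bytes, at) {
  value <- 0
  shift <- 1
  repeat {
    if (at > length(bytes)) stop("corrupt varint: truncated stream", call. = FALSE)
    b <- as.double(bytes[at])
    at <- at + 1L
    value <- value + (b %% 128) * shift
    if (b < 128) break
    shift <- shift * 128
  }
  list(value = value, next_at = at)
}
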