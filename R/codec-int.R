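# Reversible integer transforms: zigzag, delta coding of sorted sequences,
# and Stream VByte with a separated control-byte block.
#
# Stream VByte stores each unsigned 32-bit integer in 1-4 little-endian data
# bytes; the per-integer byte length minus one (2 bits each) lives in a
# separate control block, four integers per control byte, first integer of
# each group in the two least-significant bits. Unused control bits of the
# final partial group are zero. The serialized block layout is
# [u32 count LE][control bytes][data bytes].

#' Zigzag map between signed and unsigned integers
#'
#' 0 -> 0, -1 -> 1, 1 -> 2, -2 -> 3, ... so small-magnitude signed values
#' (notably the -1 missing sentinel) become small unsigned values that
#' Stream VByte stores in one byte.
#'
#' @param n Signed values in `[-2^31, 2^31)` (vectorized).
#' @return Unsigned doubles in `[0, 2^32)`.
#' @export
zigzag <- function(n) {
  if (any(n < -2^31 | n >= 2^31)) stop("zigzag input outside signed 32-bit range", call. = FALSE)
  ifelse(n >= 0, 2 * as.double(n), -2 * as.double(n) - 1)
}

#' @rdname zigzag
#' @param u Unsigned values in `[0, 2^32)`.
#' @export
unzigzag <- function(u) {
  if (any(u < 0 | u >= 2^32)) stop("unzigzag input outside unsigned 32-bit range", call. = FALSE)
  ifelse(u %% 2 == 0, u / 2, -(u + 1) / 2)
}

#' Delta-encode a sorted sequence
#'
#' Stores each value as its difference from the predecessor (the first value
#' verbatim); inverted by [prefix_sum()]. Applied to sorted variant codes so
#' most deltas are small and compress to single bytes.
#'
#' @param values Non-decreasing doubles below 2^32.
#' @return Double vector of deltas, same length.
#' @export
delta_encode <- function(values) {
  if (length(values) == 0) return(double(0))
  d <- diff(values)
  if (any(d < 0)) stop("delta_encode input is not sorted (non-decreasing)", call. = FALSE)
  c(values[1], d)
}

#' Cumulative (prefix) sum: inverse of [delta_encode()]
#'
#' @param deltas Double vector of deltas.
#' @return Reconstructed values.
#' @export
prefix_sum <- function(deltas) {
  if (length(deltas) == 0) return(double(0))
  v <- cumsum(deltas)
  if (v[length(v)] >= 2^32) stop("prefix sum overflows 32 bits", call. = FALSE)
  v
}

# byte length (1-4) needed for each unsigned value
svb_lengths <- function(values) {
  1L + (values >= 2^8) + (values >= 2^16) + (values >= 2^24)
}

#' Stream VByte encode
#'
#' @param values Unsigned doubles below 2^32.
#' @return List of class `svb_block`: `count`, `control` (raw), `data` (raw).
#' @export
svb_encode <- function(values) {
  if (any(values < 0 | values >= 2^32)) stop("values outside unsigned 32-bit range", call. = FALSE)
  n <- length(values)
  if (n == 0) {
    return(structure(list(count = 0, control = raw(0), data = raw(0)), class = "svb_block"))
  }
  lens <- svb_lengths(values)
  codes <- lens - 1L
  # pack 4 codes per control byte, first value in the low 2 bits
  ncb <- ceiling(n / 4)
  cpad <- c(codes, integer(ncb * 4L - n))
  cm <- matrix(cpad, nrow = 4)
  control <- as.raw(cm[1, ] + cm[2, ] * 4L + cm[3, ] * 16L + cm[4, ] * 64L)
  # little-endian data bytes, lens[i] bytes for value i
  b <- rbind(values %% 256,
             (values %/% 256) %% 256,
             (values %/% 65536) %% 256,
             (values %/% 16777216) %% 256)
  keep <- outer(1:4, lens, `<=`)
  data <- as.raw(b[keep])
  structure(list(count = n, control = control, data = data), class = "svb_block")
}

#' Stream VByte decode
#'
#' @param block An `svb_block` (or list with `count`, `control`, `data`).
#' @return Double vector of `count` unsigned values.
#' @export
svb_decode <- function(block) {
  n <- block$count
  if (n == 0) return(double(0))
  if (length(block$control) != ceiling(n / 4)) {
    stop("corrupt Stream VByte block: control length mismatch", call. = FALSE)
  }
  cb <- as.double(block$control)
  codes <- as.vector(rbind(cb %% 4, (cb %/% 4) %% 4, (cb %/% 16) %% 4, (cb %/% 64) %% 4))
  lens <- codes[seq_len(n)] + 1
  if (length(block$data) != sum(lens)) {
    stop("corrupt Stream VByte block: data length mismatch", call. = FALSE)
  }
  d <- c(as.double(block$data), 0, 0, 0)  # pad so fixed-stride indexing is safe
  starts <- cumsum(lens) - lens + 1
  d[starts] +
    d[starts + 1] * 256 * (lens >= 2) +
    d[starts + 2] * 65536 * (lens >= 3) +
    d[starts + 3] * 16777216 * (lens >= 4)
}

#' Serialize / deserialize an svb_block as [u32 count LE][control][data]
#' @param block An `svb_block`.
#' @return Raw vector.
#' @export
svb_serialize <- function(block) {
  c(u32_le(block$count), block$control, block$data)
}

#' @rdname svb_serialize
#' @param bytes Raw vector produced by [svb_serialize()].
#' @export
svb_deserialize <- function(bytes) {
  if (length(bytes) < 4) stop("corrupt block: shorter than its header", call. = FALSE)
  n <- rd_u32_le(bytes, 1L)
  ncb <- ceiling(n / 4)
  if (length(bytes) < 4 + ncb) stop("corrupt block: truncated control bytes", call. = FALSE)
  control <- bytes[seq_len(ncb) + 4L]
  data <- if (length(bytes) > 4 + ncb) bytes[(5L + ncb):length(bytes)] else raw(0)
  structure(list(count = n, control = control, data = data), class = "svb_block")
}
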