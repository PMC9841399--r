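# 32-bit variant codec.
#
# The genome is partitioned into 2^20-base bins per chromosome. Inside a bin,
# a small variant (combined REF+ALT length <= 4, alleles over {A,C,G,T}) is
# packed into one unsigned 32-bit code:
#
#   bits 31-12  in-bin offset (0-based position within the bin)
#   bits 11-10  REF length (1-3; 0 marks a placeholder)
#   bits  9-8   ALT length (1-3; 0 marks a placeholder)
#   bits  7-0   nucleotides of REF then ALT, 2 bits each (A=0,C=1,G=2,T=3),
#               first nucleotide in bits 7-6, unused pairs zero
#
# Placeholders (all 12 allele bits zero) mark the column slot of a long
# variant; they sort before any real code at the same offset, and unsigned
# ordering of codes is consistent with ordering by offset.
#
# Codes are carried as R doubles: exact integers below 2^53, whereas R's
# native integer type is signed 32-bit.

BIN_SHIFT <- 20L
BIN_SIZE <- 2^20
MAX_SHORT_TOTAL_LEN <- 4L
NUCS <- c("A", "C", "G", "T")

#' Is a REF/ALT pair encodable in 32 bits?
#'
#' A variant is "short" when the combined REF+ALT length is at most 4 and
#' both alleles contain only A, C, G or T. Anything else (longer indels,
#' IUPAC/N characters) is routed to the long-variant table.
#'
#' @param ref,alt Uppercase allele strings (vectorized).
#' @return Logical vector.
#' @export
#' @examples
#' is_short("A", "C")      # TRUE
#' is_short("ACGT", "A")   # FALSE: total length 5
#' is_short("A", "N")      # FALSE: N has no 2-bit code
is_short <- function(ref, alt) {
  if (any(!nzchar(ref)) || any(!nzchar(alt))) {
    stop("alleles must be non-empty", call. = FALSE)
  }
  (nchar(ref) + nchar(alt) <= MAX_SHORT_TOTAL_LEN) &
    grepl("^[ACGT]+$", ref) & grepl("^[ACGT]+$", alt)
}

#' Genome bin and in-bin offset of a 1-based position
#'
#' @param pos1 1-based VCF POS (vectorized).
#' @return List with `bin` (0-based bin index) and `offset` (0-based offset
#'   within the bin, `0 <= offset < 2^20`).
#' @export
#' @examples
#' bin_of(1)          # bin 0, offset 0
#' bin_of(1048577)    # bin 1, offset 0
bin_of <- function(pos1) {
  if (any(pos1 < 1)) stop("POS must be >= 1", call. = FALSE)
  pos0 <- as.double(pos1) - 1
  list(bin = pos0 %/% BIN_SIZE, offset = pos0 %% BIN_SIZE)
}

# 2-bit nucleotide codes for the concatenated REF+ALT, padded to 4 with "A"
# (code 0), so unused pairs come out zero. Internal, inputs already validated.
allele_bits <- function(ref, alt) {
  lr <- nchar(ref)
  la <- nchar(alt)
  concat <- paste0(ref, alt, strrep("A", MAX_SHORT_TOTAL_LEN - lr - la))
  n1 <- match(substr(concat, 1, 1), NUCS) - 1
  n2 <- match(substr(concat, 2, 2), NUCS) - 1
  n3 <- match(substr(concat, 3, 3), NUCS) - 1
  n4 <- match(substr(concat, 4, 4), NUCS) - 1
  lr * 1024 + la * 256 + n1 * 64 + n2 * 16 + n3 * 4 + n4
}

#' Encode a short variant into its 32-bit code
#'
#' @param offset 0-based offset within the bin (vectorized).
#' @param ref,alt Uppercase allele strings with `is_short(ref, alt)` true.
#' @return Double vector of unsigned 32-bit codes.
#' @export
#' @examples
#' encode32(0, "A", "C")    # 1296
#' encode32(5, "A", "C")    # 21776
encode32 <- function(offset, ref, alt) {
  if (any(offset < 0) || any(offset >= BIN_SIZE)) {
    stop("offset out of range [0, 2^20)", call. = FALSE)
  }
  ok <- is_short(ref, alt)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop(sprintf("not encodable in 32 bits: REF=%s ALT=%s", ref[bad], alt[bad]),
         call. = FALSE)
  }
  as.double(offset) * 4096 + allele_bits(ref, alt)
}

#' Decode a 32-bit variant code
#'
#' The annotation path never decodes (archived variants stay as integers);
#' this is the inverse used for testing, validation and debugging.
#'
#' @param code Double vector of codes with nonzero length bits.
#' @return List with `offset`, `ref`, `alt`.
#' @export
decode32 <- function(code) {
  offset <- code %/% 4096
  rem <- code %% 4096
  lr <- rem %/% 1024
  la <- (rem %/% 256) %% 4
  if (any(lr == 0 | la == 0)) {
    stop("placeholder codes (zero allele-length bits) cannot be decoded", call. = FALSE)
  }
  byte <- rem %% 256
  full <- paste0(NUCS[byte %/% 64 + 1], NUCS[(byte %/% 16) %% 4 + 1],
                 NUCS[(byte %/% 4) %% 4 + 1], NUCS[byte %% 4 + 1])
  list(offset = offset,
       ref = substr(full, 1, lr),
       alt = substr(full, lr + 1, lr + la))
}

#' Placeholder code for a long variant at an in-bin offset
#'
#' All 12 allele bits are zero, so a placeholder compares `<=` every real
#' code at the same offset under unsigned ordering.
#'
#' @param offset 0-based offset within the bin (vectorized).
#' @return Double vector of codes (`offset << 12`).
#' @export
placeholder32 <- function(offset) {
  if (any(offset < 0) || any(offset >= BIN_SIZE)) {
    stop("offset out of range [0, 2^20)", call. = FALSE)
  }
  as.double(offset) * 4096
}

#' @noRd
is_placeholder32 <- function(code) {
  code %% 4096 == 0
}
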