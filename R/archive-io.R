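# Archive layout and per-bin serialization.
#
# ZIP entry paths:
#   echtvar/config.json               field configuration (with inferred ftype)
#   echtvar/strings/<alias>.txt       one unique string per line; line i = code i
#   echtvar/<chrom>/<bin>/var32.bin   delta + Stream VByte block of sorted codes
#   echtvar/<chrom>/<bin>/long.bin    long-variant record stream (varint fields)
#   echtvar/<chrom>/<bin>/fields/<alias>.bin  zigzag + Stream VByte block
#
# Chromosome directory names are normalized (no "chr" prefix); bin directory
# names are plain decimal integers.

#' Construct the in-memory content of one (chromosome, bin)
#'
#' @param var32 Sorted double vector of 32-bit codes, placeholders included.
#' @param longs Data frame with columns `offset`, `ref`, `alt`, `field_index`
#'   (0-based index into the field columns), sorted by (offset, ref, alt).
#' @param columns Named list (alias -> double vector), each the same length
#'   as `var32`.
#' @return A `bin_data` list.
#' @export
bin_data <- function(var32 = double(0), longs = empty_longs(), columns = list()) {
  bd <- structure(list(var32 = as.double(var32), longs = longs, columns = columns),
                  class = "bin_data")
  validate_bin_data(bd)
  bd
}

#' @noRd
empty_longs <- function() {
  data.frame(offset = double(0), ref = character(0), alt = character(0),
             field_index = double(0), stringsAsFactors = FALSE)
}

#' @noRd
validate_bin_data <- function(bd) {
  n <- length(bd$var32)
  if (is.unsorted(bd$var32)) stop("integrity error: var32 is not sorted", call. = FALSE)
  for (alias in names(bd$columns)) {
    if (length(bd$columns[[alias]]) != n) {
      stop(sprintf("integrity error: column '%s' has length %d, expected %d",
                   alias, length(bd$columns[[alias]]), n), call. = FALSE)
    }
  }
  if (nrow(bd$longs) > 0) {
    if (any(bd$longs$field_index < 0 | bd$longs$field_index >= n)) {
      stop("integrity error: long-variant field_index out of range", call. = FALSE)
    }
    ord <- order(bd$longs$offset, bd$longs$ref, bd$longs$alt, method = "radix")
    if (!identical(ord, seq_len(nrow(bd$longs)))) {
      stop("integrity error: long records not sorted by (offset, ref, alt)", call. = FALSE)
    }
  }
  invisible(bd)
}

#' @noRd
bin_dir <- function(chrom, bin_index) {
  sprintf("echtvar/%s/%d", norm_chrom(chrom), bin_index)
}

# -- long.bin record stream: [u32 count LE] then per record
#    varint offset, varint len(ref), ref bytes, varint len(alt), alt bytes,
#    varint field_index

#' @noRd
serialize_longs <- function(longs) {
  parts <- vector("list", nrow(longs) + 1L)
  parts[[1]] <- u32_le(nrow(longs))
  for (i in seq_len(nrow(longs))) {
    r <- charToRaw(longs$ref[i])
    a <- charToRaw(longs$alt[i])
    parts[[i + 1L]] <- c(varint_encode(longs$offset[i]),
                         varint_encode(length(r)), r,
                         varint_encode(length(a)), a,
                         varint_encode(longs$field_index[i]))
  }
  do.call(c, parts)
}

#' @noRd
deserialize_longs <- function(bytes) {
  n <- rd_u32_le(bytes, 1L)
  offset <- double(n); ref <- character(n); alt <- character(n); field_index <- double(n)
  at <- 5L
  for (i in seq_len(n)) {
    v <- varint_decode(bytes, at); offset[i] <- v$value; at <- v$next_at
    v <- varint_decode(bytes, at); lr <- v$value; at <- v$next_at
    ref[i] <- rawToChar(bytes[at:(at + lr - 1L)]); at <- at + as.integer(lr)
    v <- varint_decode(bytes, at); la <- v$value; at <- v$next_at
    alt[i] <- rawToChar(bytes[at:(at + la - 1L)]); at <- at + as.integer(la)
    v <- varint_decode(bytes, at); field_index[i] <- v$value; at <- v$next_at
  }
  data.frame(offset = offset, ref = ref, alt = alt, field_index = field_index,
             stringsAsFactors = FALSE)
}

#' Serialize one bin into ZIP entries
#'
#' Returns the named raw entries for a bin; an empty bin contributes nothing,
#' and `long.bin` is omitted when the bin has no long variants.
#'
#' @param chrom Chromosome name (normalized internally).
#' @param bin_index 0-based bin index.
#' @param bd A [bin_data()] object.
#' @return Named list of raw vectors (possibly empty).
#' @export
write_bin <- function(chrom, bin_index, bd) {
  validate_bin_data(bd)
  if (length(bd$var32) == 0) return(list())
  dir <- bin_dir(chrom, bin_index)
  entries <- list()
  entries[[file.path(dir, "var32.bin")]] <-
    svb_serialize(svb_encode(delta_encode(bd$var32)))
  if (nrow(bd$longs) > 0) {
    entries[[file.path(dir, "long.bin")]] <- serialize_longs(bd$longs)
  }
  for (alias in names(bd$columns)) {
    entries[[file.path(dir, "fields", paste0(alias, ".bin"))]] <-
      svb_serialize(svb_encode(zigzag(bd$columns[[alias]])))
  }
  entries
}

#' Read one bin back from an open archive
#'
#' A (chromosome, bin) absent from the archive yields an empty [bin_data()]
#' (absence is a normal result, not an error).
#'
#' @param ar An archive handle from [open_archive()].
#' @param chrom Chromosome name.
#' @param bin_index 0-based bin index.
#' @return A [bin_data()] object.
#' @export
read_bin <- function(ar, chrom, bin_index) {
  dir <- bin_dir(chrom, bin_index)
  var32_path <- file.path(dir, "var32.bin")
  aliases <- vapply(ar$configs, `[[`, "", "alias")
  if (!(var32_path %in% ar$entries)) {
    return(bin_data(columns = stats::setNames(rep(list(double(0)), length(aliases)), aliases)))
  }
  long_path <- file.path(dir, "long.bin")
  col_paths <- if (length(aliases) > 0) {
    file.path(dir, "fields", paste0(aliases, ".bin"))
  } else {
    character(0)
  }
  missing_cols <- !(col_paths %in% ar$entries)
  if (any(missing_cols)) {
    stop(sprintf("corrupt archive: missing column entry %s", col_paths[missing_cols][1]),
         call. = FALSE)
  }
  want <- c(var32_path, if (long_path %in% ar$entries) long_path, col_paths)
  raws <- zip_read_many(ar$path, want)
  var32 <- prefix_sum(svb_decode(svb_deserialize(raws[[var32_path]])))
  longs <- if (long_path %in% ar$entries) {
    deserialize_longs(raws[[long_path]])
  } else {
    empty_longs()
  }
  columns <- lapply(stats::setNames(col_paths, aliases), function(p) {
    unzigzag(svb_decode(svb_deserialize(raws[[p]])))
  })
  bin_data(var32 = var32, longs = longs, columns = columns)
}

# -- string dictionaries: one file per field, line i holds the string with
#    integer code i (single global dictionary per field, stable across bins)

#' @noRd
strings_entry <- function(alias, strings) {
  if (any(grepl("\n", strings, fixed = TRUE))) {
    stop(sprintf("encoding error: string value for '%s' contains a newline", alias),
         call. = FALSE)
  }
  stats::setNames(list(charToRaw(paste(strings, collapse = "\n"))),
                  sprintf("echtvar/strings/%s.txt", alias))
}

#' Read the string dictionary for a field alias
#' @param ar Archive handle.
#' @param alias Field alias.
#' @return Character vector; code i is element i+1.
#' @export
read_strings <- function(ar, alias) {
  p <- sprintf("echtvar/strings/%s.txt", alias)
  if (!(p %in% ar$entries)) {
    stop(sprintf("corrupt archive: missing string dictionary %s", p), call. = FALSE)
  }
  strsplit(rawToChar(zip_read(ar$path, p)), "\n", fixed = TRUE)[[1]]
}

#' Open an archive for reading
#'
#' Loads the entry list and the stored configuration (`echtvar/config.json`);
#' archives are self-describing, so no external configuration is needed at
#' annotation time. The handle carries a single-slot bin cache and an
#' instrumentation counter of bin loads.
#'
#' @param path Path to the ZIP archive.
#' @return An environment of class `varchive_archive`.
#' @export
open_archive <- function(path) {
  if (!file.exists(path)) stop(sprintf("archive error: cannot read %s", path), call. = FALSE)
  entries <- zip_entries(path)
  if (!("echtvar/config.json" %in% entries)) {
    stop(sprintf("archive error: %s has no echtvar/config.json", path), call. = FALSE)
  }
  ar <- new.env(parent = emptyenv())
  ar$path <- path
  ar$entries <- entries
  ar$configs <- parse_config(rawToChar(zip_read(path, "echtvar/config.json")))
  ar$dicts <- list()
  for (cf in ar$configs) {
    if (identical(cf$ftype, "string")) ar$dicts[[cf$alias]] <- read_strings(ar, cf$alias)
  }
  ar$cache_key <- NULL
  ar$cache_bin <- NULL
  ar$n_bin_loads <- 0L
  class(ar) <- "varchive_archive"
  ar
}

#' @export
print.varchive_archive <- function(x, ...) {
  aliases <- vapply(x$configs, `[[`, "", "alias")
  cat(sprintf("<varchive archive> %s\n  fields: %s\n  entries: %d\n",
              x$path, paste(aliases, collapse = ", "), length(x$entries)))
  invisible(x)
}

#' Chromosome/bin pairs present in an archive
#' @param ar Archive handle.
#' @return Data frame with `chrom` and `bin` columns.
#' @export
archive_bins <- function(ar) {
  m <- regmatches(ar$entries, regexec("^echtvar/([^/]+)/([0-9]+)/var32\\.bin$", ar$entries))
  hits <- m[lengths(m) == 3]
  data.frame(chrom = vapply(hits, `[[`, "", 2),
             bin = as.double(vapply(hits, `[[`, "", 3)),
             stringsAsFactors = FALSE)
}

#' Validate all bins of an archive
#'
#' Re-reads every bin, re-checks the bin invariants (sortedness, column
#' lengths, long-record ordering and index bounds, placeholder/long-count
#' agreement) and returns per-bin statistics.
#'
#' @param path Archive path.
#' @return A tibble with one row per (chrom, bin): variant, placeholder and
#'   long-record counts.
#' @export
validate_archive <- function(path) {
  ar <- open_archive(path)
  bins <- archive_bins(ar)
  if (nrow(bins) == 0) {
    return(tibble::tibble(chrom = character(0), bin = double(0), n_variants = double(0),
                          n_placeholders = double(0), n_long = double(0)))
  }
  stats <- vector("list", nrow(bins))
  for (i in seq_len(nrow(bins))) {
    bd <- read_bin(ar, bins$chrom[i], bins$bin[i])
    n_ph <- sum(is_placeholder32(bd$var32))
    if (n_ph != nrow(bd$longs)) {
      stop(sprintf("integrity error: %s bin %d has %d placeholders but %d long records",
                   bins$chrom[i], bins$bin[i], n_ph, nrow(bd$longs)), call. = FALSE)
    }
    stats[[i]] <- tibble::tibble(chrom = bins$chrom[i], bin = bins$bin[i],
                                 n_variants = length(bd$var32),
                                 n_placeholders = n_ph, n_long = nrow(bd$longs))
  }
  do.call(rbind, stats)
}
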