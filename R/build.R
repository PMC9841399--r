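# Archive builder: stream a sorted, decomposed population VCF once, extract
# configured INFO fields, encode per 2^20-base bin, and emit the ZIP archive.

#' Quantize a float to a signed 32-bit integer
#'
#' `round-half-away-from-zero(value * multiplier)`; symmetric for negative
#' scores. [dequantize()] divides back, so the reconstruction error is at
#' most `0.5 / multiplier`.
#'
#' @param value Numeric vector.
#' @param multiplier Positive integer scale.
#' @param field Field name used in the overflow diagnostic.
#' @return Double vector of integers.
#' @export
quantize <- function(value, multiplier, field = "value") {
  q <- sign(value) * floor(abs(value) * multiplier + 0.5)
  if (any(abs(q) >= 2^31, na.rm = TRUE)) {
    stop(sprintf("field-overflow error: '%s' * %g exceeds 32 bits", field, multiplier),
         call. = FALSE)
  }
  q
}

#' @rdname quantize
#' @param q Stored integer values.
#' @export
dequantize <- function(q, multiplier) {
  q / multiplier
}

#' @noRd
infer_ftype <- function(vcf_type, field) {
  switch(vcf_type,
         Integer = "integer",
         Float = "float",
         String = ,
         Character = "string",
         Flag = stop(sprintf("config error: field '%s' is a Flag; flags have no integer representation", field), call. = FALSE),
         stop(sprintf("config error: field '%s' has unsupported header Type=%s", field, vcf_type), call. = FALSE))
}

#' @noRd
check_sorted_decomposed <- function(records) {
  if (any(grepl(",", records$alt, fixed = TRUE))) {
    i <- which(grepl(",", records$alt, fixed = TRUE))[1]
    stop(sprintf("decomposition-required error: multi-allelic record at %s:%d (%s)",
                 records$chrom[i], records$pos[i], records$alt[i]), call. = FALSE)
  }
  if (any(grepl("[<>]", records$alt))) {
    i <- which(grepl("[<>]", records$alt))[1]
    stop(sprintf("symbolic alleles are unsupported: %s at %s:%d",
                 records$alt[i], records$chrom[i], records$pos[i]), call. = FALSE)
  }
  chrom <- records$chrom
  runs <- rle(chrom)$values
  if (anyDuplicated(runs)) {
    stop(sprintf("sort error: chromosome %s appears in more than one block",
                 runs[duplicated(runs)][1]), call. = FALSE)
  }
  for (cn in runs) {
    p <- records$pos[chrom == cn]
    if (is.unsorted(p)) {
      i <- which(diff(p) < 0)[1]
      stop(sprintf("sort error: position decreases on %s at POS %d -> %d",
                   cn, p[i], p[i + 1]), call. = FALSE)
    }
  }
  invisible(records)
}

# Extract one configured field as the stored integer column (quantized
# floats, dictionary codes for strings) over all records. For string fields
# the growing global dictionary (first-seen order) is returned alongside.
#' @noRd
extract_column <- function(records, cf) {
  raw_vals <- info_extract(records$info, cf$field)
  if (cf$ftype == "string") {
    vals <- ifelse(is.na(raw_vals), cf$missing_string, raw_vals)
    dict <- unique(vals)  # first-seen order defines the codes
    list(stored = as.double(match(vals, dict) - 1L), dict = dict)
  } else {
    num <- suppressWarnings(as.numeric(raw_vals))
    bad <- !is.na(raw_vals) & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("config error: field '%s' value '%s' at %s:%d is not numeric",
                   cf$field, raw_vals[i], records$chrom[i], records$pos[i]), call. = FALSE)
    }
    stored <- if (cf$ftype == "float") {
      quantize(num, cf$multiplier, cf$field)
    } else {
      if (any(abs(num) >= 2^31, na.rm = TRUE)) {
        stop(sprintf("field-overflow error: '%s' exceeds 32 bits", cf$field), call. = FALSE)
      }
      round(num)
    }
    stored[is.na(num)] <- cf$missing_value
    list(stored = stored, dict = NULL)
  }
}

#' Build an annotation archive from a population VCF
#'
#' The input must be coordinate-sorted and decomposed (one ALT per record).
#' For each (chromosome, 2^20-base bin): short variants are encoded into
#' 32-bit codes and each long variant contributes one placeholder code plus
#' one long record carrying its column index; codes are stably sorted with
#' columns permuted identically; codes are delta + Stream VByte encoded and
#' columns zigzag + Stream VByte encoded. The user configuration (with
#' inferred field types) and the string dictionaries are stored inside the
#' archive, making it self-describing.
#'
#' @param vcf_path Source `.vcf`, `.vcf.gz` or `.bcf`.
#' @param config Field configuration: a JSON file path, JSON text, or a list
#'   of [field_config()] objects.
#' @param out_zip Output archive path.
#' @return A tibble build summary: variants, long variants, bins written.
#' @export
build_archive <- function(vcf_path, config, out_zip) {
  configs <- if (is.character(config)) parse_config(config) else config
  v <- read_vcf(vcf_path)
  records <- v$records
  records$chrom <- norm_chrom(records$chrom)
  records$ref <- toupper(records$ref)
  records$alt <- toupper(records$alt)
  check_sorted_decomposed(records)

  for (i in seq_along(configs)) {
    cf <- configs[[i]]
    if (!(cf$field %in% names(v$info_types))) {
      stop(sprintf("config error: field '%s' is not declared in the VCF header", cf$field),
           call. = FALSE)
    }
    if (is.na(cf$ftype)) configs[[i]]$ftype <- infer_ftype(v$info_types[[cf$field]], cf$field)
  }

  n <- nrow(records)
  cols <- lapply(configs, function(cf) extract_column(records, cf))
  names(cols) <- vapply(configs, `[[`, "", "alias")

  entries <- list()
  entries[["echtvar/config.json"]] <- charToRaw(as.character(config_to_json(configs)))
  for (i in seq_along(configs)) {
    if (configs[[i]]$ftype == "string") {
      entries <- c(entries, strings_entry(configs[[i]]$alias, cols[[i]]$dict))
    }
  }

  n_long_total <- 0
  n_bins <- 0
  if (n > 0) {
    bo <- bin_of(records$pos)
    short <- is_short(records$ref, records$alt)
    codes <- double(n)
    codes[short] <- encode32(bo$offset[short], records$ref[short], records$alt[short])
    codes[!short] <- placeholder32(bo$offset[!short])
    key <- paste(records$chrom, bo$bin, sep = "\r")
    groups <- split(seq_len(n), key)
    # deterministic bin order: chromosome in input order, bin ascending
    first <- vapply(groups, `[[`, 0L, 1L)
    ord_groups <- order(match(records$chrom[first], unique(records$chrom)), bo$bin[first])
    for (g in ord_groups) {
      idx <- groups[[g]]
      chrom <- records$chrom[idx[1]]
      bin_index <- bo$bin[idx[1]]
      ord <- order(codes[idx], method = "radix")  # stable: ties keep input order
      sorted_idx <- idx[ord]
      var32 <- codes[sorted_idx]
      columns <- lapply(cols, function(cc) cc$stored[sorted_idx])
      long_pos <- which(!short[sorted_idx])
      longs <- if (length(long_pos) > 0) {
        lf <- data.frame(offset = bo$offset[sorted_idx[long_pos]],
                         ref = records$ref[sorted_idx[long_pos]],
                         alt = records$alt[sorted_idx[long_pos]],
                         field_index = long_pos - 1,
                         stringsAsFactors = FALSE)
        lf[order(lf$offset, lf$ref, lf$alt, method = "radix"), , drop = FALSE]
      } else {
        empty_longs()
      }
      bd <- bin_data(var32 = var32, longs = longs, columns = columns)
      entries <- c(entries, write_bin(chrom, bin_index, bd))
      n_long_total <- n_long_total + nrow(longs)
      n_bins <- n_bins + 1
    }
  }
  zip_write(out_zip, entries)
  tibble::tibble(variants = n, long_variants = n_long_total, bins_written = n_bins,
                 fields = length(configs), archive = out_zip)
}
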