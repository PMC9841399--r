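# Annotation: per-bin cached lookup of query variants against one or more
# archives, default values for absent variants, optional include filter,
# and VCF output.

#' Load a (chromosome, bin) into an archive's single-slot cache
#'
#' Returns the cached [bin_data()] when the handle already holds exactly this
#' (chromosome, bin); otherwise reads the bin (possibly empty), replaces the
#' slot and increments the handle's `n_bin_loads` counter.
#'
#' @param ar Archive handle from [open_archive()].
#' @param chrom Chromosome name (normalized internally).
#' @param bin_index 0-based bin index.
#' @return A [bin_data()] object.
#' @export
load_bin_if_needed <- function(ar, chrom, bin_index) {
  key <- paste(norm_chrom(chrom), bin_index, sep = "\r")
  if (identical(ar$cache_key, key)) return(ar$cache_bin)
  bd <- read_bin(ar, chrom, bin_index)
  ar$cache_key <- key
  ar$cache_bin <- bd
  ar$n_bin_loads <- ar$n_bin_loads + 1L
  bd
}

#' Look up variants in a loaded bin
#'
#' Short variants are re-encoded to 32-bit codes and binary-searched in the
#' primary table (leftmost match on duplicates); long variants are matched in
#' the supplemental table by (offset, ref, alt) and resolved through the
#' record's column index. Floats are dequantized by the stored multiplier,
#' string codes decoded through the dictionary. Absence is a normal result:
#' every value of a not-found variant is its field's configured missing
#' value.
#'
#' @param bd A [bin_data()] for the variants' bin.
#' @param offset,ref,alt Vectors describing the query variants (in-bin
#'   0-based offsets, uppercase alleles). Non-lookupable entries (symbolic
#'   or non-ACGT-and-not-in-table alleles) simply come back not-found.
#' @param configs List of `field_config` (the archive's stored configs).
#' @param dicts Named list of string dictionaries.
#' @return List with `found` (logical) and `values` (named list of vectors,
#'   one per alias).
#' @export
lookup_variants <- function(bd, offset, ref, alt, configs, dicts = list()) {
  n <- length(offset)
  index <- rep(NA_real_, n)
  clean <- nzchar(ref) & nzchar(alt)
  shortable <- clean & is_short_safe(ref, alt)
  if (any(shortable) && length(bd$var32) > 0) {
    codes <- encode32(offset[shortable], ref[shortable], alt[shortable])
    ii <- findInterval(codes - 0.5, bd$var32) + 1  # leftmost candidate
    hit <- ii <= length(bd$var32) & bd$var32[ii] == codes
    index[shortable] <- ifelse(hit, ii, NA_real_)
  }
  longq <- clean & !shortable
  if (any(longq) && nrow(bd$longs) > 0) {
    qk <- paste(offset[longq], ref[longq], alt[longq], sep = "\r")
    bk <- paste(bd$longs$offset, bd$longs$ref, bd$longs$alt, sep = "\r")
    mi <- match(qk, bk)  # first (leftmost) match
    index[longq] <- bd$longs$field_index[mi] + 1
  }
  found <- !is.na(index)
  values <- lapply(configs, function(cf) {
    stored <- rep(NA_real_, n)
    stored[found] <- bd$columns[[cf$alias]][index[found]]
    if (cf$ftype == "string") {
      out <- rep(cf$missing_string, n)
      out[found] <- dicts[[cf$alias]][stored[found] + 1]
      out
    } else if (cf$ftype == "float") {
      out <- rep(cf$missing_value, n)
      real <- found & stored != cf$missing_value
      out[real] <- dequantize(stored[real], cf$multiplier)
      out
    } else {
      out <- rep(cf$missing_value, n)
      out[found] <- stored[found]
      out
    }
  })
  names(values) <- vapply(configs, `[[`, "", "alias")
  list(found = found, values = values)
}

# is_short() that tolerates arbitrary allele strings (no error on empties;
# the caller has already excluded them)
#' @noRd
is_short_safe <- function(ref, alt) {
  (nchar(ref) + nchar(alt) <= MAX_SHORT_TOTAL_LEN) &
    grepl("^[ACGT]+$", ref) & grepl("^[ACGT]+$", alt)
}

# integer-valued numbers render without exponent notation (VCF Integer
# fields must be integer literals); fractional values keep R's compact
# up-to-15-significant-digit rendering
#' @noRd
render_value <- function(v) {
  if (is.character(v)) return(v)
  vapply(v, function(x) {
    if (x == round(x) && abs(x) < 2^53) sprintf("%.0f", x) else as.character(x)
  }, "")
}

#' Annotate a query VCF from one or more archives
#'
#' Every field stored in each archive is added to the query records
#' (archives applied in order; a duplicated alias is overwritten by the
#' later archive, with a warning). Records absent from an archive get the
#' configured missing values. With an include filter, a record is written
#' iff the expression evaluates true on its merged annotation values.
#' Query records with symbolic or multi-allelic ALT pass through
#' unannotated (defaults applied, still subject to the filter).
#'
#' @param query_path Query `.vcf`, `.vcf.gz` or `.bcf`.
#' @param archives Character vector of archive paths (ordered), or a list of
#'   handles from [open_archive()].
#' @param filter Optional include-expression text (see [parse_filter()]).
#' @param out_path Output path (`.vcf`, `.vcf.gz`, `.bcf`); `NULL` or
#'   `/dev/null` discards records while still running the whole pipeline.
#' @return A tibble summary: variants read and written, bin loads per
#'   archive. The annotated records (with a `pass` column when a filter is
#'   given) are attached as attribute `"records"` for programmatic use.
#' @export
annotate_vcf <- function(query_path, archives, filter = NULL, out_path = NULL) {
  ars <- lapply(archives, function(a) if (inherits(a, "varchive_archive")) a else open_archive(a))

  # merged alias table; later archives win on duplicates
  alias_types <- character(0)
  alias_cfg <- list()
  alias_src <- character(0)
  for (ar in ars) {
    for (cf in ar$configs) {
      if (cf$alias %in% names(alias_cfg)) {
        warning(sprintf("alias '%s' provided by more than one archive; later archive wins",
                        cf$alias), call. = FALSE)
      }
      alias_cfg[[cf$alias]] <- cf
      alias_types[cf$alias] <- if (cf$ftype == "string") "str" else "num"
      alias_src[cf$alias] <- basename(if (is.character(ar$path)) ar$path else "archive")
    }
  }

  flt <- if (!is.null(filter)) parse_filter(filter, types = alias_types) else NULL

  v <- read_vcf(query_path)
  records <- v$records
  n <- nrow(records)
  chromn <- norm_chrom(records$chrom)
  bo <- bin_of(pmax(records$pos, 1))
  refu <- toupper(records$ref)
  altu <- toupper(ifelse(is.na(records$alt), ".", records$alt))
  # symbolic / multi-allelic / missing ALT: pass through unannotated
  lookupable <- !grepl("[<>,*.]", altu) & nzchar(refu) & nzchar(altu)
  refq <- ifelse(lookupable, refu, "")  # empty allele: never found, defaults apply
  altq <- ifelse(lookupable, altu, "")

  ann <- list()  # alias -> value vector over all records
  if (n > 0) {
    run_id <- cumsum(c(TRUE, paste(chromn, bo$bin, sep = "\r")[-1] !=
                               paste(chromn, bo$bin, sep = "\r")[-n]))
    for (ar in ars) {
      dicts <- ar$dicts
      res_vals <- lapply(ar$configs, function(cf) {
        if (cf$ftype == "string") character(n) else double(n)
      })
      names(res_vals) <- vapply(ar$configs, `[[`, "", "alias")
      for (run in split(seq_len(n), run_id)) {
        bd <- load_bin_if_needed(ar, chromn[run[1]], bo$bin[run[1]])
        lk <- lookup_variants(bd, bo$offset[run], refq[run], altq[run],
                              ar$configs, dicts)
        for (alias in names(res_vals)) res_vals[[alias]][run] <- lk$values[[alias]]
      }
      for (alias in names(res_vals)) ann[[alias]] <- res_vals[[alias]]
    }
  } else {
    for (alias in names(alias_cfg)) {
      cf <- alias_cfg[[alias]]
      ann[[alias]] <- if (cf$ftype == "string") character(0) else double(0)
    }
  }

  pass <- rep(TRUE, n)
  if (!is.null(flt) && n > 0) {
    warn_env <- new.env(parent = emptyenv())
    used <- flt$idents
    for (i in seq_len(n)) {
      env <- lapply(ann[used], `[[`, i)
      pass[i] <- filter_passes(flt, env, warn_once = warn_env)
    }
  }

  # assemble output
  aliases <- names(alias_cfg)
  if (n > 0 && length(aliases) > 0) {
    frag <- do.call(paste, c(lapply(aliases, function(a) {
      paste0(a, "=", render_value(ann[[a]]))
    }), sep = ";"))
    records$info <- info_append(records$info, frag)
  }
  new_info_lines <- vapply(aliases, function(a) {
    cf <- alias_cfg[[a]]
    type <- switch(cf$ftype, integer = "Integer", float = "Float", string = "String")
    sprintf('##INFO=<ID=%s,Number=1,Type=%s,Description="added by echtvar from %s">',
            a, type, alias_src[[a]])
  }, "")
  meta <- v$meta[!grepl("^#CHROM", v$meta)]
  meta <- c(meta, unname(new_info_lines))
  kept <- records[pass, , drop = FALSE]
  gt_kept <- if (!is.null(v$gt)) v$gt[pass, , drop = FALSE] else NULL
  write_vcf(out_path, meta, kept, gt_kept)

  out <- tibble::tibble(
    variants_read = n,
    variants_written = nrow(kept),
    archives = length(ars),
    bin_loads = sum(vapply(ars, function(a) as.double(a$n_bin_loads), 0)),
    filter = if (is.null(filter)) NA_character_ else filter
  )
  ann_df <- tibble::as_tibble(c(list(chrom = records$chrom, pos = records$pos,
                                     ref = records$ref, alt = records$alt), ann))
  ann_df$pass <- pass
  attr(out, "records") <- ann_df
  out
}
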