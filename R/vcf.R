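# VCF reading/writing. Parsing goes through vcfR; BCF and bgzip conversion
# through the bcftools binary. INFO keys are extracted with anchored regexes
# so a key that is a prefix of another (AF vs AF_popmax) cannot cross-match.

#' @noRd
is_bcf <- function(path) grepl("\\.bcf$", path, ignore.case = TRUE)

#' Read a VCF/BCF into header lines and a records data frame
#'
#' @param path `.vcf`, `.vcf.gz` or `.bcf` file.
#' @return List with `meta` (header lines), `records` (tibble with chrom,
#'   pos, id, ref, alt, qual, filter, info), `gt` (FORMAT/sample matrix or
#'   NULL) and `info_types` (named vector of header INFO Type= values).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read VCF: %s", path), call. = FALSE)
  src <- path
  if (is_bcf(path)) {
    src <- tempfile(fileext = ".vcf.gz")
    on.exit(unlink(src))
    status <- system2("bcftools", c("view", "-O", "z", "-o", src, path))
    if (status != 0) stop(sprintf("bcftools failed to read %s", path), call. = FALSE)
  }
  v <- suppressWarnings(vcfR::read.vcfR(src, verbose = FALSE))
  fix <- v@fix
  records <- tibble::tibble(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.double(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    qual = ifelse(is.na(fix[, "QUAL"]), ".", fix[, "QUAL"]),
    filter = ifelse(is.na(fix[, "FILTER"]), ".", fix[, "FILTER"]),
    info = ifelse(is.na(fix[, "INFO"]), ".", fix[, "INFO"])
  )
  gt <- if (ncol(v@gt %||% matrix(nrow = 0, ncol = 0)) > 0) v@gt else NULL
  list(meta = v@meta, records = records, gt = gt,
       info_types = parse_info_types(v@meta))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
parse_info_types <- function(meta) {
  info_lines <- grep("^##INFO=", meta, value = TRUE)
  ids <- sub(".*<ID=([^,>]+).*", "\\1", info_lines)
  types <- sub(".*Type=([^,>]+).*", "\\1", info_lines)
  stats::setNames(types, ids)
}

#' Extract one INFO key's raw values from INFO strings
#'
#' @param info Character vector of INFO columns.
#' @param key INFO key.
#' @return Character vector; `NA` where the key is absent.
#' @export
info_extract <- function(info, key) {
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", key)
  pattern <- paste0("(?:^|;)", esc, "=[^;]*")
  hit <- regexpr(pattern, info, perl = TRUE)
  out <- rep(NA_character_, length(info))
  has <- hit > 0
  out[has] <- sub("^[^=]*=", "", regmatches(info, hit))
  out
}

#' @noRd
info_append <- function(info, added) {
  # added: character vector of "k=v;k=v" fragments, "" allowed
  base <- ifelse(info == "." | info == "", "", paste0(info, ";"))
  out <- paste0(base, added)
  ifelse(out == "", ".", out)
}

#' Write a VCF from header lines and records
#'
#' Output format follows the extension: `.vcf` plain text, `.vcf.gz`
#' gzip-compressed, `.bcf` via bcftools. A null-device path (`/dev/null` or
#' `NULL`) discards the records.
#'
#' @param path Output path.
#' @param meta Header lines (including the final `#CHROM ...` line or not;
#'   one is built from the records if absent).
#' @param records Data frame as produced by [read_vcf()].
#' @param gt Optional FORMAT/sample matrix to carry through.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(path, meta, records, gt = NULL) {
  if (is.null(path) || path %in% c("/dev/null", nullfile())) return(invisible(path))
  header <- meta[!grepl("^#CHROM", meta)]
  chrom_line <- "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  if (!is.null(gt)) {
    samples <- colnames(gt)[-1]
    chrom_line <- paste(c(chrom_line, "FORMAT", samples), collapse = "\t")
  }
  body <- paste(records$chrom, format(records$pos, scientific = FALSE, trim = TRUE),
                records$id, records$ref, records$alt, records$qual, records$filter,
                records$info, sep = "\t")
  if (!is.null(gt) && nrow(records) > 0) {
    body <- paste(body, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  }
  lines <- c(header, chrom_line, body)
  if (is_bcf(path)) {
    tmp <- tempfile(fileext = ".vcf")
    on.exit(unlink(tmp))
    writeLines(lines, tmp)
    status <- system2("bcftools", c("view", "-O", "b", "-o", path, tmp))
    if (status != 0) stop(sprintf("bcftools failed to write %s", path), call. = FALSE)
  } else {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    writeLines(lines, con)
    close(con)
  }
  invisible(path)
}
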