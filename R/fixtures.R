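# Synthetic sorted, decomposed VCFs with configurable variant mixes and INFO
# fields, plus a naive hash-map oracle annotator. The generator stands in
# for gnomAD/CADD/dbNSFP-style population inputs: site-level records only,
# no genotypes, no linkage structure.

#' Specification for a synthetic population VCF
#'
#' Defaults emulate the study conditions used throughout the test-suite:
#' two chromosomes (one with a "chr" prefix, to exercise name
#' normalization), positions straddling at least two 2^20-base bins, 30%
#' long alleles (combined REF+ALT length 5-12, with the 4/5 boundary well
#' represented on the short side), a small rate of N-containing alleles,
#' and three INFO fields: `AF` (skewed small floats, Beta(0.2, 5)-shaped,
#' like population allele frequencies), `AC` (geometric counts) and `CSQ`
#' (categorical over a few consequence strings).
#'
#' @param seed RNG seed; identical seeds give byte-identical VCFs.
#' @param n_variants Number of records.
#' @param chrom_names Chromosome names, in output order.
#' @param pos_span Range positions are drawn from (spans >1 bin by default).
#' @param fraction_long Probability a variant's combined allele length
#'   exceeds 4 bases.
#' @param fraction_nonacgt Probability an allele carries an `N`.
#' @param fields List of field descriptors `list(name, type, gen)` where
#'   `gen(n)` draws `n` values; `type` is `"integer"`, `"float"` or
#'   `"string"`.
#' @param missing_rate Per-field probability that a record lacks the field.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(seed = 1L,
                       n_variants = 1000L,
                       chrom_names = c("1", "chr2"),
                       pos_span = c(1, 2.5e6),
                       fraction_long = 0.3,
                       fraction_nonacgt = 0.02,
                       fields = default_synth_fields(),
                       missing_rate = 0.1) {
  structure(list(seed = seed, n_variants = n_variants, chrom_names = chrom_names,
                 pos_span = pos_span, fraction_long = fraction_long,
                 fraction_nonacgt = fraction_nonacgt, fields = fields,
                 missing_rate = missing_rate),
            class = "synth_spec")
}

#' @rdname synth_spec
#' @export
default_synth_fields <- function() {
  list(
    list(name = "AF", type = "float",
         gen = function(n) round(stats::rbeta(n, 0.2, 5), 6)),
    list(name = "AC", type = "integer",
         gen = function(n) stats::rgeom(n, 0.1) + 1),
    list(name = "CSQ", type = "string",
         gen = function(n) sample(c("missense", "synonymous", "stop_gained",
                                    "intron", "splice_donor"), n, replace = TRUE,
                                  prob = c(0.3, 0.3, 0.05, 0.3, 0.05)))
  )
}

#' @noRd
random_alleles <- function(n, fraction_long, fraction_nonacgt) {
  long <- stats::runif(n) < fraction_long
  # short: total length 2..4 with the 4 boundary well represented;
  # long: total length 5..12 with 5 (first long) well represented
  total <- integer(n)
  total[!long] <- sample(2:4, sum(!long), replace = TRUE, prob = c(0.5, 0.15, 0.35))
  total[long] <- sample(5:12, sum(long), replace = TRUE,
                        prob = c(0.35, 0.2, 0.12, 0.1, 0.08, 0.06, 0.05, 0.04))
  lr <- vapply(total, function(t) sample(seq_len(t - 1L), 1L), 0L)
  la <- total - lr
  draw <- function(len) paste(sample(NUCS, len, replace = TRUE), collapse = "")
  ref <- vapply(lr, draw, "")
  alt <- vapply(la, draw, "")
  # SNPs need REF != ALT
  same <- ref == alt
  while (any(same)) {
    alt[same] <- vapply(la[same], draw, "")
    same <- ref == alt
  }
  hasn <- stats::runif(n) < fraction_nonacgt
  if (any(hasn)) {
    alt[hasn] <- vapply(alt[hasn], function(a) {
      i <- sample(nchar(a), 1L)
      paste0(substr(a, 1, i - 1L), "N", substr(a, i + 1L, nchar(a)))
    }, "")
  }
  list(ref = ref, alt = alt, long = long)
}

#' Generate a synthetic sorted VCF and its truth table
#'
#' Writes a VCF 4.2 file (plain or gzipped by extension) with proper contig
#' and INFO header lines, sorted by (chromosome, position) with unique
#' (chrom, pos) sites, and returns the exact truth table.
#'
#' @param spec A [synth_spec()].
#' @param out_path Output `.vcf` or `.vcf.gz` path; `NULL` skips writing.
#' @return A tibble with chrom, pos, ref, alt and one column per field
#'   (`NA` = the record lacks the field).
#' @export
generate_vcf <- function(spec, out_path = NULL) {
  set.seed(spec$seed)
  n <- spec$n_variants
  k <- length(spec$chrom_names)
  chrom_of <- sort(sample(seq_len(k), n, replace = TRUE))
  pos <- integer(n)
  span_n <- as.integer(spec$pos_span[2] - spec$pos_span[1] + 1)
  for (ci in seq_len(k)) {
    m <- sum(chrom_of == ci)
    pos[chrom_of == ci] <- sort(sample.int(span_n, m) + as.integer(spec$pos_span[1]) - 1L)
  }
  al <- random_alleles(n, spec$fraction_long, spec$fraction_nonacgt)
  truth <- tibble::tibble(chrom = spec$chrom_names[chrom_of], pos = pos,
                          ref = al$ref, alt = al$alt)
  for (f in spec$fields) {
    vals <- f$gen(n)
    vals[stats::runif(n) < spec$missing_rate] <- NA
    truth[[f$name]] <- vals
  }
  if (!is.null(out_path)) {
    header <- c("##fileformat=VCFv4.2",
                sprintf("##contig=<ID=%s,length=%d>", spec$chrom_names,
                        as.integer(spec$pos_span[2] + 1e6)),
                vapply(spec$fields, function(f) {
                  type <- switch(f$type, integer = "Integer", float = "Float",
                                 string = "String")
                  sprintf('##INFO=<ID=%s,Number=1,Type=%s,Description="synthetic">',
                          f$name, type)
                }, ""),
                "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    info <- rep("", n)
    for (f in spec$fields) {
      v <- truth[[f$name]]
      frag <- ifelse(is.na(v), "", paste0(f$name, "=", as.character(v)))
      info <- ifelse(frag == "", info,
                     ifelse(info == "", frag, paste(info, frag, sep = ";")))
    }
    info[info == ""] <- "."
    body <- paste(truth$chrom, truth$pos, ".", truth$ref, truth$alt, ".", "PASS",
                  info, sep = "\t")
    con <- if (grepl("\\.gz$", out_path)) gzfile(out_path, "w") else file(out_path, "w")
    writeLines(c(header, body), con)
    close(con)
  }
  truth
}

#' Naive hash-map oracle annotator
#'
#' Independent reference for the full pipeline: exact dictionary lookup on
#' (normalized chrom, pos, ref, alt) against the generator's truth table,
#' the same quantize/dequantize arithmetic as the builder (so float
#' comparisons are exact), and base R `eval()` as the reference expression
#' evaluator.
#'
#' @param truth Truth table from [generate_vcf()].
#' @param query Data frame with chrom, pos, ref, alt.
#' @param configs List of [field_config()] with `ftype` set.
#' @param filter Optional include-expression text.
#' @return Tibble: query columns, one value column per alias, `found`, and
#'   `pass`.
#' @export
oracle_annotate <- function(truth, query, configs, filter = NULL) {
  tkey <- paste(norm_chrom(truth$chrom), truth$pos, toupper(truth$ref),
                toupper(truth$alt), sep = "\r")
  qkey <- paste(norm_chrom(query$chrom), query$pos, toupper(query$ref),
                toupper(query$alt), sep = "\r")
  mi <- match(qkey, tkey)
  out <- tibble::tibble(chrom = query$chrom, pos = query$pos,
                        ref = query$ref, alt = query$alt)
  found <- !is.na(mi)
  for (cf in configs) {
    src <- truth[[cf$field]][mi]
    if (cf$ftype == "string") {
      v <- ifelse(found & !is.na(src), as.character(src), cf$missing_string)
    } else if (cf$ftype == "float") {
      v <- rep(cf$missing_value, nrow(query))
      ok <- found & !is.na(src)
      v[ok] <- dequantize(quantize(src[ok], cf$multiplier), cf$multiplier)
    } else {
      v <- ifelse(found & !is.na(src), round(src), cf$missing_value)
    }
    out[[cf$alias]] <- v
  }
  out$found <- found
  pass <- rep(TRUE, nrow(query))
  if (!is.null(filter)) {
    aliases <- vapply(configs, `[[`, "", "alias")
    expr <- parse(text = filter)[[1]]
    cols <- lapply(stats::setNames(aliases, aliases), function(a) out[[a]])
    for (i in seq_len(nrow(query))) {
      env <- lapply(cols, `[[`, i)
      res <- tryCatch(eval(expr, envir = env), error = function(e) FALSE)
      pass[i] <- isTRUE(res)
    }
  }
  out$pass <- pass
  out
}
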