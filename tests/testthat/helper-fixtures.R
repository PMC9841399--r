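# Shared fixture builders. Everything is generated in code at test time.

# all REF/ALT pairs over {A,C,G,T} with combined length <= 4 (912 pairs)
all_short_pairs <- function() {
  seqs <- function(len) {
    apply(do.call(expand.grid, rep(list(c("A", "C", "G", "T")), len)), 1, paste,
          collapse = "")
  }
  by_len <- lapply(1:3, seqs)
  out <- list()
  for (lr in 1:3) for (la in 1:(4 - lr)) {
    g <- expand.grid(ref = by_len[[lr]], alt = by_len[[la]],
                     stringsAsFactors = FALSE)
    out[[length(out) + 1]] <- g
  }
  do.call(rbind, out)
}

# standard three-field test configuration (float with the 10^6 multiplier,
# an integer count, a categorical string)
test_configs_json <- function() {
  '[{"field":"AF","alias":"g_af","multiplier":1000000},
    {"field":"AC","alias":"g_ac"},
    {"field":"CSQ","alias":"g_csq"}]'
}

test_configs <- function() {
  cfgs <- parse_config(test_configs_json())
  cfgs[[1]]$ftype <- "float"
  cfgs[[2]]$ftype <- "integer"
  cfgs[[3]]$ftype <- "string"
  cfgs
}

# generate a population VCF + archive; cached per (seed, n) for the session
.fixture_cache <- new.env(parent = emptyenv())

make_pipeline_fixture <- function(seed = 7, n = 2000) {
  key <- sprintf("pop_%d_%d", seed, n)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  vcf <- file.path(tempdir(), paste0(key, ".vcf"))
  zip <- file.path(tempdir(), paste0(key, ".zip"))
  truth <- generate_vcf(synth_spec(seed = seed, n_variants = n), vcf)
  build_archive(vcf, test_configs_json(), zip)
  .fixture_cache[[key]] <- list(vcf = vcf, zip = zip, truth = truth)
  .fixture_cache[[key]]
}

# random bin_data with optional long records and configurable columns
random_bin_data <- function(n_short = 50, n_long = 10, aliases = c("x", "y")) {
  offsets <- sort(sample(0:(2^20 - 1), n_short + n_long))
  short_off <- offsets[seq_len(n_short)]
  long_off <- offsets[n_short + seq_len(n_long)]
  codes <- c(
    if (n_short > 0) encode32(short_off, sample(c("A", "C", "G", "T"), n_short, TRUE),
                              sample(c("A", "CC", "G", "TTT"), n_short, TRUE)),
    if (n_long > 0) placeholder32(long_off)
  )
  ord <- order(codes)
  var32 <- codes[ord]
  columns <- lapply(stats::setNames(aliases, aliases),
                    function(a) sample(c(-1, 0, 5, 1000, 123457, -2^31, 2^31 - 1),
                                       n_short + n_long, TRUE))
  longs <- if (n_long > 0) {
    idx_in_sorted <- match(n_short + seq_len(n_long), ord)
    lf <- data.frame(offset = long_off,
                     ref = replicate(n_long, paste(sample(c("A", "C", "G", "T"), 4,
                                                          TRUE), collapse = "")),
                     alt = replicate(n_long, paste(sample(c("A", "C", "G", "T", "N"), 3,
                                                          TRUE), collapse = "")),
                     field_index = idx_in_sorted - 1,
                     stringsAsFactors = FALSE)
    lf[order(lf$offset, lf$ref, lf$alt, method = "radix"), , drop = FALSE]
  } else {
    data.frame(offset = double(0), ref = character(0), alt = character(0),
               field_index = double(0))
  }
  bin_data(var32 = var32, longs = longs, columns = columns)
}

# write a single-bin archive around given bin entries so open_archive works
write_test_archive <- function(path, bins, configs = NULL) {
  # bins: list of list(chrom=, bin=, bd=)
  if (is.null(configs)) {
    aliases <- names(bins[[1]]$bd$columns)
    configs <- lapply(aliases, function(a) {
      cf <- field_config(a)
      cf$ftype <- "integer"
      cf
    })
  }
  entries <- list()
  entries[["echtvar/config.json"]] <- charToRaw(as.character(
    varchive:::config_to_json(configs)))
  for (b in bins) {
    entries <- c(entries, write_bin(b$chrom, b$bin, b$bd))
  }
  zip_write(path, entries)
  path
}

# minimal hand-written query VCF from a records data frame
write_query_vcf <- function(path, chrom, pos, ref, alt, info = ".") {
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", unique(chrom)),
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- paste(chrom, format(pos, scientific = FALSE, trim = TRUE), ".", ref, alt,
                ".", "PASS", info, sep = "\t")
  writeLines(c(header, body), path)
  path
}
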