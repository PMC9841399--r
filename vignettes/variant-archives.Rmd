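---
title: "Compressed variant annotation archives: encoding, format and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressed variant annotation archives: encoding, format and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varchive)
```

## The problem

Interpreting germline or somatic variants requires decorating each record of
a call-set with information from much larger population resources: allele
frequencies, homozygote counts, deleteriousness scores, pre-computed
consequences. Those resources are orders of magnitude larger than any single
sample's VCF, so the annotation step — *find this exact (chrom, pos, REF,
ALT) in a database of hundreds of millions of sites and copy some numbers
across* — dominates pipeline cost unless the database is stored in a form
built for exactly that lookup.

varchive builds such a form: a write-once ZIP archive holding the population
sites as compressed 32-bit integer codes, with each requested INFO field
stored as a parallel compressed integer column. A query VCF is then
annotated by streaming it once, binary-searching each variant's code inside
its genome bin, and copying the indexed column values into the output; an
optional boolean expression over the annotated values decides which records
are written at all.

## The 32-bit variant code

Each chromosome is partitioned into bins of 2^20 = 1,048,576 bases. Within
a bin, a 0-based offset needs only 20 bits, which leaves 12 bits of a 32-bit
unsigned integer for the alleles. A variant whose combined REF+ALT length is
at most 4 (a SNP, a 1-3 base MNP/indel pair) over the strict {A, C, G, T}
alphabet fits:

| bits  | content |
|-------|---------|
| 31-12 | offset of the variant within its bin |
| 11-10 | REF length (1-3; 0 reserved) |
| 9-8   | ALT length (1-3; 0 reserved) |
| 7-0   | REF then ALT nucleotides, 2 bits each (A=0, C=1, G=2, T=3), first nucleotide most significant, unused pairs zero |

The sub-layout of the low 12 bits had to be fixed somewhere; this package
fixes it as above because it has two properties the rest of the design leans
on: unsigned integer ordering of codes is consistent with ordering by
position, and a *placeholder* (all 12 allele bits zero) sorts at-or-before
every real variant at the same offset.

Variants that do not fit — combined length 5 or more, or any allele
character outside ACGT (an `N`, an IUPAC code, a `*` spanning-deletion
allele) — go to a supplemental per-bin long-variant table holding the
literal allele strings, sorted by (offset, ref, alt) with byte-wise string
order. Each long variant also inserts one placeholder code into the primary
table so that the field columns keep exactly one slot per input record; the
long record carries the index of that slot. One placeholder is inserted per
long variant (not per offset), so duplicate identical variants remain
representable and lossless.

Symbolic alleles (`<DEL>` etc.) are outside the model entirely: the builder
rejects them, and the annotator passes such query records through with
default values rather than failing.

Coordinates are handled 0-based internally (`bin = (POS-1) >> 20`,
`offset = (POS-1) & 0xFFFFF`), so bin 0 covers POS 1..2^20 exactly.

## Column compression

Within a bin the codes are sorted (stably, so equal codes keep input order)
and **delta-encoded**: each value is stored as its difference from the
predecessor, inverted at read time by a cumulative (prefix) sum. Dense
sorted codes make most deltas small. The deltas then go through **Stream
VByte**: each unsigned 32-bit value occupies 1, 2, 3 or 4 little-endian
bytes, and the per-value byte lengths (2 bits each) live in a *separate*
control-byte block, four values per control byte, the first value of each
group in the two least-significant bits. Unused control bits of a final
partial group are zero, and the serialized block is
`[u32 count LE][control bytes][data bytes]` — every choice fixed so that the
byte stream is deterministic and the format self-describing.

Annotation field columns are integers too: integer INFO fields directly
(bounded to 32 bits), float fields quantized by a per-field integer
multiplier (`stored = round_half_away_from_zero(value * multiplier)`;
annotation divides back, so the reconstruction error is at most
`0.5/multiplier`), and string fields dictionary-coded against a single
global per-field table of unique strings in first-seen order. Because
columns contain negative values — notably the missing-value sentinel, -1 by
default — they are **zigzag**-mapped (0, -1, 1, -2 → 0, 1, 2, 3) before
Stream VByte so small magnitudes of either sign stay in one byte. Variant
codes skip the zigzag step: they are non-negative by construction and
delta-encoded instead.

Half-away-from-zero rounding was chosen over round-half-even for the
quantizer because it is symmetric for signed scores (GERP-style fields run
negative) and easiest to state bit-exactly. Note one corner: a decimal that
lands exactly half-way at the multiplier's resolution is not exactly
representable in binary, so reconstruction error can exceed 0.5/multiplier
by ~1e-17 — tests allow that slack explicitly.

## The archive

Everything lives in a standard ZIP file (DEFLATE-compressed entries), which
gives random access per entry, a universal toolchain, and a final
general-purpose compression pass over the already-small integer streams:

```
echtvar/config.json                the field configuration, with inferred types
echtvar/strings/<alias>.txt        one unique string per line; line i = code i
echtvar/<chrom>/<bin>/var32.bin    delta + Stream VByte code block
echtvar/<chrom>/<bin>/long.bin     long-variant records (varint-framed)
echtvar/<chrom>/<bin>/fields/<alias>.bin   zigzag + Stream VByte column
```

The `echtvar/` prefix follows the archive layout popularized by the echtvar
family of tools; byte-level compatibility with archives produced by other
implementations is *not* claimed — this package's archives are
self-describing and are read back by this package. Chromosome directory
names are normalized by stripping a leading `chr` case-insensitively on both
encode and annotate, so GRCh37-style and GRCh38-style naming interoperate.
Bin directories are plain decimal integers. The long-record stream frames
each record with standard base-128 little-endian varints (offset, REF
length, REF bytes, ALT length, ALT bytes, column index).

Storing the configuration *inside* the archive (with the field types
inferred from the source VCF header) makes annotation need no external
configuration and lets the annotator emit correct `Type=` VCF header lines.
Archive writing is fully deterministic — fixed entry order, fixed
timestamps — so building twice from the same input yields byte-identical
files, which the tests assert.

## Annotation

The annotator streams the query VCF. Per archive it holds a single-slot
cache of the most recently loaded (chromosome, bin): a query in the same bin
costs no I/O, a bin change loads the new bin's entries in one read. On a
coordinate-sorted query this means exactly one load per run of consecutive
same-bin records (an invariant the tests check with the handle's load
counter); an unsorted query gets identical annotations, just more loads.

Lookup re-encodes the query variant and binary-searches the primary table
(leftmost match on duplicates); long queries are matched exactly in the
long-variant table. The archived codes are never decoded back into variants.
A variant absent from the archive is a normal outcome: every field reports
its configured missing value (-1 / "." by default), written explicitly into
the output INFO so that downstream filters behave deterministically. For
float fields the stored sentinel is emitted as-is, *not* divided by the
multiplier — the configured missing value is a user-visible contract, not a
quantized measurement. (A real value that quantizes exactly to the sentinel
would collide with it; with the default -1 that requires a negative score of
exactly -1/multiplier, which we accept as a documented corner.)

Multiple archives are applied in command order; a duplicated output alias is
overwritten by the later archive with a warning. The include filter runs
after all archives, over the merged values.

## The filter language

The `-i` expression supports numeric literals, field aliases, unary `-` and
`!`, arithmetic `+ - * /`, comparisons `< <= > >= == !=`, and short-circuit
`&& ||`, with conventional precedence and parentheses. String-typed aliases
participate only in `==`/`!=` against quoted literals. The expression is
parsed and type-checked once against the archives' alias table *before* any
record is processed, so an unknown field or a type error fails fast.

Three semantic decisions worth knowing:

* Division is real-valued (no integer truncation), so `an / 2` means exact
  halves in a recessive-style ratio filter.
* Division by zero is a per-record event, not a crash: the record does not
  pass, and a single warning is emitted for the whole run.
* Missing values participate as their sentinel exactly as annotated; there
  is no NA logic. Filters are written by users who know the defaults.

No function calls (`abs`, `min`, ...) are supported; none were needed for
the canonical filter shapes (threshold, arithmetic ratio, OR of
thresholds).

## The synthetic-data generator

`generate_vcf(synth_spec(...))` produces the inputs every test runs on: a
sorted, strictly decomposed VCF over two chromosomes (one named with a `chr`
prefix deliberately), positions spanning multiple 2^20 bins, 30% long
alleles with both combined-length 4 (last short) and 5 (first long) well
represented, a 2% rate of `N`-containing alleles, and three INFO fields
chosen to cover the three storage paths: `AF` (Beta(0.2, 5)-shaped floats —
skewed small, like real population allele frequencies), `AC` (geometric
integers) and `CSQ` (five consequence strings). Each field is missing at
rate 0.1. The generator returns its truth table, and `oracle_annotate()` is
the independent check: a plain hash-map on (chrom, pos, ref, alt) with the
same quantization arithmetic and base R `eval()` as the reference expression
evaluator.

What the generator does **not** emulate: realistic linkage or haplotype
structure, genotype matrices, multi-allelic records, structural/symbolic
alleles, or the scale of real resources (billions of sites). Passing tests
therefore demonstrate correctness of encoding, storage, lookup and
filtering — not wall-clock performance or compression ratios on real
population data.

## Problem sizes and numerical choices

The test-suite and the acceptance script run at sizes chosen to exercise
every code path while staying desk-scale: exhaustive codec checks over all
912 short REF/ALT pairs at 1,000 sampled offsets, compression identities on
10^5 random 32-bit values, and full pipeline runs on 10^4-variant synthetic
cohorts (about 6 bins across 2 chromosomes). The float multiplier default in
examples is 10^6, matching common rank-score usage.

Other fixed choices: ties between identical codes keep input order (stable
sort); duplicate identical variants are both stored and the leftmost is
returned at lookup; records are encoded regardless of FILTER status (users
pre-filter upstream); Flag-type INFO fields are rejected at configuration
time since they have no integer representation here; multi-allelic input to
the *builder* is an error (build inputs must be decomposed), while
multi-allelic or symbolic *query* records pass through annotated with
defaults.

## Package shape

The package is a library-first toolkit with a thin CLI on top
(`varchive_main()`, plus the `inst/cli/varchive` Rscript): `encode`, `anno`
and `validate` subcommands mirror how the archives are used from pipelines.
Tabular results (build summaries, validation statistics, generator truth
tables, per-record annotation frames) are returned as tibbles; the codec and
archive layers, whose inputs and outputs are byte streams and files, are
plain functions. Heavy byte-level work is vectorized base R over doubles
(exact for unsigned 32-bit quantities, which R's native signed integers
cannot hold).

## Known limitations

* Archives are write-once; there is no append or mutation.
* No binary compatibility with other implementations of this archive style.
* Single-threaded; the single-slot cache means a sparse query against a
  dense archive pays a full bin decompression per isolated variant.
* 32-bit codes cap in-bin offsets at 2^20 and combined allele length at 4;
  everything longer rides the slower long-variant path.
* Only INFO fields are carried; genotypes are passed through untouched.
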