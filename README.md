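# varchive

Compressed variant annotation archives for rapid VCF annotation and
filtering, in R.

Annotating a call-set against population-scale resources (allele
frequencies, homozygote counts, per-variant scores) is a lookup problem:
find each exact `(chrom, pos, REF, ALT)` in a database of up to billions of
sites and copy a handful of values. varchive compresses such a database into
a write-once ZIP archive built for that lookup, then annotates and filters
query VCFs against it in a single streaming pass. It is aimed at people who
maintain variant-interpretation pipelines and want population annotation and
a first-pass rarity filter in one cheap step.

## The encoding

Each chromosome is split into 2^20-base bins. A variant whose combined
REF+ALT length is ≤ 4 over {A,C,G,T} packs into one unsigned 32-bit code:

```
bits 31-12   offset of the variant within its bin (0-based)
bits 11-10   REF length (1-3; 0 = placeholder)
bits  9-8    ALT length (1-3; 0 = placeholder)
bits  7-0    REF then ALT nucleotides, 2 bits each (A,C,G,T -> 0,1,2,3)
```

Codes within a bin are sorted, delta-encoded (each value stored as the
difference from its predecessor, inverted by a prefix sum) and compressed
with Stream VByte — 1-4 little-endian bytes per integer, with the per-value
byte lengths kept in a separate control-byte block. Longer or non-ACGT
variants go to a per-bin supplemental table of literal alleles and leave a
placeholder code in the primary table so that every annotation column keeps
exactly one slot per input record. Integer INFO fields are stored directly,
floats are quantized by a per-field multiplier `m` (error ≤ 0.5/m), strings
are dictionary-coded. Columns are zigzag-mapped before Stream VByte so the
−1 missing sentinel stays a single byte. Annotation re-encodes each query
variant, binary-searches the bin's code table (one cached bin per archive,
so a sorted query loads each bin once), and writes the indexed values into
the output INFO — optionally gated by an include expression such as
`pop_af < 0.01` or `nhomalt / (an / 2) < 0.005`.

## Worked example

Build an archive from a (sorted, decomposed) population VCF and use it to
annotate and filter — here with the package's own synthetic-cohort
generator standing in for the population resource:

```r
library(varchive)

vcf <- tempfile(fileext = ".vcf")
truth <- generate_vcf(synth_spec(seed = 1, n_variants = 5000), vcf)

writeLines('[{"field":"AF","alias":"pop_af","multiplier":1000000},
             {"field":"AC","alias":"pop_ac"},
             {"field":"CSQ","alias":"pop_csq"}]', "pop.json")

build_archive(vcf, "pop.json", "pop.zip")
#> # A tibble: 1 × 5
#>   variants long_variants bins_written fields archive
#> 1     5000          1633            6      3 pop.zip

s <- annotate_vcf(vcf, "pop.zip", filter = "pop_af < 0.01", out_path = "rare.vcf")
s
#> # A tibble: 1 × 5
#>   variants_read variants_written archives bin_loads filter
#> 1          5000             3137        1         6 pop_af < 0.01

head(attr(s, "records")[, c("pos", "ref", "alt", "pop_af", "pop_ac", "pop_csq", "pass")], 4)
#>     pos ref      alt      pop_af pop_ac pop_csq  pass
#> 1  5293 TCCC     TTACTGA 0.0845       7 missense FALSE
#> 2  6652 TCCAATTT TATA    0.00294      9 missense TRUE
#> 3  7209 C        G       0.0008       8 intron   TRUE
#> 4  8441 TTC      TA      0           1  .        TRUE
```

5000 input records (1633 of them too long for the 32-bit code, stored in the
supplemental tables) were written into 6 bins; annotating the source with
its own archive recovers every stored value, and the `pop_af < 0.01` filter
keeps 3137 records — `pass` is false for the first row because its allele
frequency (0.0845) is too common. A missing field annotates as its
configured default (`-1` / `.`), visible in the fourth row's `pop_csq`.

The same operations are available from a shell:

```sh
inst/cli/varchive encode pop.zip pop.json pop.vcf
inst/cli/varchive anno -e pop.zip -i 'pop_af < 0.01' pop.vcf rare.vcf
inst/cli/varchive validate pop.zip
```

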