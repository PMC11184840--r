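# mitocompare

Comparative analysis of small circular mitochondrial genomes, built around
the twelve protein-coding genes (PCGs) shared across Nematoda — COX1–3,
CYTB, NAD1–6, NAD4L and ATP6. Nematode mitogenomes are extremely AT-rich,
show strong strand compositional bias concentrated at particular codon
positions, and evolve fast enough that deep comparisons suffer substitution
saturation. `mitocompare` provides a tested pipeline for profiling these
genomes and relating their characteristics to species life traits, plus a
fully seeded synthetic-data generator with ground truth for validating
every stage.

## What it computes

**Composition and strand skew.** For each genome, each PCG and each codon
position, the package reports lengths, %GC and the strand skews

    GC skew = (G − C) / (G + C)        AT skew = (A − T) / (A + T)

computed on the coding strand (genome-level metrics on the stored strand
after orienting the circular molecule to start at COX1). Only unambiguous
A/C/G/T count; a zero denominator is reported as undefined, never as a
silent NaN.

**Pairwise substitution rates.** Synonymous (dS) and non-synonymous (dN)
rates per gene under the invertebrate mitochondrial genetic code (NCBI
table 5: AGA/AGG = Ser, ATA = Met, TGA = Trp, stops TAA/TAG only), using a
Nei–Gojobori-type counting estimator: expected synonymous/non-synonymous
site counts per codon (stop-creating changes excluded), differences
classified along all minimal stop-free mutational paths with equal
weights, and the Jukes–Cantor correction d = −(3/4)·ln(1 − (4/3)p). Each
ingroup sequence is compared against a five-taxon outgroup panel (two
tardigrade-like and three arthropod-like reference sequences in the
synthetic datasets) and dN/dS averaged over the estimable pairs; the
ratio ω = dN/dS is formed from the averaged rates.

**Mutational saturation.** An entropy-based index on resolved alignment
columns: mean per-site Shannon entropy normalized by the entropy of the
pooled base frequencies (the full-saturation expectation for these
AT-rich data), tested against a Monte-Carlo null of column-iid alignments
with z-score verdict bands (`not_saturated` / `substantial` /
`saturated`).

**Trait association.** Kruskal–Wallis tests of every genome characteristic
and rate against life traits (feeding habit, habitat, reproduction) and
taxonomic ranks, stratified ("blocked") by clade, with ε² = H/(n−1) effect
sizes, Benjamini–Hochberg FDR across each battery, and Dunn post-hoc
pairwise comparisons.

## Worked example

Generate a seeded 12-species synthetic dataset and run every stage:

```r
library(mitocompare)

cfg <- syntheticConfig(nSpecies = 12, seed = 20)
buildDataset(cfg, "mito_demo")

rc <- runConfig(genomes    = "mito_demo/genomes.gb",
                alignments = "mito_demo/alignments",
                traitTable = "mito_demo/traits.tsv",
                outDir     = "mito_demo/results", seed = 7,
                tree       = "mito_demo/guide_tree.nwk")
res <- runPipeline(rc)

head(res$composition$summary[, c("species_id", "genome_length",
                                 "genome_pct_gc", "pcg_gc_skew")], 4)
#>       species_id genome_length genome_pct_gc pcg_gc_skew
#> SP001      SP001         14547      26.83715  0.18689233
#> SP002      SP002         14647      26.24428  0.13121846
#> SP003      SP003         14489      26.19228  0.20883978
#> SP004      SP004         14545      25.89206  0.09137804
```

Genomes come out at ~14.5 kb with ~26% GC — the AT-rich regime the
generator targets. The rates table gives outgroup-averaged dN, dS and
their ratio per species and gene:

```r
#>  species_id gene    dN_mean   dS_mean     omega n_outgroups_used
#>       SP001 COX1 0.07733361 0.5622833 0.1375349                5
#>       SP002 COX1 0.06983392 0.5847159 0.1194322                5
#>       SP003 COX1 0.07216940 0.5848107 0.1234064                5
#>       SP004 COX1 0.06326629 0.5871991 0.1077425                5
```

ω ≪ 1 throughout: purifying selection, as planted by the generator's
feeding-habit-specific ω values. Saturation results per gene and codon
position:

```r
#>  gene codon_position    iss_obs         z       verdict
#>  COX1              1 0.07401267 -150.8770 not_saturated
#>  COX1              2 0.05785264 -128.7042 not_saturated
#>  COX1              3 0.20107378 -118.2009 not_saturated
```

The 3rd codon position carries the most entropy (most synonymous
tolerance) but at this divergence all positions sit far below the
full-saturation null. Trait tests land in `trait_tests.tsv` with H, raw
and FDR-adjusted p, and ε² per stratum.

All outputs are plain TSV plus a JSON manifest recording the seed,
thresholds and input digests; a rerun with the same config is
byte-identical.

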