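Package: mitocompare
Title: Comparative Mitogenomics of Composition, Substitution Rates and
    Life-Trait Associations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of small circular mitochondrial
    genomes, built around the twelve protein-coding genes shared across
    Nematoda. Reads annotated GenBank flat files and per-gene codon
    alignments, extracts in-frame coding sequences under the invertebrate
    mitochondrial genetic code, and profiles nucleotide composition and
    GC/AT strand skews down to codon-position resolution. Estimates
    pairwise synonymous and non-synonymous substitution rates with a
    Nei-Gojobori-type counting estimator averaged over a reference
    outgroup panel, tests mutational saturation with an entropy-based
    index against a Monte-Carlo full-saturation null, and associates
    genome characteristics with life traits via clade-blocked
    Kruskal-Wallis tests, Dunn post-hoc comparisons and
    Benjamini-Hochberg false discovery rate control. A seeded synthetic
    mitogenome generator with full ground truth supports validation and
    power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'mitocompare-package.R'
    'geneticCode.R'
    'AllClasses.R'
    'geneNames.R'
    'genbank.R'
    'extract.R'
    'traitTable.R'
    'composition.R'
    'alignment.R'
    'rates.R'
    'saturation.R'
    'traitStats.R'
    'simulate.R'
    'pipeline.R'
    'utils.R'
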