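---
title: "Methods: comparative mitogenomics with mitocompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitogenomics with mitocompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocompare)
```

# Scope and data model

`mitocompare` analyses panels of small circular mitochondrial genomes of
the kind found across Nematoda: a single circular molecule of roughly
12–26 kb carrying twelve protein-coding genes (COX1–3, CYTB, NAD1–6,
NAD4L, ATP6; *atp8* is typically absent in nematodes), 22 tRNAs and 2
rRNAs, with strongly AT-biased composition. The package consumes annotated
GenBank flat files and per-gene codon alignments; assembly, annotation and
multiple sequence alignment are upstream stages it deliberately does not
perform.

Internally, coordinates are 0-based half-open on the stored strand, with
GenBank's 1-based inclusive locations converted once at the parsing
boundary. Features that span the origin of the circular molecule carry a
`wraps_origin` flag and are sliced by concatenating across the origin.
Circular genomes are oriented to start at COX1 before genome-level
composition is computed; a pure rotation leaves every composition metric
unchanged, while a reverse-complement (COX1 annotated on the minus strand)
flips the sign of the strand skews. Whether published whole-genome skews
were computed before or after such orientation is generally ambiguous in
the literature, so this package fixes the convention — post-orientation,
stored strand — and records it in the run manifest.

Incomplete terminal stop codons (completed by polyadenylation in vivo) are
truncated to whole codons, never padded: padding invents data, truncation
loses at most two nucleotides. Gene-name reconciliation across
heterogeneous annotations (`COI`, `cox1`, "cytochrome c oxidase subunit
I", ...) uses a shipped synonym table, extensible at call time; unmatched
names become `OTHER` rather than errors.

# Composition and skew

GC skew is (G − C)/(G + C) and AT skew (A − T)/(A + T) on a designated
strand; %GC is 100·(G + C)/(A + C + G + T). Three conventions matter and
are fixed package-wide:

* Only unambiguous A/C/G/T enter numerators and denominators. IUPAC
  ambiguity codes and gaps are excluded from both, so an N-run cannot
  drag a skew toward zero.
* A zero denominator yields a typed undefined value (`NA`), which group
  summaries exclude while counting the exclusions. Silent NaN arithmetic
  hides data loss.
* Genome-level metrics are computed on the full stored strand (rRNA, tRNA
  and noncoding regions included); per-gene and codon-position metrics on
  the coding strand of each gene, since coding-strand bias is the signal
  of interest.

Codon-position skews take every third nucleotide of the frame-trimmed
coding sequence; the three position subsequences partition the sequence
exactly, a property the test suite checks on random sequences.

# Substitution rates

The rate estimator is a Nei–Gojobori-type counting method under the
invertebrate mitochondrial code (NCBI translation table 5), chosen as a
transparent desk-scale core:

1. **Sites.** For each sense codon, each position contributes the fraction
   of its three single-nucleotide changes that are synonymous, with
   changes creating stop codons excluded from that position's
   denominator; n = 3 − s. Site counts are therefore conserved exactly:
   S + N = 3 × codons for every pair, which the suite asserts to machine
   precision.
2. **Differences.** Codon pairs are classified along all minimal
   single-step mutational paths that avoid stop codons, averaged with
   equal path weights (the canonical choice absent any better
   information). If every path passes through a stop — possible only for
   a handful of pairs — classification falls back to all paths and the
   result is flagged.
3. **Correction.** Proportions pS, pN are corrected with the Jukes–Cantor
   form d = −(3/4)·ln(1 − (4/3)p), which is undefined at p ≥ 3/4; such
   pairs are reported as `saturated_dS`/`saturated_dN` rather than given
   an extrapolated distance. Below p = 0.01 the correction is linear to
   within 10⁻⁴, which the tests verify.
4. **Pairwise masking.** Codons containing a gap, an ambiguity code or a
   stop codon in either member of a pair are masked for that pair only.
   Sequences with internal stops therefore lose codons, not whole genes;
   when fewer than `minCodons` (default 30) comparable codons remain the
   estimate is `insufficient_sites`. This mirrors, with an explicit
   threshold, the missing-cell behaviour that maximum-likelihood
   pipelines exhibit when they fail outright on such sequences.

Each ingroup sequence is compared to a five-taxon outgroup panel and dN,
dS averaged over the status-ok pairs, with the number of contributing
outgroups recorded; an entry with none is flagged missing rather than
zero-filled. The ratio ω is computed from the averaged rates (ratio of
means), not averaged over per-pair ratios, because single-pair dS values
near zero make the mean of ratios unstable.

Two consequences of these choices deserve emphasis. First, a counting
estimator cannot produce the very large dS values that ML engines
extrapolate under saturation; orderings and contrasts are the comparable
surface, not absolute magnitudes, and the run manifest says so. Second,
outgroup-referenced ω reflects the whole path from ingroup tip to outgroup
tip, so when selection differs along that path the estimate lies between
the two regimes; the parameter-recovery validation therefore evolves a
single pair under one ω and recovers it directly (within ±20% at 10,000
codons over 50 replicates; in practice the suite observes ~5%).

# Saturation testing

The saturation index is the mean per-column Shannon entropy over resolved
sites (columns with unambiguous A/C/G/T in every considered taxon),
normalized by the entropy of the pooled base frequencies of the subset.
Pooled-frequency normalization, rather than log₂4, matters because these
genomes run from ~13% to >50% GC: a fully saturated AT-rich alignment can
never approach two bits per site. The index is 0 for invariant alignments
and approaches 1 as columns become iid draws from the pooled composition.

Published saturation tools ship simulation-calibrated critical-value
tables tied to tree-recovery performance; those tables are not rederivable
from first principles, so this package substitutes a transparent
Monte-Carlo full-saturation null: `nReps` (default 500, seed mandatory)
same-shaped alignments with every column drawn iid multinomial from the
pooled frequencies. The z-score of the observed index against that null
drives configurable verdict bands — z ≤ −6 `not_saturated`, z ≥ −2
`saturated`, `substantial` between. The null mean sits below 1 for finite
taxon counts (finite-sample entropy bias) and rises toward 1 with more
taxa, a property the tests check at 8/16/32 taxa. Calibration: alignments
drawn from the null itself earn the `saturated` verdict in ≥ 90% of runs,
and near-zero-divergence alignments are `not_saturated`.

Codons containing any gap or ambiguity are masked per taxon as whole
codons, because mixing resolved and unresolved positions within one codon
corrupts codon-level statistics; gap treatment in published skew and
saturation computations is rarely stated, so this explicit rule is the
package's own.

# Trait association

"Blocked" Kruskal–Wallis testing is implemented as stratified per-block
testing: a separate rank test within each clade (plus a pooled "all"
stratum), which is the reading consistent with clade-specific reported
statistics; a rank-aligned pooled alternative is deliberately not
implemented. The Kruskal–Wallis statistic comes from `stats::kruskal.test`
(tie-corrected H, chi-square p on k − 1 df); groups with fewer than 2
members are dropped and logged, strata left with fewer than two eligible
groups are retained as skipped entries with a reason (a clade consisting
entirely of one trait level is a legitimate, reportable outcome, not an
error). The fully degenerate all-values-equal case is reported as H = 0,
p = 1. Effect size is ε² = H/(n − 1), clipped to [0, 1].

FDR control is Benjamini–Hochberg, with the family defined as one metric
across all grouping variables and all blocks of one battery run; the
family definition is recorded in the output because "adjust everything"
is not reproducible without it. Dunn post-hoc z statistics use joint ranks
with the standard tie correction and BH adjustment across pairs; for two
groups without ties z² equals H, an identity the tests exploit.

Calibration (checked over 1,000 null simulations): per-stratum type-I
error at nominal 0.05 lies in (0.03, 0.07), and the chi-square p agrees
with a 100,000-permutation oracle on a 3×5 dataset to within 0.025 — the
irreducible chi-square approximation error at n = 15 plus Monte-Carlo
noise; no p-from-chi-square implementation can do better, and the
permutation comparison validates the implementation, not the asymptotics.

# The synthetic-data generator

The generator produces everything the pipeline consumes, with ground
truth. Its defaults are the study conditions the package is validated
under:

* **Panel shape.** 20 species across four clades (Enoplea, Tylenchina,
  Rhabditina, Spirurina), 12 PCGs with codon counts approximating real
  nematode genes (COX1 520, NAD4L 80, ... totalling ~10.2 kb coding),
  tRNA/rRNA placeholders and intergenic spacers giving ~14.5 kb circular
  genomes at ~70% coding — matching the observed averages for the
  well-sampled clades.
* **Composition.** Target 25% GC (nematode mitogenomes run 20–40%) and
  per-position GC skews (0.2, −0.1, 0.45): strongest G skew at the 3rd
  position, mild C skew at the 2nd, the structure seen in real panels.
  Codon frequencies are solved by iterative proportional fitting over the
  stop-free sense-codon simplex so the targets hold in expectation;
  realized skews converge as 1/√n and land within ±0.03 at 10,000 codons.
  Solving frequencies, rather than rejection-sampling whole sequences,
  gives exact expectations and a feasibility diagnostic.
* **Divergence.** Every species' gene is evolved from a shared per-gene
  root by a per-codon Gillespie process: unit proposal rate per
  nucleotide site, transition targets weighted κ, stop-creating proposals
  rejected, synonymous proposals accepted, non-synonymous accepted with
  probability ω. Defaults: ingroup t = 0.15 and outgroup t = 0.5
  proposals/site, ω by feeding habit (0.05 for animal parasites up to
  0.25 for omnivores — purifying selection strongest in parasites), and
  κ = 1. The κ default keeps the mutation spectrum matched to the
  equal-weight site counting of the estimator; raising κ is the supported
  way to study the downward ω bias that transition-rich spectra induce in
  unweighted counting methods. `divergenceTime()` converts a target
  fraction of differing sites into t exactly, from the ancestor's actual
  acceptance rate.
* **Trait effects.** Per-species 3rd-position skew targets are shifted by
  feeding habit (default −2 sd for animal parasites, +1 sd for plant
  parasites, sd unit 0.05 skew) and realized by synonymous C↔G swaps at
  fourfold-degenerate sites — protein-neutral, logged as true synonymous
  events, leaving the dN truth untouched.
* **Determinism.** Everything flows from one mandatory seed;
  byte-identical reruns are asserted in the suite.

What the generator does **not** emulate: indels and alignment error
(alignments are emitted gap-free unless gaps are injected to exercise
masking), tRNA/rRNA sequence realism, genome rearrangement, multipartite
genomes, base-composition heterogeneity along a tree, and rate variation
among sites. Passing tests on synthetic data therefore demonstrate
correctness of the computations and calibration of the statistics under
known truth — not that real nematode panels satisfy the generator's
assumptions.

# Problem sizes and numerical choices

The validation suite runs at: full codon-table enumeration (62 sense
codons, all pairs at Hamming distance ≤ 2) against independent oracles;
50-replicate ω recovery at 10,000 codons; 1,000 random sequences for skew
identities; 1,000 null simulations for test calibration; 32 taxa × 1,000
sites × 500 replicates for the saturation null; and a 20-species,
12-gene end-to-end determinism run. These sizes were chosen to make the
Monte-Carlo assertions tight while keeping a full validation run in the
minutes range on a single core.

Tie-breaks and degenerate inputs: average ranks with tie-corrected H
always; undefined skews propagate and are counted, never imputed; a
saturation subset with a single pooled base is defined to have index 0;
seeds are mandatory wherever randomness exists and sub-seeds are derived
arithmetically so stages are independently reproducible.

# Known limitations

Counting-method rates are not comparable in magnitude to ML branch-model
output under heavy saturation; the package reports saturation statuses
instead of extrapolating. The five-outgroup averaging inherits whatever
saturation the outgroup distance induces — with distant outgroups many
dS estimates are legitimately missing, and the tables say so explicitly.
Stratified testing forgoes cross-block pooling power by design. The
synonym table is a best-effort reconstruction of heterogeneous annotation
practice and is user-extensible rather than claimed complete.
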