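---
title: "Dissecting mosaic hybrid yeast genomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting mosaic hybrid yeast genomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicseq)
```

Some industrial *Saccharomyces* strains are genetic mosaics: a *S. uvarum*-like
chromosomal background carrying subtelomeric blocks of *S. cerevisiae* DNA and,
at many loci, alleles from a third, lager-type lineage that diverges a few
percent from its *S. uvarum* counterparts. `mosaicseq` implements the
computational chain used to dissect such genomes: comparative-hybridization
introgression scanning, sequence-identity ancestry classification (with
chimeric-gene breakpoints and frameshift truncations), tetrad segregation
analysis, distance phylogenetics, and microsatellite clustering — plus a
seeded simulator that generates the whole study system with recorded ground
truth, so every stage is testable without external data.

## The synthetic study system

`simulate_parents()` builds three parental genomes over a shared coordinate
system:

* a **recipient** (*uvarum*-like) genome of i.i.d. nucleotides carrying a toy
  annotation of 300-codon genes (900 bp) every 1.5 kb;
* a **lager-like** lineage derived from the recipient at
  `divergence_uv_lg = 0.07` (≈93% nucleotide identity, the regime reported
  for lager-type alleles). Substitution sites are drawn uniformly so per-gene
  divergence tracks the genome-wide rate; a site landing in coding sequence
  is realized as a synonymous change at the third position of its codon with
  probability `neutral_target = 0.97`. The default was chosen to satisfy the
  two constraints reported jointly for these alleles — ≈93% nucleotide
  identity with >99% identity of the translated proteins — which a 0.95
  synonymous fraction narrowly misses (protein identity
  1 − 0.05·3·0.07 ≈ 98.95%). Codons with no synonymous third-position
  alternative (Met, Trp) relocate the change to another free third position
  of the same gene; genuine unattainability (extreme divergence) is warned
  about and recorded;
* a **donor** (*cerevisiae*-like) genome at `divergence_ce = 0.20`,
  substituted independently.

Substituted bases follow a 2:1 transition:transversion ratio, matching the
two-parameter distance model used downstream. `implant_introgressions()`
copies donor intervals into the recipient (1-based inclusive coordinates,
total length conserved) and emits a truth record; `preset_cabc()` mirrors
the three subtelomeric donor contigs of the study system, one of exactly
30803 bp.

What the simulator deliberately does **not** model: real gene annotation and
codon bias, indels and rearrangements, recombination hotspots,
translocations, and karyotype evolution. Passing tests therefore demonstrate
that the inference chain recovers planted structure under a clean
substitution-only model, not that it is robust to every artefact of real
array or sequence data.

## Array simulation and the introgression scan

`simulate_array()` maps each probe's identity between the hybridized genome
and the probe-design genome through a three-plateau logistic response:
near-perfect targets hybridize high (1200 units), ≈93%-identical targets at
an intermediate level (≈400), and ≤80%-diverged targets at array background
(≈60), with log-normal multiplicative noise (`noise_sd`, natural-log scale).
No quantitative cross-hybridization curve is available for this chemistry,
so the plateau centres (identity 0.885 and 0.965) and scales are calibration
knobs, not measured values; they were fixed once so that the three reported
signal classes (donor strong, recipient background, ≈20%-diverged weak) are
reproduced and sit well clear of the sampling spread of background identity
over a probe footprint. The default probe footprint of 150 bp emulates a
per-gene probe-set summary rather than a single 25-mer: on a 20%-diverged
background, short footprints occasionally land on conserved stretches and
cross-hybridize, which probe-set averaging smooths out.

The scan chain (`acgh_scan()`) follows the published procedure: zoned
background subtraction, replicate normalization by a fitted
through-the-origin slope (an intercept was not reported; through-origin is
assumed), averaging, per-probe log2 ratios (the log base is unstated in the
source procedure; base 2 is the array convention), 11-probe sliding-window
smoothing for visualization, and above-background segmentation. Design
choices worth knowing:

* **Background model.** The chip-style background is re-specified as: split
  the ordered track into `zones` zones, take the mean of each zone's lowest
  2% of intensities, and subtract a distance-weighted (1/(d²+1), truncated
  beyond 2.5 zone-widths) combination, floored at 5% of the track median.
  The floor matters: a near-zero floor lets background-level probes produce
  wildly unstable log-ratios. The estimator assumes every zone contains some
  background-level probes, so zones must stay wide relative to the largest
  introgressed block; the pipeline default is 4 zones over a compact
  simulated genome whose implanted blocks are ~14% of probes (in real
  genomes introgressions are a far smaller fraction and 16 chip-like zones
  are safe).
* **Segmentation.** The original scanning tool's internals are not
  documented; the stand-in is explicit: background = track median, spread =
  MAD (scaled), a probe is elevated above median + `threshold_k`·MAD
  (default 3 — a convention, not a source value), maximal runs of ≥2
  elevated probes become candidates, and candidates on one chromosome
  separated by <1 kb of genomic gap (measured end-to-start, since the rule
  is stated in kb) are merged as false-negative hybridization gaps.
  Segmentation runs on the *raw* per-probe log-ratios; detecting on the
  smoothed track would blur boundaries by half a window.
* **Telomeric repeats** can be flagged via a `repeat_group` probe column;
  `summarize_regions()` counts each repeat group once, following the
  convention that telomeric genes are counted a single time in totals.

Under the packaged conditions (two replicates per channel, `noise_sd = 0.1`,
blocks ≥3 kb), the scanner recovers ≥95% of implanted blocks with boundary
error within one probe spacing and emits no false >1 kb regions in noiseless
runs; these are recomputed by the test suite and `scripts/acceptance.R`, not
quoted.

## Ancestry classification

`percent_identity()` is a global (Needleman–Wunsch) alignment identity:
match +1, mismatch −1, gap open −5, gap extend −1, with gap columns counted
in the denominator — a conservative, reproducible convention chosen because
the original alignment parameters are unstated (identities of indel-bearing
pairs may differ by ±1 point from other tools). `classify_marker()` applies
thresholds in order: ≥99% to the donor reference → cerevisiae; ≥98% to the
recipient → uvarum; identity to the recipient in [92, 98) → lager. The band
floor of 92 reconciles two statements in the source material — "2 to 6%
divergence" (94–98% identity) and identity tables listing 93–94% sequences
as lager-type — and covers the sampling spread of ≈93%-identity genes.
Queries fitting no band are screened by `detect_breakpoint()` and called
chimeric when splitting the query between the two references improves the
summed identity by ≥2 points (a margin guarding against spurious breakpoints
between near-identical references; exposed as a parameter). Note the
ordering consequence: a chimera of two *near-identical* references sits
inside the lager band and is classified by threshold first.

`detect_breakpoint()` maximizes matches of the 5′ segment to one reference
plus matches of the 3′ segment to the other over both orderings. The
junction is identifiable only up to the diagnostic sites flanking it
(positions where the references disagree), so the midpoint of the maximal
score plateau is reported. `neutral_fraction()` counts, per differing site,
whether the two codons encode the same amino acid (standard code; identical
sequences return `NA`, not 0 or 1). `predict_truncation()` translates frame
1 to the first stop — the operation behind calls like "a T insertion at
nucleotide 1183 truncates the 616-residue protein to 394 aa", which the
tests reproduce arithmetically on a constructed open reading frame.

## Tetrad genetics

`viability()` rounds half-up to an integer (36/52 → 69%). Cell values of
printed marker tables are normalized by a declared vocabulary
(`cell_vocabulary()`): "+"/"−" presence, "ND" missing, anything else an
allele label treated as presence (or scored against a chosen allele via
`positive=`). `segregation_ratio()` returns present:absent classes with any
missing spore giving "incomplete"; `classify_ditype()` is the standard
parental/nonparental ditype/tetratype classification, defined only when
both markers segregate 2:2. `assortment_test()` formalizes the qualitative
independence claim of the source material with the exact binomial test of
PD = NPD among PD+NPD tetrads; at four tetrads this has essentially no
power (the result is "consistent with independence"), which is why the
simulator-driven version at 1000 tetrads is what the acceptance checks
exercise. The bundled `table2.tsv` fixture transcribes the printed tetrad
table; its Contig cE row marks one reference strain positive where the
running text reads it as negative — the fixture follows the printed table
and the tests only use the four-tetrad spore columns, where text and table
agree.

`simulate_meiosis()` gives every heterozygous marker a uniform 2:2 spore
partition per tetrad (so unlinked pairs are PD:NPD:TT = 1:1:4 in
expectation); linked pairs use a four-chromatid model with crossover count
Poisson(cM/50) and no chromatid interference.

## Distance phylogenetics

`count_substitutions()` applies pairwise deletion — columns with gaps or
non-ACGT symbols are removed per sequence pair, not across the whole
alignment, following the stated per-pair treatment of ambiguous positions.
`k2p_distance()` is the two-parameter closed form
d = −½·ln(1−2P−Q) − ¼·ln(1−2Q), with saturation an explicit error rather
than an infinite distance. `nj_build()` is standard neighbor joining with
two documented conventions: ties in the Q criterion break toward the
lowest-index pair (determinism for testing), and negative branch lengths
are clamped to zero with the deficit moved to the sister edge so path
lengths are preserved. `bootstrap_support()` resamples columns, rebuilds
each replicate tree, and reports the percentage of replicates containing
each internal bipartition of the full-data tree, attached as node labels.
Alignment construction itself is out of scope — aligned FASTA is the input
— so printed tree lengths from externally aligned data are reproducible
only up to alignment-tool differences; the acceptance checks therefore
verify internal consistency (closed-form distances, exact recovery of
additive matrices, cross-implementation topology agreement against
`ape::nj`) rather than quoting figure values.

## Microsatellite clustering

`chord_distance()` uses the Cavalli-Sforza–Edwards form, per shared locus
d² = 2(1 − Σ√(xy)), averaged over loci scored in both strains before the
square root. Whether the original analysis averaged or summed over loci is
unstated; averaging was chosen (and flagged) because it keeps strains with
different locus coverage comparable and bounds the distance by √2.
Within-strain frequencies are 1 for homozygotes and 0.5/0.5 for
heterozygotes; `diploidize()` restores diploidy in aneuploids by uniform
random discard (seeded, idempotent). `midpoint_root()` delegates to the
standard midpoint algorithm; exact ties between two longest leaf-to-leaf
paths are resolved by the underlying implementation's edge order, a
measure-zero event on continuous branch lengths. Tree-based label recovery
(`population_label_recovery()`) scores each strain by whether its nearest
tip in cophenetic distance shares its population.

## The pipeline and reproducibility

`run_pipeline()` chains the stages on synthetic data — simulate → scan →
classify → tetrads → phylogeny → microsatellites — writing FASTA, TSV, BED
(converted once from internal 1-based inclusive to 0-based half-open
coordinates), Newick, JSON truth records and a summary JSON. Every output
is a function of the configuration and master seed alone; each stage
derives its own stream, and re-running a config yields byte-identical
summaries. Configurations serialize to YAML and reject unknown keys before
any computation. Problem sizes in the defaults (a 470-kb three-chromosome
genome at 250-bp probe spacing, 50 tetrads, 100 bootstrap replicates,
3 × 20 microsatellite strains at 12 loci) were chosen as the smallest
system in which every stage's signal is comfortably identifiable; the test
suite uses the same or smaller sizes.

## Known limitations

* Identity thresholds act on global-alignment percentages; markers with
  large indels or assembly artefacts may need the thresholds revisited.
* The scanner's median/MAD background assumes elevated probes are a
  minority of the track; genomes where introgressions approach half the
  probes violate it (see the zones note above).
* One breakpoint per gene: multi-junction chimeras report the single best
  split.
* K2P saturation (log argument ≤ 0) is an error by design; deeply diverged
  pairs need a different distance.
* No external-data clients: analyses of deposited array or sequence
  accessions require the user to fetch and format those inputs.
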