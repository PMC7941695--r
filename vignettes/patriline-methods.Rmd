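---
title: "Methods: Y-chromosome lineage analysis in patriline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Y-chromosome lineage analysis in patriline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patriline)
```

The non-recombining region of the Y chromosome (NRY) is inherited
strictly father-to-son, so the derived alleles a man carries place him on
a single rooted genealogy of haplogroups, and the microsatellites (Y-STRs)
he carries mutate fast enough to resolve structure *within* a haplogroup.
`patriline` implements both layers — haplogroup classification from
sequencing variants or alignments, and Y-STR genotyping with downstream
population statistics — as composable, data-frame-first functions. This
vignette records the models, the tunable parameters and the design
decisions, in the package's own words.

## Haplogroup classification by lineage tracking

### Model

A marker panel attaches to each haplogroup $h$ a set of SNP markers with
known ancestral and derived alleles. For a sample, each haplogroup with at
least one *scorable* marker receives a matching rate $n/m$: $m$ scorable
markers, $n$ of them observed in the derived state. A *lineage track* is
the root-to-terminal path of a candidate terminal haplogroup; with $r$ the
terminal's resolution (tree depth) and $R_i$ the indicator that the
$i$-th haplogroup on the path has matching rate at least the cutoff $U$,
the tracking rate is

$$ t = \frac{1}{r} \sum_{i=1}^{r} R_i . $$

Candidate terminals are haplogroups that pass $U$ and carry at least one
derived *key* marker (the lab-standard markers, flagged in the panel);
when no key haplogroup qualifies — typical for array data — the same
procedure runs over ordinary matches. The classification is the track
with maximal $t$; ties break deterministically by deeper resolution, then
more key-supported haplogroups on the track, then terminal name. From the
selected key terminal the classifier finally descends greedily into
children supported only by ordinary markers (ordinary rate $\ge U$),
annotating the supporting markers, to detect a deeper final terminal.

Unscorable haplogroups contribute $R_i = 0$: the sum runs over all $r$
levels of the track, not only the scorable ones, so missing levels dilute
$t$ rather than being silently skipped.

A consequence worth knowing: a shallow track whose every level passes
($t = 1$) outranks a deeper track with a single failed level
($t = (r-1)/r$), so one failed *shallow* node pulls the classification up
to just above it. Classification depth therefore degrades gracefully with
genotype error instead of jumping to a wrong branch.

### The hidden-reference rule

Variant callers do not emit sites at which every sample matches the
reference genome. For sequencing data the classifier therefore scores
panel positions absent from the variant table as carrying the reference
base (`mode = "sequencing"`); markers whose derived allele *is* the
reference are then correctly counted derived. For genotyping-array input
(`mode = "array"`) an absent position is simply unscorable. Heterozygous
diploid chrY calls (pseudo-autosomal leakage, artefacts) are unscorable,
never ancestral. The reference base comes from the panel's `ref` column
(defaulting to the ancestral allele), so no genome FASTA is required.

### Parameters

* `cutoff` ($U$, default **0.7**, range (0, 1]): with a dozen markers per
  haplogroup, 0.7 tolerates up to a quarter of sites miscalled while
  rejecting single-marker coincidences. Lowering $U$ can only raise
  tracking rates (monotonicity is property-tested).
* Pileup calling: majority base among reads passing `min_depth` (2),
  `min_base_q` (13), `min_map_q` (20); ties are unscorable.

## Y-STR genotyping by iterative extension

A locus reference is an ordered motif composition
$L = (M_1)_{p_1}\cdots(M_n)_{p_n}$ with total repeat number
$p = \sum p_i$; its chrY interval length must equal
$\sum p_i\,|M_i|$, which is validated on load. The sample window starts
at the locus start and initially extends one motif unit $s$ (the length
of the *last* motif) past the reference end. The motif count $q$ over the
current window is compared with the current $p$: $q \le p$ is a call of
$q$ (a contraction or reference-equal allele); a saturated window
($q = p+1$) grows by one unit, increments $p$ and recounts, until $q$
stabilises — the sample carries no further repeats. An iteration cap
(default 30, far above any plausible human allele) guards degenerate
input. For compound loci only the terminal motif block extends; the rare
case $q > p + 1$ (possible only with unequal motif lengths) is treated
like saturation and re-counted after one extension.

Per-sample consensus over spanning reads takes the modal repeat number,
requiring at least 2 informative reads and a modal fraction of 0.6 —
thresholds chosen to favour a no-call over a wrong call. The indel route
instead converts the net indel length within the locus interval to
$p + \Delta/s$, no-calling off-frame nets ("off-frame") and overlapping
contributing indels ("conflict").

The packaged panel is a synthetic stand-in: it carries the standard
forensic locus names (Minimal through PowerPlex Y23, nested 9 ⊂ 12 ⊂ 17
⊂ 23) with representative motifs and self-consistent synthetic
coordinates, so workflows and tests are fully reproducible offline; real
analyses should load a curated panel TSV. The duplicated locus DYS385a/b
is genotyped as two independent intervals and reported as two ordered
columns — a simplification relative to the forensic unordered-pair
convention, kept because every downstream statistic here treats columns
independently.

## Population statistics

* **Haplogroup frequencies** per population feed a column-centred PCA
  (`stats::prcomp`); eigenvalues are axis variances and the
  variance/eigenvalue identity is tested to 1e-9.
* **Pairwise Fst** treats haplogroup identity as one multi-allelic locus:
  $F_{ST} = (H_T - H_S)/H_T$ with $H = 1-\sum p_i^2$, $H_S$ the
  unweighted mean within-population diversity and $H_T$ from the mean
  frequency vector; negative estimates clamp to 0 so the matrix is a
  valid input for classical (Torgerson) MDS (`stats::cmdscale`, exact on
  Euclidean inputs, no seed). An $n/(n-1)$ small-sample correction is
  available behind `corrected = TRUE`.
* **HD** uses the $n/(n-1)$ unbiased form; **MPD** averages per-pair
  locus mismatches (or squared repeat differences behind a flag);
  **Gst** applies the same Nei-style identity per locus and averages
  polymorphic loci.
* **AMOVA** is one grouping level: sums of squares come from the pairwise
  distance matrix via the standard identities
  ($SS = \sum_{i<j} d_{ij}/n$ within each grouping), variance components
  from the mean squares with the unequal-size coefficient $n_0$, and
  $\Phi_{ST} = \sigma^2_a/(\sigma^2_a+\sigma^2_w)$; the p-value permutes
  population labels under a caller-supplied seed. Mismatch distance is a
  squared Euclidean distance of one-hot coordinates, which is what makes
  these identities exact (the test suite checks them against an explicit
  one-hot decomposition for all $n \le 12$ fixtures).
* **Bayesian haplogroup prediction** multiplies smoothed per-locus allele
  frequencies under each haplogroup into the prior (haplogroup totals, or
  uniform). Smoothing adds a pseudocount (default 0.5) per allele bin,
  the bins being the union of alleles seen at the locus plus the queried
  one; the packaged reference is a small synthetic demonstration set and
  the TSV schema (`haplogroup, locus, allele, count`) accepts user
  references.

## Phylogeny: two-step construction

Step one places each sample as a leaf under its haplogroup in the
haplogroup tree, prunes sample-free nodes and collapses unary chains —
the backbone is therefore exactly the haplogroup hierarchy restricted to
observed lineages. Step two resolves each polytomy, in post order, into a
bifurcating subtree built from its member clades only (each clade
represented by its alphabetically first sample), leaving the backbone
untouched; backbone-clade preservation is property-tested on 100 random
fixtures. Methods: UPGMA (average linkage on IBS mismatch distance), MP
(exhaustive over all rooted topologies up to 7 members — 10,395
candidates scored by Fitch parsimony; deterministic stepwise addition
above that, where exhaustive enumeration would need 135,135+ topologies),
and IBS (neighbour joining, rooted deterministically on the first
member's edge). Identical sequences (all-zero distances) and missing
alignments fall back to a caterpillar in sample-name order, the latter
with a warning. IBS distance is the mismatch proportion over shared
unambiguous sites; pairs with no overlap get distance 1 with a warning.

Divergence dating itself is delegated to an external Bayesian MCMC
executable; the package writes its input bundle (branch-length-free
newick with `'>lower<upper'` calibration bounds, sequential PHYLIP
alignment, control file) and parses its posterior node-time output.
The built-in calibration table is configuration data at literature scale,
overridable per node by user bounds; nothing in the package asserts those
values as estimates.

## Median-joining networks and TMRCA

Haplotype networks use the median-joining scheme adapted to integer
repeat vectors under the L1 distance (sum of absolute repeat
differences — the natural metric under stepwise mutation, rather than
Hamming). Iteratively: build the $\epsilon$-relaxed minimum spanning
network (an edge survives if its weight is within $\epsilon$ of the
minimax connection level between its endpoints), propose locus-wise
medians of partially linked triplets, greedily accept the median that
most shortens the spanning length, and finally prune median vectors of
degree ≤ 2 (they lie on geodesics and add no resolution). Haplotypes and
candidate medians are processed in lexicographic order, so the network,
its total weight and the fdi export are deterministic; the fdi file uses
a fixed circular layout and is byte-stable.

Two TMRCA estimators operate on the haplotype table or network:

* **rho** — multiplicity-weighted mean mutational distance from a
  designated root (shortest network path, or direct L1 distance when
  called on a table plus ancestral haplotype); $T = \rho/\mu$ with
  $\mu$ per *haplotype* per generation, and the reported standard error
  follows the convention $SE(T) = \sqrt{\rho\,\sum w^2}/\mu$ (stated in
  the output). Because rho counts *net observable* steps, the matching
  rate at deep time scales is the expected absolute displacement of the
  Poisson ±1 walk per generation, not the raw mutation rate — at
  $\mu_{locus} t = 0.4$ the two differ by ~17%, which is why the recovery
  analysis derives the effective step rate in closed form.
* **ASD** — mean squared repeat difference from the ancestor;
  $E[ASD] = \mu T$ exactly under symmetric single-step mutation, so
  $T = ASD/\mu$ with $\mu$ per locus per generation, unbiased on a star
  genealogy (checked against simulation to within 2 SE).

Both report generations and years (generation time default 30, a common
human pedigree value; configurable).

## The synthetic-data generators, and what tests do (not) show

All tests and the acceptance analysis run on generated data with known
truth and mandatory seeds: toy haplogroup trees with per-node markers
(default 12 per haplogroup, mirroring the marker density of the
ISOGG-scale panel: ~74,570 markers across roughly 5,800 haplogroups),
haploid multi-sample VCFs with independent per-site error-flip and
missingness processes (and records omitted whenever all samples match the
reference, reproducing the hidden-reference situation), STR read windows
with the true allele embedded in non-motif flanking context, and star
genealogies with Poisson(±1) single-step STR mutation.

Problem sizes used by the standard analyses: classifier oracle
equivalence on 100 random trees of up to ~200 nodes; recovery on a
balanced depth-5 tree (62 haplogroups, 64 samples) error-free and at 5%
genotype error; 1,000 randomized STR windows against a brute-force run
counter; star simulations with $n = 200$ lineages, 17 loci,
$\mu = 0.002$, depth 200 generations (20 seeds for ASD, 50 for rho);
100 random phylogeny fixtures of 12 samples.

What the generators deliberately do not emulate: linked read errors or
stutter noise at STRs (error processes are independent per site/read),
population structure beyond labels, recurrent SNP mutation within a
sample's path, coalescent genealogies beyond the star, and real genome
coordinates. Passing tests therefore demonstrate algorithmic correctness
and calibration under the stated models, not performance on real
sequencing artefacts.

## Numerical and degenerate-input conventions

Coordinates are 1-based inclusive throughout (VCF convention). Pileup
ties and het calls are unscorable. Empty candidate sets classify as the
root with status `"unresolved"` and exit cleanly. Negative Fst clamps to
0; MDS on rank-deficient input pads absent axes with zeros. All
randomness flows through caller-supplied seeds (`withr::with_seed`), so
identical inputs give byte-identical outputs, including the CLI files
(whose provenance headers carry version, command line and seed, and no
timestamps).
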