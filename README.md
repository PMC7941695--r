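# patriline

Y-chromosome lineage analysis from sequencing data, for population
geneticists and forensic researchers working with male samples: the
non-recombining Y (NRY) is inherited strictly paternally, so the derived
SNP alleles a sample carries place it on the rooted haplogroup genealogy,
while its Y-STR repeat numbers resolve fine structure within a
haplogroup. `patriline` covers both layers end to end — classification,
clustering, phylogeny, dating scaffolds, STR genotyping, diversity
statistics, median-joining networks and TMRCA — as tidyverse-style
functions (data frames in, tibbles out) plus a command-line interface.

## The core algorithms

**Haplogroup classification by lineage tracking.** Each haplogroup *h*
with scorable panel markers gets a matching rate *n/m* (derived hits over
scorable markers). A candidate terminal's root-to-terminal path of
resolution *r* is scored by the tracking rate

```
t = (1/r) * sum_{i=1..r} R_i ,   R_i = 1 if n_i/m_i >= U else 0
```

and the classification is the track maximizing *t* (deterministic tie
rules), refined downward through ordinary-marker-supported children.
Sequencing input applies the hidden-reference rule: panel positions
absent from the variant table are scored as carrying the reference base,
because callers omit sites where every sample matches the reference.

**Y-STR genotyping by iterative extension.** A locus reference
`L = (M1)^p1 ... (Mn)^pn` (total repeat number `p = Σ p_i`) is compared
with a sample window that initially reaches one motif unit past the
reference end; the motif count `q` is recounted while the window is
saturated (`q = p + 1` → extend by one unit, `p ← p + 1`), so expansions,
contractions and reference-equal alleles all terminate at the true
count. Consensus across spanning reads is modal with no-call-friendly
thresholds; an indel-based mode converts net VCF indel lengths instead.

Downstream: population PCA on haplogroup frequencies and classical MDS
on pairwise Fst; two-step phylogeny (haplogroup backbone, then per-
polytomy UPGMA/MP/IBS subtrees); input bundles for external Bayesian
dating; HD/MPD/Gst/one-level AMOVA with permutation p-values; Bayesian
haplogroup prediction from Y-STR profiles; median-joining networks with
fdi export; rho and ASD TMRCA estimators.

## Worked example

```r
library(patriline)

# a toy haplogroup panel (30 nodes, 12 markers each) and simulated samples
toy <- make_toy_panel_tree(depth = 4, branching = 2, seed = 7)
sim <- simulate_genotype_table(toy$panel, samples_per_terminal = 2,
                               error_rate = 0.02, seed = 8)
vcf <- tempfile(fileext = ".vcf"); write_sim_vcf(sim, vcf)

hg <- classify_samples(vcf, toy$panel, input = "vcf")
head(hg, 4)
#> # A tibble: 4 × 6
#>   sample key_haplogroup haplogroup tracking_rate mutations status
#>   <chr>  <chr>          <chr>              <dbl> <chr>     <chr>
#> 1 S001   HGAaaa         HGAaaa                 1 ""        ok
#> 2 S002   HGAaaa         HGAaaa                 1 ""        ok
#> 3 S003   HGAaab         HGAaab                 1 ""        ok
#> 4 S004   HGAaab         HGAaab                 1 ""        ok
```

Every sample's terminal haplogroup is recovered (tracking rate 1 means
every level of the selected lineage track passed the matching-rate
cutoff, despite the 2% simulated genotype error). Clustering the
assignments at resolution level 2 separates the two main clades on the
first principal axis:

```r
pop <- tibble::tibble(sample = hg$sample,
                      population = paste0(substr(hg$haplogroup, 1, 3),
                                          rep(c("_n", "_s"), 16)))
emb <- pca_embedding(haplogroup_frequencies(hg, pop, toy$panel$tree, level = 2))
tibble::as_tibble(emb)
#> # A tibble: 4 × 3
#>   unit  axis1     axis2
#>   <chr> <dbl>     <dbl>
#> 1 HGA_n  -0.5 -2.78e-17
#> 2 HGA_s  -0.5 -2.78e-17
#> 3 HGB_n   0.5  2.78e-17
#> 4 HGB_s   0.5  2.78e-17
```

The four pseudo-populations collapse onto two points — all variation sits
on axis 1 (its eigenvalue carries 100% of the variance), exactly as the
clade structure dictates. `autoplot(emb)` draws the scatter. On the STR
side, a star genealogy simulated 150 generations deep is dated by ASD:

```r
sim2 <- simulate_star_strs(n = 40, mu = 0.002, depth = 150, seed = 9)
tidy(asd_tmrca(sim2$haps, sim2$ancestor, mu = 0.002))
#> # A tibble: 1 × 8
#>   estimator statistic t_generations t_years se_generations    mu generation_time     n
#>   <chr>         <dbl>         <dbl>   <dbl>          <dbl> <dbl>           <dbl> <int>
#> 1 asd           0.288          144.   4324.             NA 0.002              30    40
```

`ASD/μ = 144` generations against a 150-generation truth, within the
sampling noise of 40 lineages.

## Command line

```sh
exec/patriline classify --vcf samples.vcf --ref panel.tsv -b 19 -o run1
exec/patriline cluster  --hg run1.hg -p samples.pop --method pca --level 3 -o clu
exec/patriline genostr  --bam sample.bam -b 38 --panel minimal -o strs
exec/patriline stat     --str strs.str.tsv -p samples.pop --stat hd,amova --seed 5 -o st
```

Eight subcommands (`classify`, `cluster`, `phylo`, `genostr`, `net`,
`stat`, `time`, `tmrca`); every output carries a provenance header with
version, command line and seed.

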