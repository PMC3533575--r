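---
title: "Methods: SNP discovery and diversity analysis in mixed-ploidy panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP discovery and diversity analysis in mixed-ploidy panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrasnp)
```

`tetrasnp` implements the analysis chain used to survey SNP diversity in a
panel of 27 alfalfa genotypes that mixes autotetraploid (2n = 4x) and
diploid (2n = 2x) material: filtering candidate variant sites from
per-genotype read counts, scoring dosage-lumped genotypes, accounting for
polymorphism within and among germplasm groups, and summarising population
structure. This vignette is the package's own account of each model, its
assumptions, the parameters that matter, and the choices made where the
design was genuinely open.

## The input and its boundary

The package starts *after* read alignment and initial variant
identification: its input is a table with one row per candidate site and,
for each genotype, the number of reads carrying the reference allele, the
number carrying the variant allele, and the mean Phred quality of the
variant-supporting bases. Positions are 0-based within assembled contigs
internally; VCF export converts to 1-based coordinates. Short InDels travel
the same path as SNPs (`variant_class` distinguishes them); multi-allelic
sites are out of scope — every site is a ref/variant pair.

## The filter cascade

A candidate site is retained as a SNP iff it passes three stages, applied
in order (the first failing stage is recorded):

1. **Sample support.** At least one genotype must support the variant:
   at least 2 variant reads, mean variant-base quality at least 20, and a
   variant-read fraction of at least 20% of that genotype's ref + var
   reads. All three bounds are inclusive; quality applies to the
   variant-supporting bases only; the fraction denominator is the
   two-allele depth. Genotypes with zero reads contribute no support.
2. **Total depth.** The summed read count over all genotypes must be
   strictly greater than 20.
3. **Genotypic contingency test.** Independence of reference and variant
   alleles (rows) across genotypes (columns) is tested on the 2 × K table
   of read counts, where K counts genotypes with nonzero depth (zero-depth
   columns are removed — keeping them would put zeros in the expected
   counts and leave the statistic undefined). The default statistic is
   Pearson's chi-square with K − 1 degrees of freedom; the site is retained
   when p < 0.01. A site whose variant (or reference) row sums to zero has
   no allele contrast and gets p = 1, as does a table with fewer than two
   covered genotypes (with a warning).

The choice of Pearson's chi-square is deliberate: a table of read counts
plus "contingency test" reads most plainly as chi-square, and the package
keeps that as the default while offering a seeded permutation mode for
sparse tables, in which allele labels are shuffled among reads holding both
margins fixed (Patefield sampling via `stats::r2dtable`) and
`p = (1 + #{T* >= T}) / (1 + B)`. Columns are put in a canonical order
before sampling so the permutation p-value is exactly invariant to genotype
column order. When all expected cells are at least 5 the two p-values agree
within Monte-Carlo error; the test suite checks this, along with the
rejection rate under a simulated null (1% at alpha = 0.01).

A practical consequence worth stating: the contingency stage requires
*between-genotype* contrast. A true variant carried at the same dosage by
every genotype — in particular one fixed in all of them — produces a table
whose columns share one expected allele fraction, so the test correctly
retains independence and the site is filtered. Sites like these are
invisible to this design no matter the sequencing depth; the error-free
recovery tests therefore assert exact recovery only for dosage-heterogeneous
sites and assert that fixed-everywhere variants fail at the contingency
stage.

## Genotype classification and the core set

Read counts cannot reliably resolve allele dosage in a tetraploid, so the
three heterozygous dosage classes (ABBB, AABB, AAAB) are lumped into a
single `AB` state and only `AA` / `AB` / `BB` / missing are scored. The
conversion from counts to states is not dictated by the read data alone and
is this package's own rule, with every threshold exposed in
`call_params()`:

* depth below `min_genotype_depth` (default 10) → missing;
* variant fraction `f <= max_hom_fraction` (default 0.10) → `AA`,
  `f >= 0.90` → `BB` — chosen so that one miscalled read at depth 10
  cannot fake a heterozygote;
* otherwise `AB`, provided each allele has at least 2 reads (else missing).

The **core SNP set** keeps PASS SNPs with at least 10 reads in *every*
genotype. With the default thresholds this matrix has no missing entries:
at depth ≥ 10, any fraction above 0.10 already implies at least 2 variant
reads. All diversity statistics run on this matrix.

Per-genotype heterozygosity is the percentage of classified sites called
`AB`. Two diploids of one subspecies can be pooled into a four-chromosome
tetraploid equivalent: the pooled call is `AB` when either member is `AB`
or the two homozygous states differ. Under within-group Hardy–Weinberg at
frequency p this pooled heterozygosity has the closed form
1 − p⁴ − (1 − p)⁴, which the tests verify by simulation.

## Diversity partition

A SNP is *polymorphic within a group* iff, among the group's non-missing
calls, some genotype is `AB` or two genotypes are opposite homozygotes —
polymorphism is defined on genotype calls, not raw reads, because the
published group accounting is built from the called matrix. A site where a
group has no non-missing call has an undefined flag; such sites are
excluded from Venn totals (and counted in a message). `venn_regions()`
partitions the SNPs polymorphic in at least one group into all 2ᵏ − 1
exclusive membership regions; the partition property (counts sum exactly to
the number of somewhere-polymorphic SNPs) is tested on random profiles
against a brute-force tabulation.

`fixed_differences()` finds sites where two groups carry only opposite
homozygous states; by construction these sites are polymorphic within
neither group. `candidate_contigs()` generalises this into the
candidate-gene scan: a qualifying SNP is polymorphic within one pooled set
of genotypes (e.g. the two wild *caerulea* diploids) while all non-missing
calls across a disjoint set (e.g. the 22 cultivated tetraploids) are the
same homozygote; contigs carrying at least `min_cluster` (default 5)
qualifying SNPs are reported. SNP density along anchored pseudomolecules
uses fixed-origin, half-open 0.5-Mbp tiles (not sliding windows) and
reports variants per kbp.

The percentages printed in diversity summaries are plain ratios of
marginal counts; `polymorphism_percentage()` centralises that arithmetic
(including its rounding) so the published worked examples can be
reproduced from their printed counts.

## Population structure

The simple-matching distance between two genotypes is one minus the
fraction of sites, among those where both calls are non-missing, with
identical states — `AB` matches only `AB`; no allele-sharing weighting.
Pairs with no comparable site are an error rather than a silent `NA`.

The tree is classical Saitou–Nei neighbor joining ("unweighted" in the
PHYLIP sense): iteratively join the pair minimising
Q(i, j) = (n − 2)·d(i, j) − Σₖd(i, k) − Σₖd(j, k), with the standard limb
lengths, finishing in the central trifurcation of the unrooted tree.
Two choices were open and are fixed as follows: ties in Q break on the
lexicographically smallest pair of representative leaf labels, making the
output deterministic; negative branch lengths — possible under classical
NJ — are kept by default, with an optional clamp to zero. On an additive
matrix the tree reproduces every pairwise distance at machine precision,
which the tests verify against random trees and an exhaustive-topology
least-squares oracle on four taxa. Newick export uses fixed 6-decimal
branch lengths and single-quotes labels containing spaces or
metacharacters (several panel genotype names contain spaces).

PCA encodes AA = 0, AB = 1, BB = 2, imputes missing entries with the site
mean (the core set has none, but the API tolerates them), centres sites,
and takes scores and eigenvalues from the SVD; variance fractions are
eigenvalues over their total, all zero for a constant matrix. Dosage
lumping means the encoding is ordinal rather than an allele count in
tetraploids; that is inherent to the AA/AB/BB scoring, and the analysis
should be read as structure among call profiles, not among allele
frequencies.

## The synthetic panel generator

The generator exists so every downstream stage can be tested against known
truth without the original sequencing data; it is first-class, tested code.
It emulates the study conditions of the 27-genotype panel:

* **Panel layout** — `alfalfa_groups()`: 16 elite tetraploids in four
  breeding-program subgroups, 6 cultivated tetraploid parents, and 5 wild
  genotypes (2 diploid *caerulea*, 2 diploid *falcata*, 1 tetraploid
  *falcata*).
* **Allele frequencies** — one ancestral frequency p per site (default
  Uniform(0.05, 0.95): a transcriptome SNP list is conditioned on
  segregation, so very rare ancestral variants are under-represented);
  each group then draws from the Balding–Nichols law
  Beta(p(1 − F)/F, (1 − p)(1 − F)/F), mean p, variance F·p(1 − p).
  F = 0 copies p exactly; F = 1 is rejected as degenerate. Defaults are
  F = 0.05 for the two cultivated pools and 0.25 for the wild group —
  modest differentiation within cultivated alfalfa (an outcrossing crop
  with large effective population sizes) and clearly diverged wild
  material, consistent with the clean wild/cultivated separation the
  structure analyses are expected to show.
* **Dosages** — Binomial(ploidy, group frequency) per genotype:
  tetrasomic or disomic Hardy–Weinberg within groups. No linkage
  disequilibrium along contigs and no selection or demography are
  modelled.
* **Read counts** — depth per genotype × site is negative binomial with
  mean 56 (the panel's reported average per-genotype coverage) and size 5
  (overdispersed, as transcriptome coverage is; Poisson available as the
  size → ∞ limit); each read carries the variant allele with probability
  dosage/ploidy, miscalled with probability 0.5%; variant-base quality is
  a truncated Normal(30, 5), recorded as 0 where no variant read exists.
* **InDels** — 3.5% of sites, matching their share among the published
  variant counts; they exercise the shared filter path and the HRM
  neighbour rule.
* **Determinism** — one integer seed in `panel_config()` fixes the entire
  panel; `write_panel()` output is byte-identical across runs.

The two French parental genotypes were represented in the original
experiment by bulks of three selfed progeny each; no mixing model for such
bulks is simulated — a plain tetraploid stands in — because the original
analysis could not explain the bulks' behaviour and any mixing model here
would be a guess.

What passing tests on this generator do **not** show about real data:
depth is independent across genotypes and sites (real coverage is
correlated within a transcript and across genotypes through expression),
base-call errors are uniform and independent, there is no allelic bias in
alignment, and sites are unlinked. The generator validates the *logic* of
the stages, not the error structure of any particular sequencing run.

## Problem sizes and numerical choices

The test suite and acceptance script run at desk scale, chosen so the full
chain is exercised in well under a minute per property: demonstration
pipelines use 200 contigs × 10 sites (2,000 sites); parameter-recovery
checks use 20,000 sites × 27 genotypes; null calibration uses 10,000
sites; the Venn partition property runs 1,000 random profiles. The
published headline counts (872,384 SNPs from ~700 M reads, the 173,947-SNP
core set, the dataset-specific 9.97%/6.70% PC variances) derive from the
full sequencing experiment and are not reproducible at this scale; what is
reproduced instead are the printed accounting ratios (from their printed
marginal counts) and the method-level properties above.

Remaining numerical conventions: chi-square expected-count terms with a
zero expectation contribute zero to the statistic; permutation p-values use
the add-one estimator and a 10⁻⁹ tolerance on statistic comparisons;
HRM eligibility treats a neighbouring PASS variant at distance exactly
`flank` (default 18 bp) as disqualifying, and positions closer than
`flank` to a contig end are ineligible because the clean primer window
would be truncated; contig-length bins are half-open `[lo, hi)` intervals.

## Known limitations

* Allele dosage is deliberately not estimated; analyses that need
  ABBB/AABB/AAAB resolution (e.g. tetraploid F-statistics) are out of
  scope.
* The contingency stage removes variants without between-genotype
  contrast, including variants fixed against the reference in all
  genotypes (see above).
* The classification thresholds are heuristics tuned for ~50× depth;
  at depths near the core floor of 10 a dosage-1 heterozygote is
  occasionally scored homozygous, which biases heterozygosity downward by
  up to about one percentage point in the tested conditions.
* Distances, trees and PCA all treat the lumped `AB` state as a single
  category; two tetraploids with dosages 1 and 3 are "identical" at that
  site.
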