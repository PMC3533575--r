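# tetrasnp

SNP discovery and diversity analysis for mixed-ploidy alfalfa panels.

`tetrasnp` re-implements, as a tested and reusable R pipeline, the analysis
used to survey single-nucleotide polymorphism across a diversity panel of 27
alfalfa (*Medicago sativa*) genotypes — 16 elite tetraploids from four
commercial breeding programs, 6 cultivated tetraploid mapping-population
parents, and 5 wild genotypes including diploid subsp. *caerulea* and
*falcata*. It is aimed at plant geneticists and breeders who work with
multi-sample read-count tables from transcriptome (or amplicon) sequencing
of polyploid species and want a transparent, scriptable version of each
analysis stage.

## What it computes

Starting from a per-site, per-genotype table of reference/variant read
counts (with mean variant-base qualities), the package provides:

* **SNP filter cascade** — a site is retained as a SNP iff
  1. *sample support*: some genotype has ≥ 2 variant reads, mean
     variant-base quality ≥ 20 and variant-read fraction ≥ 20%;
  2. *total depth*: summed reads across all genotypes > 20 (strict);
  3. *genotypic contingency test*: Pearson chi-square on the 2 × K table of
     ref/variant read counts across the K covered genotypes
     (df = K − 1), p < 0.01; a seeded permutation mode (label shuffling
     preserving both margins) is available for sparse tables.
* **Dosage-lumped genotype classification** — each genotype at each PASS
  SNP is scored AA / AB / BB from its variant-read fraction f
  (AA if f ≤ 0.10, BB if f ≥ 0.90, AB in between with ≥ 2 reads of each
  allele), lumping the tetraploid heterozygous dosage classes
  ABBB/AABB/AAAB into one AB state; the **core SNP set** keeps PASS SNPs
  with ≥ 10 reads in *every* genotype.
* **Heterozygosity** — per genotype, % of classified sites called AB;
  two diploids can be pooled into a four-chromosome tetraploid equivalent.
* **Diversity partition** — within-group polymorphism flags, exclusive
  Venn-region counts over groups or breeding-program subgroups,
  fixed-difference scans between groups, candidate contigs carrying ≥ 5
  clustered group-private SNPs, and SNP density per kbp in 0.5-Mbp windows
  along anchored pseudomolecules.
* **HRM assay selection** — PASS SNPs whose 18-bp flanks on both sides are
  free of other PASS variants and fully inside the contig.
* **Population structure** — simple-matching distances
  (d = 1 − shared-state fraction), a classical Saitou–Nei unweighted
  neighbor-joining tree (Q-criterion, deterministic lexicographic
  tie-breaks, Newick export), and PCA of the 0/1/2-encoded genotype matrix
  with variance fractions per component.
* **Synthetic panel generator** — Balding–Nichols group frequencies
  (Beta(p(1−F)/F, (1−p)(1−F)/F) around an ancestral frequency p),
  binomial tetrasomic/disomic dosages, negative-binomial depth, per-read
  miscalls, and full truth tracking, so every downstream stage is testable
  without the original sequencing data.

Everything is tibble-in/tibble-out and pipe-friendly; fitted results have
`tidy()`/`glance()`/`autoplot()` methods.

## Worked example

```r
library(tetrasnp)
library(dplyr)

cfg   <- panel_config(n_contigs = 100, sites_per_contig = 10, seed = 42)
panel <- simulate_panel(cfg)             # 27 genotypes, 1,000 sites, truth known
calls <- call_variants(panel$counts, filter_params())
count(calls, verdict)
#>   verdict         n
#> 1 PASS          999
#> 2 contingency     1

geno <- core_set(calls, panel$counts, call_params())
nrow(geno)                               # 865 SNPs deep enough in all genotypes
head(heterozygosity(geno), 3)
#>   genotype  n_classified heterozygosity_pct
#> 1 B75GH-402          865               60.2
#> 2 B85-912            865               62.8
#> 3 B85-920            865               61.7

venn_regions(group_polymorphism(geno, panel$groups))
#>   pattern region               count
#> 1 001     Group3                   1
#> 2 010     Group2                   6
#> 3 011     Group2&Group3            4
#> 4 100     Group1                  27
#> 5 101     Group1&Group3           28
#> 6 110     Group1&Group2          206
#> 7 111     Group1&Group2&Group3   593

glance(snp_pca(geno))
#>   n_genotypes n_sites pc1_variance_pct pc2_variance_pct
#> 1          27     865             17.1             7.13
```

The verdict table says 999 of the 1,000 simulated sites survive the cascade
(one fails the contingency test: its allele fractions happen to be uniform
across genotypes); 865 of the PASS SNPs are covered by ≥ 10 reads in all 27
genotypes and form the core set. The Venn table partitions the 865 core
SNPs by the groups within which they segregate — most (593) segregate in
all three — and the PCA summary reports how much genotype variance the
first two components capture. `neighbor_joining(simple_matching_distance(geno))`
returns the corresponding unrooted tree as an ape-compatible `phylo`
object, exported with `write_newick()`.

The one-shot driver runs every stage and writes all artifacts (VCF,
genotype matrix, heterozygosity and Venn tables, candidate contigs,
HRM-eligible list, PHYLIP distances, Newick tree, PCA tables, density
bedgraph, JSON report):

```r
report <- run_full(run_config("out", simulate = panel_config(seed = 1)))
```

or from a shell: `Rscript inst/scripts/tetrasnp-run.R --demo --out-dir out`.

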