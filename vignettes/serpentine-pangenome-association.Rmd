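---
title: "Pan-genome association mapping of habitat adaptation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pan-genome association mapping of habitat adaptation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

serpan implements a pan-genome environmental-association workflow for
bacterial strain collections sampled from contrasting habitats — the
motivating system is a clade of soil rhizobia collected from
nickel-enriched serpentine and adjacent non-serpentine soils across several
reserves, phenotyped for growth (OD600) in high- and low-nickel media.
This vignette is the package's own account of its statistical machinery:
the models, the tunable parameters, what the synthetic-data generator does
and does not emulate, and the numerical decisions taken where the design
was open.

## The analysis chain

1. **Pan-genome construction** (`filter_hits`, `reciprocal_best_hits`,
   `build_ortholog_groups`, `presence_absence_matrix`).  Tabular homology
   hits are filtered at strict thresholds (overlap > 0.80 of the query,
   E-value < 1e-20, identity > 50%); genes sharing a best reference-proteome
   hit share that protein's ortholog group, and the remaining ("de novo")
   genes are grouped by single-linkage closure over reciprocal best hits.
   Core genes are present in every strain of a subset; accessory genes are
   absent from at least one.
2. **Molecular evolution** (`ng86_ka_ks`, `compare_compartments`).
   Nei–Gojobori (1986) Ka/Ks with Jukes–Cantor correction, compared between
   core and accessory compartments by a Wilcoxon rank-sum test on
   log10(Ka/Ks).
3. **Association mapping** (`regress_out_structure`,
   `gene_content_association`, `snp_association`, `adjust_pvalues`).
   Growth is residualized by OLS on the admixture Q-matrix (first K − 1
   columns plus an intercept; the last column is redundant because loadings
   sum to 1).  Each accessory gene (carrier vs non-carrier) and each
   biallelic core SNP (allele classes) is tested by Wilcoxon rank-sum on
   the residuals, excluding fixed variants and singletons.  Significance is
   controlled by Bonferroni and by Benjamini–Hochberg FDR (Storey q-values
   optional); effects are reported on the raw phenotype (mean OD600 of
   carriers minus non-carriers) together with per-soil carrier frequencies.
4. **Positional clustering** (`call_clusters`,
   `match_clusters_across_strains`, `cluster_summary`).  On each contig,
   runs of at least four tandem candidate genes seed a cluster, which is
   extended outward while another candidate lies within 10 kb of the
   cluster edge; clusters are matched across strains by Jaccard similarity
   of membership (single linkage at 0.5) and summarized by span, candidate
   and Bonferroni counts, order conservation (longest common subsequence),
   and habitat assortment.
5. **Donor-distance test** (`distance_shift_test`, `ks_two_sample`).  Per
   candidate FDR tier (1/5/10%), the 16S distance between the focal clade
   and each accessory gene's nearest-homolog lineage is compared between
   candidates and non-candidates (two-sample KS and Wilcoxon; the mean
   difference estimates the donor-distance shift).
6. **Biogeography** (`snp_distance`, `gene_content_distance`, `permanova`,
   `bootstrap_r2_ci`).  Distance-based variance partitioning (sequential
   sums of squares on the Gower-centred inner-product matrix) of core-SNP
   and accessory-content distances by soil and reserve, with permutation
   p-values and strain-bootstrap percentile intervals for R².

## The synthetic-data generator

The study's draft genomes and growth measurements are not public, so
`simulate_population()` generates populations with the statistical
structure the analyses assume.  Its defaults are the study conditions:

| parameter | default | why |
|---|---|---|
| strains | 19 serpentine + 19 non-serpentine, 3 reserves | the focal-clade design |
| accessory frequency spectrum | Beta(0.3, 0.3) | genes tend to be rare or ubiquitous (U shape); the shape parameters are the only free choice, set so roughly half the accessory mass sits below 0.1 or above 0.9 |
| admixture | 2 subgroups, Dirichlet(0.2) loadings | two weakly separated subgroups, most strains near-fully assigned |
| subgroup differentiation | Balding–Nichols F = 0.1 | mild structure in both accessory frequencies and SNPs — enough to confound an uncorrected scan |
| planted clusters | 13 genes / 30 kbp, perfect assortment; 10 / 30 kbp and 11 / 15 kbp in 6/19 serpentine strains | the observed cluster geometry |
| phenotype | baseline 0.5 OD600 + 0.28 per causal cluster + 0.1 × subgroup-1 loading + N(0, 0.05) | additive Gaussian model (our design choice; no generative model is given for the real assay); 0.28 OD600 is the per-variant effect size the study system exhibits |
| low-nickel growth | same model without the causal term | nickel-specific adaptation |
| donor-distance shift | +0.033 on a Beta(2, 38) baseline | the reported average shift on a baseline centred at 5% 16S divergence |
| gene dropout | 0 | perfect gene calling by default; raise to study miscalling |

Pool sizes default to desk scale — 500 core genes, 2000 accessory genes,
1000 SNP sites — because the statistical behaviour of every stage is
governed by strain number and per-variant class sizes, not by the total
gene count; the real study's tens of thousands of genes and 2 × 10^5 SNPs
would only multiply runtime.  Scripts that need other scales say so
explicitly.

Seeding is a single master integer; each stage (population, phenotypes,
layouts, homolog distances, hit tables, dropout, SNPs) derives its own
stream by a fixed documented offset, so a stage can be re-run in isolation
and reproduce its draws, and equal configs give byte-identical outputs.

**What the generator does not emulate:** read-level sequencing and
assembly error (dropout is a gene-level Bernoulli stand-in — the original
verification simulation is not described in enough detail to reproduce its
design, so ours is labelled a stand-in); linkage between accessory genes
beyond the planted clusters; gene gain/loss phylogeny; indels, duplications
and rearrangements inside clusters (order is conserved by construction,
so order-conservation statistics on synthetic data are upper bounds); 16S
sequences themselves (donor distances are drawn, not computed from
sequence).  Passing tests on this generator therefore demonstrate the
statistical machinery, not robustness to assembly artefacts.

## Numerical and design decisions

* **Overlap denominator.**  Hit overlap is alignment length over *query*
  length; the threshold source does not specify the denominator, so it is
  configurable (`min_overlap`), and all three homology thresholds are
  strict inequalities.
* **Orthology.**  Reciprocal-best-hit ties (equal bitscore and E-value)
  break lexicographically by subject id and are flagged ambiguous.
  Multi-strain orthology is single-linkage closure, the least committal
  extension of pairwise reciprocity; reference assignment wins over RBH
  closure; in-paralogs (two genes of one strain in a group) are split to
  singleton groups, keeping the better-supported member.
* **SNP calling.**  Alignment columns containing any gap or ambiguity
  character in the strain subset are skipped entirely (complete-column
  deletion) so every retained site is called in every strain; the
  alternative, pairwise deletion, would make the SNP matrix
  pair-dependent.
* **NG86.**  Fractional synonymous site counts are averaged over the two
  sequences; multi-step codon differences average over all shortest
  mutational pathways, excluding pathways through stop codons (all
  pathways are used if every one is blocked); mutations *to* stop codons
  count as nonsynonymous in site counting; code table 11 (bacterial) is
  the default; Jukes–Cantor correction is undefined at p ≥ 3/4 and the
  result is flagged rather than clamped.  Genes with Ka = 0 or Ks = 0 are
  excluded from the log10 compartment comparison by default (a pseudocount
  is available) — zero rates carry no log-scale information and a
  pseudocount choice would be arbitrary.
* **Wilcoxon.**  The reported W is the rank sum of the first group
  (carriers).  The exact null distribution is used when the smaller group
  has ≤ 25 observations and there are no ties (`exact_max_n`,
  configurable); otherwise the normal approximation with tie and
  continuity corrections.  Residualizing on Q once and testing both
  variant kinds on the same residuals keeps the two scans comparable.
* **FDR.**  Benjamini–Hochberg is the default because it is assumption-
  free; the Storey q-value (π0 estimated at λ = 0.5) is available where a
  denser signal makes π0 < 1 worthwhile.
* **Cluster calling.**  "Tandem" means consecutive in gene order,
  regardless of strand or intergenic distance (draft-genome coordinates
  make bp gaps between neighbours unreliable); the 10-kb gap rule is
  applied edge-to-proximal-gene-boundary, which makes the caller exactly
  invariant under coordinate mirroring; extension iterates to a fixed
  point and clusters brought into contact merge.  Candidates at 10% FDR
  seed clusters.
* **PERMANOVA.**  Sequential (Type-I) sums of squares with soil entered
  before reserve, matching the common adonis default; free permutation of
  strain labels (no strata); all n! permutations are enumerated when
  n! ≤ 10 000 so small-sample p-values are exact.  The bootstrap resamples
  strains with replacement (duplicates get zero mutual distance) and
  discards replicates in which a factor collapses to one level, reporting
  the count.  Note that R² of a null factor is positively biased (null
  expectation ≈ df/(n − 1)), so bootstrap intervals for a null factor sit
  above zero; interpret intervals by separation, not by exclusion of zero.
* **Degenerate inputs** raise errors rather than silently returning:
  empty strain subsets, an all-absent pan-genome (e.g. dropout rate 1),
  a homolog table in which every accessory gene is a candidate, empty
  Wilcoxon/KS classes, factors with one level, strains sharing no called
  SNP sites.

## Statistical behaviour worth knowing

* The exact Wilcoxon is discrete: at α = 0.05 and minor-class sizes of
  2–5 the achievable rejection rate is 0.045–0.050, so genome-wide
  false-positive rates sit just under nominal even at the pure null.
* Residualizing the phenotype on Q makes the scan slightly conservative
  for variants whose presence correlates with structure (the projection
  removes part of the between-class contrast).  At the default mild
  structure this costs little; under strong confounding the corrected
  scan is clearly valid but noticeably conservative, while the
  *uncorrected* scan is badly inflated — the motivation for the
  correction.
* Under the global null, Benjamini–Hochberg returns at least one
  candidate with probability up to the FDR level, so a 20% FDR scan of a
  null phenotype is empty in about 80% of replicates, not always.

## Problem sizes used by the tests and scripts

The test-suite simulations use 10–38 strains, 50–2000 accessory genes and
up to 100 replicates; the acceptance script runs the full default scenario
(38 strains, 2500 gene pool, 1000 SNPs, 999 permutations, 200 bootstrap
replicates), 100 power replicates, three null replicates (~2300 tests) and
a 40-replicate dropout simulation.  These sizes were chosen as the
smallest at which the Monte-Carlo bounds asserted by the tests are sharp.

## Limitations

Annotation, GO enrichment, network inference (NeighborNet), STRUCTURE
inference and 16S homolog searching are out of scope: the pipeline
consumes a prepared Q-matrix and a prepared homolog-distance table.
Mixed-model (kinship) association is not implemented; the structure
correction is a fixed-effect OLS residualization.  Ka/Ks is counting-based
(NG86), not maximum-likelihood.  The cluster caller assumes correct gene
order within contigs and does not attempt insertion-site inference.
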