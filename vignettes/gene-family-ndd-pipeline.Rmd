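---
title: "Gene-family analysis of de novo variation in neurodevelopmental disorders: methods and design"
author: "famburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-family analysis of de novo variation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famburden)
```

# The problem

Exome sequencing of parent–child trios has implicated hundreds of genes in
neurodevelopmental disorders (NDDs), but statistical evidence accumulates
slowly for individually rare disorders. Most Mendelian disease genes belong
to gene families whose members share structure and function — the
heterogeneous nuclear ribonucleoproteins (hnRNPs), a family of 33 RNA-binding
proteins, are a canonical example. When one family member is a confirmed NDD
gene, its close paralogs are strong candidates: they may produce similar
phenotypes through similar molecular failure modes even before any single
gene reaches exome-wide statistical significance on its own.

`famburden` implements that gene-family discovery strategy as a tested,
fully reproducible pipeline:

1. **ingest** — parse proband variant tables, classify variants, apply
   proband exclusion rules, tabulate inheritance, and apply the
   minimum-proband candidate rule;
2. **homology** — pairwise protein percent identity, identity-profile
   correlations, hierarchical family grouping, and candidate expansion by
   group membership;
3. **dnv_enrichment** — per-gene excess of de novo variants against
   expected counts from pluggable mutation-rate models;
4. **missense_clustering** — a position-clustering score with
   case/control permutation tests, phenotype stratification and
   domain-overlap summaries;
5. **expression** — cell-type enrichment, fold-change Z-scores,
   expression-profile correlations, gene-set region enrichment, and
   family-vs-external similarity comparisons;
6. **phenotype** — proband-by-phenotype matrices, the characteristic-term
   filter, cohort frequency profiles, pairwise Fisher contrasts, and
   homology–phenotype concordance;
7. **cnv** — intersection of family genes with genomic-disorder intervals
   and gene-focal CNV filtering;
8. **synthetic_data** — generators for every input with known ground
   truth;
9. **orchestration** — `run_pipeline()` gluing the stages together with a
   single seed and TSV/JSON reports.

Every stage runs without network access or external downloads: real data
enter as plain TSV/FASTA/BED/GMT files, and the synthetic module emulates
their statistical structure for testing.

# Variant classification and proband rules

Variants are classified by consequence and CADD deleteriousness score:

* **LGD** (likely gene disrupting): stop gain, frameshift, splice
  disruption — and start loss by default (`start_loss_lgd = FALSE`
  reclassifies it), regardless of CADD;
* **MIS30**: missense with CADD ≥ 30 (top 0.1% of predicted deleterious
  variants); **MIS20**: 20 ≤ CADD < 30 (top 1%); **MIS_noCADD**: missense
  without a score, retained rather than dropped because inheritance
  tabulations report it as its own row; missense with CADD < 20 is
  `excluded`. All thresholds are inclusive on the ≥ side.

Probands are excluded when any of seven criteria holds: another causative
NDD variant, an inherited (non-mosaic) family-gene variant, presence of the
variant in a population database, missense CADD < 20, consanguinity,
prematurity (< 37 weeks gestation), or age < 1 year (too young to assess
developmental delay). A missing field never triggers a criterion: clinical
metadata are routinely incomplete, and treating absence of evidence as an
exclusion would silently bias cohorts. `apply_exclusions()` returns every
triggered reason so the audit trail is complete.

Mosaic variants are tallied with de novo events in `tabulate_inheritance()`
— a mosaic variant is a post-zygotic new mutation — but the record keeps its
`mosaic` label. A gene becomes a candidate when ≥ 3 distinct probands carry
retained variants (`select_candidate_genes()`, threshold configurable);
a proband with several variants in one gene counts once.

# Protein homology grouping

`pairwise_identity()` computes Needleman–Wunsch global alignments with
affine gap penalties for every sequence pair (match +1, mismatch 0, gap
open −5, gap extend −1 by default; a gap of length $l$ scores
$g_{open} + l\,g_{ext}$). Percent identity is identical aligned columns
divided by **all** alignment columns, including gap columns; the
alternative denominator (shorter sequence length) is available via
`denominator = "shorter"`. The column denominator is the stricter choice
and is the one under test in the group-recovery contract. A pre-aligned
FASTA can be supplied instead (`identity_from_alignment()`), in which case
columns where both sequences gap are dropped for that pair.

`profile_correlation()` correlates two proteins' identity *profiles* — how
similarly they relate to the rest of the family — excluding the
self-entries of the pair being compared, which would otherwise inflate R.
This is one of two defensible readings of a family correlation plot; direct
identity-as-similarity clustering is supported via
`cluster_groups(use = "identity")` and recovers the same planted groups in
the tests. Clustering is average-linkage on distance $1 - R$, genes
ordered by name before linkage so the dendrogram is deterministic;
`expand_candidates()` returns every member of any group containing a known
NDD gene.

# De novo burden

For a rate model giving per-gene, per-class, per-haploid-genome mutation
rates $\mu$, the expected de novo count in $N$ trios is
$\lambda = 2N\mu$. The observed count $o$ (de novo + mosaic; missense
restricted to CADD ≥ 20 tiers) is tested with the exact Poisson upper tail

$$p = P(X \ge o), \quad X \sim \mathrm{Poisson}(\lambda),$$

computed via the survival function — no normal approximation, because
per-gene expectations are typically far below 1. The "protein" class
observes $o_{LGD} + o_{mis}$ against the table's own `mu_protein` (defaults
to the sum of class rates when a model does not provide it).

Multiple testing uses the family-wise Bonferroni threshold
$\alpha / (G \times 3 \times 2)$ — $G$ genes in the rate model, three
mutation classes per gene, two rate models per class. With $\alpha = 0.05$
this gives $4.4\times10^{-7}$ at $G = 18{,}946$ and $4.2\times10^{-7}$ at
$G = 19{,}618$, the two model sizes used in published NDD meta-analyses.
Significance labels use strict `<`; genes absent from a rate table are
flagged in the result attributes and skipped for that model. Rate models
are pluggable TSV inputs: the statistical machinery is the implemented
contract, not any particular model fit.

# The position-clustering score

Pathogenic missense variants often cluster in specific domains. The score
treats the $m$ mutated residues of a protein of length $L$ (recurrences
kept with multiplicity — a recurrent residue is itself evidence of
clustering) as points $x_i = \mathrm{pos}_i / L \in (0, 1]$ and solves
exact 1-D $k$-medoids for $k = 1, \ldots, \min(k_{max}, m, \#\text{unique})$:

$$S = \frac{1}{m}\sum_i \left|x_i - \mathrm{med}(x_i)\right|,$$

the mean distance to the nearest medoid at the selected $k$. Lower $S$
means tighter clustering; $S = 0$ when all positions coincide; $S$ is
invariant under shifting all positions by a constant.

Numerical details, fixed so results are inspectable and reproducible:

* optimal 1-D $k$-medoids clusters are contiguous runs of the sorted
  positions, so the exact optimum is found by dynamic programming over
  segment boundaries (C++, `src/clump.cpp`); each segment's medoid is its
  lower median; backtracking prefers the leftmost feasible boundary, making
  the partition canonical;
* $k$ is selected by maximum mean silhouette width computed from the
  partition memberships; singleton clusters score 0; $k = 1$ is the
  baseline with silhouette 0 and is forced when $m < 3$; ties go to the
  smallest $k$;
* $k_{max}$ defaults to **3**: proteins harbor at most a few mutational
  hotspot domains, and allowing many medoids on small position sets lets
  the medoid count absorb genuine hotspot signal (each stray position gets
  a private medoid, collapsing $S$ toward 0 for clustered and uniform data
  alike);
* the tests verify the scorer against an exhaustive
  contiguous-partition enumeration oracle on 200 random instances.

`case_control_permutation()` compares case and control position sets on the
same protein: $\Delta = S_{control} - S_{case}$, positions pooled and
re-split preserving group sizes, with the add-one-corrected one-sided
$p = (1 + \#\{\Delta_{perm} \ge \Delta_{obs}\})/(1 + n_{perm})$, which is
never zero and keeps the test valid at any $n_{perm}$. Runs below 100
permutations are flagged. `family_paired_test()` aggregates per-gene
(case, control) score pairs with a one-sided paired t-test;
`phenotype_stratified()` reruns the permutation test on phenotype-defined
case subsets, skipping strata with fewer than two positions; exons with
inadequate control coverage can be masked with a residue-interval
blacklist on input. The per-gene permutation approach is this package's
concrete choice where published descriptions defer to an external tool
whose $k$-selection rule is not fully specified; equivalence with that tool
is not claimed.

# Expression analyses

`celltype_enrichment()` tests one gene per cell type with a two-sample
Wilcoxon rank-sum (in-type vs all other cells) — a rank test, so p-values
are invariant under monotone transforms of the expression values — with a
fold change of means using pseudocount $\varepsilon = 10^{-9}$ and
Bonferroni correction by the number of cell types. Constant genes are
flagged, with p = 1 and undefined fold change. `foldchange_z()` standardizes
the log2 fold changes across cell types per gene; a zero-SD profile yields
all-zero Z with a flag rather than NaNs.

`expression_correlation()` works on per-type mean profiles with Pearson R;
p-values get a configurable Bonferroni factor defaulting to
$n_{genes} \times n_{types}$ (conventions for profile-correlation
corrections differ between publications, so the factor is an explicit
argument). `region_enrichment()` is a one-sided Fisher exact test of a gene
set against named region/window sets over a background universe, with
Benjamini–Hochberg correction across sets. `family_vs_external()` asks
whether family members' expression profiles resemble each other more than
they resemble genes of phenotypically similar external disorders (paired
one-sided t over per-gene mean correlations). Adult-tissue two-way
comparisons reuse `expression_anova()` on a long-format table; no external
expression resource is bundled or downloaded.

# Phenotype convergence

`build_matrix()` produces a proband × term binary matrix in which missing
is **not** absent; quantitative measurements map to qualitative terms at
the extreme percentiles (≤ 3rd / ≥ 97th, inclusive). All denominators use
assessed (non-missing) probands per term — this is why published cohort
denominators vary from analysis to analysis, and the package reproduces
that behavior rather than imputing. The ≥ 20% characteristic filter
(`characteristic_filter()`, boundary inclusive, threshold $\tau$
configurable) is likewise computed on assessed probands per cohort; the
filter is monotone in $\tau$ and keeps every observed term at $\tau = 0$.

Pairwise cohort contrasts use two-sided Fisher exact tests with a layered
Bonferroni factor (genes × phenotypes × mutation categories, default
12 × 88 × 3, each factor overridable). Odds ratios use the
Haldane–Anscombe +0.5 correction when a table cell is zero — the exact p
is unaffected — and Woolf (log-OR) confidence intervals on the corrected
table. `homology_phenotype_concordance()` compares a protein-similarity
matrix with a phenotype-correlation matrix: concordant pairs above
R = 0.5 (configurable), the Pearson correlation of the upper triangles,
and a Mantel label-permutation p (via vegan). `shared_hpo_comparison()`
contrasts mean shared characteristic-term counts (or Jaccard indices)
within the family versus against external disorders with a paired
one-sided t-test.

# Genomic intervals

Coordinates are 0-based half-open internally (`[start, end)`, `chr`
prefixes stripped); 1-based inclusive clinical tables convert via
`dialect = "onebased"`. Gene/region intersection is an any-overlap join
(≥ 1 shared base) through GenomicRanges, with whole-gene containment
available via `containment = TRUE` since the minimum-overlap convention
differs between published interval lists. `filter_focal_cnvs()` keeps CNVs
that overlap the target gene and whose other overlapped genes are all
flagged non-haploinsufficient; a neighbor with a missing flag makes the
CNV indeterminate, excluded by default.

# What the synthetic generators emulate — and what they do not

Each generator reproduces the *statistical* structure of one input:

* `sim_rate_table()` / `gen_dnv_cohort()`: per-gene Poisson de novo counts
  at $\lambda = 2N\mu$ with optional per-gene enrichment multipliers;
  LGD/missense consequences and severe CADD scores attached;
* `gen_positions()`: mixture of uniform positions and a truncated-normal
  hotspot (center, σ, weight);
* `gen_expression()`: lognormal base expression with fold-multiplied
  enriched cell types;
* `gen_phenotype_cohorts()`: Bernoulli term statuses with prevalence
  $w \cdot \mathrm{base} + (1 - w) \cdot \mathrm{cohort}$, so $w$ dials
  cohort similarity from independent (0) to identical in expectation (1),
  plus uniform missingness;
* `gen_protein_family()`: per-group random ancestors with independent
  per-residue substitutions, so within-group identity is ≈
  $100(1 - p_{sub})$ (plus chance agreement) and between-group identity
  sits at the random-alignment baseline.

All randomness flows from explicit integer seeds; the pipeline derives
per-stage seeds from one master seed by fixed offsets so any stage can be
regenerated independently.

These generators deliberately do **not** model: trinucleotide mutational
signatures or CpG hotspots (real rate models do; here rates are inputs),
ascertainment bias across referral centers, linkage between phenotype
terms, cell-type proportions or dropout noise of real single-cell data, or
insertions/deletions in protein evolution. Passing tests therefore
demonstrate that the statistical machinery is correct and well calibrated
under its stated model — not that any particular real dataset will show an
effect.

# Test and simulation scales

The test suite and `scripts/acceptance.R` size their simulations so the
whole suite runs comfortably on a single CPU:

* burden null calibration: 1,000 genes with per-class rates uniform on
  $[10^{-6}, 10^{-5}]$, 5,000 trios, 20 replicate cohorts; empirical
  type-I error at α = 0.05 is required to stay at or below nominal (the
  discrete Poisson test is conservative, and measures ≈ 0.013);
* planted burden signal: one gene with the rate profile of a large,
  highly mutable gene ($\mu_{LGD} = 2\times10^{-5}$,
  $\mu_{mis} = 4\times10^{-5}$ — the family's largest member is physically
  large, and large constrained genes occupy the top of the per-gene rate
  distribution) inflated 50×. At these settings the analytic per-seed miss
  probability is ~10⁻⁶, so recovery in ≥ 19/20 seeds is a property of the
  design rather than a tuned outcome;
* clustering: oracle agreement on 200 random instances (m ≤ 8); null
  calibration on 1,000 simulated genes at 199 permutations; planted
  hotspot (weight 0.8, σ = 0.01·L, m = 20) against 160 uniform control
  positions — the per-gene scale of a population-database control cohort
  (≈ 2,000 control missense variants across a 12-gene family) — at 10,000
  permutations;
* expression: 8 cell types × 200 cells, 5× planted marker, 20 seeds;
* phenotype: 6 cohorts × 50 probands for the shared-profile check
  (w = 0.85); 3 homology groups × 3 cohorts with a 0.6 global / 0.4
  group-specific prevalence mixture for the concordance check;
* homology: 3 families × 4 members, 80-residue ancestors, 10%
  substitution, 20 seeds, exact recovery (Rand index 1) required.

# Known limitations

* The position-clustering score fixes its own $k$-selection and
  normalization conventions; other clustering tools may differ in detail,
  and no equivalence with any specific external implementation is claimed.
* Percent identity from pairwise global alignments is not identical to
  identity read off a progressive multiple alignment; for family grouping
  the two agree in the tested regimes, and a precomputed multiple
  alignment can be supplied directly.
* The Poisson burden test treats the rate tables as known constants;
  uncertainty in the mutation-rate models is not propagated.
* Bonferroni-style corrections are intentionally blunt (matching field
  practice for these analyses); no hierarchical or empirical-Bayes
  alternative is provided.
* Phenotype analyses treat terms independently; no ontology propagation or
  semantic similarity is performed, and correlated terms will correlate
  cohorts.

# End-to-end example

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(seed = 7, out_dir = "famburden_report",
                       n_trios = 5000, n_genes = 150)
res <- run_pipeline(cfg)
res$burden[res$burden$tier == "exome_wide", ]
res$clump$p
res$homology$groups$n_groups
```

The report directory contains the inheritance table, the burden results,
the candidate list, phenotype frequencies, and a machine-readable JSON
summary echoing the full configuration and seed.
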