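# famburden

Gene-family burden, clustering, expression and phenotype-convergence
analysis for neurodevelopmental-disorder (NDD) gene discovery.

## What problem this solves

Individually rare NDD genes accumulate statistical evidence slowly, but
most Mendelian disease genes sit inside gene families whose members share
structure and function (the hnRNP family of RNA-binding proteins is a
canonical example). `famburden` implements the family-based discovery
strategy end to end, for statistical geneticists and clinical researchers
assembling multi-cohort variant collections:

* **candidate selection** — variant classification (LGD; severe missense by
  CADD tier), proband exclusion rules, the ≥ 3-distinct-probands rule, and
  candidate expansion through protein-homology groups;
* **de novo burden** — for per-gene mutation rate μ and N trios, the
  expected count is λ = 2Nμ and the observed de novo count o is tested with
  the exact Poisson tail p = P(X ≥ o), X ~ Poisson(λ), against the
  family-wise threshold α/(G·3·2) (G genes × 3 mutation classes × 2 rate
  models);
* **missense position clustering** — mutation positions normalized by
  protein length are scored with exact 1-D k-medoids,
  S = (1/m) Σᵢ |xᵢ − nearest medoid|, k chosen by silhouette; lower S =
  tighter clustering; case/control differences Δ = S_control − S_case get
  an add-one-corrected permutation p;
* **expression** — per-cell-type Wilcoxon rank-sum enrichment with
  Bonferroni correction, fold-change Z-scores, profile correlations, and
  Fisher/BH region-set enrichment;
* **phenotype convergence** — proband × HPO-term matrices (missing ≠
  absent), the ≥ 20% characteristic-phenotype filter, pairwise Fisher
  tests with layered Bonferroni (genes × phenotypes × categories), odds
  ratios with Haldane–Anscombe correction, and homology–phenotype
  concordance (upper-triangle correlation + Mantel permutation p);
* **CNV intersection** — half-open interval joins of family genes against
  genomic-disorder regions, and gene-focal CNV filtering by neighbor
  haploinsufficiency;
* **synthetic data** — seeded generators for every input (Poisson variant
  cohorts, hotspot position mixtures, lognormal expression with planted
  markers, Bernoulli phenotype cohorts, protein families mutated from
  group ancestors) so the whole pipeline runs and is tested without any
  download.

The methods vignette (`vignettes/gene-family-ndd-pipeline.Rmd`) documents
every model, parameter default and numerical convention.

## Worked example

Classify variants and reproduce a published-style inheritance table from
per-class tallies:

```r
library(famburden)

classify_variant(c("missense", "stop_gained", "missense"), c(25, NA, 12))
#> [1] "MIS20"    "LGD"      "excluded"

tally <- read.table(system.file("extdata", "inheritance_tally.tsv",
                                package = "famburden"),
                    header = TRUE, sep = "\t")
tab <- tabulate_inheritance(expand_inheritance_tally(tally))
round(tab[c("LGD", "all_MIS", "all"), 1:4], 1)
#>         de_novo inherited unknown total
#> LGD         114         1      24   139
#> all_MIS      50         1      35    86
#> all         164         2      59   225

str(inheritance_summary(tab))
#> List of 3
#>  $ pct_known_inheritance  : num 73.8
#>  $ pct_de_novo_among_known: num 98.8
#>  $ pct_lgd_share          : num 61.8
```

73.8% of the 225 variants have known inheritance; 98.8% of those are de
novo (mosaic counted as de novo); LGD variants are 61.8% of the cohort.

Run the full pipeline on synthetic inputs with one planted 50×-enriched
gene:

```r
cfg <- pipeline_config(seed = 7, out_dir = "famburden_report",
                       n_trios = 5000, n_genes = 150)
res <- run_pipeline(cfg)
b <- res$burden
head(b[order(b$p), c("gene", "class", "model", "observed", "expected",
                     "p", "tier")], 4)
#>     gene   class  model observed expected        p       tier
#> 1  g0001     LGD modelA        6    0.099 1.20e-09 exome_wide
#> 52 g0001     LGD modelB        6    0.102 1.40e-09 exome_wide
#> 35 g0001 protein modelA        6    0.117 3.28e-09 exome_wide
#> 86 g0001 protein modelB        6    0.120 3.72e-09 exome_wide
res$clump$p
#> [1] 0.000999001
res$homology$groups$n_groups
#> [1] 3
```

The planted gene `g0001` observed 6 de novo LGD events against an
expectation of ~0.1 and reaches exome-wide significance under both rate
models (p far below the family-wise threshold, here 8.3×10⁻⁶ for the
150-gene model); the planted missense hotspot is detected by the
permutation test (p ≈ 0.001); the three planted protein families are
recovered. The report directory holds TSV tables plus a JSON summary
echoing the seed and configuration.

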