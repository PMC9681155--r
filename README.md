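# ervscan

Locus-level analysis of transposable-element (TE) repression and enhancer
activity in cloned mouse embryos.

Embryos produced by somatic cell nuclear transfer (SCNT) inherit somatic
epigenetic marks, and endogenous retroviruses (ERVs) — silenced in somatic
cells but transiently active in normal preimplantation embryos — are prime
suspects for reprogramming failure. `ervscan` is for epigenomics /
regulatory-genomics analysts who start from per-embryo RNA-seq count tables
over a repeat annotation (plus ChIP/input counts) and want to:

* classify TE loci as **SCNT-low / SCNT-high / unchanged** with an NB Wald
  test on RLE-normalized counts — SCNT-low iff log₂(SCNT/IVF) ≤ −1 and
  BH-adjusted p < 0.1;
* score **enhancer-like** chromatin per locus from H3K27ac ChIP/input,
  using the sliding-bin normalizer
  RPKM = count / ((length/1000) × (bin total/10⁶)) over 2-kb bins every
  1 kb, enrichment = log₂((RPKM_ChIP + 0.5)/(RPKM_input + 0.5)), and the
  enhancer-like rule enrichment ≥ 1.5;
* **link loci to nearby genes** whose TSS lies 5–50 kb or 50–200 kb from
  the locus boundary and measure the Spearman correlation of the TE and
  gene SCNT/IVF log₂ ratios;
* analyze **enhancer-knockout** experiments: expression-based genotype
  calls (both target loci < 5 TPM), Welch t-tests on adjacent genes,
  KO-vs-SCNT ratio correlation, and a 1:2:1 Mendelian chi-square.

A seeded synthetic-data generator plants repressed loci, enhancer loci and
linked genes with known effect sizes, so sensitivity, false discovery and
calibration are measurable facts, not hopes. See
`vignettes/ervscan-methods.Rmd` for the models, parameter choices and
limitations.

## Worked example

One seed drives the whole run — simulation, depth-matching, and every
analysis stage:

```r
library(ervscan)

cfg <- run_config(sim = sim_config(seed = 1), out_dir = "example_run")
res <- run_pipeline(cfg)
r <- res$report

r$differential[c("n_te_expressed", "n_scnt_low", "n_scnt_high")]
#> $n_te_expressed  [1] 1999
#> $n_scnt_low      [1] 115
#> $n_scnt_high     [1] 0

head(res$diff[res$diff$klass == "SCNT_low", ], 3)
#> # A tibble: 3 x 7
#>   feature_id base_mean log2fc        p tested     padj klass
#>   <chr>          <dbl>  <dbl>    <dbl> <lgl>     <dbl> <chr>
#> 1 te_00072       12.0   -2.14 9.25e-17 TRUE   2.58e-15 SCNT_low
#> 2 te_00091       14.1   -2.11 4.93e-26 TRUE   2.46e-24 SCNT_low
#> 3 te_00140        3.35  -1.11 1.69e- 4 TRUE   2.22e- 3 SCNT_low

r$enrichment$mean_planted_enrichment   # planted ChIP fold 8 -> log2 ~ 3
#> [1] 2.9
unlist(r$enrichment$enhancer_of_scnt_low_ervk)
#> n 69   total 115   fraction 0.6   percent 60
c(r$enrichment$fisher_odds_ratio, r$enrichment$fisher_p)
#> [1] 1.91e+02 1.84e-49

unlist(r$linkage$planted)              # planted transfer slope 0.8
#> rho 0.727   p 7.37e-13   n 71
```

Reading the numbers: of 1,999 expressed TE loci, 115 are called SCNT-low
(the generator planted 120 repressed RLTR45-int loci at a median 4-fold —
sensitivity 0.96 here, no false positives, and no SCNT-high artifacts).
Planted enhancer loci score a mean log₂ enrichment of 2.90 against the
generating value log₂ 8 = 3 (the 0.5 pseudocount shrinks mildly), the
SCNT-low and enhancer-like sets overlap far beyond chance (Fisher
OR = 191), and the planted TE-to-gene ratio coupling is recovered as a
strong positive Spearman correlation over the planted pairs. The pooled
correlation over *all* nearby pairs (`r$linkage$pooled`) is much weaker
because most nearby genes are not regulated by the locus — the same
dilution that keeps such correlations modest in real data. The knockout
stage reports genotype calls, adjacent-gene ratios (linked and unlinked
neighbours pooled), and the Mendelian chi-square on the recovered
genotypes.

`run_pipeline()` writes `diff.tsv`, `enrichment.tsv`, `linkage.tsv`,
`composition.tsv`, `ko.tsv`, a reusable copy of its inputs, and
`report.json`; re-running on `example_run/inputs` (the load path)
reproduces the report byte for byte.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/scan.R run --seed 1 --out example_run
```

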