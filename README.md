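# dhscreen

Screening gene- and cell-type-specific enhancers from DNase I
hypersensitive site (DHS) panels.

## What this is for

Cell-type-specific gene expression is driven largely by enhancers, and
open chromatin — mapped as DHSs by DNase-seq — marks where candidate
enhancers sit. Given peak panels across many cell types, expression
data, and dual-luciferase reporter measurements, `dhscreen` runs the
full screening strategy used to find erythroid-specific enhancers
around the human Krüppel-like factor (KLF) genes, as a reusable,
tested R pipeline:

1. **Expression screen** — RPKM = `counts / ((L/10³)(N/10⁶))` with a
   0.01 detection floor; genes strictly higher in every erythroid
   sample than in the reference are nominated. qPCR confirmation by
   2^(−ΔΔCt) against 18S rRNA with per-gene t-tests.
2. **Specificity classification** — within each locus domain (TSS − 70 kb
   to poly(A) + 20 kb), peaks from all cell types are merged into named
   sites (`GENE-I`, `GENE-II`, … 5′→3′). A site is *target-specific* if
   present only in target (erythroid) cell types, *putative* if present
   in ≤ 2 non-target cell types at signals < ½ the weakest target peak,
   *non-specific* otherwise.
3. **Reporter scoring** — firefly/renilla well ratios, batch-mean
   summaries; minP call = fold ≥ 5 over the minimal-promoter baseline
   (log₂ 5 = 2.32); gene-promoter call = two-group one-way ANOVA
   (F = t²) at p < 0.01 with a required mean increase; a site activating
   the promoter in K562 but in neither HeLa nor HEK293 is an
   *erythroid-specific enhancer*.
4. **Evidence cross-tabulation** — conservation, FAIRE, H3K4me1/H3K27ac
   (with target-specific flags), GATA-1/NF-E2 occupancy; site × TF
   ChIP cluster-score matrix with seed-stable k-means classes; summary
   counts and positional histograms.
5. **Synthetic data** — `simulate_screen()` generates every input with
   a planted ground-truth ledger, so the whole pipeline is testable
   offline.

## Worked example

Replaying the packaged cross-tabulation of the published screen (23
candidate sites over 10 KLF genes; the table records the boolean
enhancer calls):

```r
library(dhscreen)
rep1 <- replay_table1(read_table1())
rep1$summary
#> <screen_summary>
#>   sites: 23
#>   minP enhancers (fold >= threshold): 15
#>   promoter enhancers in target line:  15
#>   target-specific enhancers:          10
#>   over the target-specific set: 5 conserved, 10 histone-marked,
#>     7 with target-specific marks, 6 GATA-1/NF-E2 occupied
```

That is the published arithmetic: 15 of 23 sites (65%) activate the
minimal promoter five-fold or more, 15 activate their own gene promoter
in K562, and 10 (43%) do so in K562 only — the erythroid-specific
enhancers — of which 5 are conserved in placental mammals, all 10 carry
H3K4me1 and/or H3K27ac, 7 carry erythroid-specific marks, and 6 are
bound by GATA-1 and/or NF-E2.

Running the same machinery on synthetic data with planted truth:

```r
sim <- simulate_screen(sim_config(seed = 42, n_genes = 6))
screen_locus(sim$domains[["GENE001"]], sim$peaks, sim$panel)$sites[, c(1, 3, 4, 6)]
#>       site_id  start    end           label
#> 1   GENE001-I 106706 107079    non_specific
#> 2  GENE001-II 145598 146500 target_specific
#> 3 GENE001-III 152603 153178    non_specific

calls <- score_reporter_plate(sim$plate)$calls
head(calls[, c("site_id", "minP_fold", "minP_enhancer", "erythroid_specific", "category")], 3)
#>       site_id minP_fold minP_enhancer erythroid_specific     category
#> 1  GENE001-II 0.9921788         FALSE              FALSE non_enhancer
#> 2  GENE002-IV 0.9469907         FALSE              FALSE non_enhancer
#> 3 GENE002-III 8.3923994          TRUE               TRUE         dual
```

`GENE002-III` was planted as a dual (minP + promoter) erythroid-specific
enhancer: it activates minP 8.4-fold (≥ 5) and its gene promoter in the
target line only, so the decision tree recovers `dual` /
erythroid-specific; the flat sites stay `non_enhancer`.

## Command line

```sh
Rscript -e 'dhscreen::dhscreen_cli()' simulate --out simdir --seed 4 --n-genes 10
Rscript -e 'dhscreen::dhscreen_cli()' run --config config.json --out outdir
```

`run` executes expression → specificity → reporter → evidence → summary,
skipping stages whose inputs are absent; a config with
`inputs: {table1: ...}` runs the call-replay mode above. Configs are
YAML or JSON with keys mirroring `pipeline_config()`.

## Layout

- `R/` — intervals/gene models, specificity classifier, expression
  screen, reporter scoring, evidence annotation, simulator, pipeline/CLI
- `inst/extdata/table1_dhs.tsv` — verbatim transcription of the
  published 23-site cross-tabulation
- `tests/testthat/` — unit, property and acceptance suites with
  brute-force oracles
- `vignettes/enhancer-screening.Rmd` — models, assumptions, parameter
  rationale, limitations
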