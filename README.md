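# qhtscreen

Analysis pipeline for quantitative high-throughput screening (qHTS)
cell-viability assays in 1536-well format, built for drug-repurposing
screens on primary patient cells — the motivating case is screening an
approved-drug library against chronic lymphocytic leukemia (CLL)
lymphocytes alongside lymphocytes from unaffected donors, to find
compounds that kill the leukemic cells selectively.

In qHTS every compound is tested as a full concentration titration (here
8 points, 1:5 from 57 µM to 0.7 nM, titrated across a stack of plates),
so the unit of analysis is a concentration-response curve per compound
per sample. The package covers the whole chain:

* **Plate model** — 32 × 48 layout with DMSO control columns, a
  doxorubicin titration column (1:2, 10 µM → 5 nM) and a fixed 10 µM
  doxorubicin full-kill column; dilution-series and pintool-transfer
  arithmetic (23 nL of 10 mM stock into 4 µL ⇒ 57 µM top dose).
* **Normalization & QC** — per-plate anchoring at DMSO (0%) and full kill
  (−100%); spatial pattern correction by relative background fields from
  the DMSO-only plates bracketing each stack, interpolated across stack
  position; Z′-factor, signal-to-background and CV reports.
* **Dose-response** — bounded Levenberg–Marquardt fits of the
  four-parameter logistic
  `y(c) = y0 + (yinf − y0)/(1 + (AC50/c)^h)`,
  with deterministic initialization and fit diagnostics.
* **Curve classification** — the qHTS CRC taxonomy (1.1/1.2 complete,
  2.1/2.2 incomplete, 3 low-confidence, 4 inactive) and its collapse to
  active / inconclusive / inactive.
* **Hit calling** — consensus hits (active in *every* CLL sample, all
  IC50 < 30 µM), tumor-vs-normal selectivity (> 5-fold potency shift, or
  > 40-point efficacy difference at the two top doses, or inactivity in a
  majority of normal donors), screen summaries, integer-coded activity
  heatmaps and average-linkage profile clustering with newick export.
* **Caspase module** — DMSO-relative activation normalization (100% =
  2-fold induction) and EC50 fitting with automatic masking of
  bell-shaped high-dose fall-off.
* **Synthetic screen generator** — plants ground-truth 4PL pharmacology
  (inactive / pan-cytotoxic / partial / top-dose-only / CLL-selective
  archetypes) on realistic plates with spatial artifacts and log-normal
  well noise, so the full pipeline is testable without patient data.

All user-facing functions take and return tibbles and chain with the
pipe; fitted objects have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

A 64-compound mini screen over 6 CLL-like and 5 normal-like samples,
simulated, corrected, normalized, fitted, classified and summarized in
one call:

```r
library(qhtscreen)
library(dplyr)

cfg <- mini_screen_config()       # 64 compounds, seed 1
res <- run_pipeline(cfg, "screen_out")
res$summary
#> <screen_summary>
#>   64 compounds; 28 (43.8%) active in >=1 CLL sample; 32 (50.0%) inactive in all
#>   23 (35.9%) consensus hits; 6 selective
#> # A tibble: 11 × 6
#>    sample_id n_tested n_active n_inconclusive n_inactive pct_active
#>    <chr>        <int>    <int>          <int>      <int>      <dbl>
#>  1 CLL01           64       26              5         33       40.6
#>  2 CLL02           64       26              6         32       40.6
#>  # ... 9 more rows
```

The percentages are per-sample active fractions (CLL samples run hotter
than normal-donor samples because the selective compounds only kill the
former). Consensus hits come ranked by geometric-mean IC50 across the six
CLL samples:

```r
head(res$consensus, 3)
#> # A tibble: 3 × 5
#>   compound_id ic50_gm ic50_min ic50_max n_samples
#>   <chr>         <dbl>    <dbl>    <dbl>     <int>
#> 1 CMPD-0063    0.0705   0.0215    0.144         6
#> 2 CMPD-0046    0.0947   0.0435    0.151         6
#> 3 CMPD-0035    0.109    0.0703    0.194         6
```

and the selectivity table reports each clause separately — here
CMPD-0041 is called by its 37-fold potency shift, CMPD-0034 by its
86-point efficacy gap at the two top doses:

```r
res$selectivity |> filter(selective) |> head(3)
#> # A tibble: 3 × 8
#>   compound_id ic50_gm_cll ic50_gm_normal fold_shift efficacy_diff ...
#> 1 CMPD-0026         0.221          7.03      31.9            27.1
#> 2 CMPD-0034         0.397          0.129      0.325          86.3
#> 3 CMPD-0041         0.176          6.56      37.3            12.2
```

All six planted selective compounds are recovered with no false
positives. Single curves work the same way at small scale:

```r
conc <- 57 / 5^(0:7)                       # the assay series, µM
fit  <- fit_4pl(conc, fourpl(conc, 0, -100, 1, 1.5))
fit
#> <fit_4pl>
#>   y0 = 0.00  yinf = -100.00  ac50 = 1 uM  hill = 1.50
#>   efficacy = 100.0  r2 = 1.000  n = 8
classify_crc(fit)
#> [1] "1.1"
```

`run_pipeline()` writes every stage artifact (`qc.csv`, `normalized.csv`,
`fits.csv`, `consensus_hits.csv`, `selectivity.csv`, `summary.json`,
`heatmap.tsv`, `dendrogram.nwk`, `pipeline.log`) into the output
directory; a thin subcommand CLI over the same functions ships in
`inst/cli/qhtscreen.R` (`simulate`, `qc`, `fit`, `classify`, `hits`,
`report`). See the vignette in `vignettes/qhts-screen-analysis.Rmd` for
the models, thresholds and design decisions.

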