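---
title: "Analysis of a qHTS primary-cell cytotoxicity screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysis of a qHTS primary-cell cytotoxicity screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qhtscreen)
library(dplyr)
```

## The analysis problem

In quantitative high-throughput screening (qHTS), every compound of a
library is tested as a full concentration titration rather than at a single
dose, so the primary readout of a screen is a concentration-response curve
per compound per assay. `qhtscreen` implements the complete analysis chain
for a 1536-well cell-viability screen of this kind, as used to search an
approved-drug library for compounds that kill primary chronic lymphocytic
leukemia (CLL) lymphocytes while sparing lymphocytes from unaffected
donors:

1. plate-layout and dilution arithmetic,
2. spatial pattern correction from compound-free DMSO plates,
3. control-anchored normalization and Z'-factor / signal-to-background QC,
4. four-parameter logistic (4PL) curve fitting,
5. concentration-response curve (CRC) classification,
6. consensus hit calling across patient samples, tumor-versus-normal
   selectivity, and activity-profile clustering,
7. caspase-activation curve analysis with bell-shape masking.

Because primary patient material cannot be redistributed, the package
ships a synthetic-screen generator with planted ground-truth pharmacology.
Every downstream stage is validated against that ground truth.

## Screen architecture

The assay plate is 32 rows by 48 columns. Columns 1 and 3 hold DMSO-only
wells (the basal, 0% anchor), column 2 a doxorubicin titration (1:2 from
10 µM down to 5 nM; the 12-point block is cycled over the 32 rows rather
than diluted below the stated floor), column 4 doxorubicin at a fixed
10 µM full-kill dose (the −100% anchor), and columns 5–48 the library:
32 × 44 = 1408 compound wells per plate. Compounds are titrated across
plates (inter-plate titration): each compound keeps its well through a
stack of eight plates, one per concentration of the 1:5 series from 57 µM
to 0.7 nM. The 57 µM top dose is set by pintool transfer arithmetic:
23 nL of a 10 mM stock into a 4 µL assay volume gives
$10\,000 \cdot 23 / (4000 + 23) \approx 57.2$ µM. Each stack is bracketed
by a compound-free DMSO-only plate at the beginning and end.

Protocol write-ups of such screens sometimes describe the compound area
as starting at column 4, overlapping the last control column; this
package treats columns 1–4 as controls throughout and places compounds in
columns 5–48, consistent with the per-column control assignments above.

## Normalization and pattern correction

Raw luminescence is normalized per plate to percent activity,

$$\mathrm{norm}(w) = 100 \cdot \frac{\mathrm{raw}(w) - \mu_n}{\mu_n - \mu_p},$$

where $\mu_n$ and $\mu_p$ are the DMSO and positive-control anchors, so 0
is untreated and −100 matches the doxorubicin full kill; cytotoxicity is
negative. (An equivalent formulation anchors the positive control at
+100; the negative convention is used throughout because it keeps the
signs of kill, efficacy and the −100 full-kill reference consistent.)
Anchors are
per-plate **medians**, robust against occasional dead or skipped wells;
the Z'-factor,

$$Z' = 1 - \frac{3(\sigma_p + \sigma_n)}{|\mu_p - \mu_n|},$$

uses means and SDs, as is standard for the screening-window coefficient.
The titration column is excluded from control statistics.

Pattern correction runs on raw signal, before normalization. Each
DMSO-only plate $k$ yields a relative background field
$b_k(w) = \mathrm{dmso}_k(w)/\mathrm{median}(\mathrm{dmso}_k)$; for an
assay plate at stack position $x$ the field is interpolated linearly in
$x$ between the bracketing DMSO plates and the raw values are divided by
it. Division by a relative field is the simplest model that removes a
multiplicative artifact exactly: a gradient common to all plates of a
stack is eliminated to machine precision, and the correction is idempotent
(a corrected stack's own DMSO fields are identically 1). The cost is a
modest noise inflation of corrected wells (the field itself is estimated
from noisy wells), visible as a DMSO CV slightly above the configured
well CV. No B-score/median-polish variants are provided.

## Curve fitting

Each compound × sample series is fitted with the four-parameter logistic

$$y(c) = y_0 + \frac{y_\infty - y_0}{1 + (\mathrm{AC}_{50}/c)^{h}},$$

by bounded Levenberg–Marquardt least squares, parametrized in
$\log_{10}\mathrm{AC}_{50}$. Initialization is deterministic: $y_0$ and
$y_\infty$ from the means of the two lowest- and two highest-concentration
responses, $h = 1$, and $\mathrm{AC}_{50}$ from the best of a 20-point
log-spaced grid spanning one decade beyond the tested range. Bounds —
$h \in [0.3, 10]$, $\mathrm{AC}_{50}$ within two decades of the tested
range, $y_\infty \in [-120, 30]$, $y_0 \in [-30, 30]$ — keep incomplete
curves from extrapolating pathologically. Efficacy is
$|y_\infty - y_0|$ from the fitted asymptotes (not raw extremes), capped
at 120 points. Series with a response span under 5 points are declared
flat and returned unconverged rather than fitted; no outlier masking is
performed, keeping fits reproducible. IC50 is the fitted AC50 of a
descending (cytotoxic) curve; for incomplete curves it is an
extrapolation, and the curve class carries that confidence qualifier.

## CRC classification

The class cascade operationalizes the qHTS curve taxonomy:

* **class 4** — no observed response beyond the activity threshold
  (default 25 points toward kill), or a fitted excursion in the
  signal-increase direction (a viability *increase* is never an active
  call);
* **class 3** — responses beyond threshold only at the single highest
  concentration, an unconverged fit on non-flat data, $r^2 < 0.3$, or a
  Hill slope pinned at its 0.3 lower bound (shallow);
* **classes 1.x / 2.x** — complete versus incomplete by a plateau test on
  the *fitted* curve: complete iff
  $|y(c_{\max}) - y_\infty| < 0.05 \cdot \mathrm{efficacy}$; the .1/.2
  split is efficacy ≥ 80 versus < 80.

The activity threshold, $r^2$ floor, plateau tolerance and Hill bound are
configuration: the qHTS curve-class taxonomy describes its
low-confidence bucket — shallow curves and single-point extrapolated
activity — without numeric boundaries, and these values are this
package's operationalization of it. Classes collapse to
three categories: *active* (class 1.1–2.2 **and** efficacy > 60),
*inactive* (class 4), *inconclusive* (everything else, including all of
class 3).

## Hit calling and selectivity

The long activity matrix (compound × sample: category, class, IC50,
efficacy) feeds three operations:

* **Consensus hits** — active in *every* CLL sample with every per-sample
  IC50 < 30 µM, ranked by geometric-mean IC50 (potencies are
  log-distributed, so the geometric mean is the natural across-sample
  average).
* **Selectivity** — a consensus hit is CLL-selective if *any* of three
  clauses holds: a > 5-fold potency shift (normal over CLL geometric-mean
  IC50), a > 40-point efficacy difference averaged over the two highest
  tested concentrations (19 and 57 µM in the default series), or
  inactivity in at least half (rounded up) of the normal samples. The
  clauses are alternatives because the phenomena they capture are
  distinct (a pure potency shift versus a normal-cell efficacy ceiling);
  each clause is reported separately so an analyst can demand a
  conjunction if desired.
* **Clustering** — outcomes are encoded active = 1, inconclusive = 2,
  inactive = 3, untested = 4; the distance between compounds is the
  fraction of assays tested in both where codes differ (untested cells
  are non-informative and excluded, not treated as a mismatch), with
  average-linkage hierarchical clustering and rows pre-sorted by compound
  id for a deterministic leaf order.

## The synthetic screen

The generator plants, per compound × sample, a true 4PL curve drawn from
one of five archetypes: `inactive` (|response| < 5 points),
`pan_cytotoxic` (complete high-efficacy kill, $y_\infty \in [-100, -85]$,
midpoints 0.03–2 µM, Hill 1.2–2.5), `partial` (efficacy 45–70),
`top_only` (steep curves with midpoints 25–60 µM: appreciable kill at
57 µM, essentially none one 1:5 step below), and `selective`
(CLL-potent; in normal samples either a 30-fold potency shift, emulating
the auranofin/dimercaprol pattern, or a collapsed efficacy of 10–20
points, emulating the azacitidine/podofilox pattern). Per-sample AC50s
scatter log-normally (σ = 0.3 log~10~ units) around the compound center to
emulate inter-patient potency spread — patient-level spreads are not
publicly available, so this is a free parameter, chosen so the tail of
the distribution reproduces ~30-fold extreme patient-to-patient shifts
of the kind such screens report; `top_only`
compounds use a tighter σ = 0.1 because their defining feature occupies a
narrow potency window. The default mix is 80% inactive, 9% pan-cytotoxic,
4% partial, 4% top-only, 3% selective, approximating the ~85% inactive
fraction such screens report.

Raw counts are
`baseline × signal(y) × spatial(w) × lognormal(1, cv)`. Planted responses
are defined **on the normalized scale**: the expected signal interpolates
between the DMSO level and the full-kill background floor,
$\mathrm{signal}(y) = \max\!\big(1 + \tfrac{y}{100}(1 - 1/\mathrm{SB}),\;
1/\mathrm{SB}\big)$, with the signal-to-background ratio SB = 11.2 by
default. Full kill therefore still leaves 1/SB of signal (the positive
controls sit exactly at the floor), and control-anchored normalization
inverts the generator exactly — at zero noise the pipeline recovers
planted AC50s to ~10⁻⁹ relative error, which is what makes the round-trip
tests sharp. The spatial artifact is a deterministic corner-to-corner
gradient plus an edge-row/column depression (default amplitude 10%,
mean 1), giving the pattern correction a realistic target; well noise is
multiplicative log-normal (counts are positive and CV-scaled), default
CV 5%.

What the generator does **not** emulate: liquid-handling failures
(clogged tips, skipped rows), batch effects across donors, compound
degradation, assay drift within a plate run, and any mechanistic
pharmacology (caspase pathways, PK). Passing recovery tests therefore
demonstrates the correctness of the analysis chain, not robustness to
every failure mode of real plates.

A note on classification rates: pan-cytotoxic true efficacies extend down
to 85, within fit-noise reach of the 80-point class-1.1/1.2 boundary, so a
few percent of pan-cytotoxic fits land in class 1.2 at 5% CV. The planted
archetypes are recovered at ≥ 95% (class 1.1 for pan-cytotoxic, class 4
for inactive) on the default mini screen.

## Caspase activation

Caspase-3/7, -8 and -9 readouts are normalized to the matched DMSO
control, with 100% defined as a two-fold induction:
$100 (x - \mu_{\mathrm{DMSO}})/\mu_{\mathrm{DMSO}}$. Strongly cytotoxic
compounds produce bell-shaped curves (cells die before the readout at
high dose), so the fitter finds the peak and, if any post-peak response
falls below 50% of the peak, masks the whole post-peak suffix and fits a
rising 4PL to the ascending limb; the EC50 is its midpoint. The
bell-shape phenomenon is well described qualitatively but has no standard
numeric rule; the 50%-of-peak threshold is this package's
operationalization and is configurable. Flat curves — the expected outcome for caspase-8/9 under
intrinsic-pathway apoptosis — return an unconverged fit, not an error.

## Problem sizes and determinism

The unit-test default is a 64-compound mini screen (6 CLL + 5 normal
samples, 8 concentrations: 220 plates' worth of wells in seconds); curve
recovery statistics use 200 pan-cytotoxic compounds; the full-size screen
(2,816 compounds × 8 concentrations × 11 samples, ≈ 31,000 fits) runs end
to end in well under a minute on one CPU, so the whole analysis is cheap
to rerun. Every stochastic step is seeded: reruns of `run_pipeline()`
under a fixed config are byte-identical, and per-sample generator seeds
are derived deterministically from the master seed.

## A worked mini screen

```{r pipeline, eval = FALSE}
cfg <- mini_screen_config()
res <- run_pipeline(cfg, "screen_out")
res$summary
res$consensus
res$selectivity |> filter(selective)
autoplot(res$qc)
```

## Known limitations

* Class boundaries (activity threshold 25, $r^2$ 0.3, plateau tolerance
  0.05) are operationalizations; the full rule sets of proprietary
  curve-classification software are not re-derived.
* Selectivity is a rule, not a test: the clauses are screening
  heuristics and no p-values are attached.
* The pattern-correction model is multiplicative with linear interpolation
  across stack position; additive artifacts or abrupt mid-stack changes
  are out of scope.
* IC50s of class-2 curves are extrapolations beyond the tested range;
  treat them with the confidence the class label implies.
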