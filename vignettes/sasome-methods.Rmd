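---
title: "Methods: surfaceome screen normalization, bimodality detection and bootstrap GSEA"
author: "sasome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surfaceome screen normalization, bimodality detection and bootstrap GSEA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sasome)
```

## The problem

Inducing senescence in tumor cells with chemotherapeutic agents
(therapy-induced senescence, TIS) remodels the cell surface. Antigens that
appear or increase on senescent cells are candidate handles for
immunotherapy — antibodies, bispecifics, CAR cells — provided they can be
identified reliably from two kinds of data:

1. a **flow-cytometry surfaceome screen**: a plate of wells, each stained
   for one surface antigen, yielding per-cell fluorescence intensities per
   marker under an untreated condition and several senescence-inducing
   treatments; and
2. **bulk RNA-seq differential expression** (log2 fold changes per gene,
   per cell line, treatment and timepoint) from the same models.

`sasome` implements the computational chain from raw per-event intensities
and per-gene fold changes to ranked candidate antigens: isotype-baseline
normalization with a density-mode rule, fold-change selection with Venn and
ternary summaries, a nonparametric bimodality detector built on quantile
density functions, preranked gene-set enrichment standardized by a bootstrap
null, and a GO-based membrane-target triage. Because public screens of this
design are not available, the package ships a synthetic-data module that
generates both data types with planted ground truth; every stage is tested
by parameter recovery against that truth.

## Baseline normalization

Each marker well's signal is summarized by its **median fluorescent
intensity (MFI)** — the median of the per-event intensities. Staining signal
is only meaningful relative to nonspecific binding, measured by an **isotype
control**: an antibody of the same isotype with irrelevant specificity. The
normalized MFI is the ratio of the marker's MFI to its isotype baseline.

Two baseline rules apply, switching on the number of markers that share one
isotype control on a plate:

* **Small isotype sets (≤ 40 markers):** the baseline is the isotype
  control well's own MFI.
* **Large isotype sets (> 40 markers):** a single control well's sampling
  variability would propagate to every one of its markers. Instead the
  baseline is the **mode of a Gaussian kernel density estimate** of the
  member markers' own MFIs (bandwidth 0.05 in log10 units, per condition).
  In a broad antibody panel most antigens are not expressed, so the MFI
  density's mode tracks the unexpressed majority and is robust to the
  expressed minority — unlike a mean or even a median.

The KDE operates on log10 MFIs: fluorescence spans decades, and a bandwidth
of 0.05 is plausible only on the log scale (about a 12% coefficient of
variation in linear units). The mode is the argmax over a 512-point grid
spanning the data range padded by three bandwidths; ties break to the lowest
grid point, making the estimate deterministic and conservative. Tests
compare it against an exhaustive evaluation on a 10-fold finer grid.

Baselines are computed per condition (plate-wise), the cytometry
convention: treated markers are normalized to the treated plate's baseline,
which cancels any plate-level intensity scaling — a property the test suite
checks exactly (multiplying every intensity in one condition by a constant
leaves all normalized MFIs unchanged).

## Differential surface expression

Differential expression of marker *m* under treatment *t* is the fold
change of normalized MFIs,

$$\mathrm{FC}_{m,t} = \frac{\mathrm{nMFI}_{m,t}}{\mathrm{nMFI}_{m,\mathrm{untreated}}}.$$

A marker is **selected as upregulated** when FC ≥ 1.5 under at least one
treatment (the threshold is inclusive), and assigned to the Venn region of
exactly the treatments where it passes. No test statistic gates selection:
the fold-change rule is the only quantitative criterion, and the package
deliberately keeps it that way rather than inventing a significance test
the procedure does not define. Downregulation mirrors the threshold at
1/1.5, the symmetric choice on the ratio scale.

For three treatments the selected markers are placed on a **ternary plot**:
the barycentric coordinate for treatment *i* is
$\mathrm{FC}_i / (\mathrm{FC}_1+\mathrm{FC}_2+\mathrm{FC}_3)$, so position
shows the relative contribution of each treatment to the average fold
change, and the size metric is that average. Coordinates use the raw fold
changes, the literal reading of "contribution to the average"; an
excess-over-1 convention was considered and rejected because it is undefined
for markers downregulated under one treatment yet selected under another.

## Bimodality detection by quantile density functions

Some antigens are expressed by only a subpopulation of cells; their MFI
understates what a sorted subpopulation would show, so flagging such
**bimodal** markers matters for target triage. The detector avoids any
parametric mixture assumption:

1. Compute the empirical **quantile function** Q(p) of log10 intensity on
   the percentile grid p = 0, 1, …, 100 (linear interpolation between order
   statistics).
2. Estimate the **quantile density function (QDF)** q(p) = dQ/dp with a
   quadratic Savitzky–Golay derivative filter over a 5-percentile window
   (the filter's polynomial boundary fit handles the grid ends); negative
   estimates are clipped to zero. Since q(p) = 1/f(Q(p)), the QDF is large
   where the intensity density is *sparse*: a pronounced interior peak marks
   the gap between two subpopulations.
3. Pool **all** marker × condition QDFs of the run and form the
   **reference function**: the pointwise 95th percentile across QDFs at
   each grid percentile. Dividing a QDF by the reference expresses how
   extreme its local sparsity is relative to the whole screen.
4. The **score** is the maximum of q/reference over percentiles 5–95. A
   score > 2 flags the marker **bimodal** and the argmax percentile is the
   **separating quantile** — the boundary between the low- and
   high-intensity populations, so the low-population fraction is that
   percentile / 100. Scores in (1, 2] are **potentially bimodal**, ≤ 1
   unimodal.

Numerical choices: the ratio is evaluated on the interior band 5–95 because
quantile-derivative estimates at extreme percentiles are dominated by
single extreme order statistics; argmax ties break to the lowest
percentile; wells need ≥ 100 events. The score is invariant to a global
intensity rescale (a log shift cancels in the derivative), which the tests
assert exactly.

On synthetic screens of 100 markers (99 lognormal, one 50/50 two-component
mixture separated by 6 within-component sds, 2000 events/well) the planted
marker is flagged in 10/10 screens with the separating quantile within a
few percentiles of the mixture weight, and no unimodal marker is flagged —
the conservative behavior the thresholds aim for. QDF accuracy is checked
against closed forms (exponential: q(p) ∝ 1/(1−p); normal:
q(p) ∝ 1/φ(Φ⁻¹(p))). Agreement is measured as the *mean* absolute relative
deviation over percentiles 10–90, about 4% at n = 10,000; a pointwise
maximum would not be a meaningful accuracy measure at that sample size,
since the per-point relative sampling noise of an empirical quantile
density with a 5-point window is itself ≈ √(0.26/(nΔp)) ≈ 5%, independent
of the percentile.

## Preranked GSEA with bootstrap z-scores

Transcriptome-level pathway shifts are scored by preranked gene-set
enrichment. Genes are ranked by log2 fold change; one ranking is built per
cell line × treatment, averaging the two timepoints (the design yields one
enrichment per cell line/treatment cell; a per-timepoint switch would be a
trivial extension and rankings are exposed for it). The **enrichment score
(ES)** is the classic weighted Kolmogorov–Smirnov running sum with weight
exponent p = 1: walking down the ranking the sum rises by
$|r_g|/\sum_{g' \in S}|r_{g'}|$ at members of set *S* and falls by
$1/(N-|S|)$ otherwise; the ES is the signed extremum.

Instead of permutation p-values, each ES is standardized against a
**bootstrap null**: 1000 random gene sets of the same size drawn without
replacement from the ranked universe, giving
$z = (\mathrm{ES} - \hat\mu_0)/\hat\sigma_0$. Nulls are cached per set size
within a ranking, and all sampling is seeded, so runs are reproducible
bit-for-bit. Under a global null the z-scores of fresh random sets are
approximately standard normal (mean within 0.1 of 0, sd within 0.85–1.15 in
the calibration tests), and z is exactly invariant to a positive rescale of
the metric because the hit weights normalize.

The running-sum implementation evaluates only the candidate extrema at hit
positions (between hits the sum decays linearly), making one ES O(|S|);
tests verify exact agreement with a full O(N) brute-force running sum and
with an independent GSEA implementation (`fgsea::calcGseaStat`), which
serves purely as a cross-check oracle.

The calibration checks use hallmark-scale gene sets (100 genes; curated
hallmark collections average ~150) and a planted additive effect equal to
+2 sd of the ranking metric at 5000 genes, under which the planted set
reproducibly attains z > 3 and tops every ranking.

## Membrane-target triage

An antibody panel covers only a few hundred antigens; transcripts outside
it can still point at surface targets. A gene **passes a treatment** when
its fold change is ≥ 1.5 (LFC ≥ log2 1.5) in *every* cell line at *both*
timepoints and its LFC does not decrease from the first to the second
timepoint in any cell line (monotonic, i.e. sustained rather than transient
induction). A gene is **emitted** when it passes ≥ 1 treatment, carries the
"plasma membrane" GO annotation (supplied as a flat gene → term table; the
package does not traverse the ontology), and is *absent* from the screen
panel — the point is to surface what the screen could not see. Emitted
genes are partitioned by the number of treatments passed (1/2/3), the Venn
summary. "Substantial" is operationalized as the same 1.5-fold rule used
for the screen, the only printed threshold; whether a p-value should also
gate inclusion is left to the caller's upstream filtering since the
procedure defines none.

## The synthetic-data generator

The generator defines the study conditions for every test:

* **Screen:** 100 markers × (untreated + alisertib, CX5461, etoposide), a
  desk-scale stand-in for a ~360-antigen panel; two isotype groups of 95
  and 5 markers so both baseline branches run; intensities lognormal with
  log10 location 2.0 and spread 0.25 (typical cytometer dynamic range and
  CV); treatments act multiplicatively; isotype wells drawn from the shared
  baseline with no marker effect; 2000 events/well by default (real
  acquisitions vary; the count is configurable and recovery tests also run
  at 5000).
* **Bimodal markers:** two-component lognormal mixtures; the default planted
  case separates components by 6 within-component sds, a clearly resolved
  two-population stain.
* **Transcriptome:** 2 cell lines × 3 treatments × 2 timepoints; per-gene
  LFC = planted effect + N(0, 0.5²) noise; disjoint 50-gene sets with one
  planted +2 effect; 12 membrane genes planted to pass triage under exactly
  1, 2 or 3 treatments (4 each) plus annotated decoys and panel-listed
  genes. Planted membrane entries are written with exact, noise-free LFCs
  (1.5 then 2.5): their role is to define an unambiguous ground-truth
  multiplicity class, which additive noise would blur across the threshold.

What the generator deliberately does **not** emulate: spectral spillover
and compensation, doublets, acquisition drift, autofluorescence,
gene–gene correlation, or set overlap. Passing recovery tests therefore
demonstrates that the *algorithms* recover planted effects under idealized
noise — not that real screens are free of those artifacts.

## Reproducibility and problem sizes

Every stochastic entry point takes an explicit integer seed and restores
the caller's RNG state. The pipeline driver (`run_all()`) writes all stage
tables plus a manifest (package version, seed, config hash) and reruns
byte-identically under the same seed. Test and calibration problem sizes —
100-marker screens, 2000–5000 events per well, 5000-gene rankings, B = 1000
bootstrap sets — were chosen so the full suite exercises the stated
operating points of the method while remaining a desk-scale computation.

## Known limitations

* The KDE-mode baseline for large isotype sets assumes most member markers
  are unexpressed; a plate where most antigens are induced would bias the
  baseline upward.
* The QDF detector needs enough events for stable interior quantiles
  (≥ 100 enforced; hundreds recommended) and cannot separate mixtures whose
  components overlap heavily (score grows monotonically with separation —
  tested — but sensitivity at < 3 sds separation is low by design).
* The bootstrap z-score calibrates location and scale of the ES null but
  does not correct its skew; extreme tail probabilities should not be read
  off the normal distribution.
* Triage treats the GO table as flat annotation; callers wanting ancestor
  propagation must pre-expand it.
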