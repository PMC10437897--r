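---
title: "Detecting multi-locus imprinting disturbance from methylation arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting multi-locus imprinting disturbance from methylation arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlidscan)
```

## The problem

Imprinted differentially methylated regions (iDMRs) are methylated on one
parental allele only, so normal somatic tissue sits near 50% methylation
(beta value about 0.4–0.6) at these loci. Imprinting disorders arise when a
disease-specific imprinting control region loses or gains methylation:
hypomethylation of ICR2 (`KCNQ1OT1:TSS-DMR`) or hypermethylation of ICR1
(`H19/IGF2:IG-DMR`) in Beckwith–Wiedemann syndrome, hypomethylation of ICR1
in Silver–Russell syndrome. A substantial minority of patients additionally
carry aberrant methylation at other imprinted loci — multi-locus imprinting
disturbance (MLID). Genome-wide methylation arrays make it possible to scan
all catalogued iDMRs at once, but the cohorts are tiny: each patient must be
compared individually against a handful of controls.

`mlidscan` implements that workflow as composable, tested functions: probe
QC, per-sample BMIQ normalization, per-CpG single-case testing, region-level
aberrance calling, epigenotype and MLID classification, cohort summaries,
and the accompanying clinical scores.

## The statistical model

### Single-case testing per CpG

For a patient value $x$ and $n$ control values $c_1,\dots,c_n$ at one CpG,
the Crawford–Howell statistic treats the patient as a sample of size one
drawn from the control population:

$$ t = \frac{x - \bar c}{s_c\sqrt{(n+1)/n}}, \qquad \mathrm{df} = n - 1, $$

with $s_c$ the sample ($n-1$ denominator) standard deviation and a
two-tailed p-value. The $\sqrt{(n+1)/n}$ factor inflates the standard error
to account for the case lying outside the control sample; with $n = 4$
controls the test has 3 degrees of freedom, so it is deliberately
conservative. Its type-I error is calibrated: on null cohorts the fraction
of CpGs with $p < 0.05$ is 0.05 up to Monte-Carlo error (the test suite
checks this on 10,000 simulated null probes with 4 controls).

A CpG is a **differentially methylated position (DMP)** when both gates
hold, strictly:

* $|\Delta\beta| > 0.2$, where $\Delta\beta = x - \bar c$ — an effect-size
  gate of more than 20 percentage points of methylation;
* $p < 0.05$, uncorrected.

No multiple-testing correction is applied at the probe level. This is a
deliberate property of the rule, not an oversight: the joint gate with the
large effect-size requirement is what controls false calls, and the
region-level rule below adds a further consecutivity requirement. Users who
want a stricter probe-level rule can lower `p_threshold`.

### Region-level calling

Within each catalogued iDMR, probes are taken in genomic order and a region
is **aberrantly methylated** when

* at least `min_significant = 4` probes pass the DMP rule,
* at least `min_consecutive = 2` *adjacent* passing probes share the same
  direction (adjacent among the region's mapped probes, not genome-wide),
* and all passing probes agree in direction. Mixed-direction regions are
  never called aberrant; they are flagged for manual review.

The count condition is ambiguous between "≥ 4 significant probes" and
"region covered by ≥ 4 probes"; we default to the former (it is the reading
consistent with borderline published calls reporting exactly 4 significant
probes) and expose the latter as `rule = "mapped_probes"`. Raising either
threshold can only remove aberrant calls, never add them — a monotonicity
property the test suite checks on randomized significance patterns.

### Epigenotype and MLID

The disease epigenotype derives solely from the two 11p15.5 imprinting
control regions: ICR2 aberrant-hypo gives IC2-LoM, ICR1 aberrant-hyper
IC1-GoM, ICR1 aberrant-hypo IC1-LoM. If both ICRs were ever aberrant the
label follows the larger mean $|\Delta\beta|$ and both regions are recorded
as disease regions (a tie-break that published cohorts have not needed). A
patient has **MLID** when at least one *additional* iDMR — aberrant,
not excluded, and not a disease region — is found. Regions flagged
`excluded` in the catalog never contribute; the bundled catalog pre-flags
the VTRNA2-1 DMR, which is polymorphically imprinted in the general
population and would otherwise generate spurious MLID calls.

### BMIQ normalization

Infinium arrays mix two probe chemistries; type II probes show compressed
beta distributions relative to type I. BMIQ corrects this per sample:

1. fit a three-state beta mixture (unmethylated U, hemimethylated H,
   methylated M) to the type I and type II values separately, by EM;
2. assign each type II probe to its maximum-posterior state;
3. quantile-map type II U-state values onto the type I U component,
   $\beta' = F^{-1}_{U,I}(F_{U,II}(\beta))$, and M-state values likewise;
4. carry the H state by an affine dilation that places it between the
   images of the U/M boundaries, preserving the empirical gaps.

Type I values are returned bit-identical, the transform is monotone within
each state, and on a synthetic compression model (a logit shrink of type II
values) the Kolmogorov–Smirnov distance between type II and type I
distributions strictly decreases — all three are tested invariants.
Normalization is strictly per-sample; no information crosses samples. The
pipeline default is filter-then-normalize (`normalize = TRUE` in
`run_mlid_pipeline()`), switchable off.

Numerical choices for the EM: values are clipped to
$[10^{-6}, 1-10^{-6}]$ (the beta density is undefined at 0/1);
initialization is deterministic by tercile cut-points with moment-matched
shapes, so fits are reproducible without a seed; the M-step maximizes each
component's weighted log-likelihood numerically (L-BFGS-B on log-shapes,
warm-started), which keeps the EM objective non-decreasing; convergence at
a log-likelihood increment below `tol = 1e-6` or `max_iter = 500`
iterations, with non-convergence reported via a flag; a component weight
collapsing below $10^{-4}$, or a degenerate (zero-variance) slice at
initialization, is an error. Posterior ties in state assignment break
toward H.

## Probe QC

Rules are applied in a fixed order — detection ($p \ge 0.05$ in any sample
by default; `mode = "all_samples"` relaxes this), SNP flag, cross-reactive
flag, chrX/chrY, missing values — and each removed probe is counted against
the first rule it trips, so the report is deterministic and partitions the
input. The detection aggregation ("any sample") is the strictest reading of
a detection threshold stated without an aggregation rule; it is
configurable. SNP/cross-reactivity blacklists are taken as manifest flags
rather than bundled, since published blacklists are array- and
version-specific.

## Coordinates and data model

All coordinates are 1-based, fully closed intervals on a single genome
build (default tag: hg19); a probe belongs to a region iff
$start \le pos \le end$ on the same chromosome, both boundaries inclusive.
Chromosome names are normalized to `chr`-prefixed strings on load. Missing
beta values are an explicit `NA` sentinel; any probe with `NA` in an
analysis sample is dropped by QC with a logged count. The bundled iDMR
catalog is a demonstration fixture: two of its intervals (PPIEL, FAM50B)
carry literature hg19 coordinates, the rest are synthetic placeholders of
realistic width — real analyses should supply a full published catalog
(they exist for ~77 iDMRs; the package accepts any BED-like TSV).

## The synthetic-cohort generator

`simulate_cohort()` emulates the study design this pipeline targets: 4
controls and ~15 patients by default, iDMR probes at control mean beta 0.5
with between-sample SD 0.02 (imprinted regions in blood are tightly
regulated), background CpGs drawn from a bimodal mixture mostly near 0 or
1, roughly 80% type II probes, and rare detection failures. Noise is beta-
distributed with moment-matched shapes — so values respect $[0,1]$ without
clipping — rather than Gaussian. Planted epimutations shift a patient's
mean at a region's probes by $\pm\,\text{effect} \times \text{mosaic}$:
mosaicism is modelled as a linear attenuation of the bulk shift, which is
exactly what a cell-fraction mixture of epimutated and normal cells does to
an array signal. Type II probes are then passed through a fixed monotone
compression (an affine shrink of the logit, factor 0.8), giving BMIQ a
realistic bias to correct.

What the generator does **not** emulate: raw two-channel intensities,
batch/chip effects, cell-composition differences between samples, probe-
specific noise, or genuine biological variation of imprinted methylation
between individuals. Passing the recovery tests therefore demonstrates that
the *algorithms* are implemented correctly and behave as specified under
the stated noise model — not that the pipeline's operating characteristics
on real arrays equal those observed in simulation.

## Validation strategy and problem sizes

The published genome-wide results this design follows (per-patient DMP
counts in the hundreds-to-thousands, 74 group-level DMPs, specific patient
MLID calls) depend on raw array data that is not publicly deposited, so
they cannot be recomputed directly. Validation is therefore two-pronged:

* **Exactly reproducible quantities** — clinical scores of published
  patient profiles, Fisher's exact p-values from published 2×2 counts, and
  the DMP breakdown percentage — are recomputed by
  `scripts/acceptance.R` and the acceptance tests.
* **Property-based checks at study scale** — 50 seeded synthetic cohorts
  (4 controls, 6 patients, 12 catalog regions × 8 probes plus the
  generator's default 2,000 background probes, effect size 0.3, mosaic
  fraction 1, control SD 0.02):
  planted aberrant iDMRs must be recovered with sensitivity ≥ 0.9 and null
  patients must stay MLID-negative in ≥ 90% of replicates. Alongside:
  type-I calibration of the single-case test on 10,000 null probes,
  equivalence of DMP/region/Fisher/Mann–Whitney results with independent
  brute-force enumerations, the BMIQ invariants, and region-rule
  monotonicity. These sizes keep the full suite within a few minutes while
  leaving each property comfortably powered.

A note on panel size: BMIQ fits three-component beta mixtures per sample
and per design type, so it needs enough probes of each type for the fits
to be stable. On panels of only a few hundred probes the per-sample fits
become multi-modal and sample-inconsistent, which *adds* cross-sample
variance at mid-range (iDMR) probes instead of removing it — we observed
exactly this when simulating with a few hundred background probes. The
generator's default of 2,000 background probes is the smallest size at
which the fits behave like they do on real arrays; smaller panels should
be analyzed with `normalize = FALSE`. To make routine fitting at this
size cheap, the EM's M-step maximizes the weighted beta likelihood through
its sufficient statistics (the objective is O(1) in the number of probes
once they are accumulated), with analytic gradients.

Statistical building blocks that R provides are delegated, not rewritten:
Fisher's exact test (`stats::fisher.test`, whose two-sided convention is
the point-probability sum the clinical tables use), the Mann–Whitney test
(`stats::wilcox.test`; exact for ≤ 12 untied observations, tie-corrected
normal approximation otherwise), Welch's t, and
`hclust`/`cutree` for the sample dendrogram (Euclidean distance, average
linkage — the common defaults for methylation heatmaps, chosen because the
figure style this reproduces does not state its parameters). The tests
still compare each of these against hand-written enumeration oracles.

## Known limitations

* Single-case testing with 3 df is conservative; subtle or highly mosaic
  epimutations (realized $|\Delta\beta|$ near the 0.2 gate) will be missed
  — consistent with the clinical observation that low-level mosaic MLID is
  hard to detect in blood.
* The pipeline analyzes one tissue; tissue mosaicism is invisible.
* Epigenotype assignment covers the 11p15.5 disorders; other imprinting
  disorders (Temple, transient neonatal diabetes, …) appear only through
  their iDMRs in the additional-region list.
* No copy-number or UPD mechanism calling: an 11p15.5 paternal UPD and an
  isolated IC2 epimutation look alike at the methylation level here.
* BMIQ needs ≥ 30 usable probes of each design type per sample; panels
  smaller than that should run with `normalize = FALSE`.
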