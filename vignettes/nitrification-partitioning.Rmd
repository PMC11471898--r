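---
title: "Partitioning nitrification and N2O production with nested inhibitors"
author: "nitropart"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitropart)
```

## The measurement model

A nitrification microcosm is a closed serum bottle holding a few grams of
sample (biofilm or sediment) whose ammonia oxidizers deplete extractable
NH₄⁺-N and, as a side reaction, emit N₂O into the headspace. Bottles are
destructively sampled: at each timepoint a fresh set of replicate bottles
is sacrificed for a KCl extraction (NH₄⁺) and a headspace gas draw (N₂O).
Three consequences shape everything downstream:

1. replicates at different timepoints are **unpaired** — there is no
   per-bottle trajectory;
2. the headspace mixing ratio at time *t* already integrates all
   production since *t* = 0, so cumulative emission is
   **baseline-subtracted mass**, not a summed flux, and no leakage
   correction applies;
3. each bottle yields its NH₄⁺ and N₂O readings together, which fixes
   the natural resampling unit for the bootstrap.

We assume zero-order (linear) substrate kinetics over the incubation:
rates reported as constant µg N g⁻¹ d⁻¹ over three days imply NH₄⁺ is
not yet limiting at these concentrations. The package therefore fits
straight lines, not Michaelis–Menten curves, which a four-timepoint
design could not constrain anyway.

### Headspace conversion

With headspace volume $V$ (bottle minus sample volume), pressure $P$ and
temperature $T$, a mixing ratio $x$ ppb corresponds to

$$ m \;=\; \frac{PV}{RT}\; x\cdot 10^{-9}\; \cdot 2 M_N \,/\, m_\mathrm{sample} $$

ng N₂O-N per gram, with $R = 8.314$ J mol⁻¹ K⁻¹ and $M_N = 14.007$
g mol⁻¹. Defaults are $T = 298.15$ K (incubation at 25 °C) and
$P = 101.325$ kPa. N₂O-N counts **both** nitrogen atoms of the molecule;
this nitrogen-basis convention is carried through to the cell-specific
rates (below), where it is the one that reproduces values as they are
conventionally reported. The headspace volume is a config field rather
than a constant because bottle geometry (sample displacement) varies
between studies. Dissolved-phase N₂O (Henry partitioning into the slurry
water) is ignored and flagged as a limitation in the report: emissions
here are headspace-only quantities.

### Rates

The nitrification rate of a treatment is **minus the OLS slope of
NH₄⁺-N against time**, fitted over all replicate points jointly (one
regression per treatment). Pooling is the default because unpaired
destructive replicates carry no per-replicate trajectory information; a
`per_replicate` mode (average of per-replicate slopes) exists and agrees
with the pooled fit on balanced data. Negative estimated rates are
clamped to zero for reporting, with the raw value retained. The slope SE
comes from the residual variance and is defined as 0 for a saturated
two-point fit. An N₂O "rate" for per-cell metrics is cumulative emission
divided by the incubation duration (72 h by default).

## The partition

Treatments are ordered so each silences a superset of the previous one's
groups — ∅ ⊆ {AOB} ⊆ {AOB, CMX} ⊆ {AOA, AOB, CMX} in the canonical
1-octyne / DMPP / acetylene design. A group's rate and emission are the
difference between the last treatment where it is active and the first
where it is silenced; the all-inhibitor treatment's emission is the
non-nitrification residual. Any nested chain of ≥ 2 treatments is
accepted (the scheme is data, not code), but a step that silences two
groups at once leaves those groups confounded: their fields are `NA` and
the result is marked not fully resolved, rather than splitting the
difference arbitrarily.

Two numerical choices matter here:

- **Differencing uses the raw (pre-clamp) treatment rates.** Clamping a
  treatment-level rate at zero before differencing biases every group
  measured against a near-zero-rate treatment: the all-inhibitor
  treatment's estimated slope is centred on zero, and `max(·, 0)` shifts
  its expectation upward, dragging the adjacent group's difference down.
  The clamp is applied once, to the group-level difference.
- **Negative group differences are clamped to zero, never
  renormalised.** A negative difference is evidence of inhibitor
  non-specificity or noise; renormalising the remaining groups would
  hide it. The clamp leaves a visible `residual_after_clamp`, the raw
  value is kept, and contribution percentages are computed from the
  clamped emissions against the control total — which is why a
  sediment-style input where the DMPP and octyne treatments coincide
  yields an exactly zero CMX contribution.

Contributions are computed on treatment means (destructive sampling
breaks pairing); the replicate level enters only through the bootstrap.

### Bootstrap intervals

`propagate_uncertainty()` resamples replicate bottles with replacement
within every (treatment, timepoint) cell — both analytes travel with
their bottle — recomputes the full partition, and reports percentile
intervals. With triplicate cells, plain case resampling systematically
understates the measurement variance: the empirical deviations in a cell
of $m$ bottles have SD $\sqrt{(m-1)/m}$ times the true one. Resampled
values are therefore recentred deviations inflated by $\sqrt{m/(m-1)}$,
the standard finite-sample correction; single-bottle cells are left
untouched. All randomness flows from one integer seed and reruns are
bit-identical.

## qPCR quantification

Standard curves are OLS fits of Cq on log₁₀ copies; amplification
efficiency is $10^{-1/\text{slope}} - 1$, exactly 100% at the
perfect-doubling slope $-1/\log_{10} 2 \approx -3.3219$, and R² is
computed from sums of squares. A curve passes QC when R² > 0.98 and the
efficiency lies in a configurable band (default 90–105%; observed field
values of 93–96% sit comfortably inside — the band is an acceptance
gate, not a description). Technical replicates are averaged as mean Cq
before inversion, matching common practice; per-replicate quantification
is available. The reaction-to-per-gram scale (elution volume over
template volume times sample mass) is a required input because no
universal value exists. Estimates below the limit of quantification
(default 1.0 × 10² copies g⁻¹) are flagged, never zeroed — a zero would
poison every downstream division — and a strict mode suppresses
cell-specific rates built on them.

## Yields and cell-specific rates

The N₂O yield of a group is its emission divided by the NH₄⁺-N it
oxidized: ng µg⁻¹, which is a permil fraction by construction. The
cell-specific rate divides the hourly emission by $M_N$ and by *amoA*
copies per gram:

$$ r_\mathrm{cell} \;=\; \frac{m_\mathrm{N_2O\text{-}N}}{\Delta t \; M_N \; C} $$

in amol (10⁻¹⁸ mol) N₂O-N copy⁻¹ h⁻¹. The nitrogen basis (mass of
N₂O-N over the atomic mass of N, i.e. two countable N per molecule) is
deliberate: a per-molecule basis gives exactly half these values, and
the nitrogen basis is the convention consistent with reported per-cell
activities. No copies-per-genome correction is applied (AOB genomes
often carry 2–3 *amoA* copies); copies are taken as a direct cell proxy,
and a correction can be applied to the `copies` input by the caller.
Group emissions may be supplied directly or as contribution × total —
the two paths are algebraically identical and both are exercised in the
tests.

## Abundance dynamics

Marker abundances are mapped reads over gene length (optionally over
total mapped reads); MAG abundances are the MAG's summed contig coverage
over the sample's total, × 100, so a disjoint partition of contigs sums
to exactly 100%. Fold changes are late/early ratios with a zero-early
flag. Correlations pair each abundance with the covariate observed the
same month — no lagging — using mean-per-month values by default,
because that is how such panels are ordinarily assembled; pooled groups
(e.g. summing two comammox MAGs) are summed before correlating. Raw
Pearson p values are the primary display, with an optional
Benjamini–Hochberg column.

## What the generator emulates — and what it does not

`simulate_microcosm()` produces exactly the structure above: linear
group-specific NH₄⁺ depletion with nested inhibitor efficacies (efficacy
1 for every declared treatment–group pair unless an efficacy matrix
says otherwise), group N₂O via fixed yields plus a non-nitrification
background, an ambient headspace baseline (330 ppb), and additive
Gaussian measurement noise per destructively sampled bottle —
triplicates at 0/24/48/72 h by default. The default truth mirrors a
mature, comammox-dominated coastal biofilm: rates AOA 0.22, AOB 0.04,
CMX 0.49 µg N g⁻¹ d⁻¹ and yields scaled so the control emits 2.52
ng N₂O-N g⁻¹ over 3 days with a 55.9% non-nitrification share. Initial
NH₄⁺ is 10 µg N g⁻¹ — comfortably above the ~2.25 µg g⁻¹ consumed in
three days at these rates, consistent with the zero-order assumption.
Noise SDs default to 0 so that a default run is an exact oracle; the
property tests use 0.5 µg N g⁻¹ (5% of initial) where noise is the
point.

The generator does **not** emulate: process noise (real biofilms drift),
inhibitor side effects on non-target guilds beyond the efficacy matrix,
NH₄⁺ regeneration by mineralisation, N₂O consumption by denitrifiers,
or dissolved-gas partitioning. Passing tests therefore certify the
estimators under the stated measurement model, not the chemistry of any
particular incubation.

`simulate_qpcr()` draws standards from an exact log-linear response and
`simulate_abundance_series()` interpolates to a target fold change —
linearly by default, so a noise-free series correlates perfectly with a
linearly trending covariate (a geometric shape is available when
exponential growth is wanted).

## Degenerate inputs and numerical conventions

- All-identical ANOVA inputs raise an "F undefined" error rather than
  returning 0/0.
- A yield with zero oxidation but nonzero N₂O is flagged undefined, not
  infinite; zero emission with zero oxidation is a clean 0.
- Missing *t* = 0 records make baseline subtraction impossible and say
  so explicitly.
- Reports serialise doubles at 17 significant digits so a written
  report parses back bit-identically; rerunning a pipeline with the same
  config and seed writes byte-identical JSON.
- Validation returns all design violations at once instead of stopping
  at the first.

## Problem sizes

The test suite runs the full design (4 treatments × 3 replicates × 4
timepoints × 2 analytes = 96 records) throughout; bootstrap checks use
50–200 resamples, and the coverage experiment uses 100 seeded
replications at 200 resamples each — sizes at which the percentile
intervals are stable while a complete run stays interactive.

## Known limitations

Inhibitor efficacies are assumed complete for declared pairs; partial
1-octyne efficacy against comammox in particular would shift activity
from AOB to CMX, and the efficacy-matrix hook exists to quantify exactly
that bias (the conservation property — the control-minus-acetylene span
is invariant — is tested). Headspace-only accounting understates true
production where dissolved N₂O is appreciable. *amoA* copies equate to
cells only up to copy-number variation. And with four timepoints and
triplicates, bootstrap intervals are honest but coarse; they are
percentile intervals, not BCa.
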