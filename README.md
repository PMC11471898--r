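# nitropart

Partitioning nitrification and N₂O production among ammonia-oxidizer
groups in microcosm incubations with nested differential inhibitors.

## The problem

Coastal biofilms — including the "plastisphere" colonising marine plastic
debris — can develop dense nitrifying communities whose ammonia oxidation
releases the greenhouse gas N₂O. Three guilds share the work: ammonia-
oxidizing archaea (AOA), ammonia-oxidizing bacteria (AOB) and comammox
*Nitrospira* (CMX), and their relative contributions cannot be read off a
single bulk measurement. The classic solution is a nested inhibitor
series: incubate parallel serum-bottle microcosms in which

| treatment | inhibitor | silenced groups |
|---|---|---|
| control | none | — |
| octyne | 0.03% (v/v) 1-octyne | AOB |
| dmpp | DMPP | AOB + CMX |
| acetylene | low-conc. acetylene | AOA + AOB + CMX |

so that differences between adjacent treatments isolate one group each:

```
AOB = control − octyne,  CMX = octyne − dmpp,  AOA = dmpp − acetylene,
non-nitrification N₂O  = acetylene treatment's emission.
```

`nitropart` implements this chain end to end for NH₄⁺ depletion and
headspace N₂O time series, for users analysing (or simulating) such
incubations:

- **headspace gas** — ideal-gas conversion of N₂O mixing ratios (ppb v/v)
  to mass emissions: `m = (P·V/(R·T)) · x·10⁻⁹ · 2·M_N / m_sample`
  (ng N₂O-N g⁻¹, both N atoms counted), with destructive-sampling
  baseline subtraction;
- **kinetics** — zero-order nitrification rates as the sign-flipped OLS
  slope of NH₄⁺-N over all replicate points, plus one-way ANOVA and
  Fisher's LSD for treatment comparisons;
- **partition** — the nested differencing above, with negative
  differences clamped to zero (raw values retained, no renormalisation)
  and replicate-level bootstrap percentile intervals;
- **qPCR** — *amoA* standard curves (efficiency `10^(−1/slope) − 1`,
  R² gate), copy quantification with a limit-of-quantification flag;
- **metrics** — N₂O yield (ng N₂O-N per µg NH₄⁺-N oxidized, ‰) and
  cell-specific N₂O production (amol N₂O-N copy⁻¹ h⁻¹, nitrogen-basis
  moles, *amoA* copies as a cell proxy);
- **abundance** — length-normalised *amoA* read abundances, MAG
  coverage percentages, temporal fold changes, Pearson correlations with
  environmental covariates (EPS, seawater NH₄⁺);
- **synthetic data** — a seeded generator for microcosm, qPCR and
  abundance datasets with known ground truth, used throughout the tests.

## Worked example

A noise-free simulated incubation under the default "mature plastisphere"
truth (rates AOA 0.22, AOB 0.04, CMX 0.49 µg N g⁻¹ d⁻¹; 2.52 ng N₂O-N g⁻¹
total emission, 55.9% non-nitrification):

```r
library(nitropart)
design <- microcosm_design()            # 50 mL bottle, 2 g sample, 0/24/48/72 h
tab <- simulate_microcosm(simulation_truth(), design)
tab <- add_n2o_mass(tab, design)        # ppb -> ng N2O-N g^-1
summ <- summarize_all_treatments(tab, design)
part <- partition(summ, design$inhibitor_scheme)
part
#> Inhibitor-based source partition
#>   total N2O: 2.52 ng N2O-N g^-1 | nitrification-attributed: 44.1% | non-AO: 55.9%
#>   AOA    rate  0.220 ug N g^-1 d^-1 | N2O  0.539 ng g^-1 |  21.4%
#>   AOB    rate  0.040 ug N g^-1 d^-1 | N2O  0.121 ng g^-1 |   4.8%
#>   CMX    rate  0.490 ug N g^-1 d^-1 | N2O  0.451 ng g^-1 |  17.9%
#>   non_AO rate     -- ug N g^-1 d^-1 | N2O  1.409 ng g^-1 |  55.9%
```

Each row is one source: its nitrification rate, its cumulative N₂O over
the 3-day incubation, and its share of the control microcosm's total
emission. Yields and per-cell activity follow from *amoA* abundances:

```r
group_metrics(part, list(AOA = 1.6e6, AOB = 6.1e4, CMX = 1.5e7),
              duration_h = 72)[, 1:4]
#>   group yield_permil yield_undefined cell_specific_amol
#> 1   AOA    0.8170909           FALSE         0.33420790
#> 2   AOB    1.0080000           FALSE         1.96623000
#> 3   CMX    0.3068571           FALSE         0.02981842
```

CMX here oxidizes the most ammonia yet converts the smallest fraction of
it to N₂O (0.3‰) and is the least active per cell (0.03 amol copy⁻¹ h⁻¹)
— the pattern that makes comammox-dominated biofilms strong nitrifiers
but comparatively modest N₂O sources per unit activity.

`run_pipeline()` drives the whole chain (measurements → headspace →
kinetics → partition → metrics → abundance correlations) from a YAML or
list config and writes a JSON report plus a text summary.

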