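# redsnow

Red-pigmented snow algae ("watermelon snow") darken melting Arctic snow
fields: the carotenoids they accumulate absorb strongly at 400–700 nm, so
blooming snow reflects less sunlight, absorbs more energy, and melts
faster. `redsnow` implements, as a tested R package plus a set of analysis
scripts, the computations behind a pan-Arctic red-snow survey: the
integrated bio-albedo change model that puts a season-scale number on this
feedback, the field-measurement arithmetic (radiometer albedo, cell
biovolume, biomass–albedo correlation), and the amplicon OTU-table
statistics used to contrast cosmopolitan snow algae with
location-structured snow bacteria. A synthetic-study generator emulating
the 40-site, four-location sampling design makes every stage runnable and
testable without any sequence downloads.

It is aimed at cryosphere microbiologists and glaciologists who want to
re-derive, perturb or extend the bio-albedo numbers, and at method readers
who want the statistics behind the community analyses in executable form.

## The model

Anchor albedo values (average, minimum and maximum, oriented "in terms of
decrease in albedo") are tabulated for three surface states: dry clean
winter snow, wet clean melting snow, and red snow. Albedo decays with the
square root of time, so each scenario is fitted by ordinary least squares
as

    alpha(t) = a − b · sqrt(t)

where `t` is days into the melt season. Integrating over a season of
length `T` gives the closed form `a·T − (2/3)·b·T^1.5` (albedo·days).
Differencing a clean-melt benchmark (scenario 1) against a red-bloom
trajectory (scenario 2) yields

    Δα = |a₂ − a₁|·T + (2/3)·|b₂ − b₁|·T^1.5

whose two terms, at T = 100 days, evaluate to 1.85 and 11.30 albedo·days —
combined 13.15, i.e. a ≈ 13 percentage-point mean albedo decrease
attributable to the algal bloom. A band sensitivity analysis (fitting the
minimum, average and maximum anchor columns separately at days 0/50/100)
brackets this headline with coefficients 0.0409 and 0.0038 and a spread of
roughly 0.3 about the mean.

Around the model sit the survey statistics: albedo as the ratio of mean
reflected to mean incident radiometer readings (with a 10%
coefficient-of-variation QC), spherical cell biovolume `V = (4/3)·π·r³`
times cell concentration, Pearson tests of the biomass–albedo coupling,
and OTU-table operations (singleton exclusion, rarefaction without
replacement, Shannon diversity, rank aggregation, covariance-form PCA,
per-taxon one-way ANOVA across locations, taxon–geochemistry
correlations).

## Worked example

```r
library(redsnow)
reproduce_table1()
```

```
Integrated bio-albedo change report
  horizon           = 100 days
  clean fit         : a = 0.89924, b = 0.02025
  red fit           : a = 0.91774, b = 0.03720
  linear term       = 1.85 albedo-days
  t^1.5 term        = 11.30 albedo-days
  combined          = 13.15 albedo-days
  headline          = 13%
  sensitivity coeffs: |da| = 0.0409, (2/3)|db| = 0.0038
  sensitivity range = ~0.3 about the mean
```

The two fits are the clean-melt and red-bloom scenario curves; the
combined 13.15 albedo·days over 100 days is the ≈13 percentage-point mean
albedo decrease the bloom causes, bracketed by the ~0.3 band sensitivity.

The synthetic pipeline runs the same way:

```r
study <- simulate_study(study_config(), seed = 1)
analyse_study(study)
```

```
Red-snow study analysis
  location separation: bacterial 2.68 vs algal 0.23
  ANOVA: 86% of bacterial classes p<0.05; 100% of algal species p>=0.05
  biomass-albedo: r = -0.80, P = 6.63e-09
```

Bacteria cluster by location (high separation ratio, significant
per-class ANOVAs) while the algal species do not, and recovered albedo
falls with algal biovolume — the study's central contrast.

## Analysis scripts

The `analysis/` directory holds the narrative drivers, each a thin script
over package functions, writing its tables under `results/`:

| script | what it does |
|---|---|
| `01_albedo_model.R` | anchor-table scenarios, fits, integration, sensitivity |
| `02_simulate_study.R` | writes the default 40-site synthetic study |
| `03_community_analysis.R` | rarefaction, diversity, PCA, ANOVA, correlations |
| `04_power_checks.R` | coupling calibration and biogeography power over replicates |

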