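# primorisk

Dietary risk assessment of pesticide residues in single-commodity monitoring
data, in the style of EFSA's PRIMo (Pesticide Residue Intake Model)
calculator.

Multiresidue monitoring programs produce one table of quantified
concentrations (mg/kg) per sample and active substance. `primorisk` turns such
a table, together with per-substance regulatory constants (MRL, ARfD, ADI) and
a population consumption profile, into the standard battery of food-safety
outputs:

- **Residue summaries** — per-substance detection counts, mean/min/max/total
  concentration over detects, concentration shares by substance and by
  pesticide class, and the distribution of residues per sample, with
  limit-of-quantification (LOQ) censoring.
- **MRL compliance** — each measurement as a percentage of its EU maximum
  residue limit; a sample is non-compliant if any residue strictly exceeds
  100% of its MRL (decided at full precision; display rounds half-up).
- **Acute exposure** — the International Estimated Short-Term Intake for a
  commodity with unit weight under 25 g (Case 1; Cases 2a/2b are implemented
  for larger units):

  `IESTI = LP × HR × PF × CF / BW`

  with LP the large portion (kg/day), HR the highest residue (mg/kg), PF/CF
  processing and conversion factors and BW the body weight (kg), compared to
  the acute reference dose: `%ARfD = IESTI × 100 / ARfD`.
- **Chronic exposure** — the National Estimated Daily Intake from the average
  residue over detects (APR, mg/kg) and the mean consumption
  (g/kg bw/day): `NEDI = APR × consumption / 1000`, compared to the
  acceptable daily intake: `%ADI = NEDI × 100 / ADI`.
- **Hazard index** — a per-sample cumulative screen: the sum of the %ARfD
  contributions of the co-occurring residues in one sample.
- **Synthetic campaigns** — a seeded generator drawing per-substance Bernoulli
  detections and LOQ-truncated lognormal concentrations, moment-matched to
  published summary statistics, for testing pipelines when raw per-sample
  data are not deposited.

The package bundles, as fixtures, the published results of a 2023–2024
strawberry monitoring campaign from an intensive production area in Southern
Italy (83 samples, 31 active substances) and the EU PRIMo "NL toddler"
consumption profile (body weight 10.20 kg, large portion 166.70 g/day, mean
strawberry consumption 0.344 g/kg bw/day) — the most exposure-sensitive
European subgroup for this commodity.

## Worked example

```r
library(primorisk)

refs    <- load_reference_table()                      # 31 substances
profile <- load_consumption_profile("NL toddler")
ds <- read_residues(
  primorisk_example("strawberry_residues_reconstructed.csv"),
  n_samples_total = 83)

# MRL compliance
assess_compliance(ds, refs)$noncompliant_samples
#> [1] "A5" "I4" "S2" "V1"

# Acute risk: the flupyradifurone residue of 0.68 mg/kg in sample A5
e <- iesti(0.68, profile)
signif(as.numeric(e), 3)                  # 0.0111 mg/kg bw
round_half_up(percent_arfd(e, 0.15), 2)   # 7.41 % of the ARfD

acute <- assess_acute(ds, refs, profile)
acute[which.max(acute$percent_arfd), c("pesticide", "hr", "percent_arfd")]
#> # A tibble: 1 × 3
#>   pesticide       hr percent_arfd
#>   <chr>        <dbl>        <dbl>
#> 1 tebufenpyrad 0.133         10.9

# Chronic risk: cyflumetofen at its campaign mean of 0.112 mg/kg
nd <- nedi(0.112, profile$mean_consumption)
nd                                        # 3.8528e-05 mg/kg bw/day
round_half_up(percent_adi(nd, 0.17), 3)   # 0.023 % of the ADI
```

All acute exposures stay below 11% of their ARfD and all chronic exposures
below 1.6% of their ADI, i.e. well inside the acceptability threshold of
100%, even though four samples are non-compliant with an MRL — the legal
limit is a trade standard, not a toxicological one.

The full pipeline (summary, composition, compliance, acute, chronic, hazard
index, plus a text summary and run log) is one call:

```r
cfg <- pipeline_config(
  residue_path = primorisk_example("strawberry_residues_reconstructed.csv"),
  n_samples_total = 83, output_dir = "report")
run_pipeline(cfg)
```

or, from a shell, `Rscript inst/cli/primorisk.R assess --residues FILE --out DIR`
(`simulate` draws a synthetic campaign; see `inst/cli/primorisk.R`).

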