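---
title: "Dietary exposure assessment for single-commodity residue monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dietary exposure assessment for single-commodity residue monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primorisk)
```

## The problem

Regulatory monitoring of pesticide residues answers two distinct questions.
*Compliance*: does any measurement exceed its maximum residue limit (MRL), a
legal trade standard set from good agricultural practice? *Risk*: could the
observed residues harm a consumer, judged against toxicological reference
values — the acute reference dose (ARfD, the amount ingestible in one
meal/day without appreciable risk, mg/kg body weight) and the acceptable
daily intake (ADI, the lifetime daily equivalent, mg/kg bw/day)? MRLs can sit
orders of magnitude below or above a toxicological threshold, so the two
questions routinely give different answers: `primorisk` computes both, the
way the EU's PRIMo calculator does, for a single commodity.

The bundled campaign is a 2023–2024 strawberry monitoring program from an
intensive production district (83 samples, 31 detected active substances;
LOQ 0.010 mg/kg), assessed for the PRIMo "NL toddler" subgroup (8–20 months,
body weight 10.20 kg), which has the highest strawberry consumption per kg
body weight among the model's European populations.

## Models

### Acute: IESTI

For a commodity whose unit weight is below 25 g (a strawberry), one eating
occasion can mix many units, so unit-to-unit variability averages out and the
FAO/WHO Case 1 equation applies:

$$\mathrm{IESTI} = \frac{LP \cdot HR \cdot PF \cdot CF}{BW}$$

with $LP$ the large portion (kg/day — supplied in g/day and divided by 1000
internally), $HR$ the highest residue observed for the substance across the
campaign (mg/kg), $PF$ and $CF$ processing and conversion factors (both 1 for
raw strawberries), and $BW$ the body weight (kg). For unit weights of 25 g
and above, `iesti()` implements Cases 2a and 2b with the profile's
variability factor $\nu$: Case 2a,
$(U \cdot HR \cdot \nu + (LP - U) \cdot HR) \cdot PF \cdot CF / BW$ when a
unit is smaller than the portion; Case 2b, $LP \cdot HR \cdot \nu \cdot PF
\cdot CF / BW$ when one unit exceeds the portion. The strawberry profile
never triggers them; they are covered by unit tests. Acceptability is
$\%\mathrm{ARfD} = 100 \cdot \mathrm{IESTI}/\mathrm{ARfD} < 100$.

Taking HR as the campaign-wide maximum per substance is a worst-case
simulation: the highest observed residue eaten in a high-end portion by the
lightest consumers.

### Chronic: NEDI

$$\mathrm{NEDI} = \frac{\mathrm{APR} \cdot \text{mean consumption}}{1000}$$

where APR is the *average pesticide residue*: the mean concentration over the
samples in which the substance was detected (mg/kg), and mean consumption is
in g/kg bw/day (0.344 for the NL toddler), with 1000 converting grams to
kilograms. Body weight does not appear because consumption is already
normalized per kg bw. Acceptability is $\%\mathrm{ADI} = 100 \cdot
\mathrm{NEDI}/\mathrm{ADI} < 100$.

Two caveats are worth stating prominently. First, the APR replaces the
supervised-trials median residue (STMR) that harmonized assessments use; a
monitoring mean reflects the local market more faithfully but is not
regulatory practice. Second, the APR is conditional on detection — it
averages over detects only, because the published per-substance means equal
total/(number of detects). This inflates the APR relative to a mean over all
83 samples (a substance seen once at 0.03 mg/kg has APR 0.03, not 0.03/83);
the chronic figures are therefore conservative.

### Cumulative screen: hazard index

The campaign found multiple residues in over half its samples.
`hazard_index()` sums, within each sample, every residue's own %ARfD (its
concentration treated as the HR). Dose addition across substances with
different modes of action is a first-tier screening assumption, not a
toxicological prediction; residues without an established ARfD cannot
contribute and are reported as excluded rather than silently counted as zero.

## Reference values and their inconsistencies

ARfD and ADI are not established for every substance. The package encodes
"not established" as `NA` — a distinct state that propagates to a
"not applicable" result — never as zero or infinity; 19 of the 31 substances
are acutely assessable, 30 chronically (ethirimol has neither value).

The published report is internally inconsistent in places, and the bundled
reference table resolves each conflict in favor of the values its own printed
percentages are arithmetically consistent with (each case is also noted in
the fixture file's comments):

- fenpyroximate: ARfD 0.02 mg/kg bw (the reference table prints "-", but the
  acute table's printed 6.46% requires 0.02); ADI kept at 0.2 per the
  reference table although the chronic table's 0.27% uses 0.010.
- acetamiprid ARfD 0.005 and spinetoram ARfD 0.1 per the tables (narrative
  passages say 0.025 and 1).
- The acute table's acetamiprid row uses 0.013 mg/kg although the campaign
  maximum is 0.033; `assess_acute()` follows the HR definition and reports
  10.79%, not the printed 4.25%.
- The chronic table prints emamectin at 15.136% of its ADI, tenfold what its
  own inputs give (0.022 × 0.344/1000 / 0.0005 = 1.514%); the package
  reports the computed value.

## The bundled fixtures

The study deposited no per-sample residue table, so the package carries
three plain-text reconstructions of its printed data:

- `pesticide_reference.csv` — MRL/ARfD/ADI and class for the 31 substances.
- `campaign_summary.csv` — the published per-substance mean/min/max/total.
  Class-composition shares are computed from these totals (the grand total is
  17.617 mg/kg), since some substances' printed per-sample values are
  incomplete (e.g. 15 of 25 cyflumetofen values are printed).
- `strawberry_residues_reconstructed.csv` — all 149 printed per-sample
  values. Assignments the study text pins are honored exactly: the four
  non-compliant samples (A5 with flupyradifurone 0.680, S2 and V1 with
  cyflumetofen 0.627 and 0.735, I4 with spirotetramat 0.340, each with the
  stated residue counts), pyrimethanil 2.000 in I5, tebufenpyrad 0.133 in D3,
  fenpyroximate only in M3, lambda-cyhalothrin only in A7, seven residues in
  D2, tetraconazole with fenhexamid in E5, trifloxystrobin always together
  with fluopyram and difenoconazole always with fluxapyroxad (mixed
  formulations). The remaining assignments are **synthetic**: plausible
  (72 of 83 samples carry residues; 20 samples carry exactly one, close to
  the study's 28%) but not measured. Every statistic that depends only on
  per-substance values — summaries, compliance, HR, APR, exposure — is exact;
  sample-level structure beyond the pinned facts is illustrative.

Names are canonicalized through a bundled synonym map because the source
tables mix English and Italian spellings ("Pirimentanil", "Bupirimato",
"Lambda cialotrina"); `normalize_name()` is idempotent and warns on unknown
names instead of failing.

## The synthetic generator

`default_study_config()` encodes the campaign as a generative model so every
pipeline stage is testable at any scale:

- **Detection**: per substance, a Bernoulli draw per sample with probability
  equal to the published detection count over 83 (cyflumetofen 25/83,
  pyrimethanil 6/83, ...). Counts not stated in the text are recovered as
  total/mean from the campaign summary, which is integer to within 0.1 for
  every substance.
- **Concentration**: lognormal, because the campaign data are strongly
  right-skewed (pyrimethanil mean 0.634 vs max 2.000 mg/kg). Only summary
  statistics are published, so `lognormal_from_summary()` moment-matches:
  the mean exactly, and the maximum as the P99 quantile, taking the smaller
  root for `sdlog`; degenerate cases (single detections, where max = mean)
  fall back to a floor of 0.2 and a cap of 2 on `sdlog` — a range typical of
  residue data — rather than a degenerate point mass.
- **LOQ truncation** at 0.010 mg/kg by redraw (up to 100 attempts, then
  clamping), so the configured detection probability is preserved exactly
  instead of being eroded by discarding sub-LOQ draws.
- **Co-occurrence**: the two fixed pairs the study reports are enforced by
  adding the companion wherever the trigger fired. The study names no other
  joint-detection structure, so none is modeled.
- **Determinism**: each substance draws from its own RNG stream (seed plus a
  stable name hash, mod 2^31−1), so one seed gives byte-identical campaigns
  and adding a substance never perturbs the others' draws.

What the generator does *not* emulate: seasonal/farm-level clustering of
applications, correlated residue levels within a sample beyond the fixed
pairs, measurement error, or MRL exceedances (unless the optional upper-tail
inflation is configured). Tests passing on synthetic campaigns therefore
demonstrate pipeline correctness — not that real campaigns look like the
generator.

## Numerical conventions

- Full precision is carried internally; rounding happens only at reporting.
  Reports round **half-up** (`round_half_up()`): integers for MRL%, two
  decimals for %ARfD/%ADI. Base R's banker's rounding would print 122.5% as
  122%, where enforcement tables print 123%. A relative epsilon (1e-9)
  absorbs binary representation error on decimal ties such as 0.627/0.6.
- Compliance and acceptability are decided on unrounded values with strict
  inequalities: exactly 100% of an MRL is compliant.
- A measurement exactly at the LOQ is kept; censoring removes values strictly
  below.
- The worked acute figure is reported as 7.41% (full precision 7.4089, which
  2-dp half-up rounding gives); the published acute table prints 7.40 in one
  place and 7.41 in the narrative — the package sides with the arithmetic.
- Test problem sizes: parameter-recovery checks run at n = 5000 samples,
  frequency checks at n = 2000, oracle-equivalence sweeps over 100 seeded
  campaigns at the study's n = 83 — sizes at which the binomial/lognormal
  tolerances used (99% intervals, 5% relative error) are comfortably
  discriminating while the whole suite stays fast.

## Design choices

- The large portion is accepted in g/day (as published: 166.70) and converted
  to kg inside `iesti()`; the published derivation of that constant from a
  0.48 g/kg bw standard value does not reproduce it, so LP is treated as a
  supplied constant.
- `n_samples_total` is dataset metadata (83 here) because residue-free
  samples have no rows; the residues-per-sample distribution needs it.
- The published 17/28/55% residue-free/single/multiple split is not exactly
  reconstructible from printed data (17% of 83 is not an integer), so the
  package reproduces the *shape* of that distribution, not those exact
  figures.
- Exposure results keep non-assessable substances in the output with
  `assessable = FALSE` rather than dropping them, so report totals always
  account for all 31 substances.

## Worked numbers

```{r example}
refs    <- load_reference_table()
profile <- load_consumption_profile("NL toddler")
ds <- read_residues(
  primorisk_example("strawberry_residues_reconstructed.csv"),
  n_samples_total = 83)

assess_compliance(ds, refs)$noncompliant_samples

acute <- assess_acute(ds, refs, profile)
acute[which.max(acute$percent_arfd), ]

chronic <- assess_chronic(ds, refs, profile)
head(dplyr::arrange(chronic, dplyr::desc(percent_adi)), 3)

hi <- hazard_index(ds, refs, profile)
hi[which.max(hi$hi_percent), ]
```

## Limitations

Single commodity only: PRIMo's full diet basket aggregates many commodities,
so these figures bound strawberry-borne exposure, not total dietary exposure.
No probabilistic (Monte Carlo) exposure modeling, no measurement-uncertainty
expansion of residue values, no relative-potency cumulative assessment
groups. The hazard index is a screen; substances sharing a mode of action
deserve a proper cumulative assessment.
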