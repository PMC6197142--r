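---
title: "The theoretical postmortem redistribution factor: model, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The theoretical postmortem redistribution factor: model, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmrft)
```

## The problem

Postmortem redistribution (PMR) is the movement of drugs after death from
tissue reservoirs — liver, myocardium, muscle, fat — into the blood. Blood
drawn at autopsy, especially from central sites, can carry drug
concentrations well above the concentration circulating at death, so
postmortem toxicology read at face value overstates exposure. Peripheral
blood (iliac or femoral) is less affected than cardiac blood, but even
peripheral concentrations inflate for many drugs. The practical questions
for a forensic toxicologist are: *by how much should a postmortem
peripheral-blood concentration be discounted*, and *which drugs demand that
discount at all?*

## The model

The package is built around three relationships linking an antemortem
whole-blood concentration $AM$, a postmortem peripheral-blood concentration
$P$, and a drug's characteristic liver-to-peripheral-blood ratio $R$ (L/kg):

$$F = P / AM$$

the *determined* (observed) redistribution factor from a paired case;

$$F_t = \frac{\sqrt{2\,(R + 2.5)}}{2.6}$$

the *theoretical* redistribution factor, a function of $R$ alone; and the
inversion used in casework,

$$AM = P / F_t \quad (\text{or } P/F).$$

$F_t$ is continuous and strictly increasing in $R$: the more strongly a
drug sequesters in the liver relative to peripheral blood, the larger its
expected postmortem inflation. The constants 2.5 and 2.6 are fixed model
constants; at $R = 2.6^2/2 - 2.5 = 0.88$ L/kg the factor is exactly 1
(no expected redistribution), which `ft_exact(0.88)` reproduces in closed
form. Because $F$ and $F_t$ are ratios of like-unit quantities, the model
is unit-agnostic (mg/L for most drugs, g/dL for ethanol) — units must only
be consistent within a case.

The L/P ratio also carries an interpretive classification, implemented in
`classify_propensity()`: below 5 L/kg, minimal propensity for PMR; 20 L/kg
and above, propensity for significant PMR; moderate between. The
literature describes the upper threshold as a 20–30 L/kg band, so we fix
half-open intervals $[5, 20)$ and $[20, \infty)$ for determinism and treat
calls inside 20–30 L/kg as borderline.

## Reference data and display conventions

`load_reference_table()` ships a curated 44-drug table: each drug's median
L/P ratio (from 867 source cases in total) and its published $F_t$. One
entry — ethanol — has a literature-derived factor (1.0) and no L/P median;
all 43 others are computed from their medians.

The published factors follow a specific reporting convention, implemented
in `format_ft()` and guarded permanently by
`validate_reference_fixture()`:

* factors $\ge 1$ are **truncated** (floored) to one decimal — e.g. an
  exact factor of 1.991 (propranolol, $R = 10.9$) is reported as 1.9, not
  2.0. Truncation is forced by the reference values themselves (nine rows
  distinguish it from rounding) and has the convenient property of never
  overstating expected redistribution;
* factors $< 1$ are rounded half-up to two decimals (gabapentin,
  $R = 0.65$: exact 0.9654, reported 0.97).

A numerical guard of $10^{-9}$ absorbs binary floating-point representation
error before truncation so that mathematically exact tenths (the anchor
$F_t(0.88) = 1$) are not pushed down a decimal.

Determined factors $F$ are reported rounded half-up to one decimal
(`format_f()`); base R's `round()` is not used for display because its
round-half-to-even rule does not match the reporting convention. On the
shipped 13-case table the recomputed display agrees with the recorded
column on 12 of 13 records; the single discrepancy (the 0.34/0.19
methamphetamine record: exact 1.789, displaying 1.8, recorded 1.7) is a
documented erratum in the source material, which the package reports but
does not reproduce.

## The validation analysis

`run_validation()` reproduces the model's published empirical support from
the 13 paired cases:

* a per-case tabulation of determined versus theoretical factors
  (`compare_cases()`), with absolute and relative differences;
* a summary of the postmortem delay covariate (mean 17.2 h, median 13 h,
  range 5.2–42 h on the shipped cases — all within the model's 48-hour
  applicability window);
* an ordinary least squares regression of the **theoretical factor on the
  determined factor**. That orientation is fixed by design: it is the one
  under which the shipped data reproduce the published coefficients
  ($y = 1.0194x + 0.1035$, $R^2 = 0.7006$); the reverse orientation does
  not. By default the regression consumes the one-decimal displayed
  columns, since that is the form in which the factors are reported and
  compared; `precision = "full"` regresses the exact recomputed values
  instead (useful for simulation work, where display rounding is pure
  noise).

The determined-factor column enters the display-precision regression *as
recorded* in the case table rather than re-rounded, so the erratum row
participates at its recorded value — this is what reproducing the published
fit requires, and the recomputed display is tabulated alongside for audit.

Two reported quantities in the source material are internally inconsistent
with its own printed data and are deliberately not targeted: the overall
F statistic (19.946 as printed; $R^2 = 0.7006$ at $n = 13$ implies 25.745,
which `ols_fit()` reports, satisfying the identity
$F = R^2 (n-2)/(1-R^2)$ exactly) and the delay standard deviation (8.4 as
printed; the 13 recorded delays give a sample SD of 10.93). The p-value is
computed from the upper tail of the $F(1, n-2)$ distribution.

`ols_fit()` itself is a validated wrapper around `stats::lm()`; the test
suite cross-checks it against an independent hand-written normal-equations
oracle to $10^{-10}$ on random small designs.

## Ranking

`rank_drugs()` orders a reference table by increasing displayed $F_t$ — a
propensity continuum from gabapentin (0.97) to sertraline (4.8). Drugs
sharing a displayed factor form a tie group; the reported factor carries
one decimal, so no finer ordering is meaningful within a group, and the
package uses an alphabetical tie-break for determinism. Consumers who care
about tie structure should compare tie groups as sets (as the tests do),
not row order.

## The synthetic cohort generator

`simulate_cohort()` draws paired cases with exactly the statistical
structure the model assumes, so every pipeline stage can be exercised, and
recovery of generating parameters quantified, without real case data. For
each case of a drug with true median ratio $R$:

* $AM \sim \text{log-uniform}(0.01, 10)$ mg/L — spanning the three orders
  of magnitude that separate potent opioids from over-the-counter drugs in
  the reference panel;
* $F = F_t(R)\,e^{\varepsilon}$, $\varepsilon \sim N(0, \sigma_F^2)$ with
  default $\sigma_F = 0.1$;
* $P = F \cdot AM$ (the forward direction of the factor definition, so the
  casework inversion $AM = P/F$ is exact at zero noise);
* a per-case liver/peripheral ratio $R\,e^{\eta}$,
  $\eta \sim N(0, \sigma_{LP}^2)$ with default $\sigma_{LP} = 0.2$;
* a postmortem delay drawn uniformly on 5–48 h as an inert covariate
  (within its applicability window the model treats delays as
  exchangeable, and the paired-case data showed no delay trend).

Multiplicative lognormal noise is the natural choice for positive,
right-skewed concentrations and ratios, and its median of 1 keeps
drug-level medians centred on the generating truth. The source material
publishes medians only — no within-drug dispersion — so the default scales
are conventions chosen to represent realistic assay-plus-biology scatter
(about ±10% case-level factor noise, ±20% ratio scatter), fixed once and
recorded, with the seed, in every cohort. Passing tests on such cohorts
demonstrate correctness of the pipeline under the model's own assumptions;
they do not demonstrate that real casework obeys those assumptions (real
L/P scatter is unknown and likely drug-dependent, overdose kinetics violate
the model, and delay is generated as inert by construction).

`recover_ft()` closes the loop the way the reference table was built:
median of per-case ratios, fed through the factor model, compared with
truth. At the defaults (200 cases per drug, $\sigma_{LP} = 0.2$) every
factor in the 43-drug panel is recovered within 0.1 — the resolution of
the displayed column.

## Numerical choices and degenerate inputs

* All concentration, ratio, and factor inputs must be finite and strictly
  positive; violations raise errors naming the argument. Zero or negative
  values are physically meaningless here, not edge cases to coerce.
* `ols_fit()` refuses fewer than 3 points and constant predictors
  (degenerate design); $R^2 = 1$ designs report an infinite F statistic
  and zero p-value rather than `NaN`.
* CSV I/O is strict RFC-4180-style (comma, `.` decimal, mandatory header);
  malformed numerics are reported with their row numbers, duplicate drug
  names (case-insensitive) are rejected at load and write, and a
  write-then-load round trip is the identity on valid collections.
* Estimation warns — deliberately does not error — when a supplied
  postmortem delay exceeds 48 h, since the model may still inform such
  cases but was not established there.

## Problem sizes

The shipped analyses are small by nature (44 reference drugs, 13 paired
cases) and run in well under a second. Simulation-backed tests use 200
cases per drug for recovery checks and up to 1000 cases per drug for the
convergence check, sizes at which median sampling error is comfortably
below the display resolution; the full suite completes in a few seconds.

## Known limitations

* $F_t$ models the *central tendency* of redistribution. Individual cases
  scatter around it (the validation $R^2$ is 0.70, not 1), so an estimated
  antemortem concentration is an interpretive aid, not a measurement.
* The model is established for autopsies within 48 hours of death and
  without decomposition; beyond that window redistribution becomes
  inconsistent and the factor should not be trusted.
* Overdose cases with incomplete distribution, and specimens from central
  or cardiac sites, violate the model's premises.
* The constants 2.5 and 2.6 are treated as fixed; the package does not
  refit them, and no mechanistic meaning is claimed.
* Ethanol's factor is literature-derived, not computed from an L/P median;
  it participates in lookups and ranking but not in recomputation checks.
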