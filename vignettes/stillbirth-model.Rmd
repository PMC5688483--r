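---
title: "Modelling stillbirths averted by intervention scale-up"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stillbirths averted by intervention scale-up}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stillavert)
```

## The model

`stillavert` implements a linear, deterministic deaths-averted model for
stillbirths in the style of the Lives Saved Tool (LiST). The starting point is
a country's stillbirth *envelope* — the total number of late fetal deaths
(≥28 weeks or ≥1000 g) in a year, taken from external estimates — split into
an antepartum and an intrapartum compartment by a single `prop_intrapartum`
input. Cause-of-death estimates do not exist for stillbirths, so the model
works on this timing dichotomy rather than on causes.

For one intervention, the fraction of a compartment's stillbirths averted by
a coverage change is

$$ f = E \times (C_{target} - C_{base}) \times AF $$

where $E$ is the intervention's effectiveness (fraction reduction among those
who could benefit), $C$ is population coverage, and $AF$ is the *affected
fraction* — the share of the compartment's stillbirths susceptible to the
intervention. Where a risk factor's prevalence $p$ and its relative risk of
stillbirth $RR$ are known, the affected fraction is the population
attributable fraction

$$ AF = \frac{p(RR - 1)}{1 + p(RR - 1)}, $$

clamped at zero for protective exposures, since an affected fraction is a
proportion of deaths. Where no excess-risk estimate exists (balanced energy
supplementation), the prevalence itself is used, which understates the
affected fraction if the exposed are at higher risk. Where an intervention
can benefit every pregnancy (micronutrient supplementation) or every
intrapartum stillbirth (childbirth care), $AF = 1$. Malaria prevention uses a
composite: the fraction of pregnant women exposed to falciparum malaria is
multiplied by the placental-malaria rate among the exposed (0.278, the
primigravida figure; 0.208 and 0.156 for second and higher-order pregnancies
are available as overrides) before the attributable-fraction step, with the
placental-malaria odds ratio 2.19 treated as a relative risk — stillbirth is
rare enough for the approximation to be immaterial, and attributing the full
benefit regardless of parity follows current practice even though the
intervention was originally planned for first and second pregnancies only.

Two canonical examples of the arithmetic: syphilis detection and treatment at
82% effectiveness scaled from 0 to 50% coverage averts
$0.82 \times 0.50 = 41\%$ of syphilis-attributable antepartum stillbirths;
balanced energy supplementation at 40% effectiveness scaled from 0 to 50% in
a population where 20% are food-insecure averts
$0.40 \times 0.50 \times 0.20 = 4\%$ of all antepartum stillbirths.

## The intervention registry

`load_default_interventions()` ships the eight interventions of the current
model as ten specifications (childbirth care is carried as three mutually
exclusive levels). Effectiveness for RR-sourced interventions is defined as
$1 - RR$: micronutrient supplementation is therefore 0.08 even though the
source review's prose rounds it to a "9% reduction"; the RR is the primary
estimate, and the one-percentage-point conflict is noted on the spec.
Induction for prolonged pregnancy carries the all-cause perinatal-death RR
0.31 rather than the underpowered stillbirth-only RR 0.30. Delphi-derived
effects (diabetes 10%, hypertensive disorders 20%, BEmOC 45%, CEmOC 75%)
carry interquartile ranges, not confidence intervals. Two removed
interventions (folic acid supplementation, fetal-growth-restriction
detection) ship as `status = "legacy"` and load only on request; folic acid's
effect is null because the published record documents its removal but not the
effect size earlier versions used. Registries round-trip through YAML/JSON so
sensitivity variants can be run without touching code; the hypertensive
exposure RR 2.1, which lacks a source reference, is the first candidate for
such variation.

## Coverage proxies

Baseline coverage is rarely surveyed directly, so the registry carries proxy
rules: syphilis screening is a step-dependent share of ANC4+ attendance
(20%/50%/70%/100% of ANC4+ by tier, boundaries assigned to the upper tier —
the printed tier labels overlap, so a deterministic convention is needed);
diabetes and hypertensive-disorder management reach 5% of ANC4+ attendees;
the BEmOC/CEmOC shares are tier-dependent proportions *of facility
deliveries* (interpreting them as shares of all births would exceed facility
delivery itself below 30%); malaria prevention reads the IPTp-or-ITN survey
indicator directly; micronutrient and balanced energy default to zero.
Induction coverage is capped at the CEmOC delivery share, and by default all
CEmOC deliveries are assumed to have access to induction at baseline.
Facility births not assigned to BEmOC/CEmOC are counted with skilled
attendance outside those facilities: the category name suggests otherwise,
but the four delivery categories must sum to 1 and this is the only
mass-conserving assignment.

## Multi-year projections

`run_scenario()` interpolates each coverage linearly from baseline to the
scenario target (or steps immediately after the base year), and per year:

1. applies the childbirth-care mix shift to the intrapartum compartment in
   the plain linear form $deaths \times \sum_c e_c \Delta c_c$ with category
   effects 0.23/0.45/0.75 relative to home birth without a skilled attendant;
2. applies the remaining interventions to each compartment as a
   multiplicative residual cascade,
   $residual = deaths \prod_i (1 - f_i)$.

The model's published arithmetic is single-intervention only; the cascade is
this package's combination rule. It is order-free, can never exceed a 100%
reduction, and — not coincidentally — equals the expectation of an
individual-level model in which intervention receipt is independent across
interventions. Jointly averted deaths are attributed to interventions in
proportion to their single-intervention fractions $f_i$, so attributed deaths
plus residual equal the envelope exactly, every year. Childbirth care is
applied before the cascade; because its form is linear while the cascade is
multiplicative, the order matters and is fixed.

Other conventions: the envelope is static (no secular mortality trend), so a
zero-change scenario holds the stillbirth rate flat; negative coverage
changes increase deaths symmetrically, and the residual may then exceed the
envelope (it is floored at zero, never at the envelope, so that conservation
holds exactly); per-year childbirth mixes are interpolated componentwise
between the base and target mixes rather than re-derived from interpolated
facility rates, which would jump at tier boundaries mid-projection;
fractional deaths are carried at full precision and rounded only in the text
report. The baseline envelope already reflects whatever intervention coverage
exists, and the linear form does not renormalise for it; a renormalised
childbirth mode (`renormalise_childbirth = TRUE`) that compares mix-weighted
relative risks is provided but off by default, matching the published
examples, which all start from zero baseline. Induction's effect is applied
to both timing compartments without down-weighting antepartum deaths that
occur before 41 weeks; the evidence gives no basis for a finer split.

## The microsimulation oracle

`simulate_cohort()` is an individual-level Monte-Carlo twin of the
deterministic arithmetic, used to validate it rather than to replace it. Each
pregnancy draws risk-factor exposures as independent Bernoulli variables at
the profile prevalences, intervention receipt as independent Bernoulli
variables at the configured coverages, and a delivery category from the
childbirth mix; risks multiply on the probability scale and are clamped at 1.
A received intervention removes a fraction $E$ of the *excess* risk of
exposed pregnancies (for PAF-rule interventions) or scales the whole risk of
affected pregnancies by $1 - E$ (for everyone-affected and prevalence-proxy
rules). The excess-risk reading is deliberate: it is the only one under which
the simulated averted deaths equal $E \cdot \Delta C \cdot AF$ of the
envelope, i.e. under which the microsimulation embodies the same claim as the
deterministic model. Exposures are drawn independently of each other and of
intervention receipt — the same implicit assumptions the linear model makes
(in reality, ANC-based proxies likely overestimate coverage among the
exposed).

`engine_microsim_agreement()` scales each intervention from zero coverage in
turn and checks the simulated reduction against the deterministic prediction,
using the simulated baseline death counts as the engine's envelope so that
the comparison isolates the averted-deaths arithmetic; z-scores use binomial
standard errors of the two runs. Scale-ups start at zero baseline with an
all-home delivery mix because that is the regime in which the linear
non-renormalised form is exactly the expectation of the structural model;
with non-zero baselines the two conventions diverge, which is precisely the
renormalisation question discussed above. The induction coverage cap is a
scenario-level policy constraint and is not applied inside the agreement
check.

`generate_profile_fixture()` emits synthetic country profiles in three
archetypes (high-burden: SBR 20–35, ANC4+ 30–60%, endemic malaria;
transition: SBR 12–20; low-burden: SBR 3–10, near-universal facility birth),
deterministic per seed. The ranges are chosen to bracket the global spread of
the model's inputs; the profiles are fixtures, not estimates for any real
country. What passing tests on them shows is that the implementation computes
the model faithfully across its input space — not that the model's
effectiveness estimates, proxy rules or independence assumptions hold in any
real population, several of which the published record itself flags as soft
(Delphi effects, the unreferenced hypertensive RR, ANC4-based coverage
proxies with known poor correlation to measured syphilis-screening coverage).

## Problem sizes and numerics

The validation suite uses cohorts of $10^6$ pregnancies per simulation run —
large enough that the Monte-Carlo standard error on a typical averted count
is a few percent — with 50 random (prevalence, RR) pairs for the closed-form
PAF check and 20 seeded synthetic profiles for the engine agreement suite,
each comparison required to sit within 3 standard errors. Property-based
invariant checks (PAF bounds and monotonicity, delivery-mix normalisation,
cascade conservation and order invariance, static-envelope projections,
config round-trips) run 200 random cases each under fixed seeds. Childbirth
mixes must sum to 1 within $10^{-9}$; cascade conservation is exact by
construction (the residual is defined as envelope minus attributed deaths);
tier boundaries are half-open with the boundary in the upper tier; config
files reject fractions above 1 rather than guessing percent units; YAML is
written at 15 significant digits so profiles round-trip losslessly.

## Limitations

Uncertainty intervals on outputs are out of scope (the upstream methodology
for them is unpublished). The model inherits the structural limits of the
linear approach: static envelope and cause structure, no interaction between
risk factors, no gestational-age resolution, no competing risks with neonatal
death, and no misclassification between intrapartum stillbirth and early
neonatal death. Country-level totals depend entirely on user-supplied
envelopes, prevalences and coverage indicators; this package ships none.
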