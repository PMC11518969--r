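---
title: "Simulating a linked population: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a linked population: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linksim)
```

`linksim` produces ground-truth-linked synthetic administrative records by
running an individual-based demographic microsimulation and observing it
through census-, tax-, WIC-, and survey-style collectors. This vignette is
the package's own account of the models it implements, the parameters that
matter, and the choices made where the design was genuinely open.

## The discrete-time event model

The simulation advances a population of person-agents in 28-day steps
(`step_days`, configurable), from a start date (default 2019-01-01) until
the clock strictly exceeds an end threshold (default 2041-05-01; 292 steps).
The 28-day step is a compromise between temporal resolution and cost: a
month-like step is short enough that demographic events are rare per step,
long enough that a multi-decade run is a few hundred steps.

Every stochastic event family is specified as a hazard rate per person-year
(or household-year) stratified by demographics. A rate $\lambda$ becomes a
per-step event probability through the standard exponential-survival
conversion

$$p = 1 - \exp(-\lambda \cdot \text{step\_days}/365.25),$$

which is monotone in $\lambda$ and stays in $[0, 1)$. Within a step,
components run in a fixed order: mortality, fertility, domestic migration
(individual, then household), emigration, immigration, employment change,
then any observers due. The order is a free design choice — the underlying
model does not specify one — and it only affects within-step interactions;
we document it and keep it fixed. One consequence is convenient for
plausibility: a simulant removed by mortality is no longer at risk for
fertility or migration in the same step. Simulants born or immigrating
mid-step are not at risk for other events until the following step, the
simplest consistent exposure rule.

Reproducibility is handled by per-(component, step) RNG substreams: each
component at each step seeds R's generator with an integer derived from the
master seed by an explicit Lehmer-style mix modulo $2^{31}-1$. Runs are
therefore bit-reproducible for a fixed master seed, and altering one
component's draws does not shift any other component's stream.

Each step's event counts satisfy, exactly,

$$\text{present}(t+1) = \text{present}(t) + \text{births} +
\text{immigrants} - \text{deaths} - \text{emigrants},$$

asserted by `check_accounting_identity()` on the event log.

## Initialization

The starting population is drawn from household-clustered microdata (the
bundled synthetic stand-in for public survey microdata): entities — whole
non-GQ households, or individual group-quarters (GQ) residents — are sampled
with replacement, with probability proportional to weight, until the target
population is reached. Sampling whole households preserves the joint
structure of ages, relationships, and household size.

Because target populations exceed the microdata size, many simulants share a
source record. To avoid unrealistically easy linkage between such clones,
integer ages are first made precise by adding a uniform fraction of a year,
and then every sampled entity receives one shared age shift drawn from a
standard normal (in years); any resulting negative age has its sign flipped.
The shift is shared within an entity so that within-household age gaps are
preserved; the sign flip is applied per member because a household-level
shift may push only an infant negative. Date of birth is then set to
`reference_date - round(age * 365.25)` days, consistent with the precise age
to within a day.

Other initialization rules:

- **Race/ethnicity.** Separate race and Hispanic-ethnicity codes collapse to
  one composite with seven exhaustive categories; a true Hispanic indicator
  maps to Latino regardless of race code, the conventional
  ethnicity-precedence rule.
- **Group quarters.** Microdata distinguish only institutional vs
  non-institutional GQ; the specific kind is drawn uniformly from the three
  kinds consistent with that status (carceral / nursing home / other
  institutional; college / military / other non-institutional). GQ residents
  are pooled into one unit per kind — the observers need only the kind and
  an address, and the microdata do not identify GQ facilities.
- **Nativity and SSN.** US-born simulants always hold an SSN; foreign-born
  simulants hold one with probability `p_ssn_foreign_born` (default 0.6, a
  round configurable figure — the true quantity depends on visa composition
  that the model does not represent).
- **Mailing addresses.** A residential household's mail goes to a PO box
  with probability `p_po_box` (default 10%; the mechanism matters for
  linkage realism, the rate is a configurable guess).

## Demographic components

**Mortality** applies an (age group, sex) all-cause hazard; the synthetic
default is Gompertz-like, $\lambda(a) = \lambda_0 e^{0.08a}$ with
$\lambda_0 = 10^{-4}$/yr and a 1.4 male multiplier, chosen to give a
realistic age gradient and an order-of-magnitude-plausible crude death rate
under the fixture age structure. When a residential
reference person dies, the oldest remaining present member becomes the new
reference person — even if implausibly young — and the other members'
relationships are remapped by a deterministic rule table
(`remap_relationship()`): non-kin stay non-kin, same-generation children
become siblings, children of the old reference person become grandchildren
when a parent takes over, and anything not directly derivable collapses to
"Other relative". The table is the minimal kinship-consistent mapping; the
13 recorded relationship values cannot represent every true relationship, so
collapsing to "Other relative" is the honest default. Emptied households are
closed and their addresses vacated, never to be reused.

**Fertility** gives each present female simulant a per-step birth
probability from an age-specific rate table (defaults confined to ages
15–49, peaking at 0.10/yr at 25–29 — a stylized age profile). The event time
is uniform within the step and sets the newborn's date of birth. A fixed 4%
of birth events are twin events (`twin_probability`); twins share household,
date of birth, and (through inheritance) last name, deliberately creating
hard linkage cases. Newborns inherit household, race/ethnicity, and last
name from the single identified parent, are US-born with an SSN, and get a
relationship to the reference person from a deterministic table keyed by the
parent's relationship (reference person → biological child; child types →
grandchild; lateral kin → other relative; non-kin → other nonrelative).
Zygosity is not modeled (twin sexes are independent), and there is no
maternity-spacing constraint — consecutive-step births are possible but rare
at realistic rates. A GQ-resident parent's newborn is placed in the parent's
GQ unit; this is a known oddity (a college dorm acquiring a newborn) that we
prefer over inventing an unspecified household-formation rule.

## Migration

**Domestic individual moves** occur at an (age group, sex, race/ethnicity)
rate, at most once per simulant per step. The destination is drawn from
`destination_split` — default 50% establish a new one-person household (the
mover becomes its reference person), 40% join an existing residential
household, 10% enter group quarters (uniform kind). The three destination
kinds are part of the model; their split is not stated anywhere, so the
default is a configurable choice favoring household formation. Joiners are
always recorded as "Other nonrelative", and join targets are uniform over
residential households. Both rules have a visible consequence: the
population's share of "Other nonrelative" relationships drifts upward over a
multi-decade run. The direction of that drift is a tested property; its
magnitude depends entirely on calibration and is not asserted.

**Domestic household moves** relocate an entire household of more than one
member as a unit, at a rate stratified by the reference person's
demographics (households have no demographics of their own). Relationships
are unchanged; the household receives fresh physical and mailing addresses.

**Working-age movers change employment.** Any mover aged 18+ re-draws an
employer at the move, the same resampling used by the employment component.

**Emigration** applies per-person hazards stratified by age group, sex,
race/ethnicity, nativity, and state of residence, with three move types:
household events (drawn by reference persons, removing the whole household),
GQ-person events, and non-reference-person events (which by construction
never remove a reference person, so they never trigger succession).
Emigrants are never tracked again.

**Immigration** arrives as Poisson-distributed event counts per step (mean =
yearly count × step/365.25; constant over time, no seasonality) of the same
three types, sampled from the recent-immigrant subset of the microdata.
Immigrants' ages are made precise but receive no normal shift — each
immigrant is a fresh entity, so clone-decorrelation is unnecessary. The
default yearly counts (3 household, 1 GQ-person, 3 non-reference events) are
absolute numbers sized for a desk-scale run of about a thousand simulants
and should be scaled with the target population.

## Employment and income

The employer registry holds `n_employers` regular employers with initial
sizes drawn from a log-normal (meanlog 1, sdlog 1.5 — heavy-tailed, so a few
large and many small employers), plus two distinguished states: unemployment
and a single military employer, entering the assignment draw with fixed
weights (defaults 5% and 1%; the three states are part of the model, their
weights are not quantified anywhere and are configuration). Employer
assignment — identical at initialization and at every change event — is a
categorical draw with probability proportional to initial size, which keeps
population-level employment shares proportional to the size attribute
indefinitely (a chi-square-tested property). Working-age (18+) simulants,
including the unemployed, change employment at 50 changes per 100
person-years; a change may re-draw the current employer and still counts as
a change, because excluding self-draws would distort the proportionality.

Wages are annual, log-normal per (age group, sex, race/ethnicity) stratum,
independent of employer, resampled at assignment; the unemployed earn zero.
The parameters are synthetic and uncalibrated: a common median (default
$32{,}000) with a concave age profile, a small sex gap, small
race/ethnicity offsets, and constant log-scale 0.7. They produce a
plausible-looking wage distribution for income-tested observers, nothing
more. Retirement, multiple simultaneous jobs, and business dynamics
(openings, closures, renames, mergers) are not modeled.

## Identity attributes

Names, SSNs, and ITINs are assigned by the identity module as simulants
enter the simulation (initialization, birth, immigration). The functions are
usable post-hoc on a whole population; assigning at entry keeps observer
output complete in a single pass while preserving the one ordering
constraint that matters — a newborn's last name is the mother's, already
assigned.

- **Names.** First and middle names are drawn frequency-weighted within
  (sex, birth-decade cohort); last names frequency-weighted within
  race/ethnicity, independently of first names (first–last correlation is a
  known, accepted simplification). With probability `p_compound` (default
  5%, split evenly hyphen vs space) a last name becomes a two-part compound.
  The synthetic name tables impose a minimum frequency of 5, mirroring the
  suppression of rare names in public name files.
- **SSNs** are uniform over the valid space: area 001–899 excluding 666,
  group 01–99, serial 0001–9999 (888,931,098 combinations), unique within a
  run, formatted `AAA-GG-SSSS`. **ITINs** are issued lazily to SSN-less tax
  filers: nine digits, leading 9, group digits restricted to the
  conventional allowed ranges (50–65, 70–88, 90–92, 94–99 by default).
- **Employer names** come from a bigram multigraph over a business-name
  corpus: words are nodes with `<start>`/`<end>` sentinels, one directed
  multi-edge per adjacent word pair occurrence. A name is a random walk from
  `<start>` choosing uniformly among outgoing multi-edges (prob ∝ edge
  count) until `<end>` or `max_path_length` words (default 10; truncation
  emits the partial name rather than rejecting, the simpler rule). Every
  adjacent word pair in a generated name therefore occurs somewhere in the
  corpus — a tested closure property — while whole names recombine freely.

## Observers

Observer schedules are design choices (the datasets are specified, their
cadences are not): decennial census on April 1 of decade years; tax and WIC
once per completed calendar year; household survey every step at a small
sampling rate. All outputs carry the true simulant ID. The census is a full
enumeration of present simulants with floored age, date of birth, sex,
race/ethnicity, relationship, address, and GQ kind; coverage error and
record noising belong to downstream tooling, not to this package. Tax
observation emits one W2/1099 row per employment stint overlapping the year
(form kind is an employer attribute, default 85% W2), wages prorated
linearly by the stint's fraction of the year, plus one 1040 per filer; the
tax table is dated January 1 of its year, so simulants who died during the
year still file, while anyone gone before the year began cannot appear. WIC
is observed December 31: members of households whose summed income is below
`multiplier × (base + per_member × (size − 1))` — default 1.85 × a
poverty-guideline-shaped schedule — restricted to mothers of the year's
newborns and children under five (the eligible categories are assumptions,
configurable). No observer ever includes a simulant whose death or
emigration predates the observation date.

## Synthetic fixtures: what they emulate and what they do not

The fixtures module generates every calibration input in code: microdata
(truncated-geometric household sizes with mean 2.5, one reference person per
household, relationship-consistent member ages, person weights, household-
level recent-immigrant flags), deterministic rate tables (rates are smooth
parametric functions of config, so acceptance checks are sharp; a seed only
matters if jitter is enabled), name tables, a business-name corpus, and an
address lexicon. When the recent-immigrant fraction is positive the
generator guarantees at least one flagged multi-member household and one
flagged GQ record, so every immigration move type has a sampling subset.

These fixtures emulate the *shapes* of the real inputs — household
clustering, stratification, weights, heavy tails — not US distributions.
Passing tests therefore demonstrate that the simulator's mechanisms are
correct (rates are honored, structure is preserved, identities are valid and
unique, accounting balances), not that its output matches US demography.
Calibration to real microdata, rate estimates, and name files is an explicit
non-goal of the fixtures.

## Numerical choices and degenerate inputs

- Per-step probabilities are clamped to the largest double below 1, keeping
  the documented $[0,1)$ range even for absurd rates.
- `num_steps` uses integer day arithmetic: the smallest $k$ with
  start $+ k \cdot$ step strictly after the threshold; equal dates give one
  step.
- Empty inputs are legal where they are meaningful (zero households, zero
  corpus names, zero rates) and rejected where they are not (empty microdata
  at initialization, empty corpus for the bigram graph, missing rate
  strata abort with the component and step named).
- Address uniqueness is enforced on components, with resampling on
  collision and a hard failure if the synthetic space is exhausted; address
  IDs are strictly increasing and never reused.
- Ages use 365.25-day years throughout; census ages are floored elapsed
  years. Newborns' precise ages are set exactly from date of birth at the
  end of their birth step; immigrants keep their entry-time precise age
  until the next step (a sub-step approximation bounded by 28 days).

## Problem sizes used in the checks

The bundled test-and-acceptance suite runs entirely at desk scale, chosen so
the full suite completes in minutes on one core: statistical oracles use
10,000–100,000 draws (binomial/Poisson/chi-square checks at 3 standard
errors or α = 0.001), the accounting identity is verified on a 50-step run
of ~10,000 simulants, and the relationship-drift property uses 20 seeded
runs of ~250 simulants over an 11-year window with only migration active.
Production-scale national runs (hundreds of millions of simulants over
multiple decades) are outside this package's scope; the mechanisms, not the
scale, are what it implements and validates.

## Known limitations

Household substructure interacting with migration is simplified (children
can move alone; joiners are always "Other nonrelative", so irregular
household structures accumulate by design); fertility and mortality ignore
income and race/ethnicity; there is no retirement, adoption, second parent,
return migration, or seasonality; GQ moves ignore age-kind plausibility
(an 80-year-old can enter college housing); and all rate tables are
synthetic stand-ins. Record noising — typos, OCR error, blanks, nicknames —
is deliberately out of scope: this package produces the clean,
ground-truth-linked substrate that noising layers consume.
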