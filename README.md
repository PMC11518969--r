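# linksim

Entity-resolution (ER) research needs realistic person-level records — names,
addresses, dates of birth, identification numbers — but the real datasets that
carry them are locked behind privacy restrictions. `linksim` sidesteps this by
*simulating* a population: individual agents ("simulants") living in
households and group quarters evolve through mortality, fertility, migration,
and employment on a 28-day clock, and dataset observers emit census-, tax-,
WIC-, and survey-style tables in which every row carries the true simulant ID.
Because the ground truth is known, linkage algorithms can be scored exactly.

The package is aimed at researchers building or benchmarking record-linkage
methods, and at anyone needing structured, internally consistent synthetic
population data with longitudinal dynamics.

## The model

- **Population.** Simulants are initialized by weighted sampling of entities
  (whole households, or individual group-quarters residents) from
  survey-style microdata, preserving within-household structure. Integer ages
  become precise ages (uniform fraction), then each sampled entity receives
  one shared standard-normal age shift with negative results sign-flipped,
  decorrelating the many simulants that share a source record. Race and
  Hispanic ethnicity codes map to a single composite race/ethnicity with
  seven exhaustive categories (Hispanic ⇒ Latino).
- **Clock.** Time advances in 28-day steps from 2019-01-01 until the clock
  exceeds 2041-05-01 (292 steps by default). A yearly hazard rate λ becomes a
  per-step probability `1 − exp(−λ · 28/365.25)`.
- **Events, in fixed order per step:** mortality (age/sex rates; a dead
  reference person triggers succession by the oldest remaining member, with
  relationship remapping) → fertility (age-specific rates for female
  simulants; 4% of birth events are twins; newborns inherit household,
  race/ethnicity, and last name from the single identified parent) →
  domestic migration (individual moves into a new one-person household, an
  existing household as "Other nonrelative", or group quarters; whole-
  household moves preserve relationships) → emigration and immigration
  (household / GQ-person / non-reference-person move types) → employment
  change (50 changes per 100 person-years; employers re-drawn with
  probability proportional to a heavy-tailed initial size; wages log-normal
  by demographic stratum).
- **Identity.** First/middle names are drawn by sex and birth-decade cohort,
  last names by race/ethnicity (with occasional hyphen/space compounds);
  SSNs are uniform over the valid `AAA-GG-SSSS` space (area 001–899
  excluding 666); ITINs go to SSN-less tax filers; employer names are
  generated by uniform random walks over a bigram multigraph built from a
  business-name corpus.
- **Observers.** Decennial census (April 1 of decade years), tax forms
  (W2/1099 per employment stint per year, wages prorated by stint duration,
  plus a 1040 per filer), WIC (income-tested, mothers of the year's newborns
  and children under five), and a per-step household survey. Addresses are
  never reused after vacancy; dead and emigrated simulants never reappear.

All calibration inputs — microdata, rate tables, name frequency tables, the
business-name corpus, an address lexicon — are produced by the bundled
synthetic-fixtures module, so everything runs offline. The synthetic rate
shapes are plausible but deliberately uncalibrated stand-ins.

## A worked example

```r
library(linksim)

fixtures <- generate_fixtures(seed = 1, n_households = 500)
config <- sim_config(target_population = 800, master_seed = 7, steps = 14,
                     observers = list(survey = FALSE))
result <- run_simulation(config, fixtures)
result
#> <sim_result>
#>   14 steps: 2019-01-01 .. 2020-01-28
#>   population: 802 -> 819 present
#>   totals: 10 births, 7 deaths, 15 immigrants, 1 emigrants
#>   2 observation tables
check_accounting_identity(result$event_log)
#> [1] TRUE

tax <- result$observations[["tax_2019"]]
head(tax[tax$tax_form == "W2", c("simulant_id", "last_name", "ssn",
                                 "employer_name", "wages")], 3)
#>  simulant_id last_name         ssn       employer_name wages
#>          309    Fawell 441-40-5485 Family Practice LLC   474
#>          335     Kelez 349-66-4809           Grand Oak    90
#>          508  Quinwell 693-13-6144   Crown Landscaping   106
```

The 14-step run covers calendar year 2019, so the tax and WIC observers fire
once each (a census would first appear on 2020-04-01). Each tax row is one
employment stint overlapping the year, with wages prorated by the stint's
fraction of the year — the rows above are short end-of-year stints, and a
simulant who changed employers mid-year appears under several employers with
the same SSN: exactly the linkable-but-messy structure ER methods must
handle. Every count printed above balances: present(t+1) = present(t) +
births + immigrants − deaths − emigrants at every step.

A command-line front end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/simulate", package="linksim"))')" \
  --seed 3 --population 300 --steps 15 --output-dir out/
```

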