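# cholinetrace

Quantitative analysis of stable-isotope (D9-)choline tracer kinetics in
neonatal target organs.

## The problem

Choline demand peaks during rapid perinatal growth: phosphatidylcholine
(PC) synthesis for parenchymal membranes, lipoproteins, bile and surfactant
competes with choline oxidation to betaine, the methyl donor feeding the
one-carbon pool. A tracer study makes these fluxes measurable — neonatal
rats receive a single intraperitoneal dose of D9-choline chloride
(50 mg/kg ≈ 336 nmol/g body weight; all three N-methyl groups
trideuterated), and liver, plasma, lung, lung lavage fluid, cerebrum and
cerebellum are assayed by LC-MS/MS in selected-reaction-monitoring mode at
1.5, 6 and 24 h for endogenous, D9- and D3-labeled choline metabolites and
choline phospholipids.

`cholinetrace` is for analysts working with such data (or designing such
studies). It implements:

* **SRM quantification** — natural-abundance ¹³C correction
  (`C[i,j] = choose(n,2) p² (1−p)^(n−2)` for the M+2 double-bond overlap,
  solved as `C x = raw`), chain-length response factors, internal-standard
  ratio quantification, acyl-subgroup grouping;
* **pool accounting** — whole-organ/whole-plasma pools (plasma volume =
  body weight × 0.125 × (1 − 0.40) / 1.025), descriptive organ fractions;
* **label accounting** — methyl-corrected fractions of dose
  (`100 · pool · n_CD3/3 / dose`), enrichments `100·L/(L+U)`, label
  balance with explicit residual;
* **kinetic statistics** — percent/fold contrasts, PC subgroup profiles
  vs. equilibrium composition, Tukey-within-family /
  Bonferroni-across-families comparisons, summary-statistics (mean ± SE)
  mode;
* **a compartmental tracer-network simulator** (first-order mass-action
  over organ × species × label states, conserving methyl-weighted label)
  that generates complete synthetic per-animal studies, so the entire
  pipeline is testable end-to-end without animal data.

## Worked example

```r
library(cholinetrace)
library(dplyr)

# a full synthetic study: 27 animals, 3 sacrifice times, raw SRM counts
study <- sample_study(simulation_config(seed = 20220720))
run <- run_pipeline(study$measurements, study$animals)

run$fractions %>% filter(category == "D9_phospholipid")
#> # A tibble: 3 × 5
#>   time_h category            n percent_of_dose    se
#>    <dbl> <chr>           <int>           <dbl> <dbl>
#> 1    1.5 D9_phospholipid     9           14.7  0.606
#> 2    6   D9_phospholipid     9           12.5  0.516
#> 3   24   D9_phospholipid     9            9.48 0.309
```

About 15% of the administered label is in D9-phospholipids at 1.5 h,
declining toward ~10% by 24 h — the tracer is incorporated into PC within
the first sampling interval and is thereafter redistributed between organs
rather than newly synthesized. Descriptive fractions from the packaged reference pool
summary:

```r
descriptive_fractions()
#> # A tibble: 7 × 3
#>   organ              pct_body_mass pct_choline_pl
#>   <chr>                      <dbl>          <dbl>
#> 1 liver                      2.95            8.09
#> 2 plasma                     7.63            1.95
#> 3 lung                       1               2.38
#> 4 cerebrum                   3.12            7.09
#> 5 cerebellum                 0.950           2.06
#> 6 all_organs_plasma         15.6            NA
#> 7 investigated_total        NA              21.7
```

The liver is 2.9% of body mass but 8.1% of the body's choline
phospholipids; all investigated compartments together hold 21.7% of the
estimated whole-body pool (10 µmol/g) in 15.6% of the body weight — the
quantitative sense in which these organs are choline-enriched.

A command-line wrapper is installed with the package
(`system.file("cli", "cholinetrace.R", package = "cholinetrace")`) with
subcommands `validate`, `quantify`, `pools`, `fractions`, `contrasts`,
`simulate` and `run-all`.

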