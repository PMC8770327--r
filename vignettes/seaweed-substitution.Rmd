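---
title: "Usual intake and risk characterization for food substitution scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Usual intake and risk characterization for food substitution scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbfood)
```

## The problem

`rbfood` implements a low-tier dietary risk–benefit assessment for diet
substitution scenarios. The motivating case study asks what happens to the
intake of two nutrients (iodine, sodium) and the exposure to five chemical
contaminants (total and inorganic arsenic, cadmium, lead, mercury) when a
fraction of the habitual consumption of pasta, bacon and rocket lettuce is
replaced by analogues made from the kelp *Saccharina latissima*. Kelp is
iodine-rich — a benefit where intakes sit below the adequate intake — but
also accumulates heavy metals, notably arsenic, so the same substitution
moves risk and benefit at once.

The pipeline has five stages, each usable on its own:

1. **Consumption data** (`read_survey()`, `simulate_survey()`): 2×24-h
   recall records, one row per food per person per day, with cooked and raw
   gram amounts.
2. **Occurrence data** (`read_concentrations()`,
   `normalize_concentrations()`, `build_index()`): substance concentrations
   per kg food, censored values imputed, dry weight converted to wet
   weight, indexed over a hierarchical food classification with fallback.
3. **Scenario** (`apply_scenario()`): a stated fraction of each matching
   consumption record's mass is redirected to a replacement food.
4. **Usual intake** (`fit_lnn()`, `usual_distribution()`,
   `bootstrap_usual_intake()`): a two-part logistic-normal-normal model
   turns repeated short-term observations into a chronic (usual) intake
   distribution.
5. **Risk characterization** (`to_daily()`, `classify_result()`,
   `margin_of_exposure()`, `exceedance_fraction()`): comparison against
   health-based guidance values and benchmark-dose reference points.

## The usual-intake model

Daily intake of a substance is assembled per person-day as
$Y_{ij} = \sum_f A_{ijf} \, c_f$, with $A_{ijf}$ the consumed mass (kg) of
food $f$ by person $i$ on day $j$ and $c_f$ its concentration per kg.
Cooked amounts feed the nutrient path (results in µg/day or mg/day); raw
amounts feed the contaminant path and are divided by body weight exactly
once (results in µg/kg bw/day).

Observed daily intakes mix *within-person* day-to-day variation with the
*between-person* variation that actually matters for chronic risk. The
two-part model separates them:

* **Frequency part.** Person $i$ consumes on any day with probability
  $p_i$, where $\mathrm{logit}(p_i) \sim N(\mu_q, \sigma_q^2)$. Day-level
  indicators are Bernoulli given $p_i$. The marginal likelihood of the
  positive-day counts integrates over the latent normal; we evaluate it
  with Gauss–Hermite quadrature (21 nodes by default, configurable via
  `gh_nodes`; 21 nodes is the usual accuracy/cost compromise for
  one-dimensional logit-normal integrals) and maximize it numerically.
  When every person-day is positive — the normal situation for total-diet
  intake of nutrients and ubiquitous contaminants — the logistic stage is
  detected and skipped, degenerating to $p = 1$.
* **Amount part.** Positive amounts are log-normal:
  $\log Y_{ij} = \mu_a + b_i + e_{ij}$ with $b_i \sim N(0, \sigma_b^2)$
  (between-person) and $e_{ij} \sim N(0, \sigma_w^2)$ (within-person).
  The components are estimated by a weighted ANOVA-type moment
  decomposition: $\hat\sigma_w^2$ pools squared deviations from person
  means over persons with ≥ 2 positive days; $\hat\sigma_b^2$ is the
  weighted variance of person means minus the expected within-person
  contribution, truncated at zero. This transparent moment estimator is a
  deliberate choice over full REML: for the balanced 2-day designs the
  package targets it is nearly as efficient, has no convergence failure
  modes inside the bootstrap, and its bias terms are exactly the ones the
  correction removes.
* **Independence.** The frequency–amount correlation is fixed at zero, in
  the model and in the synthetic generator, so the two parts can be fitted
  separately.

A person's **usual intake** is their long-term expected daily intake given
their latent effects,
$$ UI_i = p_i \exp\!\left(\mu_a + b_i + \sigma_w^2/2\right), $$
the $\sigma_w^2/2$ term being the log-normal mean correction that averages
the day-to-day residual out. The population usual-intake distribution is
obtained by Monte Carlo: draw $(\mathrm{logit}\,p_i, b_i)$ independently
from the fitted normals and back-transform (`usual_distribution()`,
default $10^5$ draws). Percentile estimates use the weighted empirical
distribution; sampling weights enter the likelihood and all summaries as
frequency weights.

Confidence intervals come from a percentile bootstrap (default $B = 200$)
that resamples *individuals* — the clusters of the repeated-recall design
— with replacement, re-running the fit and the Monte-Carlo step per
replicate; replicate failures are skipped and more than 20% failures is an
error. The bootstrap is the assumed interval method since the assessment
convention the package follows reports 95% CIs without prescribing one;
resampling clusters respects the within-person correlation that an
observation-level bootstrap would break.

As a model-choice diagnostic, the log-normality assumption for positive
amounts can be inspected with any normality test on `log(value[value > 0])`
from `compute_daily_intakes()`; the package deliberately does not switch
models automatically.

## Occurrence handling

* **Censoring.** Values below the LOD/LOQ are assigned
  `censored_fraction × limit`, default 0.5 (middle bound). Setting the
  fraction to 0 or 1 gives the lower/upper-bound sensitivity runs, and the
  resulting exposures are provably ordered.
* **Dry-to-wet conversion.** Concentrations measured on dried seaweed are
  divided by 4.7 (the water-content ratio of fresh vs dried kelp) when the
  food is eaten fresh or rehydrated. The packaged fixture keeps dried
  products (seaweed bacon) on their as-eaten basis. Full precision is kept
  internally; `round_half_up()` exists only to reproduce printed integer
  tables. Note that 40333/4.7 = 8581.49 rounds to 8581, one unit away from
  the 8582 quoted in the source table for total arsenic — that printed
  value evidently derives from unrounded source data; the other printed
  conversions (94, 24, 11) reproduce exactly.
* **Hierarchy fallback.** Foods are classified on a FoodEx2-style path
  (`"Grains>Pasta>Dried pasta"`). Every internal node of the indexed tree
  stores the *unweighted* arithmetic mean of the entries beneath it, and a
  lookup walks from the food's own path up to the root, taking the deepest
  hit. Unweighted (rather than consumption-weighted) aggregation keeps the
  index independent of any particular survey. Foods with no indexed
  ancestor contribute zero, with a logged warning and an `unmatched`
  provenance tag — occurrence tables in this field cover the foods
  expected to matter, not the whole diet, and a hard failure would make
  every realistic table unusable. Aggregates average over indexed entries
  (not over underlying samples, which are not available at this level).

## Scenarios

A substitution rule redirects `fraction` of each matching record's mass to
the replacement food, on the cooked and raw basis alike, so person-day
mass is conserved exactly. Substitution is applied per consumption record
rather than to a person's habitual mean — the intake model consumes daily
records, and for a fixed fraction the two formulations agree in
expectation. Matching is by ancestor-path prefix so one rule written at
the `Pasta` level captures all pasta subtypes; records are claimed by the
first matching rule only, and replacement records are never
re-substituted. The replacement inherits the record's cooked/raw split
(no yield change), the simplest mass-conserving choice in the absence of
yield data for the novel foods.

## The synthetic generator and what it does (not) show

No individual-level consumption survey of this kind is public, so the
package ships a generator (`population_spec()`, `simulate_survey()`) whose
generative process is exactly the LNN data model, plus a ground-truth
oracle (`true_usual_intake_distribution()`) that computes each simulated
person's true usual intake from the latent effects. Parameter recovery
against this oracle is the package's central validation claim: on 2-day
surveys of n = 2000, fitted P50 and P95 track the oracle within 5% across
a grid of variance parameters, and the Monte-Carlo back-transformation
alone matches the oracle within 3% at matched parameters. Estimator
validation uses a **single-food** population: only then is "total intake
follows one LNN process" exactly true, so oracle and estimand coincide.
The multi-food default population (`study_food_params()`) exists for
end-to-end, scenario and contributor tests, where no single-process truth
is claimed.

The default food parameters were set once so that population-mean
consumption mirrors published summaries for Dutch adults — pasta ≈ 26
g/day with about a third of the population consuming on a given day,
bacon ≈ 3 g/day, lettuce ≈ 1.3 g/day — with bread and sea fish as
background staples; body weight is normal (mean 75 kg, SD 14, truncated
at 40 kg) and sampling weights follow a configurable sex × age
post-stratification (equal targets by default, normalized to mean 1).
Cooked-to-raw yield factors are not reported anywhere for these foods;
the generator's defaults (0.45 for dried pasta, 1 otherwise) are
conventional cooking-yield magnitudes and are configurable per food.
`synthetic_study_concentrations()` extends the packaged case-study
concentration table with synthetic background entries for bread and fish
(realistic magnitudes, labelled synthetic) so every default food carries
occurrence data.

What passing these tests does **not** show: real recall data have
reporting error, seasonal and weekday structure, frequency–amount
correlation and covariate effects (age, sex) that the generator omits by
design; the recovery results certify the estimator under its own model
assumptions, not robustness to their violation.

## Numerical choices and degenerate inputs

* Quadrature: 21 Gauss–Hermite nodes; likelihood maximized by Nelder–Mead
  on $(\mu_q, \log\sigma_q)$ with a moment-based start.
* All-zero intake → explicit error; one recall day for everyone →
  explicit error ($\sigma_w$ unidentifiable); no within-person variation
  → $\hat\sigma_w = 0$ and the usual distribution equals the person-mean
  distribution; negative variance estimates truncate at zero.
* Monte-Carlo sizes: $10^5$ draws for reported distributions, smaller
  (4000–10000) inside bootstrap replicates where only the replicate
  spread matters; `n_mc < 1000` warns. Test-suite simulations use
  n = 1000–5000 individuals and 50 outer replications for bootstrap
  coverage — sizes at which the Monte-Carlo error sits comfortably inside
  the asserted bounds.
* Contributor ties break lexicographically by food path; weekly/monthly
  guidance values convert with week = 7 and month = 30 days (30 reproduces
  the conventionally quoted 25/30 = 0.83); daily values are reported
  rounded half-away-from-zero to 2 decimals with full precision retained.

## Risk characterization

Guidance values live in a versioned YAML registry
(`health_references()`): adequate intake and upper level for iodine,
safe-and-adequate intake for sodium, (provisional) tolerable weekly or
monthly intakes for cadmium and mercury, and BMDL reference points for
inorganic arsenic and lead. Characterization follows the conventions of
the assessment this package operationalizes:

* **Most conservative reference.** When several authorities cover one
  substance, classification uses the lowest daily value (for a BMDL
  range, its lower bound).
* **Precautionary speciation** (default on, switchable): total mercury is
  compared against the methyl-mercury PTWI and total arsenic against the
  inorganic-arsenic reference points.
* **Traffic light.** Red when the population mean breaches the reference
  (or, for adequate-intake references, when the median falls below);
  orange ("at risk") when the mean complies but P95 breaches; green
  otherwise. The orange rule formalizes the verbal "at risk of exceeding"
  convention of such tables; the original rule is not published, so this
  is a documented interpretation.
* **MoE.** BMDL divided by exposure, a pair of values for BMDL ranges;
  exceedance fractions are weighted tail probabilities of the usual
  distribution with bootstrap-replicate bounds.

## Known limitations

* The LNN variant with nonzero frequency–amount correlation is not
  implemented, nor is covariate adjustment; designs are validated at 2
  recall days (the code accepts any D ≥ 2).
* Speciation is handled only through precautionary reference mapping —
  there is no model converting total arsenic or mercury into their toxic
  species.
* Hierarchy aggregation averages indexed entries without consumption or
  sample-size weighting.
* The moment estimator of $\sigma_b^2$ can truncate at zero in small
  samples, which propagates a point-mass-like usual distribution; the
  bootstrap makes this visible as a degenerate lower CI.
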