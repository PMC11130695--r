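---
title: "Methods: trend analysis of grocery purchases across income-adequacy levels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trend analysis of grocery purchases across income-adequacy levels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baskettrend)
```

## The scientific question

Households differ in how well their disposable money covers their
needs. Perceived income adequacy (PIA) is a five-level ordinal
self-assessment of that margin (1 = "must compromise on almost
everything" to 5 = "get along very well"; a sixth level records a
declined answer). `baskettrend` asks how grocery purchasing varies
across PIA levels, using loyalty-card transaction data: do households
with a larger margin pay more per kilogram within the same food group,
and do they allocate their energy and money across the 17 food groups
differently?

The package operationalises this as, per food group, five outcome
variables at the participant level:

* **E%** and **EX%** — the group's share of the participant's total
  purchased energy and total expenditure (percent; they sum to 100
  across groups within a participant);
* **€/kg** and **€/MJ** — group expenditure divided by group volume or
  group energy (undefined for participants who never bought the group);
* **NRFI** — a volume-weighted nutrient-density score of the
  participant's purchases in the group (below).

Each outcome is summarised as the median per (group, PIA level) cell —
purchase variables are strongly right-skewed, so means would be
dominated by heavy buyers — and tested for a monotone trend across
levels.

## Trend testing

The core test is the two-sided Jonckheere–Terpstra (JT) statistic for
ordered alternatives. For observations grouped by ordered labels,

$$U = \sum_{\ell < \ell'} \sum_{a \in \ell,\; b \in \ell'}
      k(x_a, x_b), \qquad
  k(x_a,x_b) = \begin{cases} 1 & x_a < x_b \\ 0.5 & x_a = x_b \\ 0 &
  x_a > x_b. \end{cases}$$

With unit weights the package uses the closed-form null mean
$(N^2 - \sum_i n_i^2)/4$ and the standard tie-corrected null variance,
and a normal approximation for the two-sided p-value. For total
$n \le 9$ an exact route enumerates every label assignment. $U$ depends
on the data only through ranks, so it is invariant under strictly
increasing transforms — convenient for prices spanning orders of
magnitude.

### Confounding and inverse-probability weighting

PIA is not randomised: education and sex predict both PIA and
purchasing. The package therefore estimates
$\hat p(\text{PIA} = \ell \mid \text{education}, \text{sex})$ with a
multinomial propensity model — by default the saturated
cell-proportion estimate over the 8 education-by-sex strata, with an
additive multinomial logit as an option — and weights each participant
by $1/\hat p$ (optionally stabilised by the marginal level
probabilities). The weighted statistic replaces each pair's kernel
contribution with $w_a w_b\, k(x_a, x_b)$.

The weighted statistic's null distribution is obtained by seeded
Monte-Carlo permutation (default 10,000 draws for a standalone test).
A design point deserves emphasis: **the permutation is carried out
within covariate strata**, shuffling (label, weight) pairs over the
observation slots of each stratum. Unrestricted label permutation is
not a valid null here — the weights and the outcome share the
confounder, so permuting labels over everyone destroys exactly the
dependence the weighting is meant to adjust for, and in our
calibration experiments it rejected a true conditional null roughly
40% of the time at the 5% level. Within-stratum permutation is the
exact conditional test of "no trend given education and sex": under
that null the outcomes within a stratum are exchangeable against the
stratum's fixed multiset of (label, weight) pairs. In a simulation
with education shifting both PIA and the outcome (and no direct PIA
effect), the within-stratum IPW test's empirical size was 0.049 over
1,000 replicates, while the unweighted test rejected essentially
always. The add-one Monte-Carlo correction $(r+1)/(n_\text{perm}+1)$
keeps reported p-values valid.

The two-sided permutation p-value uses the tail of
$|U - \overline{U^*}|$; the permutation mean is the appropriate centre
because with unequal weights the closed-form unweighted moments no
longer apply.

### Multiplicity, effect size, and correlations

Tests are corrected by the Benjamini–Hochberg step-up procedure at a
5% false discovery rate (via `stats::p.adjust`), by default one family
per outcome column (17 groups per family), mirroring how a
groups-by-outcomes result table is read column-wise; a pooled family
is available by configuration.

Because with tens of thousands of participants nearly everything is
"significant", each (group, outcome) also gets a descriptive effect
size: with $m_{g\ell}$ the median of the outcome in group $g$ at level
$\ell$,

$$\mathrm{ES}_g = 100 \times
  \frac{\sum_\ell (m_{g\ell} - \bar m_{g\cdot})^2}
       {\sum_{g,\ell} (m_{g\ell} - \bar m)^2} \; \%$$

— the share of the total variability of all cell medians that sits
within group $g$ across PIA levels. The printed description of this
quantity ("intragroup variance of medians relative to overall
variability") admits several normalisations; the sum-of-squares ratio
is the one implemented, chosen because the group-wise values then sum
to at most 100 and are directly comparable across groups. When every
cell median is identical the ratio is 0/0 and the effect size is
reported missing rather than zero.

Price structure is summarised by Spearman correlations of €/kg versus
€/MJ: within each group over participants, and across groups over the
17 (median €/kg, median €/MJ) pairs. The two can disagree
substantially — within a group the two prices share the numerator and
correlate strongly, while across groups energy density varies by an
order of magnitude and decouples them.

## The nutrient-density score

The NRFI per 100 g of an item uses 8 qualifying nutrients (protein,
fiber, polyunsaturated fatty acids, calcium, iron, vitamin D,
vitamin C, folate) and 3 disqualifying ones (saturated fatty acids,
saccharose, salt):

$$\mathrm{NRFI} = \sum_{i \in \text{pos}}
  \min\!\left(\frac{x_i}{RV_i}, 1\right) \times 100
  \;-\; \sum_{j \in \text{neg}} \frac{x_j}{RV_j} \times 100.$$

Qualifying contributions are capped at 100% of the daily reference
value $RV$ (so the positive subscore is at most 800), disqualifying
ones are uncapped; the score may be negative. The shipped reference
table fixes salt at the Finnish recommendation of 5 g/day; the other
ten values are *illustrative* round numbers in the range of Nordic
recommendations, kept in a configurable table because scoring is only
meaningful relative to an authoritative reference set.

A participant's group-level NRFI aggregates item scores weighted by
purchased volume. Both the volume-weighted *sum* and the
volume-weighted *mean* are computed (`nrfi_volume_sum` and `nrfi`);
the pipeline compares PIA levels on the weighted mean, which stays on
the per-100-g scale and is insensitive to how much a participant
bought in total — the weighted sum mixes nutrient density with
purchase volume, which E% and EX% already measure. A group basket with
zero recorded volume has no defined score and is reported missing.

## Cohort definition and aggregation rules

Participants enter the analysis when (i) their self-estimated degree
of loyalty — the share of their grocery purchases made at the study
retailer — is at least 41%, (ii) their recorded annual expenditure is
at least 100 €, and (iii) they answered the PIA question
substantively (levels 1–5). Both numeric bounds are inclusive: the
exclusions are "below 41%" and "below 100 €". Each excluded
participant is logged with the first rule that removed them.

Food groups with only marginal purchases are dropped: a group whose
population-wide share of expenditure is below 1% *or* whose share of
energy is below 0.2% is excluded (both thresholds configurable).

Two aggregation decisions matter for interpretation:

* A participant with no purchases in a group has a true share of 0 for
  E% and EX%, but *no* price or NRFI — those medians run over
  purchasers only. Imputing a price for a non-purchase would
  manufacture data.
* Even-sized median cells use the midpoint convention.

Equivalised household income is the category midpoint divided by
$\sqrt{\text{household size}}$ (OECD square-root scale). The lowest,
open-ended income category ("under 1500 €/month") is assigned a
midpoint of 750 €, the top category 1.25 times its lower bound
(11,250 €); interior midpoints follow a plausible category grid. All
midpoints are a configurable table, because the exact category bounds
of a given questionnaire vary.

## The synthetic cohort

Real loyalty-card data are proprietary, so the package ships a
generator whose outputs have the same schema and the statistical
structure the pipeline must handle, with known ground truth:

* **Confounded ordinal PIA.** Education (4 levels) and sex are drawn
  first; PIA is drawn per (education, sex) stratum from a configurable
  row-stochastic matrix. The default shifts PIA upward with education
  and slightly with male sex. 5% of participants are assigned level 6
  (declined); their purchasing follows a hidden uniform draw from
  levels 1–5, so the inclusion filter has genuine work to do.
* **Price gradients.** Within a group with gradient $g$, the expected
  unit price paid at PIA level $\ell$ is
  $\text{base price} \times g^{\ell-1}$ (marginally over the group's
  items). Prices are lognormal around that location (σ = 0.25 on the
  log scale), hence positive and right-skewed — the very skewness that
  motivates median summaries. The default gradient is 1.05 per level
  in every group except potatoes (1.00), encoding the study condition
  that price trends are positive nearly everywhere with a plausible
  exception.
* **Volume gradients.** A group's expected volume share shifts
  additively per PIA level (then renormalised): positive defaults for
  vegetables, fruits and fish; negative for snacks, sweets,
  sugar-sweetened beverages, bakery, grain-based foods, potatoes and
  alcohol; the remainder near zero.
* **Scale.** The default cohort has 1,000 participants averaging
  1,600 € of annual purchases spread over Poisson-many single-item
  lines (about 2.5 € per line); 3% of participants are "light users"
  whose spending is scaled down ~30-fold so the 100 € filter removes
  someone. Loyalty is Beta-distributed over [0, 100]% with roughly a
  sixth of the mass below 41%.
* **Catalog.** 5 items per group; energy density uniform over a
  per-group interval; nutrient composition varying ±30% around
  illustrative per-group means; an item-level price multiplier
  (mean 1) spreads prices within a group.

Everything is a pure function of the configuration and its seed —
identical inputs give byte-identical tables. Timestamps are uniform
over the study year; no seasonality, store choice, discounts or
multi-card households are modelled (no downstream stage consumes
them). Consequently, passing tests demonstrate that the *pipeline*
recovers known gradients under realistic skew, confounding and
missingness — not that real purchase data satisfy the generator's
independence assumptions.

## Numerical and operational choices

* The JT permutation core is compiled; one statistic evaluation is
  $O(n \log n)$ for the initial sort and $O(nk)$ per permutation, so
  2,000 permutations at $n = 1000$ cost tens of milliseconds.
* The full pipeline (`run_pipeline()`) defaults to 2,000 permutations
  per weighted test — with 17 groups × 5 outcomes this keeps a
  complete run on the default cohort under half a minute while the
  Monte-Carlo standard error of a p-value near 0.05 stays below 0.005.
  Standalone `jt_test()` defaults to 10,000.
* Simulation-based checks in the test suite use 2,000 replicates for
  size calibration (5 groups × 50 observations per replicate; the
  confounded scenario uses 400 participants per replicate) and 100
  seeded runs of 2,500 participants for gradient recovery — sizes at
  which binomial noise on an empirical rejection rate is ~0.005.
* Saturated propensity cells can be empty in small strata; a warning
  is raised and a 0.5 pseudo-count is added to the affected stratum's
  cells (configurable) so weights stay finite.
* Ties in outcomes use the 0.5 kernel and the tie-corrected closed-form
  variance; a fully degenerate outcome (all values equal) yields
  $z = 0$, not a failure.
* Every stochastic routine takes an explicit seed; the pipeline
  derives one sub-seed per (group, outcome) test from the base seed so
  results are reproducible test-by-test.

## Known limitations

* The weighted permutation null conditions on education and sex only;
  unmeasured confounders (age, region, household composition) are out
  of scope, as they are for the weighting itself.
* The nutrient reference defaults are illustrative; substantive NRFI
  values require an authoritative reference table and a real
  composition database.
* The effect-size normalisation is one consistent reading of a
  verbally specified quantity; comparisons against other variance
  ratios should recompute from the median matrix, which is exported.
* The generator draws income category from PIA directly rather than
  from a joint socioeconomic model; the induced PIA–income rank
  correlation (~0.55 on defaults) is an emergent property, not a
  calibrated estimate.
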