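---
title: "Methods: the economics of welfare-friendly swine rearing"
author: "swinecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the economics of welfare-friendly swine rearing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swinecon)
```

## The problem

Most commercially reared piglets undergo surgical castration, tail docking
and teeth clipping in their first days of life. An alternative,
welfare-friendly management replaces surgical castration with anti-GnRH
immunocastration, avoids tail docking and teeth clipping, and provides
environmental enrichment. Measured against conventional rearing, this
management raises mean slaughter weight (97.1 kg to 103.4 kg), lowers
pre-slaughter mortality (14% to 5%) and reduces the odds of a pig being
weak or dead by roughly a factor 1.89.

`swinecon` turns those production contrasts into economics at two levels:

1. **Farm level** — annual profit of a fixed-price producer slaughtering
   12,000 pigs per year at $2.2/kg.
2. **Market level** — a partial-equilibrium model of the entire US pork
   market in which the per-kg cost saving shifts the supply curve, moving
   the equilibrium price and quantity and redistributing surplus between
   producers and consumers.

Every number the package reports is computed, at run time, from a small set
of published inputs; a synthetic herd generator reproduces the statistical
structure of the underlying cohort so that the full pipeline is testable
without any external data.

## The market model

Linear demand and supply curves are backed out from one observed
equilibrium $(P_0, Q_0)$ and point elasticities $\varepsilon_d < 0$,
$\varepsilon_s > 0$:

$$ Q_d = a_d + b_d P, \qquad b_d = \varepsilon_d \frac{Q_0}{P_0}, \qquad
   a_d = Q_0 - b_d P_0 $$

and symmetrically for supply. Both curves pass through the observation by
construction. A per-kg marginal-cost saving $\Delta C$ moves the *inverse*
supply curve down by $\Delta C$, i.e. the quantity-form intercept up by
$b_s \Delta C$ (a parallel shift). Solving the shifted system gives the new
equilibrium; for linear curves the price change has the closed form

$$ \Delta P = -\Delta C \cdot
   \frac{\varepsilon_s}{\varepsilon_s + |\varepsilon_d|}, $$

the *pass-through rate*, which the package exposes separately
(`pass_through()`) and uses as an independent oracle on the solver in the
test suite.

Surplus accounting under linear demand is exact:

* consumer-surplus change: trapezoid $-\Delta P (Q_0 + Q_1)/2$;
* consumer-surplus level: triangle to the choke price,
  $(\text{choke} - P) Q / 2$;
* producer-surplus change: the sector profit difference **excluding common
  costs**, $(P_1 - c_1) Q_1 - (P_0 - c_0) Q_0$, the accounting convention
  of the source analysis. The geometric alternative (area above the supply
  curve, $(\Delta C + \Delta P)(Q_0 + Q_1)/2$) is available via
  `ps_method = "geometric"`; the two differ because the profit convention
  nets out unit costs rather than the supply curve.

Total welfare change is defined as $\Delta W = \Delta CS + \Delta PS$ and
holds exactly by construction.

### Parameters, units, defaults

| parameter | default | units | why |
|---|---|---|---|
| $Q_0$ | 9,463.032 | million kg/yr | published US pork quantity |
| $P_0$ | 2.2026 | $/kg | reconstructed baseline price (below) |
| $\varepsilon_d$ | −1.078 | — | literature average, US pork demand |
| $\varepsilon_s$ | 0.417 | — | literature average, US pork supply |
| $c_0$ | 0.2045 | $/kg | published conventional production cost |
| $\Delta C$ | 0.1375 | $/kg | published per-kg cost saving |

Internal units are canonical throughout: quantity in million kg (equal to
thousand tonnes), price and cost in \$/kg, money in million \$. The printed
source equations express quantity in 1,000 t and price in \$ per 1,000 t;
`print.linear_curve()` performs that display conversion (slope divided by
$10^6$) but no computation ever uses the display units.

**Baseline price.** The source text quotes "\$2.2 per kg" while its
equilibrium table prints 2.203 and profit rows consistent with a slightly
higher baseline. The default $P_0 = 2.2026$ is a reconstruction chosen so
that the published equilibrium tables reproduce; it is accepted as an
ordinary config value, and passing 2.2 changes headline results by less
than 0.15%.

**Elasticity grid.** The sensitivity analysis sweeps demand
$\{-0.5, -1.078, -2.75\}$ against supply $\{0.2, 0.417, 0.6\}$ (literature
minimum / average / maximum). We use the *unrounded* averages in every
"average" row and column: recomputing all 27 published grid cells shows
they are consistent with −1.078/0.417 (e.g. the consumer-surplus cell at
demand −2.75, average supply prints 0.1732 billion, which matches 0.417
exactly and is 0.6% off with 0.42). Grids are reported with rows = demand
elasticity and columns = supply elasticity, the orientation consistent with
all published cells.

## The cost model

Two modes:

* **headline** (default): per-kg production costs are the published figures
  0.2045 (conventional) and 0.0670 (welfare-friendly) \$/kg, a saving of
  0.1375 \$/kg.
* **itemized**: per-head costs built from labor (2 h per 32 head
  conventional vs 1 h per 180 head welfare-friendly, wage back-solved from
  the published \$1.65/head saving), materials (\$0.5617/head for pain
  relief and surgical equipment, conventional only), the anti-GnRH vaccine
  (\$1.6648 per male, averaged over the male fraction), and the
  extra-raising cost — mortality rate × \$120 average rearing cost, the
  expected cost of rearing replacements for pigs lost before slaughter.

Headline is the default because the itemized reconstruction from the
published per-head components yields ≈0.197/0.068 \$/kg (shift ≈0.130),
about 3% below the printed per-kg values; the full cost breakdown behind
the printed figures is in a supplementary table that is not recoverable
from the main text. The itemized mode is retained for sensitivity analysis,
and the extra-raising formula is implemented exactly as stated (rate × cost,
not rate/(1 − rate) × cost). Euro-denominated analgesic prices are subsumed
in the aggregate materials figure; enrichment hardware carries zero cost by
default, mirroring the source accounting, with a config hook
(`enrichment_per_head`) to add it.

## The synthetic herd

`generate_herd()` emulates the study cohort: four treatment groups of 8
litters each, litter sizes uniform on 9–13, sexes Bernoulli(0.5). Groups
1–2 are mapped to the conventional regime and groups 3–4 to
welfare-friendly — the source defines its two economic arms only as
"conventional" vs "welfare-friendly", and this pooled mapping matches how
its headline weight means are reported. Per regime, survivor slaughter
weights are normal with the study means and with standard deviations
back-derived from the printed 95% confidence intervals via
`sd_from_ci()` — half-width / 1.96 × √n with n = 75 (conventional) and
n = 77 (welfare-friendly); which arm had which n is not stated in the
source, so both are overridable. Mortality is Bernoulli (14% / 5%), dead
pigs carry `NA` slaughter weight (never zero), and the composite
weak-or-dead flag is generated from per-regime odds (defaults 0.21 vs 1/9,
ratio 1.89) with dead pigs always flagged, so summary stages must handle
missingness explicitly.

Choices the source does not pin down:

* **Weaning weights** (7.0 / 11.1 kg, sd 1.5 kg) are chosen values
  consistent with the reported +4.1 kg contrast; nothing downstream
  consumes them.
* **Welfare-friendly weak-or-dead probability** (0.10, hence odds 1/9) is a
  chosen baseline; the source prints only the odds *ratio*.
* **Litter effect**: weights are independent across litter mates by
  default. The source fits litter (dam) random effects but reports no
  variance component, so an optional shared normal litter effect is
  available (`litter_effect_fraction`, the fraction of total weight
  variance between litters, default 0) with the marginal variance held
  fixed.

RNG: each group draws from its own stream derived from the root seed, so
identical (config, seed) is byte-reproducible and appending a group never
perturbs earlier groups' records.

What a green test establishes: that the *stated* generative world (normal
weights, independent Bernoulli deaths, the configured odds) is recovered
and correctly propagated. Real production data have litter and pen
correlation, seasonal effects and non-normal tails that this generator does
not emulate.

## The bootstrap

The source procedure is an *empirical (basic) bootstrap on deviations*: one
million pairs of normal slaughter-weight samples (sizes 75 and 77, the
original sample sizes) are drawn; each pair's sample means feed the outcome
functions; per outcome, the 5th and 95th percentiles of (simulated − point)
are added to the point estimate. `bootstrap_outcomes()` implements exactly
that, with the percentile pair configurable. Two documented quirks:

* 5/95 percentiles give a **90%** central interval although the source
  labels its intervals 95% CIs, and its printed weight CIs are consistent
  with ±1.96 se. Passing `lower_percentile = 2.5, upper_percentile = 97.5`
  reproduces the printed-table convention. Because of this ambiguity the
  test suite validates the bootstrap against the analytic normal oracle for
  a linear outcome (half-width $z \sqrt{s_1^2/n_1 + s_2^2/n_2}$), not
  against the printed intervals.
* Only slaughter weights are resampled; costs per kg and mortality are held
  fixed, as the source's degenerate conventional-cost interval confirms.

Replicates with non-finite outcomes are excluded with a message; more than
1% exclusions aborts. The default `n_reps` is the published $10^6$; the
test suite and pipeline default use $10^5$, which changes the interval
endpoints by under 0.2% while keeping runtimes in seconds.

## Numerical choices and degenerate inputs

* Equilibrium existence requires the supply slope to exceed the demand
  slope; parallel or sign-crossed curves raise an error rather than return
  nonsense.
* The solver cross-checks that both curves agree on the equilibrium
  quantity to $10^{-9}$ relative.
* `consumer_surplus_level()` refuses prices at or above the choke price.
* Negative profit margins in the producer-surplus accounting warn but still
  compute, since a sensitivity sweep may legitimately cross zero.
* Zero-width cost shifts propagate to an exactly-zero policy comparison.
* `odds_ratio()` applies the Haldane–Anscombe 0.5 correction only when a
  cell is zero; a fully empty arm raises.
* Weight summaries use the normal 1.96 multiplier, not Student-t, because
  the source intervals are consistent with 1.96 · se.

## Known limitations

* The farm model is single-year and fixed-price: no transition costs,
  discounting, or multi-year dynamics.
* The market model is linear and closed: no export demand,
  willingness-to-pay premia, or isoelastic alternatives.
* "Common costs" (feed, housing) are excluded throughout, so profit levels
  are margins over the modelled costs only; differences between regimes are
  unaffected.
* The itemized cost mode under-shoots the published per-kg figures by ≈3%
  (unrecoverable supplementary breakdown); headline mode is authoritative
  for reproduction.

## A worked run

```{r headline}
pc <- policy_comparison()
pc
```

```{r grid}
g <- sensitivity_grid()
round(attr(g, "summary") / 1000, 4)  # billion $US
```

```{r farm}
costs <- cost_config()
compare_farm(
  farm_outcome(farm_scenario(12000, 97.1, 2.2,
                             per_kg_cost("conventional", costs))),
  farm_outcome(farm_scenario(12000, 103.4, 2.2,
                             per_kg_cost("welfare_friendly", costs))))
```

```{r bootstrap}
b <- bootstrap_outcomes(bootstrap_spec(n_reps = 1e4, seed = 1),
                        farm_outcome_fn(), vectorized = TRUE)
b
```
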