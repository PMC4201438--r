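---
title: "Simulating mangrove stand recovery from expert-scored impacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating mangrove stand recovery from expert-scored impacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mangrovesim)
```

## The model

`mangrovesim` couples two things that are usually kept apart: an
individual-based simulator of a single-species *Rhizophora apiculata* stand,
and the arithmetic used to aggregate expert-elicitation (Delphi) surveys.
The link between them is the impact scenario: experts score each disturbance
type by an intensity $I \in [0,1]$ and a spatial scale $S \in [0,1]$, and
those two numbers fully parameterize a disturbance–recovery experiment in
the simulator.

### Trees, fields of neighborhood, and competition

Each tree is a stem with a position, a diameter at breast height $D$ (cm), an
age, and a five-slot memory of its recent relative growth. Around every stem
lies its *field of neighborhood* (FON): a disc of radius

$$R_{FON} = a\, r_{stem}^{\,b}, \qquad r_{stem} = D/200 \;\text{(m)},$$

on which the tree exerts a competitive intensity: 1 on the stem disc itself,
decaying exponentially to `fon_min` at $R_{FON}$, zero beyond. The
competition index of a focal tree is the mean over its own FON disc of the
summed intensities of all neighbours,

$$F_i = \frac{1}{A_i}\int_{FON_i} \sum_{j \ne i} f_j(x)\, dx,$$

so $F = 0$ for an isolated tree, and $F$ near or above 1 under a closed
canopy. Growth is multiplied by $\max(0,\, 1 - cF)$ with slope $c$
(`comp_slope`).

### Growth, memory, mortality, recruitment

Diameter growth follows the classical forest-gap-model (JABOWA-family)
kernel

$$\Delta D = \frac{g\,D\,\bigl(1 - D H / (D_{max} H_{max})\bigr)}
  {274 + 3 b_2 D - 4 b_3 D^2}\;\max(0, 1 - cF)\; z,$$

with the parabolic height allometry $H = 137 + b_2 D - b_3 D^2$ anchored at
breast height (137 cm) and at $H(D_{max}) = H_{max} = 50$ m, and $z$ the
impact-zone growth factor. Without competition, iterating $\Delta D$ traces
a sigmoid that converges to $D_{max}$ — one of the package's property tests.

Each year's relative increment $\Delta D / D$ is pushed into the tree's
five-year memory. A tree whose five-year mean falls below
`suppression_threshold` is *suppressed* and dies with probability
`p_die_suppressed` per year. This single mechanism produces both
density-dependent self-thinning and the death of senescent trees (whose
increments vanish as $D \to D_{max}$); saplings carry no memory for their
first five years and are safe from it, so briefly suppressed juveniles can
be released by a neighbour's death, as in the KiWi family of models. An
optional hard `max_age` cap is available as an old-forest correction but is
disabled by default — senescence already emerges from the growth-memory
mechanism.

Seed dispersal is random: candidate saplings arrive as a Poisson process at
390 seedlings ha⁻¹ yr⁻¹ over the whole domain, and each establishes with
probability $\max(0,\, 1 - \sum_j f_j)$ at its landing point — a closed
canopy admits nothing, gaps recruit freely. Establishment enters at
`recruit_dbh` = 1 cm.

The annual update order is: competition → growth → memory → mortality →
recruitment → ageing. Everything is deterministic given the RNG seed.

### Domain and census

The domain is 120 × 120 m; all summaries (density, basal area
$\sum \pi (D/200)^2$, biomass $\sum s D^t / 1000$) are taken on the inner
100 × 100 m hectare, so the 10 m band buffers edge effects. Summaries
census stems with $D \ge 5$ cm (`min_dbh`): the reference densities the
model is calibrated against count established trees, and the transient
sapling bank — hundreds of 1–4 cm stems waiting in gaps — would otherwise
dominate the stem count while contributing almost nothing to basal area or
biomass.

## Parameters and calibration

The literature on this system prints only a handful of constants: maximum
height 50 m, recruitment 390 ha⁻¹ yr⁻¹, and a reference stand of 1344
trees ha⁻¹ carrying 31.89 m² ha⁻¹ of basal area with a healthy-forest
standing biomass of ~375 t ha⁻¹ (300–400 t ha⁻¹ band). Everything else —
FON scaling, growth constant, competition slope, suppression threshold — is
a calibration surface. The biomass allometry $B = s D^t$ uses the exponent
2.42 typical of *R. apiculata* and a coefficient fixed so the reference
stand's mean diameter (17.4 cm, implied by basal area over density) carries
223 kg, i.e. 1344 stems ≈ 300 t ha⁻¹.

`calibrate()` performs a cyclic coordinate search over any named subset of
parameters, scoring each candidate by the summed squared relative error of
the year-300 (density, basal area, biomass) against those anchors, averaged
over seeds. The shipped defaults are the outcome of that procedure:

| parameter | default | meaning |
|---|---|---|
| `d_max` | 70 cm | maximum diameter |
| `h_max` | 5000 cm | maximum height |
| `g_growth` | 275 | growth constant (cm-scale) |
| `fon_a`, `fon_b` | 10, 0.5 | FON radius scaling (m) |
| `fon_min` | 0.1 | FON boundary intensity |
| `comp_slope` | 1 | growth reduction slope in $F$ |
| `allom_s`, `allom_t` | 0.222, 2.42 | biomass allometry (kg, cm) |
| `suppression_threshold` | 0.003 yr⁻¹ | 5-yr mean relative increment below which a tree is suppressed |
| `p_die_suppressed` | 0.3 yr⁻¹ | annual death probability while suppressed |
| `recruit_dbh` | 1 cm | sapling entry diameter |
| `resolution` | 0.25 m | FON quadrature grid |

Two of these deserve comment. `comp_slope` = 1 (not the steeper 2 one might
first write down): at the reference density the canopy competition index
sits near 0.9, and a slope of 2 would shut growth down entirely, driving
the equilibrium far below the anchors; the calibration prefers the gentler
slope. And `suppression_threshold` is the sharpest lever on equilibrium
density — moving it from 0.002 to 0.004 swings the stem count by several
hundred per hectare. Under the shipped defaults the 300-year equilibrium
sits at roughly 1530–1570 stems ha⁻¹ (+15% of the anchor), 33–35 m² ha⁻¹
(+7%), and 350–380 t ha⁻¹ of biomass — inside the healthy band, with the
density bias accepted as the price of hitting basal area and biomass
simultaneously under a one-parameter-per-process demography.

From a bare domain the stand takes ~130 years to first reach 300 t ha⁻¹,
overshoots while the founding cohort matures, and relaxes into the band
with a slowly damping cohort oscillation — the reason control runs are
checked on their across-seed median rather than per-seed extremes.

## Impact scenarios

An impact clears a strip covering fraction $S$ of the sample hectare
(extended through the edge band at the same x-range) in a single killing
event, and installs regrowth reduction factors inside that strip. The
published scenario table reduces recruitment, density and growth by the
factor $1 - I(1 - S)$; this is the default `literal` mode. Read literally,
that factor *weakens* as $S$ grows — at odds with the same table clearing
the whole scaled zone — and the wording leaves open whether "$(1-S)$" was
meant as "$\times S$". Rather than guess, the package exposes a second
`zone_intensity` mode ($1 - I$ inside the zone, independent of $S$) behind
a switch, defaults to the printed formula, and reports the mode in every
result object. A `thin` killing mode (reduce zone density by the literal
factor instead of clearing) is likewise available behind an argument.

`recovery_time()` runs the annual update until the sample biomass re-enters
the 300–400 t ha⁻¹ band, declared at the band's *lower edge* — the halting
rule is a band, not a point, and the first credible "recovered" claim is
its boundary. Runs that do not recover within `max_years` (default 200)
return a censored flag rather than an error; censored replicates enter
scenario medians at the horizon, flagged. `run_scenario()` replays one
shared spinup snapshot under replicate-specific seeds — sharing the
snapshot isolates impact-response variance from spinup variance and is the
cheaper design; per-replicate spinups are a one-line change (`spinup()`
inside your own replicate loop) if the conflation matters for a question.

## Delphi aggregation

The survey arithmetic is deliberately plain and fully tabular:

- `weighted_likert_scores()`: level $k$ carries weight $k$; an option's
  score is $\sum_k k\, n_k$, expressed as a percentage. "Percentage scale"
  is ambiguous in the source; the default normalizes by the maximum
  attainable score ($5 \times$ votes), so 100% = unanimous top rating and
  the attainable floor is 20%. A `share` normalization (score over summed
  scores) is available via argument. Ties share a rank, sort
  alphabetically, and are flagged — never silently broken.
- `consensus_list()`: strict majority — strictly more than 50% of votes;
  an item at exactly the threshold is excluded.
- `plurality_choice()`: argmax with explicit tie and empty-poll reporting.
- `aggregate_timeframes()`: the four recovery bins (0–10, 10–20, 20–30,
  >30 years) collapse at the 20-year line into short/long term, stratified
  by the HD/LD development level of the country each expert reported on
  (2011 Human Development Index classes; "very high"+"high" = HD,
  "medium"+"low" = LD). The mapping ships as an editable CSV.

## Synthetic data

The raw survey responses and the elicited per-impact $(I, S)$ scores were
never deposited, so the generators emulate their *structure*, not their
values:

- `gen_vote_table()` draws each vote level as
  $\min(5, \max(1, \lceil 5\,\sigma(\lambda (q - 1/2) + \varepsilon)\rceil))$
  with option quality $q \sim U(0,1)$, strength $\lambda$, and standard
  logistic noise $\varepsilon$. The quantile (ceiling) form makes
  $\lambda = 0$ exactly uniform over levels — the property the tests check —
  while positive $\lambda$ shifts an option's modal level with its quality.
- `gen_impact_set()` scatters $(I, S)$ pairs on $[0.2, 0.9]^2$ (experts
  rarely score a listed impact as negligible or total) and can force the
  `development` impact to the componentwise maximum, mirroring its elicited
  dominance.
- `gen_timeframe_responses()` draws bins from given probabilities and
  countries from the bundled roster.
- `gen_fixture_stand()` builds Poisson-scattered stands with
  truncated-normal diameters for unit tests.

A green test on synthetic data establishes that the pipeline's arithmetic
and orderings behave as specified — not that the real experts' scores would
reproduce any particular published figure. Real response data would add
inter-expert correlation, country clustering, and non-logistic vote shapes
that these generators deliberately omit.

## Numerical choices

- FON integrals use a square grid of spacing ≤ 0.25 m clipped to the focal
  disc; a brute-force 0.02 m integrator in the test suite pins the error
  below 1% on small configurations. During the annual update the quadrature
  stops early once $F$ provably exceeds $1/c$ — growth is zero there
  regardless — which roughly halves runtime in closed canopy without
  changing any trajectory.
- The quadrature grid is anchored at the focal tree, so indices are exactly
  symmetric for identical tree pairs.
- Tree diameters are capped at `d_max`; increments are nonnegative.
- Growth memories of new saplings are `NA`-filled and excluded from the
  suppression test until five increments exist.
- All stochastic steps draw from R's global RNG; every pipeline function is
  a pure function of (inputs, seed). Generator seeds are plain integers.

## Limitations

- Single species, flat environment: no salinity, inundation, or climate
  forcing, and no multi-species interactions — the simulated system is a
  homogeneous *R. apiculata* stand, which is what the impact-recovery
  question was posed for.
- Recovery is biomass recovery. Functional recovery (the quantity experts
  were actually asked about) is proxied by standing biomass re-entering the
  healthy band.
- The equilibrium carries a slowly damping cohort oscillation inherited
  from bare-domain initialization; analyses sensitive to it should average
  over seeds, as the shipped tests do.
- The elicited per-impact $(I, S)$ values are not public; only the
  top-of-scale development scenario (0.8, 0.8) has a published recovery
  claim to compare against, and the other nine impacts can only be studied
  on synthetic score sets.
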