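---
title: "Energetics-based honeybee foraging and exposure dilution: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energetics-based honeybee foraging and exposure dilution: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beescape)
```

## The model in brief

`beescape` simulates a single day of honeybee nectar foraging in a landscape
of discrete resource patches, and converts the outcome into a pesticide
exposure estimate at the hive entrance. The colony is a central-place
forager: each trip flies to a patch, fills the crop to capacity, and returns.
Patch choice is governed by **net energetic efficiency** (NEE), the net
energy gain of a trip divided by its energy cost — the currency that
experimental and modelling work on honeybee foraging most consistently
supports. In-hive colony dynamics, pollen foraging and individual flight
paths are deliberately out of scope: the model is built to be applied over
thousands of candidate hive sites on landscape-scale data.

## Per-trip energetics

Within a patch, flowers are visited according to a Holling type-II
functional response,

$$f = \frac{aF}{1 + ahF},$$

with attack rate $a$ (m² s⁻¹), handling time $h$ (s) and open-flower
density $F$ (m⁻²). A full load of $\gamma$ mg takes $t_L = \gamma/(fg)$
seconds, where $g$ is the nectar obtained per flower. Trip duration adds the
round-trip flight $2D/v$. Energy expenditure has a field part and a travel
part,

$$EE = \frac{\gamma e_F}{gaF} + \frac{2D}{v}e_F,$$

where the handling time cancels from the field term because sitting on a
flower is taken as energetically free (it is roughly an order of magnitude
cheaper than flight). Intake is always a full load, $EI = \gamma e_R$, with
$e_R$ the energy density of the nectar (sugar share × 17.2 J mg⁻¹). Then

$$NEE = \frac{EI - EE}{EE}, \qquad \frac{EI}{EE} = NEE + 1 .$$

Setting the energy balance to zero gives the **threshold distance**

$$D_T = \frac{v\gamma}{2}\left[\frac{e_R}{e_F} - \frac{1}{gaF}\right],$$

beyond which a patch cannot be exploited. In the mass-flowering limit
($F \to \infty$) this simplifies to $D_T \approx [\gamma v/(2e_F)]\,e_R$:
linear in nectar energy density with a slope made of honeybee constants
only. On the return flight the bee consumes $E_c = e_L D/v$ joules of its
load, so only $\gamma - E_c/e_R$ mg of nectar reaches the hive.

All rates are per second; the simulation layer converts to hours. This keeps
every formula above dimensionally literal.

### The two flight-cost parameterizations

The tabulated unloaded/loaded flight costs (0.037/0.075 J s⁻¹) give a mean
flight cost $e_F = 0.056$ J s⁻¹ and threshold distances of 9.6 km (oilseed
rape) and 15.1 km (clover). Flight-cost estimates in the literature vary
considerably, and a slightly higher mean of $e_F = 0.066$ J s⁻¹ — within
that range — yields 8.1 and 12.7 km instead. Because both parameterizations
are in circulation and the choice only rescales absolute thresholds (never
the ranking of patches evaluated under a common $e_F$), both are exposed:
`bee_preset("default")` and `bee_preset("calibrated")`. For internal
consistency `travel_energy()` always uses the $2(D/v)e_F$ form, so a custom
$e_F$ propagates identically into $EE$, NEE and $D_T$; the return-flight
consumption keeps its own coefficient $e_L$ in both presets.

A property worth knowing when building scenarios: with the default
coefficients, clover has higher NEE than oilseed rape at any common distance
beyond ≈120 m, but *lower* NEE very close to the hive, where its more
expensive search (low $g \cdot a$ product) dominates and travel costs cannot
tip the balance. The package tests assert the ordering from 200 m outwards,
which is the range that matters for the mitigation scenarios.

## The foraging day

The day is simulated in `day_hours` (default 10) hourly steps. Each hour a
patch is *feasible* if its flowers are open (anthesis is binary), it lies
within `D_max` (default 2000 m, appropriate when sites border a large
resource patch), it was detected, flowers remain, and the energy balance is
positive. Detection defaults to perfect knowledge ($P = 1$ per patch); the
general detection law $P = 1-(1-\sigma)^s$ is implemented for per-patch
scout-encounter probabilities $\sigma$.

Each forager makes $b = \Delta t/(t_{trip} + t_{UD})$ trips per hour, kept
fractional: $b$ is a rate, and truncating it would create artificial
discontinuities. With $n$ foragers on a patch, $n(\gamma - E_c/e_R)b$ mg of
nectar and $n(\gamma e_R - E_c)/e_{SUGAR}\,b$ mg of sugar arrive per hour.

Flower densities update synchronously once per hour:

$$F_{t+1} = F_t - \frac{n\gamma}{gA}b - \frac{aF_t}{1+ahF_t}Z + r(F_0-F_t),$$

clamped to $[0, F_0]$: colony depletion (a full load visits exactly
$\gamma/g$ flowers), competitors at density $Z$ (default 0), and renewal of
a fraction $r$ (default 0) of spent flowers. Small patches therefore deplete
within hours and can force patch switches; large fields effectively never
deplete.

### SO model

All `n_foragers` (default 100, constant through the day) go to the patch
with maximum NEE. Ties are broken deterministically: smaller distance, then
lexicographic patch id. Note that ties between identical patches are
fragile by construction — after one hour the chosen patch is marginally
depleted and the argmax flips — so exact-tie behaviour is only observable on
a single decision or under full renewal.

### RL model

Recruitment through the waggle dance limits how fast the colony can
redirect effort, so several high-NEE patches are exploited at once. The
dynamics used here are a parameterized stand-in honouring that mechanism
(NEE translated into abandonment of poor patches and recruitment of
followers), with all three constants exposed in `sim_config()`:

1. **Abandonment.** Each employed forager on patch $i$ abandons with
   probability $\kappa_a (1 - NEE_i/NEE^*)$, where $NEE^*$ is the hour's
   maximum (so the best patch loses nobody); foragers on patches that have
   become infeasible abandon with probability 1. Default $\kappa_a = 0.3$.
2. **Recruitment.** A fraction $\rho$ (default 0.3) of the unemployed pool
   is recruited, distributed over feasible patches proportionally to dance
   strength $n_i \max(NEE_i, 0)$; unoccupied patches carry a floor weight
   $\varepsilon \max(NEE_i,0)$ (default $\varepsilon = 0.01$) so
   exploitation can start anywhere profitable.
3. Deliveries and depletion then proceed per patch with its $n_i$.

All foragers start unemployed (the day opens with a recruitment round), and
$\sum_i n_i + U = $ `n_foragers` holds every hour. By default the
transitions are expected-value (fractional) updates, which makes RL days
deterministic and reproducible; `stochastic = TRUE` switches to
binomial/multinomial draws of whole foragers. Because fractional allocations
put vanishing effort on many patches, the RL "number of exploited patches"
statistic is defined as the smallest set of patches accounting for 90% of
the day's sugar (`patches_for_sugar_fraction()`).

These forms are not a published recruitment model; they are a documented,
replaceable surface (any alternative with the same signature can be swapped
in) and results that depend on their constants should be read as
qualitative.

## Exposure and dilution

Patch $i$ carries a nectar concentration $C_i$ (µg mg⁻¹; treated fields get
the reference concentration $C_P$, others 0 in the scenarios). Daily
chemical influx is $\sum n_i \gamma b_i C_i$ if the chemical is not
metabolized with the consumed sugar (the whole load arrives — the
concentration is *enriched* en route), or
$\sum n_i(\gamma - E_{c,i}/e_{R,i})b_i C_i$ if it is. Dividing by the sugar
influx gives the sugar-based concentration $X_e$ or $X_m$, and dividing that
by the sugar-based reference $X_P = C_P\,e_{SUGAR}/e_R$ gives the
**dilution factor** $\varphi = X/X_P$: 1 means undiluted treated-field
exposure, 0 means no exposure; $\varphi_e$ can exceed 1. On a single-resource
landscape $\varphi$ is independent of $C_P$ and reduces to the
trip-weighted fraction of treated-field deliveries; with treatment
probability $p$ per field, mean $\varphi_m$ approximates $p$. A day that
collects no sugar at all has no defined concentration; the package returns
`NA` as an explicit marker rather than `NaN`, and such sites are tabulated
separately in assessments.

## Landscapes, hive sites and scenarios

A landscape is a table of polygonal patches (planar metric coordinates, no
CRS) in four categories: target fields, alternative fields, flower strips,
off-field elements. GeoJSON and CSV-with-WKT readers/writers are provided.
The synthetic generator emulates an arable region: rectangular target and
alternative fields (2–10 ha, grid-snapped, non-overlapping) and hundreds of
small elongated off-field elements, on a square extent (defaults: 50/20/500
patches on 5×5 km). It reproduces the *structure* that drives the model —
patch sizes, spacing and category mix — but not real-world features such as
irregular field shapes, road networks, spatial autocorrelation of crops or
regional anthesis calendars, so passing scenario tests demonstrate model
behaviour, not site-specific predictions.

Candidate hive sites are all 25 m grid cells that are not inside a target
field but 8-adjacent to one; a seeded 10% sample is used by default, and the
same seed yields the identical site subset for every scenario so that
comparisons are paired. Hive–patch distance is the Euclidean distance from
the cell centre to the nearest point of the patch polygon, floored at half a
grid cell: the adjacent field stays near-optimal without a zero-distance
singularity. The target field adjacent to a site is always treated — the
worst-case assumption under which dilution is measured.

The three mitigation scenarios:

* **Alternative fields** — every other target field is treated i.i.d.
  Bernoulli($p$); alternative-crop fields are never treated and their sugar
  content is scaled by 0.8–1.2 to span less-to-more attractive than the
  target crop.
* **Flower strips** — each target field gets up to 4 clover strips at its
  edges, each present with probability $p$, of length perimeter/4 and width
  $w \in \{1,2,5,10\}$ m. Strip area is subtracted from the host field
  (in-field, off-crop habitat) and conserved exactly; the strip polygon used
  for distance is the thin rectangle along the corresponding field side.
  All target fields are treated in this scenario.
* **Off-field habitats** — each off-field element is a clover patch with
  probability $p$, with flower density scaled 0.5/1/1.5 (low/medium/high
  quality); at quality 1 these patches are identical in resource terms to
  flower strips. All target fields are treated.

`run_assessment()` sweeps (scenario, $p$, variant) over sites ×
realizations (default 100) with seeds derived from a master seed by stable
integer hashing, so realization $k$ reuses the same seed at every $p$
(paired draws; treatment indicators are coupled monotonically in $p$, which
removes Monte-Carlo noise from grid comparisons). Summaries report the 10-,
50- and 90-percentiles of the per-site *mean* dilution factor — percentiles
over site means, not pooled site×realization values, which is the reading
adopted here of "average dilution for a site, summarized over sites" — using
the linearly interpolated empirical quantile (`type = 7`; configurable).
`area_efficiency()` compares flower-strip and off-field assessments on an
area basis by interpolating each scenario's (managed area, p90 φ) curve at
matched dilution levels.

## Numerical choices and degenerate inputs

* $F = 0$, distance beyond $D_T$ or $D_{max}$, closed anthesis: handled by
  a feasibility predicate, not exceptions; hours with no feasible patch
  contribute zero.
* Flower density is clamped to $[0, F_0]$; deliveries in the emptying hour
  use the start-of-hour density (synchronous update), so a patch's last
  hour can slightly overdraw its standing crop — negligible at realistic
  patch sizes and the price of the hourly time step.
* SO ties: smaller $D$, then smaller id; RL zero-weight hours leave the
  pool unemployed.
* `NA` is the no-exposure marker throughout; fractions of sites at
  $\varphi = 0$ (exposure-free foraging) and $\varphi = 1$ (no dilution) are
  reported alongside percentiles.
* Seeds: every stochastic element (detection, treatment draws, stochastic
  RL, site sampling) flows from explicit seeds; derived seeds stay below
  $2^{31}$.

## Problem sizes used in the test-suite

The packaged tests exercise the full chain at sizes chosen to make the
statistical checks sharp while keeping a complete run in minutes: a ring of
20 interchangeable fields × 1000 treatment realizations for the
mean-dilution law; 100 randomized ≤20-patch landscapes for the
SO/brute-force equivalence; a 120-patch abundance sweep for the
exploited-patch scaling; and a 3×3 km synthetic landscape with 12 target
fields, ~15 sampled sites and 8 paired realizations per grid point for the
scenario sweeps. Full-size assessments (5×5 km, 100 realizations, 10%
sites) run in minutes to tens of minutes depending on the scenario.

## Known limitations

* The RL recruitment constants are a stand-in; absolute RL patch counts
  are parameter-dependent (their scaling with patch abundance is not).
* No pollen foraging, no in-hive dynamics, no diurnal forager-number
  variation (the hourly structure supports it; the shipped scenarios use a
  constant 100).
* Contamination is a fixed daily per-patch input: no fate kinetics and no
  spray-drift model (a per-patch `C` field accepts externally computed
  drift deposits).
* Planar coordinates only; no raster ingestion or CRS transformations.
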