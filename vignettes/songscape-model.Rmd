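---
title: "The songscape model: humid-air acoustics and an agent-based singing population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The songscape model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(songscape)
```

## The question

Territorial songbirds advertise and defend their territories by song. How far
a song carries depends on the state of the air it travels through: hot, dry
air absorbs high-frequency sound much more strongly than cool, humid air. As
semi-arid grasslands warm and dry, morning singing conditions deteriorate,
and a bird may simply stop being audible to the neighbors it needs to reach.
songscape simulates this situation end to end: weather drives an atmospheric
absorption model, absorption sets each song's audible radius, and a
population of simulated birds on a hexagonal territory grid tries, minute by
minute through each morning, to make vocal contact with every adjacent
neighbor. The headline output is the *completion percentage*: the share of
interior birds that contacted all six neighbors by the end of a morning.

## Atmospheric absorption

For a pure tone of frequency $f$ (Hz) at absolute temperature $T$ (K),
station pressure $p_s$ and reference values $T_0 = 293.15$ K,
$p_0 = 101325$ Pa, the absorption coefficient is the standard humid-air
(ISO 9613-1 style) form, in nepers per meter:

$$\alpha = f^2\left[1.84\times10^{-11}\frac{p_0}{p_s}
\left(\frac{T}{T_0}\right)^{1/2}
+\left(\frac{T}{T_0}\right)^{-5/2}\left(
0.10680\,e^{-3352/T}\frac{f_{r,N}}{f_{r,N}^2+f^2}
+0.01278\,e^{-2239.1/T}\frac{f_{r,O}}{f_{r,O}^2+f^2}\right)\right]$$

converted to dB/m with $20/\ln 10$ so that all downstream audibility
arithmetic stays in decibels. The nitrogen and oxygen relaxation frequencies
depend on the percentage molar concentration of water vapor $H$,

$$f_{r,N} = \frac{p_s}{p_0}\left(\frac{T_0}{T}\right)^{1/2}
\left(9 + 280\,H\,e^{-4.17\left[(T_0/T)^{1/3}-1\right]}\right),\qquad
f_{r,O} = \frac{p_s}{p_0}\left(24 + 4.04\times10^4 H\,
\frac{0.02+H}{0.391+H}\right)$$

with $H = \rho_{sat}\,\mathrm{rh}\,p_0/p_s$, $\rho_{sat} = 10^{C_{sat}}$ and
$C_{sat} = -6.8346\,(T_{01}/T)^{1.261} + 4.6151$. Two reference temperatures
appear deliberately: $T_0 = 293.15$ K scales the relaxation physics, while
the saturation exponent uses the triple-point temperature
$T_{01} = 273.16$ K, as the standard formulation requires; both are exposed
via `acoustic_constants()`. The implementation is cross-checked in the test
suite against an independently written scalar routine to $10^{-6}$ relative
over a cube of temperature, humidity and frequency.

```{r}
attenuate(tibble::tibble(tair = c(22, 38), relh = c(75, 15), pres = 97000),
          freq = c(4000, 8000, 12000))
```

The hot-dry row attenuates roughly twice as strongly at every frequency —
that asymmetry is the entire climatic mechanism of the model.

## From absorption to an audible radius

A song is a single carrier frequency with a source level referenced to 1 m
(`song_spec()`), heard down to a 30 dB detection threshold — the assumed
ambient noise floor (`propagation_settings()`). The audible radius solves
$L(r^\*) = 30$ dB by bisection to 0.01 m, capped at `max_radius` when the
song is audible everywhere, and 0 when it is audible nowhere.

Two propagation laws are available. The default, `absorption_only`, applies
only atmospheric absorption: $L(r) = SL - \alpha\,(r - r_{ref})$.
`spreading_plus_absorption` adds spherical spreading
($-20\log_{10} r/r_{ref}$). The default source level of 90 dB at 1 m is a
*calibration choice* paired deliberately with the absorption-only law: the
resulting 60 dB attenuation budget yields a ~2.6 km audible radius at 4 kHz
under mild morning air (spanning adjacent 1-km territories, so low-frequency
singers reliably reach all neighbors), ~770 m at 8 kHz (partial contact) and
~360 m at 12 kHz (rare contact) — the qualitative regime in which the
population experiments are meaningful. Under the spreading law a 90 dB
source would be audible only to ~350 m even at 4 kHz and essentially no
contact would ever occur at 1-km territory spacing; users who prefer the
spreading law should raise `source_level` accordingly. Both the mode and the
level are plain configuration.

## The arena

`hex_grid(rows, cols, diameter)` builds an offset-row hexagonal tiling.
"Diameter" means the flat-to-flat width of a hexagon, which equals the
center-to-center distance of adjacent territories — so "1 km territories"
puts neighboring birds' centers exactly 1 km apart. The population
experiments use the 10 × 11 arena: 110 territories of which
$(10-2)\times(11-2) = 72$ interior territories have the full six neighbors;
this is the unique small factorization consistent with both counts. Edge
birds run the full behavior model (so interior birds face realistic
neighbors) but are excluded from all reported metrics, since they cannot
contact six neighbors. Within-territory positions are sampled uniformly over
the closed hexagon by rejection from its bounding box (acceptance 3/4),
verified in the tests by centroid and equal-sector chi-square checks.

## The behavior model

Time advances in 1-minute steps through a 360-step morning (sunrise to
sunrise + 6 h, the dawn-chorus window). Each bird chooses among three
behaviors — sing, move, rest — with equal probability 1/3 (the uniform
choice; probabilities sum exactly to one). Then:

* **Sing**: the song reaches every point within the current audible radius.
  Every neighbor standing inside it records a *mutual* contact with the
  singer, and is induced to sing in the same time step. Induced singing
  propagates as a FIFO cascade — an induced bird's song can induce its own
  neighbors — with each bird singing at most once per step, which guarantees
  termination. A song that reaches no neighbor is a failure: for exactly one
  subsequent step the bird's probabilities become (0, 0.5, 0.5), after which
  they revert.
* **Move**: relocate to a uniform random position within the territory.
* **Rest**: do nothing.

A bird that has contacted its full neighbor set is *finished*: it stops
singing and moving for the rest of the day, but remains in place and can
still be contacted by its neighbors. Positions, contacts, penalties and
water budgets all reset at the start of each day.

## The water budget (EWL)

Aridity does not only shrink the audible radius; it also dehydrates the
singer. The optional evaporative water loss model (`ewl_model()`) charges
every bird a mass-specific loss each minute,
$\mathrm{rate}(T) = a\,e^{b\,\max(0,\,T - T_{uc})} + c$ (g water per g body
mass per minute), a flat baseline below an upper critical temperature with
exponential growth above it — the canonical shape of avian evaporative
water loss curves. Cumulative loss (TEWL) linearly depresses the sing and
move probabilities by the fraction of the lethal budget already spent
(`rule = "multiplicative"`, which reaches exactly zero at the bound; the
literal subtractive variant is kept as `rule = "subtractive"`). At 15 % of
body mass lost — the conventional lethal dehydration bound — the bird is
incapacitated and only rests until the next day.

Defaults ($a = 5\times10^{-5}$, $b = 0.2\,°\mathrm{C}^{-1}$,
$T_{uc} = 30\,°\mathrm{C}$, $c = 2\times10^{-5}$, body mass 21 g, a
house-finch-sized passerine) were chosen once so that a resting bird loses
about 2.5 % of body mass over a mild 18–29 °C morning (far from the bound)
but approaches the 15 % bound late in a 31.5–43.5 °C climate-change-drought
morning. These constants set a qualitative regime; all water-budget claims
made by the package's tests are directional (EWL can only reduce
completion), never value-based.

## Weather handling

`read_weather_csv()` ingests Mesonet-style tables (`TAIR` °C, `RELH` %,
`PRES` with automatic Pa/hPa/atm detection, plus a timestamp column), treats
any reading at or below −900 as a missing-value sentinel and carries the
previous record forward. Series are assumed pre-restricted to the morning
window; each day's window starts at its first record. The 5-minute records
drive 1-minute model steps by step-hold (each record repeated five times),
not interpolation — and since weather is constant within a block, audible
radii are memoized per block, a 5× saving with bit-identical results.
`apply_climate_delta()` applies the projected-2070 transform for the region
(+7.5 °C, −6 percentage points RH, humidity clamped to [0, 100]).

`synthetic_weather()` generates fixture mornings: linear temperature and
humidity ramps with Gaussian noise (defaults 0.5 °C, 2 % RH, 50 Pa) at
constant pressure, 72 records per day. The `"contemporary"` profile ramps
18→29 °C and 85→45 % RH; `"drought"` ramps 24→36 °C and 55→20 % RH, both at
96.5 kPa — bracketing typical late-spring mornings in the south-central
semi-arid prairies. The generator emulates the *shape* of morning station
data, not its full richness: real mornings have day-to-day autocorrelation,
weather fronts, non-monotone humidity, pressure trends and seasonal drift.
Tests passing on synthetic weather therefore demonstrate the model's
internal logic and directional climate responses, not quantitative
agreement with any particular station record.

## The two experiments

**Population completion** (`run_scenario()`): for each of `iterations`
replicates and each day, a fresh population runs a 360-step morning; the
end-of-day completion percentage over the 72 interior birds is averaged
across days within a replicate, then summarized as mean ± SE (sample
SD / $\sqrt{n}$) across replicates. The per-step mean completion curve is
reported alongside, since both views of "completion" are informative.

```{r}
w <- synthetic_weather(days = 5, profile = "drought", seed = 42) |>
  apply_climate_delta()
cs <- run_scenario(w, scenario_config(freq = 8000, diameter = 1500,
                                      iterations = 3, seed = 42,
                                      ewl = ewl_model(enabled = TRUE)))
glance(cs)
```

```{r completion-curve}
autoplot(cs)
```

**Two-bird sweep** (`run_pairwise_sweep()`): a simplified model of two birds
on adjacent hexagons, run on one day's weather across a grid of frequencies
and territory radii (half the flat-to-flat diameter; the full design is
1–12 kHz × 25–1500 m by 25 m). The two birds run the standard state machine
*without* the finished rule. "Contact percentage" is not self-defining for a
pair, so the package defines it as the share of the day's song attempts that
reached the other bird, averaged over both birds and over iterations — a
continuous [0, 100] measure comparable across cells. `diff_grid()`
subtracts two sweeps cell-wise to map which frequency/territory-size
combinations lose the most under harsher weather.

## Numerical and design choices

* Radius solver: bisection to 0.01 m absolute; cap at `max_radius`
  (default 50 km, above the arena diagonal of every standard
  configuration); radius 0 when the source is below threshold at the
  reference distance.
* Hexagon orientation is fixed (vertical shared edges between row
  neighbors); it affects only geometry cosmetics, not adjacency.
* Replicate independence: per-iteration (and per-sweep-cell) seeds are
  drawn up front from the master seed, so results do not depend on
  execution order and identical configurations are bit-reproducible.
* Ties in directional comparisons are allowed: when two scenarios both
  saturate at 100 % completion, the orderings are reported as weak
  inequalities.
* Desk-scale experiment sizes: the test suite and the acceptance script run
  population scenarios at 10 days × 5 iterations on synthetic weather — the
  package's chosen balance between Monte-Carlo stability of the completion
  means and keeping a full check run in well under a minute per scenario.
  The full 61-day design is a single argument change.

## Limitations

* Excess attenuation from wind, turbulence, ground effect and vegetation is
  not modeled; absorption is the only frequency-dependent loss, so absolute
  radii are optimistic.
* A song is a single carrier frequency with no bandwidth, no directionality
  and no receiver hearing curve beyond the fixed 30 dB threshold.
* Singing itself incurs no extra water cost beyond the resting EWL rate,
  and birds cannot drink or rehydrate within a day.
* The exact source level and propagation law of the original field-scale
  calibration are configuration choices here, so quantitative completion
  percentages are conditional on those defaults; directional climate,
  frequency, and territory-size effects are the robust outputs.
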