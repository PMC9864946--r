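---
title: "Methods: germination synchrony indices, dormancy model and simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germination synchrony indices, dormancy model and simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germsync)
```

## The indices and their definitional choices

Both statistics operate on a single replicate's census: counts `n_i` of
newly germinated seeds per day, `N = Σ n_i` in total.

**Asynchrony** is the Shannon entropy, in bits, of the relative frequencies
`f_i = n_i / N`. The denominator is the number of *germinated* seeds, not
seeds sown: an entropy requires `Σ f_i = 1`, and seeds sown would break
that whenever germination is incomplete. The standard convention
`0·log2(0) = 0` applies, so explicitly recorded zero-count days carry no
mass; days simply absent from a census (gaps) are treated identically.
With no germinated seed, the frequencies — and hence the index — are
undefined, and the package raises an error rather than returning 0, since
"zero asynchrony" means perfectly synchronous germination, the opposite of
no germination at all.

**Synchrony** `Z` divides the number of same-day pairs of germinated seeds,
`Σ_i C(n_i, 2)`, by all pairs `C(N, 2)`. It is defined exactly when a pair
exists, i.e. `N ≥ 2`. A replicate with 0 or 1 germinated seeds is flagged
as *excluded* (with a warning at summary time) instead of contributing a
silent 0: an undefined overlap is not the same observation as two seeds
germinating on different days. Excluded replicates still contribute to
germination fractions, and to the entropy summary when `N = 1` (a
single-day census with entropy 0 is well defined).

Both indices depend only on the multiset of daily counts — permuting day
labels changes nothing — and they move in opposite directions under
coarsening: merging two census days can only increase `Z` (pairs across the
merged days become same-day pairs) and only decrease the entropy
(concavity). The test suite checks both properties on random censuses, and
checks `Z` against an independent oracle that expands the census into one
day label per seed and enumerates all unordered pairs explicitly.

**Group summaries** average per-replicate indices; the dispersion term is
the standard error of the replicate mean (sample SD / sqrt(r)). Published
treatment tables in this field are ambiguous about whether "±" denotes SE
or SD, so the SD is emitted alongside. Summaries are groupable by species,
treatment and incubation temperature, or marginal over temperature, since
treatment-level synchrony tables do not always state the temperature at
which they were computed. Pooling counts across replicates before indexing
is offered (`pool = TRUE`) but is never the default: synchrony is defined
within a replicate, and pooling conflates between-replicate timing shifts
with within-replicate spread.

## Thermal time and the dormancy-type niche

Germination timing follows the thermal-time relation `θ = (T − Tb)·t`:
at incubation temperature `T` (°C) above the base temperature `Tb`, a seed
requiring `θ` degree-days germinates after `t = θ/(T − Tb)` days. At or
below `Tb` no thermal time accrues; the package treats prediction requests
there as an error, and simulated germinable seeds at such temperatures
simply never germinate.

Dormancy is represented by a continuous level `d ∈ [0, 1]` (1 fully
dormant), a modelling construct layered under the categorical classes used
for seedbank cycling: dormant (D) for `d > 2/3`, conditionally dormant (CD)
for `1/3 < d ≤ 2/3`, nondormant (ND) for `d ≤ 1/3`. The symmetric
tripartition is a default, not a claim; the thresholds are configurable.

The six types of non-deep physiological dormancy are implemented as
geometries of the permissive temperature window over the taxon range
`(Tmin, Tmax)`: anchored low and widening upward as dormancy is released
(type 1), anchored high and widening downward (type 2), anchored at an
intermediate `T_mid` and widening both ways (type 3), fixed high (type 4),
fixed low (type 5), always the full range (type 6). Window edges
interpolate linearly in the released fraction `1 − d` between a fully
dormant core window (breadth `breadth_frac` of the taxon range, default
1/3 — wide enough that a 5-degree grid retains at least one permissive
temperature, narrow enough that dormant type-1 and type-3 lots are
distinguishable on that grid) and the full range. The literature describes
the widening only qualitatively, so linearity is the minimal choice; a
logistic alternative is available behind a switch. Type 3's widening is
symmetric in the interpolation parameter, another default the literature
does not pin down.

Dormancy also caps the fraction of seeds able to germinate anywhere:
`gmax(d) = (1 − d)^γ` with `γ = 0.5`. The endpoints are forced —
fully dormant lots do not germinate, fully nondormant lots are limited only
by viability — but the curve between them is concave by design: lots of the
dormancy types modelled here germinate to high percentages at their optimal
temperature even while still classed dormant, so germinable fraction rises
steeply at the start of release. A concave curve also keeps partially
dormant dishes populated with enough germination events that the entropy
index measures timing spread rather than small-sample artefacts (with very
few germinated seeds the empirical entropy is capped near `log2 N`
regardless of the underlying spread). For the fixed-window types 4–6 a
floor on `gmax` may be configured, since those types are described as
raising germination percentage during release without moving the window.

Dormancy-breaking treatments release `d` by first-order decay
`d(t) = d0·exp(−rate·t)`. Only the ordering of the two agents' speeds is
established — days of cold stratification achieve what months of dry
after-ripening do — so the defaults encode that ordering with round
half-lives: 30 days for after-ripening (90 days ≈ three half-lives), 2 days
for stratification (5 days ≈ 2.5 half-lives). Exponential kinetics are the
simplest monotone [0,1] → [0,1] map with a single rate; nothing in the
package depends on the functional form beyond monotonicity.

## What the simulator emulates

`simulate_trialset()` reproduces the standard trial design: dishes of 50
seeds, four replicates, incubation at 5/10/20/25/30 °C, a daily census that
stops after three consecutive germination-free days. Each seed
independently dies (probability `dead_frac`, default 0.05 — a typical
viability loss for fresh seed lots), is germinable with probability `gmax`
inside the niche window or a small `leak` (default 0.01, configurable to 0)
outside it, and if germinable draws a lognormal thermal-time requirement
with dispersion `theta_sigma·(1 + κ·d)`. The inflation factor `κ`
(default 2) is the package's mechanistic assumption: dormancy spreads
germination timing, so release synchronises it. Empirically the literature
reports the dormancy–synchrony correlation without a mechanism; `κ` and
the fraction effect of `gmax` are separately switchable so their
contributions to synchrony can be distinguished.

Numerical conventions: germination day is `ceiling(t)` (a daily census
detects at the end of the day), days are 1-based, and the stop-rule clock
starts at the *first* germination event. A clock running from day 1 would
terminate every trial whose germination lag exceeds three days — at 5 °C
the default thermal model's median lag is 12 days — so the onset-anchored
reading is the only one under which the protocol can observe germination at
all. Seeds whose germination would fall after the truncation point are
recorded as viable ungerminated, so the accounting identity
`germinated + viable + dead = sown` holds in every simulated census.

Default thermal parameters (`Tb = 0` °C, `theta50 = 60` °C·d — three days
to median germination at 20 °C — and `theta_sigma = 0.15`) are **synthetic**
placeholders for a fast-germinating Brassicaceae lot; no published `Tb` or
`θ` values exist for the motivating species, and fitted values should
replace them when real censuses are available.

Randomness: one user-visible seed; each replicate draws from a substream
derived deterministically from (seed, temperature index, replicate index),
so repeated runs are bit-identical and enlarging a design never changes
the replicates already generated. The seed and full configuration are
recorded in the pipeline's provenance JSON.

What the generator does **not** emulate: soil microclimate (burial forcing
is an idealised 12-month cosine on `d`, the minimal periodic model),
between-replicate heterogeneity (dishes are exchangeable), secondary
dormancy induction, seed aging beyond the constant dead fraction, and any
water-potential (hydrotime) limitation. Passing tests therefore demonstrate
that the indices and analysis recover the structure this mechanism
generates — not that real seed lots follow lognormal thermal-time with
entropy-linear dormancy effects.

## The cycling analysis

`run_burial()` drives `d` through `d_mean + d_amp·cos(2π(m − phase)/12)`
(clipped to [0, 1]; defaults `d_mean = 0.5`, `d_amp = 0.4`, giving a
D → CD → ND → CD → D year) and assays an exhumed sample each month at a
single temperature, defaulting to 20 °C — the intermediate optimum at which
a dormant type-3 lot is testable all year. The monthly table records the
latent `d`, its class, germination percentage and the replicate-mean
indices. `cycling_correlation()` is the Spearman rank correlation
(tie-corrected, two-sided) between two monthly trajectories: rank-based
because the germination–synchrony relationship is monotone but not
plausibly linear on the raw scales. The default pair is the *measurable*
one — germination % versus mean Z — since in real burials the dormancy
level is never observed directly; the latent-`d` correlations are also
available in simulation (`x = "dormancy"`), where they are negative against
both observables.

## Problem sizes and test calibration

The acceptance-level checks run at sizes chosen to make each qualitative
claim statistically unambiguous while keeping the whole suite near twenty
seconds: 1000 random censuses for the oracle equivalence, 200 replicates
per dormancy level for the monotone-synchronisation trend, 150 per
treatment arm for directionality, 100 seeded burial years for the positive
co-movement and 400 for the null (flat-forcing) calibration of the 5%
rejection rate. Under flat forcing the monthly assays are exchangeable, so
the Spearman test's rejection rate should sit at its nominal level; this is
a genuine property of the estimator pipeline, not of any tuning.

## Known limitations

* The dormancy level `d`, its tripartition thresholds, and the niche
  interpolation are constructs: only their qualitative consequences
  (ordering, window geometry, cycling classes) are supported by evidence.
* Published treatment-level synchrony tables cannot be reproduced
  numerically because the underlying raw censuses are unpublished; the
  package targets the reproducible layer: index definitions, boundary
  identities, orderings and signs.
* `Z` compares only same-day completion; near-misses (one day apart) count
  as fully asynchronous. The entropy index is likewise blind to the
  *ordering* of days. Complementary spread measures (e.g. quantile ranges
  of germination time) are out of scope.
* With fewer than ~5 germinated seeds both indices are noisy and the
  entropy is bounded by `log2 N`; the summaries report how many replicates
  were excluded, and downstream analyses should treat sparse censuses with
  care.
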