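---
title: "Quantifying yeast survival from outgrowth kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying yeast survival from outgrowth kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(outgrowr)
```

## The measurement principle

Chronological life span (CLS) experiments in budding yeast ask how long a
non-dividing cell stays viable during post-diauxic arrest. The traditional
readout — serial dilution, plating, colony counting — is accurate but slow.
The outgrowth alternative works from a single physical fact: when a fixed
volume of an aging culture is diluted into fresh rich medium, the optical
density the regrowing culture reaches after any fixed time is proportional
to the number of viable cells that went in. A culture that has lost half
its viable cells produces an outgrowth curve that is identical in shape
but displaced to the right by exactly one doubling time.

That displacement is what this package measures. For a well tracked across
age-points, the survival fraction at age-point $n$ is

$$ s_n = \left(\tfrac{1}{2}\right)^{\Delta t_n / \delta}, $$

where $\Delta t_n$ is the time shift of the age-point's outgrowth curve
relative to the first (reference) age-point, measured at a fixed
background-corrected OD level, and $\delta$ is the doubling time estimated
from that well's **reference** curve. The first age-point is by definition
maximal survival, $s_1 = 1$: survival is always relative to the earliest
sample, never an absolute viable count. A single-number summary, the
survival integral (SI), is the area under the survival-versus-age curve,
computed by the trapezoid rule so that uneven sampling (days 2, 4, 6, 9,
11, 13) is weighted correctly.

The same machinery handles non-aging assays: treatments (minutes of heat
shock, drug doses) can be encoded as pseudo-age-points with the untreated
condition as the reference, and a single run can be exported in "runs"
mode for growth-rate-only analyses.

## From raw file to survival curve

**Input.** One delimited file per age-point, in the plate-reader export
layout: first column elapsed time as `HH:MM:SS` (hours unbounded, so
multi-day reads are fine), each subsequent column one well, at most 200
wells (two 100-well Honeycomb plates). A single header row is detected
automatically. A separate well-info table
(`position,name,group,media,role`) assigns names, replicate groups and the
media-only blank role; well positions must be loaded in the same order at
every age-point.

**Background.** Every reading has the optical density of cell-free medium
subtracted. The background is either a fixed value — defaulting to 0.15,
roughly the reading of 150 µL of plain YPD — or taken from a named blank
well. From a blank well we use the *median* of the whole series rather
than the mean: a single contaminated or smudged reading then has no
influence. Corrected ODs are floored at $\varepsilon = 10^{-4}$ so that
logarithms stay finite on blank and dead wells; the floor is far below any
biologically meaningful reading.

**Crossing times.** All downstream quantities reduce to "when does the
corrected OD first reach level $L$?". Between samples the culture grows
exponentially, so we interpolate linearly in $(t, \log_2 \mathrm{OD})$,
which makes crossing times *exact* for exponential growth regardless of
the sampling grid. A curve already above $L$ at its first sample returns
that first time; a curve that never reaches $L$ returns "absent" — the
signature of a dead culture or a blank, and a valid outcome rather than an
error (except for the reference curve, whose failure invalidates the whole
lineage and is reported as such).

**Doubling time.** Two estimators are provided, both operating between
configurable corrected-OD thresholds (defaults 0.2–0.5, inside the
instrument's reliable range):

* *inflection*: the reciprocal of the steepest $\log_2$ slope over
  consecutive sample pairs lying within the thresholds — the classical
  "maximal growth rate" readout;
* *interval* (the default): the time to traverse from the lower to the
  upper threshold divided by $\log_2(\mathrm{OD_{max}}/\mathrm{OD_{min}})$,
  the number of doublings that traversal represents.

For a pure exponential the two agree exactly with the generative doubling
time (the test suite checks this to $10^{-9}$ relative error). Under
additive OD noise the interval method averages over the whole window while
the inflection method picks a maximum of noisy pairwise slopes — a
statistic biased toward upward noise excursions — so the interval estimate
is systematically closer to truth; the suite verifies this over 100 seeded
noisy curves, and the interval method is therefore the default and the one
fed into survival conversion. An affine correction
$\delta' = a\delta + b$ is available for users who have calibrated their
reader against an independent growth-rate measurement; its default
$(a, b) = (1, 0)$ is an explicit no-op.

**Time shifts and survival.** Shifts are measured at a single corrected-OD
level (default 0.3, the middle of the reliable window). The doubling time
entering $s_n$ always comes from the *first* age-point's curve of the same
well: later curves may be dominated by a resistant subpopulation or
stress-adapted physiology, and the reference curve is the only one whose
growth rate describes the population being assayed. A dead culture (no
crossing) scores survival 0 rather than missing, so survival integrals
remain defined.

**Cleaning.** Raw survival estimates can exceed 1 (a slightly negative
shift at an early age-point) and can rise late in the experiment —
"gasping", when a handful of survivors or petite mutants regrow and the
apparent viability spikes. Since true relative survival cannot increase,
cleaning pins the reference at 1 and applies a running minimum capped at
1: $\tilde s_1 = 1,\; \tilde s_i = \min(1, s_i, \tilde s_{i-1})$. One
deterministic pass removes both small inversions and terminal spikes, is
idempotent, and never invents values below any later observation. Raw
values are retained alongside cleaned ones in all outputs; cleaning can be
disabled per export.

## Replicate groups and comparisons

Wells sharing a `group` in the well info are biological replicates. Group
summaries report a center (mean or median — medians are useful when one
replicate well fails) and always the sample standard deviation
($n-1$ denominator; 0 for a singleton). Against a designated reference
group, survival integrals are compared by percent change,
$\log_2$ ratio, and a two-sample *t*-test. The *t*-test is Welch's
(unequal variances, Welch–Satterthwaite degrees of freedom, two-sided):
with the field's typical $n = 3$ biological replicates per genotype,
assuming equal variances is not safe, and the Welch test's type-I error
remains calibrated either way — the suite verifies a rejection rate
within [0.03, 0.07] at $\alpha = 0.05$ over 1000 null simulations. No
multiple-testing correction is applied; when screening many strains
against one control, apply your own (e.g. `p.adjust`) across the exported
p-values.

## The simulator: what it emulates, and what it does not

`sim_spec()`/`simulate_experiment()` generate complete experiments in the
exact file dialect the parser reads — one run CSV per age-point, identical
well order, a shared media-only blank well, a well-info table — plus a
ground-truth table of programmed viable fractions, so every pipeline stage
can be tested against known answers.

Curves are logistic in base-2 parameterization,

$$ \mathrm{OD}(t) = b + \frac{K}{1 + (K/x_0 - 1)\,2^{-t/\delta}}
   + \mathcal{N}(0, \sigma^2), $$

with $x_0$ the inoculum OD scaled by the programmed viable fraction —
which embodies exactly the proportionality assumption the assay rests on.
Defaults: $\delta = 1.5$ h (wild type in rich medium), inoculum OD 0.04,
background 0.15, noise $\sigma = 0.005$ OD, 30-minute readings for 24 h,
age-points on days 2, 4, 6, 9, 11, 13.

Two deliberate choices deserve explanation:

* **Carrying capacity $K = 200$, far above the analysis window.** The OD
  scale here is viable-biomass-equivalent and strictly proportional to
  cell number; instrument compression of dense cultures is not modeled.
  Real outgrowth in glucose-replete medium is still fully exponential at
  corrected OD 0.2–0.5 — deceleration only begins near the diauxic shift —
  but a logistic decelerates continuously from $t = 0$. Placing $K$ near a
  realistic *reading* (≈1.2) would put the analysis window at 17–42% of
  saturation, inflate the interval doubling-time estimate by tens of
  percent, and propagate multiplicatively into survival at low fractions —
  misrepresenting precisely the part of the curve the analysis reads. With
  $K = 200$ the window is effectively exponential (residual end-to-end
  recovery bias below 1% down to viable fractions of 0.01) while curves
  still saturate well inside the 24 h read. No analysis quantity depends
  on the saturation level, which is why trading its realism for in-window
  fidelity is the right exchange.
* **Seeded Gaussian additive noise.** Each well/day curve gets its own
  deterministic seed derived from the experiment seed, so simulations are
  reproducible to the byte and the analysis path itself contains no
  randomness. The simulator restores the caller's RNG state afterwards.

What the simulator does *not* emulate — and hence what passing tests do
not certify about real data: diauxic two-phase growth, plate edge effects
and evaporation drift, optical nonlinearity at high density,
heteroscedastic or correlated noise, contamination, and wells whose
doubling time changes with age. Recovery results on synthetic data bound
the pipeline's numerical error, not the biological error of the assay.

## Numerical conventions and degenerate inputs

* Time stamps must be strictly increasing; duplicated stamps are an error
  rather than silently averaged.
* More than 200 well columns is an error (instrument capacity), as are
  ragged rows and non-numeric OD cells, each reported with coordinates.
* Corrected ODs are floored at $10^{-4}$; crossing levels at or below the
  floor are rejected.
* A flat-in-$\log_2$ bracket during interpolation (possible only at the
  floor) resolves to the later sample time.
* Doubling-time estimation returns "absent" (`NA`) — never 0 — when no
  sample pair lies within the thresholds or the curve does not grow;
  absent reference doubling times abort the lineage with the well named.
* Exports print reals to 6 decimals; column order is fixed and documented
  so downstream scripts can rely on it.

## Problem sizes in the test suite

The suite exercises the pipeline at the scale of a typical two-plate
experiment and at the statistical sizes the methods are quoted for: 100
seeded noisy curves for estimator accuracy, a 6-age-point two-group
triplicate experiment (42 curves) for end-to-end recovery, and 1000 null
simulations at $n = 3$ per group for *t*-test calibration. These sizes
were chosen to make the Monte-Carlo assertions stable across seeds.

## Known limitations

* The survival conversion assumes the reference doubling time applies at
  every age-point; strains whose outgrowth rate changes with age violate
  this and will show biased survival (a limitation inherited from the
  assay, not fixable in software).
* Very low survival fractions push crossing times toward the end of the
  read; a 24 h read at $\delta = 1.5$ h resolves fractions down to
  roughly $10^{-3}$ before curves stop reaching the time-shift level.
* The cleaning rule is deliberately conservative: it removes increases but
  cannot distinguish genuine regrowth (gasping) from a pipetting error at
  a single age-point.
* Group comparisons treat wells as independent replicates; technical
  replicates of one aging culture will understate variance.
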