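---
title: "Evaluating water-by-nitrogen trials with entropy-weighted TOPSIS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating water-by-nitrogen trials with entropy-weighted TOPSIS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wntopsis)
```

## The problem

A deficit-irrigation by nitrogen-rate factorial trial measures, per
treatment, water consumption (ET), yield, fruit-quality traits and the
derived efficiency indices. These objectives conflict: the treatment that
minimizes water use is never the one that maximizes yield, and quality
peaks somewhere in between. `wntopsis` condenses the indicator table into
one score per treatment using the entropy-weight method (EWM) for
objective weighting and TOPSIS for ranking, and provides the upstream
stages — soil-water balance, efficiency indices, correlation screening —
that produce the indicator table in the first place.

The packaged data are the printed per-treatment tables of a two-season
eggplant trial under mulched drip fertigation in a cold-arid oasis
region: three water regimes applied during flowering/fruiting (moderate
deficit W1 = 50–60 % of field capacity, mild deficit W2 = 60–70 %, full
irrigation W3 = 70–80 %) crossed with three nitrogen rates (N1 = 215,
N2 = 270, N3 = 325 kg ha⁻¹), plus an unfertilized full-irrigation
control (CK).

## Water balance

Gravimetric moisture of each layer is (wet − dry)/dry; stage water
consumption is

$$ET = 10\sum_{i=1}^{n} \gamma_i H_i (\omega_{i1}-\omega_{i2}) + M + P + K - C$$

with γ in g cm⁻³, H in cm and contents as fractions, the factor 10
yielding mm. Contents are handled internally as *fractions*; percent
appears only at the I/O boundary, which prevents silent 100× unit errors.
Defaults: groundwater recharge K = 0 (water table far below the root
zone) and deep percolation C = 0 (deficit drip applications never exceed
field capacity); both remain settable for other sites. The design
irrigation depth \(M = 10\gamma HP(\omega_j-\omega_i)\) is clamped at
zero when the profile is already at target — a scheduler never extracts
water. The planned wetted layer defaults to 0–60 cm (three 20-cm
layers), the root-active profile of the packaged trial; it is an
argument, not a constant. Effective rainfall is accepted as an input:
how it is derived from gross precipitation is outside this package's
scope.

## Efficiency indices

WUE = Y/ET and IWUE = Y/I in t ha⁻¹ mm⁻¹; NPFP = 1000·Y/F_N in kg kg⁻¹.
The factor 1000 converts yield from t ha⁻¹ to kg ha⁻¹; it is confirmed by
the packaged trial's own printed nitrogen-level means, which are
reproduced only under this convention. Level means are computed as means
of per-treatment ratios (not ratios of level means); the packaged
reference values discriminate between the two conventions and match the
former. NPFP is undefined for the zero-nitrogen control, which is why CK
is excluded from the multi-criteria evaluation.

## Indicator screening

Candidate indicators are often near-collinear (IWUE with WUE, the
sugar/solids traits with each other); strongly correlated columns would
double-count one underlying signal. `pearson_matrix()` computes the
correlation and two-sided p-value matrix; `prune_indicators()` applies a
greedy rule — scan indicators in a priority order, drop any whose |r|
with an already-retained indicator reaches the threshold (default 0.8).

Screening has two modes because the packaged trial's retained set
\{ET, Y, WUE, NPFP, TSS, VC\} was decided by its authors on plot-level
replicate data that was never published. *Paper mode* (the default)
applies that retained list directly and is what the reproduction uses.
*Auto mode* runs the greedy rule on whatever table it is given; on the
packaged treatment-mean fixtures it drops one of TSS/VC as well (their
mean-level correlation is 0.99), which is a faithful consequence of the
rule on means rather than replicates — a known limit of reconstructing a
screening decision from printed summary tables. The packaged candidate
table carries the nine printed indicators; the two fruit-diameter traits
of the original trial were published only as figures and are therefore
not included.

## The EWM-TOPSIS chain

With m treatments and n indicators, each column is min-max standardized
in its direction (benefit: \((x-\min)/(\max-\min)\); cost: reversed), so
1 is always best. Column proportions \(P_{ij}=z_{ij}/\sum_i z_{ij}\) give
the entropy \(e_j=-\frac{1}{\ln m}\sum_i P_{ij}\ln P_{ij}\) with the
convention 0·ln 0 = 0 — load-bearing here, because min-max
standardization produces exact zeros. Weights are
\(w_j=(1-e_j)/\sum_k(1-e_k)\): a column that separates the treatments
(low entropy) is informative and gets weight. Distances to the ideal
solutions (column extrema of z, i.e. the all-ones and all-zeros vectors)
use by default

$$d_i^\pm=\sqrt{\textstyle\sum_j w_j\,(z_{ij}-z_j^\pm)^2},$$

weights *linear* inside the squared deviations. The alternative
`"literal"` variant weights the matrix first (v = w·z) and takes plain
Euclidean distances, which effectively squares the weights. Both appear
in the MCDA literature; the weights-linear form is the default because
it is the convention under which the packaged trial's published distance
table is recovered digit for digit, and it bounds d in [0, 1] (weights
sum to 1, z ∈ [0, 1]). Closeness is \(T_i=d_i^-/(d_i^-+d_i^+)\); ranks
descend in T with ties broken by input order (ties are measure-zero on
real data; the policy only makes the output deterministic).

Direction tags default to all-benefit for the packaged evaluation —
including ET. Treating water consumption as a benefit is a substantive
modelling choice (in this trial higher ET tracks fuller irrigation and
higher yield), and it is the convention under which the published
weights and distances are reproduced; users can re-tag ET as a cost,
which changes the question being asked.

Numerical policies: a constant indicator column either aborts (default)
or is dropped with a warning (`constant = "drop"`) — it carries no
information and would get zero weight, but silently keeping it would
divide by zero during standardization. An object with zero distance to
both ideals (only possible in a degenerate 1-row matrix) is an error.

## Reproduction of the packaged evaluation

`evaluate_trial_year(2022)` rebuilds the screened matrix from the
fixtures (ET, Y printed; WUE, NPFP recomputed, never stored) and runs the
chain; `reproduce_evaluation()` additionally diffs against the published
weight and ranking tables. For 2022 every weight (3 d.p. entropies,
2 d.p. percentages) and every distance/closeness (3 d.p.) matches for
eight of nine treatments. The exception, W1N3, holds the worst value of
all six indicators simultaneously in the reconstructed matrix, forcing
d⁻ = 0 and T = 0 exactly; the published 0.066/0.064 cannot be produced
from the printed inputs under any weighting variant, so W1N3 is compared
at rank level only (its rank 9 does hold). For 2023 the printed distances
are likewise not recoverable from the rounded printed inputs; the rank
order is, and is what the package checks. The original text is also
internally inconsistent about the candidate-indicator count (11 in
prose, n = 12 in the matrix definition, 6 after screening); the fixtures
simply expose the nine printed candidates and the six retained ones.

## The synthetic generator

`generate_indicator_table()` emulates the structure the analysis
assumes, not any particular dataset: concave quadratic response surfaces
for yield and quality with an interior optimum at the mild-deficit /
medium-nitrogen cell (65 % FC, 270 kg ha⁻¹), water consumption linear
and increasing in the water level with a weak nitrogen term, independent
Gaussian noise per indicator, and the efficiency columns derived through
the same functions the real pipeline uses. Default surface magnitudes
and noise standard deviations (yield ≈ 2 t ha⁻¹, ET ≈ 6 mm) follow the
replicate scatter printed in the packaged tables. What it does *not*
emulate: replicate-level structure (it generates treatment means),
season effects, spatially correlated noise, or any soil physics. A
passing closed-loop test therefore shows the pipeline recovers a planted
optimum under realistic mean-level noise — not that it would survive
pathological field data.

`generate_soil_moisture_season()` inverts the water balance: it emits
layer trajectories whose balance returns a specified true ET exactly,
spreading the required storage change across layers in proportion to
their capacity and refusing infeasible trajectories (contents outside
[0, saturation]). Optional Gaussian content noise makes recovered ET an
unbiased noisy estimate, which the tests verify by Monte Carlo.

`generate_weighting_stress_matrix()` builds columns at the two entropy
extremes. Because min-max standardization is scale-free, a merely
low-variance column does **not** lose weight — after rescaling its jitter
fills [0, 1] like any other column. The shape that maximizes entropy for
a standardized column (and thus minimizes weight) is a plateau with a
single low outlier: proportions are then near-uniform over m − 1
objects, e → ln(m−1)/ln m. The generator's "near-constant" columns use
exactly that plateau-with-dip shape, so the near-zero-weight property
the tests assert is forced by construction rather than luck; informative
columns single out one object far above the rest (entropy far below 1).

## Problem sizes and determinism

All evaluations are 9 × 6 desk-scale computations; the property tests
use random 4×3 and 9×4–5 matrices, 10–20 seeds for oracle equivalence,
and 100–200 seeds for the Monte-Carlo properties (optimum recovery, ET
unbiasedness, weight symmetry). The whole suite runs in a few seconds.
Generators restore the caller's RNG state and are reproducible to
1e−12 given a seed.

## Known limitations

* Screening from treatment means cannot reproduce a replicate-level
  screening decision (see above); paper mode exists for exactly that
  reason.
* Effective rainfall is an input, not a model; no evapotranspiration
  modelling (Penman–Monteith) is attempted.
* No alternative MCDA methods (PCA, grey relational analysis, fuzzy
  comprehensive evaluation) and no sensitivity machinery beyond the
  distance-variant switch.
* The two published seasons are reproduced at the level the printed
  (rounded) inputs permit: fully for 2022 (one documented impossible
  row), rank-level for 2023.
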