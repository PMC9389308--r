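---
title: "Standardizing a cohort on two growth charts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardizing a cohort on two growth charts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthbands)
```

## The model

Pediatric anthropometry is age- and sex-dependent and skewed, so raw
measurements are not comparable across children. The LMS method represents
a reference population's distribution of a measure at each age by three
curves: the Box–Cox power $L(t)$ that symmetrizes the distribution, the
median $M(t)$, and the coefficient of variation $S(t)$. A measurement $x$
at age $t$ maps to a standard deviation score

$$
z = \frac{(x/M)^L - 1}{L\,S} \quad (L \neq 0), \qquad
z = \frac{\log(x/M)}{S} \quad (L = 0),
$$

which is approximately standard normal in the reference population, and to
a centile $100\,\Phi(z)$. The assumption doing the work is that a power
transform renders each age slice normal; everything downstream
(classification cutoffs, the closed forms the simulation tests use) leans
on it. BMI is `weight / height^2` in kg/m²; heights are carried in cm as
measured and converted to metres only inside `bmi()`.

When both charts tabulate $(L, M, S)$, the exact z-score is used for both.
For references published only as centile curves, `approx_sds()` offers the
fallback linear score $(x - P_{50}) / \tfrac12 (P_{50} - P_{3})$: exact at
the median, $-2$ at the 3rd centile by construction. Since the true
z-score at the 3rd centile is $\Phi^{-1}(0.03) = -1.8808$, this fallback
overstates $|z|$ by a fixed factor $2/1.8808 \approx 1.063$ in the lower
tail; it is deliberately not the pipeline default.

## Band classification

Two schemes are built in, both defined on the z scale.

* **Five bands** at SDS cutoffs $-1.88$, $-1.66$, $+1.66$, $+1.88$,
  labelled per measure (weight/BMI: underweight, normal, normal,
  overweight, obesity; height: growth deficiency, normal, normal, normal,
  high growth). Boundary inclusivity is exactly $z < -1.88$,
  $[-1.88, -1.66)$, $[-1.66, 1.66]$, $(1.66, 1.88]$, $> 1.88$: the value
  $-1.88$ itself is Normal.
* **Three bands** for the headline comparison: under ($z < -1.88$), the
  wide norm ($-1.88 \le z \le 1.88$, i.e. 3rd–97th centile), over
  ($z > 1.88$). Overweight flagging above the 90th centile is available
  through the five-band scheme, but chart comparison runs on the
  three-band partition.

A deliberate quirk is preserved: the conventional cutoff table equates the
10th/90th centiles with $\pm 1.66$ SDS, although the true normal quantile
is $\pm 1.2816$ ($\pm 1.66$ is really the ~4.85th/95.15th centile). The
scheme is a *definition in SDS terms*, so we classify as printed;
`band_scheme(cutoff_mode = "quantile")` swaps in the exact quantiles for
sensitivity analyses rather than silently "correcting" the convention.

## The dual-chart comparison

Adults are excluded first (pediatric references end at 18 years; the
boundary is *retain age < 18*). Each child is standardized against both
reference sets; children outside a chart's tabulated age span are flagged
and excluded from that chart's tally, never dropped silently, so column
totals are allowed to differ. Per measure the three-band counts form a
3 × 2 table; percentages are computed at full precision and rounded
half-up only for display. For a band, the comparison reports
`pct_standard − pct_specialized` in percentage points and a Pearson
chi-squared test (1 df, no continuity correction by default — the
differences of interest are far from the correction's regime, and a flag
enables it) on the in-band/out-of-band × chart 2 × 2 table.

That independence test mirrors common published practice but ignores that
the *same children* appear in both columns; `compare_references_paired()`
implements the statistically preferable McNemar test on the paired
in-band indicators and is recommended when child-level data are in hand.
Supporting operations (`chi_square_test`, `spearman_corr`,
`mann_whitney`) delegate to base R's implementations behind fixed
contracts: mid-rank ties throughout; `U = min(U_a, U_b)` with an exact
p-value for untied samples of at most 20 per arm and a tie-corrected,
continuity-corrected normal approximation beyond; missing covariates are
handled per analysis (pairwise deletion) with the effective n reported.

## The synthetic generator

No copyrighted reference tables ship with the package, so testing rests on
a synthetic world with known truth.

**Base reference.** Median curves for height and weight are monotone
(Hyman) splines through realistic anchor values from birth to 18 y,
tabulated at 0.1-y knots; $S$ is constant (height 0.04, weight 0.12); and
$L \equiv 0$, i.e. log-normal age slices. The choice of $L = 0$ is load
bearing: when the specialized chart is built by moving the median to the
base chart's value at $z = \delta$ (with $S$ unchanged), a child at
specialized-chart z-score $z_{\mathrm{true}}$ sits at standard-chart
z-score *exactly* $z_{\mathrm{true}} + \delta$, so discordance proportions
have closed forms — e.g. $\delta = -1$ puts
$\Phi(-1.88 + 1) = \Phi(-0.88) = 18.9\%$ of the cohort below the standard
chart's 3rd centile. With $L \ne 0$ a cross term $L S \delta z$ breaks the
identity and the recovery checks would hold only approximately.

**BMI consistency.** A simulated child's BMI is *derived* from simulated
weight and height, so the BMI reference cannot be chosen freely. With
$L = 0$, $\mathrm{BMI} = M_w/(M_h/100)^2 \cdot
\exp(S_w z_w - 2 S_h z_h)$; the base BMI reference therefore uses median
$M_w/(M_h/100)^2$ and $S_{\mathrm{bmi}} = \sqrt{S_w^2 + 4 S_h^2 -
4\rho S_w S_h}$ ($\approx 0.086$ at the default latent weight–height
correlation $\rho = 0.7$), which makes the derived BMI z-score exactly
standard normal on the truth chart. For the same reason
`make_reference_pair()` derives the specialized BMI median from the
shifted weight and height medians when no explicit BMI offset is given.

**Cohort defaults.** The generator's defaults emulate the marginals of a
national Down-syndrome cohort: 54% boys; birth weight 2898 ± 513 g
(truncated at 0); gestation 37.7 ± 2.17 weeks (truncated to [22, 43] wk,
the viability-to-post-term range); 78% breastfed; 64% on L-thyroxine; and
chart offsets $\delta_{\mathrm{weight}} = -1$,
$\delta_{\mathrm{height}} = -1.2$ SDS. The offsets are scenario
parameters, not estimates — published growth data for the condition give
no single age-constant offset, and the magnitudes were fixed once as
round values reproducing the qualitative picture (height more shifted
than weight, BMI mildly shifted via the derived curve). Ages follow a
log-normal truncated to [0.1, 18] y with `meanlog = 1.7349`, `sdlog = 1`,
calibrated once so the *truncated* median is 4.85 y, the young-skewed
median such cohorts report; a log-uniform alternative is available but
its median on the same span would be
$\sqrt{0.1 \times 18} \approx 1.3$ y, which understates the age mix.
L-thyroxine is decoupled from growth by default so emitted truth z-scores
are exactly standard normal; setting
`lt_height_sd = c(treated = 0.8, untreated = 1.2)` reproduces the
reported subgroup effect (treated children more often inside the wide
norm because their height-z dispersion is smaller) as an explicit
scenario.

**What the generator does not emulate:** longitudinal trajectories,
age-varying $L$ and $S$, secular trends, measurement error, informative
missingness, or realistic comorbidity co-occurrence. Passing recovery
tests therefore validates the pipeline's *arithmetic and plumbing* on
LMS-consistent data, not the clinical fidelity of any particular chart.

## Numerical choices

* Box–Cox switch at $|L| < 10^{-7}$; continuity across the switch is
  tested to $10^{-6}$ and the z↔value round trip to $10^{-9}$.
* Age interpolation of $L$, $M$, $S$ is piecewise linear between knots
  (knot-exact; no spline overshoot) — a documented choice, since chart
  calculators rarely state theirs. No extrapolation beyond the tabulated
  span, ever; callers see an error or an `in_range = FALSE` flag.
* Percentages: full precision internally; display rounding is half-up
  (26.5 → 27), matching how published tables round.
* Degenerate tables (a zero margin) skip the chi-squared test with a
  warning but still report the percentage-point difference; empty cohorts
  produce a `no_data` report, not an error.
* Prematurity: postnatal age is not gestation-corrected (matching common
  chart practice); gestational age is carried as a covariate so sensitivity
  runs can exclude births ≤ 36 weeks.
* All randomness flows from a single integer seed recorded in every
  output; CLI runs write a manifest echoing their options.

## Problem sizes

The test suite standardizes cohorts of 10,000 for distribution-recovery
checks (binomial SE ≈ 0.17 pp on a 3% proportion), 1,000 × 50 replicates
for the discordance-sign property, and 10,000 random parameter draws for
the round-trip property; the whole suite runs in well under a minute on
one core. The acceptance script uses the same 10,000-child scenario.

## Known limitations

The independence chi-squared on paired classifications is anticonservative
in principle (kept as the default because it mirrors the comparison as
usually published; the paired test is one call away). The approximate
centile-curve scorer has the fixed lower-tail bias described above. The
synthetic charts are internally consistent but not any country's reference;
conclusions about real charts require real LMS tables, which the readers
for the `sex, age, L, M, S` format are designed to ingest directly.
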