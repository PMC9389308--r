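# growthbands

Dual growth-chart assessment of pediatric anthropometry: LMS
standardization, percentile-band classification, and quantification of how
the same cohort is classified differently by two growth references.

## The problem

Children's weight, height and BMI are assessed by converting each
measurement to a standard deviation score (SDS, z-score) against an age-
and sex-specific growth reference. For populations with distinct growth
patterns — the motivating case is Down syndrome — two references compete: a
general-population ("standard") chart and a condition-specific
("specialized") chart. The choice matters clinically: a child in the
normal band of the specialized chart may be far below the 3rd centile of
the standard chart. `growthbands` is for biostatisticians and clinical
researchers who need to standardize a cohort against both charts, classify
children into centile bands, and quantify the discordance.

## The model

A growth reference is represented by the LMS method: three age curves —
Box-Cox power *L(t)*, median *M(t)*, coefficient of variation *S(t)* —
under which

```
z = ((x / M)^L − 1) / (L · S)      (L ≠ 0)
z = log(x / M) / S                 (L = 0)
```

is approximately standard normal. Centiles follow as `100 · Φ(z)`.
Z-scores are classified into bands at the conventional SDS cutoffs −1.88,
−1.66, +1.66, +1.88 (nominally the 3rd/10th/90th/97th centiles): a
five-band scheme (underweight / normal / overweight / obesity; for height,
growth deficiency / high growth) and a headline three-band scheme (below
the 3rd centile / the wide 3rd–97th norm / above the 97th). For each
measure and band, the two charts are compared by the percentage-point
difference and a Pearson chi-squared test on the in-band/out-of-band × chart
table (a paired McNemar variant is provided). A synthetic generator
produces LMS reference pairs with a known SDS offset δ between the charts,
and cohorts with known true z-scores, so the whole pipeline is testable
against normal-theory closed forms.

## Worked example

```r
library(growthbands)

# a synthetic standard chart, and a specialized chart whose medians sit
# 1 SDS (weight) / 1.2 SDS (height) below it
pair <- make_reference_pair(make_base_reference(),
                            delta = c(weight = -1, height = -1.2, bmi = NA))

# a cohort of 386 children that truly follows the specialized chart
sim <- simulate_cohort(simulate_config(n = 386, seed = 20220805), pair)
run <- run_comparison(sim$cohort, pair$standard, pair$specialized)
run$table
#> <band_table> counts (display %):
#>   weight:
#>     under  standard   93 (24)   specialized   15 ( 4)
#>     norm   standard  292 (76)   specialized  363 (94)
#>     over   standard    1 ( 0)   specialized    8 ( 2)
#>   height:
#>     under  standard  104 (27)   specialized   12 ( 3)
#>     norm   standard  282 (73)   specialized  365 (95)
#>     over   standard    0 ( 0)   specialized    9 ( 2)
#>   bmi:
#>     under  standard   23 ( 6)   specialized    9 ( 2)
#>     norm   standard  352 (91)   specialized  363 (94)
#>     over   standard   11 ( 3)   specialized   14 ( 4)
run$comparisons$weight.under
#> <comparison_result> weight, band 'under': 24.1% vs 3.9% (+20.21 p.p.);
#> chi-sq = 65.5, df = 1, p = 5.82e-16
```

Reading: on its own (specialized) chart the cohort shows roughly the
nominal 3% below the 3rd centile, but against the standard chart 24% of
children are classified underweight and 27% growth-deficient — the chart
shift, not the children, produces the excess. `report(run, "out/")` writes the band table
(TSV) and a machine-readable JSON summary. File-based runs are available
through the CLI wrapper (`inst/scripts/growthbands`): `simulate`,
`make-refs`, `standardize`, `compare`.

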