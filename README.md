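# fuzzrisk

Fuzzy FMEA and hybrid multi-criteria risk ranking for expert-elicited
failure-mode registers.

## What it does, and for whom

Risk teams in healthcare (the worked example is post-transplant patient
care) and other safety-critical settings prioritise failure modes with
FMEA: each mode is scored on Occurrence (O), Severity (S) and Detection
(D) and the scores are multiplied into a Risk Priority Number,
`RPN = O × S × D`. When the scores come from an expert panel speaking in
linguistic grades, crisp integers misrepresent the uncertainty, and any
single multi-criteria ranking method imposes its own logic on the result.
`fuzzrisk` addresses both problems:

* **Triangular fuzzy numbers** `(α, β, γ)` carry every rating, weight and
  index; arithmetic is componentwise, and defuzzification uses the
  centroid mean `(α+β+γ)/3` or the graded mean `(α+4β+γ)/6`.
* **Fuzzy RPN**, multiplicative (`frpn_rank()`) or via a **Mamdani
  max–min inference engine** with clipping implication, max aggregation
  and centroid defuzzification (`mamdani_frpn()`).
* **Three fuzzy MCDM rankers** over the O/S/D decision matrix:
  ARAS (utility degree `K_i = S_i/S_0`), VIKOR (compromise index `Q_i`
  with trade-off `v = 0.5`) and WASPAS
  (`K'_i = λ·WSM + (1−λ)·WPM`, `λ = 0.5`).
* **The hybrid ultimate utility index**, the package's centrepiece: the
  three per-method benefit indices (`K_i`, `1−Q_i`, `K'_i`) form a matrix;
  per-column maxima/minima define positive and negative ideal vectors
  `η⁺`, `η⁻`; each failure mode's Euclidean distances `ψ⁺`, `ψ⁻` to the
  ideals are converted into

  `UUI = ψ⁻/Σψ⁻ − ψ⁺/Σψ⁺  ∈ [−1, 1]`,

  and failure modes are ranked by descending UUI — a single ranking that
  blends the logics of all three methods.

Supporting machinery: linguistic rating scales (overridable via JSON), a
seeded synthetic register generator with a known-ground-truth dominance
chain, rank-agreement statistics (Spearman, Kendall, top-k overlap), a
pipeline runner with CSV/JSON/markdown reports, and a CLI.

## Worked example

The packaged fixture `table7` holds the per-method indices of twenty
post-transplant failure modes (FM1 = irregular immunosuppressant use,
FM6 = elapsed cold-ischemia time, ...). The hybrid stage ranks them:

```r
library(fuzzrisk)
t7 <- load_fixture("table7")
hybrid_rank(t7)
#> Hybrid MCDM ranking (ultimate utility index, riskiest first):
#>  fm_id psi_plus psi_minus       uui rank
#>    FM1 0.000000  1.154526  0.132746    1
#>    FM6 0.247142  0.936935  0.090920    2
#>   FM11 0.346938  0.810639  0.069612    3
#>   FM10 0.526939  0.632220  0.036856    4
#>   FM12 0.609973  0.556958  0.022556    5
#>   ...
#>    FM7 1.130652  0.036898 -0.072650   20
#> sum psi+: 14.704329   sum psi-: 8.697286
```

FM1 attains every column maximum, so its distance to the positive ideal
is 0 and it owns the largest share of the negative-ideal distances: it is
the unambiguous top risk (UUI 0.133). FM7 (strenuous activity after
transplant) sits at the other extreme (UUI −0.073). Four failure modes
with identical index rows (FM2/FM3/FM12/FM13) tie exactly and share rank 5
under competition ranking.

The same analysis from raw linguistic ratings:

```r
reg <- load_fixture("table6")          # expert-rated register
report <- run_pipeline(reg)            # F-RPN + ARAS + VIKOR + WASPAS + hybrid
print(report)
render_report(report, "report.csv")
```

Or from the shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","fuzzrisk.R",package="fuzzrisk"))') \
  hybrid --indices inst/extdata/table7_indices.csv --out table8.csv
```

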