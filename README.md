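# clamtox

Multi-biomarker assessment of contaminant toxicity in bivalves — an R
package plus a numbered analysis workflow for the statistical side of a
chronic water-borne exposure experiment (three groups at 0, 1 and 5 µg/L of
bisphenol A, five replicate aquaria of eight clams per group, 21 days), with
endpoints read in the digestive gland:

* **Survival** — Kaplan–Meier product-limit curves per group on daily event
  data (death = event, survivors censored at day 21, individuals pooled
  across aquaria) and a k-group log-rank test with the tied-data
  hypergeometric variance.
* **Biochemical biomarkers** — MDA, GSH, CAT and AChE group means ± SE,
  signed percent change versus control, one-way ANOVA and Tukey HSD with
  compact letter displays.
* **DNA damage (comet assay)** — per-cell endpoints from a one-dimensional
  intensity profile: tail length (µm), tail DNA (%), extent tail moment
  (tail length × tail-DNA fraction), and the percent of tailed cells at a
  configurable tail-DNA cutoff (default 5 %).
* **Histopathology** — the weighted condition index for individual *h*,

  `I_h = Σ_j w_j a_jh / Σ_j M_j`,

  over seven digestive-gland alteration categories *j* with severity weights
  `w_j ∈ {1,2,3}` (vacuolation 1, tubular atrophy 2, tubular necrosis 3,
  hemocyte infiltration 1, brown cells/lipofuscin 1, fibrosis 2,
  intertubular necrosis 3), scores `a_jh ∈ {0,2,4,6}` and
  `M_j = w_j × 6`, so `Σ M_j = 78` and `I_h ∈ [0,1]` classed low
  (≤ 0.30), moderate (≤ 0.60) or high; plus tubule histomorphometry
  (relative lumen and wall area, % of tubule area).
* **Inference utilities** — a studentized-range upper-tail probability by
  numerical quadrature (the reference distribution of Tukey's HSD), ANOVA
  audits from printed sums of squares, and an insert-and-absorb compact
  letter algorithm.

Raw laboratory measurements for this design are not publicly deposited, so
the package ships a calibrated synthetic-data generator
(`default_config()`, `generate_all()`) that emulates every data stream at
the study's published effect sizes; all downstream stages consume plain CSV
tables and work identically on real data with the same schemas.

## Worked example

```r
library(clamtox)

cfg <- default_config(seed = 1)
records <- generate_survival(cfg)
logrank_test(records)
#> Log-rank test: chi-square = 8.297, df = 2, p = 0.01579
#>   group observed expected
#> 1     0        0 1.347483
#> 2     1        0 1.347483
#> 3     5        4 1.305035

km <- km_estimate(records, group = "5")
100 * (1 - km_survival_at(km, 21))
#> [1] 10
```

The log-rank χ² of 8.30 on 2 df (p ≈ 0.016) says the three survival curves
differ beyond chance; the product-limit estimate in the high-dose group,
S(21) = (39/40)(37/39)(36/37) = 0.90, is the 10 % cumulative mortality —
four deaths among forty clams, all at 5 µg/L.

```r
condition_index(c(vacuolation = 2, tubular_atrophy = 4, tubular_necrosis = 0,
                  hemocyte_infiltration = 2, brown_cells = 0, fibrosis = 2,
                  intertubular_necrosis = 6))
#> [1] 0.4358974        # 34/78 -> "moderate"

studentized_range_sf(4.34, 3, 6)
#> [1] 0.04996499       # ~0.05: 4.34 is the k=3, df=6 critical value
```

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end and write
tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # all five data streams -> results/data/
Rscript analysis/02_survival.R        # KM curves, log-rank, mortality
Rscript analysis/03_biomarkers.R      # ANOVA + Tukey + percent changes
Rscript analysis/04_comet.R           # four DNA-damage endpoints
Rscript analysis/05_histopathology.R  # condition index + morphometry
Rscript analysis/06_report.R          # orchestrated report.json
```

Each stage reads only the CSVs of the previous stages, so pointing
`results/data/` at real measurement tables reruns the identical analysis.

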