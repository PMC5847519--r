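# naquant

Quantitative brain sodium (²³Na) MRI from multi-echo acquisitions.

## The problem

Sodium MRI offers a window on ionic homeostasis — the ~140 mM extracellular
vs 10–15 mM intracellular gradient — but ²³Na magnitude signal in tissue
decays *biexponentially*, with a short T2\* component (~0.5–5 ms) from
restricted environments and a long component (~15–55 ms). Single-echo
protocols cannot separate the two, and the rapid short-component decay makes
naïve quantification lose up to 60% of the signal. A multi-echo acquisition
(24 echoes from 0.3 to 100 ms, interleaved over three runs) samples the whole
decay curve, so both components, their signal fractions, and the
concentrations they carry can be estimated per region.

`naquant` implements that analysis for ROI-mean decay curves:

- **Decay model.** Each ROI curve is fitted by bounded multi-start nonlinear
  least squares to

  `S(TE) = sqrt( [A (f e^(−TE/T2*short) + (1−f) e^(−TE/T2*long))]² + Ric² )`

  where `A` is the amplitude, `f` the short-fraction weight and `Ric` the
  Rician noise floor that magnitude images approach at long TE.
- **Calibration.** Agar reference tubes of known concentration (10–75 mM),
  imaged with the subject, are fitted monoexponentially; ordinary least
  squares of tube `M0` on concentration gives the signal-to-mM line.
- **Quantification.** The component magnetizations `M0_SF = A·f` and
  `M0_LF = A·(1−f)` map through the calibration to `Na_SF` and `Na_LF` (mM);
  `TSC = Na_SF + Na_LF` and `EcF = Na_LF / 140 mM`.
- **Group statistics.** Per metric: fixed-effects ANOVA (tissue type or
  region, plus sex and continuous age; Type II sums of squares), Steel–Dwass
  all-pairs nonparametric post-hoc comparisons, and a Bonferroni-corrected
  α = 0.05/6 = 0.008 across the six metrics.
- **Synthetic cohort.** A seeded generator emulates the full study design
  (13 subjects, 5 female, ages 20–32; 10 regions; 24-echo schedule; 6 tubes;
  Rician noise; between-subject spread), so the entire pipeline is testable
  without scanner data.

Intended users: researchers processing multi-echo ²³Na-MRI ROI data, and
methodologists who need a reproducible simulation/fitting testbed for sodium
relaxometry.

## Worked example

```r
library(naquant)

cfg <- cohort_config(seed = 42, snr = 50)   # 13 subjects x 10 regions, 24 echoes
ds  <- simulate_cohort(cfg)

fit <- fit_biexp(subset(ds$curves, subject_id == "S01" & roi == "GM"))
fit
#> biexp decay fit (24 echoes)
#>       A       f     t2s     t2l     ric
#> 91.7590  0.3375  2.8268 24.0861  3.8019
#> r^2 = 0.9950  rss = 65  converged = TRUE

res <- run_pipeline(pipeline_config(seed = 42, cohort = cfg), quiet = TRUE)
res$calibrations$pooled
#> sodium calibration: M0 = 2.034 * C + -0.5946  (r^2 = 0.9998, 6 tubes)

subset(res$summary, roi %in% c("GM", "WM"))
#>  roi stat t2s_ms t2l_ms na_sf_mM na_lf_mM tsc_mM  ecf
#>   GM mean   4.56  31.60    20.67    25.03  45.70 0.18
#>   GM   sd   0.97   4.50     3.72     3.23   3.57 0.02
#>   WM mean   4.20  37.09    22.37    15.86  38.23 0.11
#>   WM   sd   0.88   5.45     2.68     3.75   1.86 0.03

subset(res$stats$posthoc_tissue, metric == "tsc")
#>  metric group_a group_b       z   p_adjusted
#>     tsc      GM      WM 4.25641 2.077354e-05
```

Reading the output: the single-curve fit recovers a grey-matter-like curve
(short fraction 0.34, T2\*short 2.8 ms, T2\*long 24 ms, floor ≈ 3.8 signal
units) with r² = 0.995 at SNR 50. The pooled six-tube calibration is
2.03 a.u./mM. Cohort means land where the generator put them — e.g. GM total
sodium 45.7 mM vs WM 38.2 mM, extracellular fraction 0.18 vs 0.11 — and the
Steel–Dwass test flags the GM–WM TSC difference (z = 4.26; the statistic
saturates at |z| = 4.31 for complete separation of two n = 13 groups).

One curve can also come from a 4D volume plus a mask via `roi_mean_curve()`,
and a thin CLI (`inst/cli/naquant.R`) exposes `simulate`, `fit`, `calibrate`,
`quantify`, `stats` and `run` subcommands over CSV files.

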