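# pckinetics

Kinetic modelling of long-lived plasma-cell (PC) engraftment from
longitudinal serum antibody data.

## The problem

Ex vivo differentiated human plasma cells can be transferred into
immunodeficient mice as a living protein-delivery platform. Whether they
*engraft* — how many cells settle in the bone marrow, and how quickly they
are lost — cannot be observed directly over a year; what can be measured is
the serum concentration of the human IgG they secrete, plus short-term ex
vivo viable counts and single-cell ELISPOT secretion assays. `pckinetics`
estimates the underlying cell kinetics from those readouts.

## The model

PC number `N(t)` and antibody amount `G(t)` follow

    dN/dt = -β N
    dG/dt = γ N - λ G

with decay rate β (1/day), per-cell secretion rate γ (pg/cell/day) and
serum IgG clearance λ (1/day). The closed form

    G(t) = γ N₀ / (λ - β) · (e^{-βt} - e^{-λt})

(limit `γ N₀ t e^{-βt}` at λ = β) is fitted per animal by bounded nonlinear
least squares for the two unknowns: `N₀`, the long-lived PCs retained at
engraftment, and β. γ, λ and the plasma volume are fixed, documented
constants. Observations before day 21 are excluded: they reflect a
short-lived compartment the model deliberately ignores. Half-life is
`ln 2 / β` — a fitted β of 0.005/day corresponds to ~138 days.

Short-term ex vivo cultures use the biphasic survival model

    N(t)/N₀ = e^{-(β₀ t + β₁ t²)}

whose instantaneous rate `β₀ + 2β₁ t` captures rapid early loss (acute
rate β₀) that decelerates (β₁ < 0) toward the long-term rate.

The package also ships the cohort statistics the design calls for (Welch
and paired t, trapezoidal AUC per animal, Pearson correlation, min–max
normalization, t-based mean/CI bands), ELISPOT spot-size distribution
analysis (unit-norm scaling, Gaussian KDE with Scott's rule, per-subject
mean comparisons, per-cell secretion rates), a seeded synthetic cohort
generator reproducing the statistical structure of all three assays, and a
file-based pipeline (`run_pipeline()`) with config-hash-stamped CSV
artifacts.

## Worked example

```r
library(pckinetics)

spec   <- cohort_spec(seed = 42)          # two-arm study: control vs hIL-6
cohort <- simulate_igg_series(spec)       # 15 serum IgG time series
fits   <- lapply(cohort, fit_longterm)    # per-animal (N0, beta)
est    <- fits_to_data_frame(fits,
  conditions = vapply(cohort, `[[`, character(1), "condition"))
hi <- est$condition == "hIL6"

welch_t(est$n0[hi], est$n0[!hi])
#> <group_comparison> Welch two-sample t (two-sided)
#>   t = 4.536, df = 7.918, p = 0.00196 (n = 8 vs 7)

welch_t(est$beta[hi], est$beta[!hi])
#> <group_comparison> Welch two-sample t (two-sided)
#>   t = 1.167, df = 8.974, p = 0.2733 (n = 8 vs 7)

half_life(median(est$beta))
#> [1] 127.8937
```

The two tests read off the study's central finding in miniature: the hIL-6
arm holds significantly more engrafted PCs (p ≈ 0.002), while the decay
rates are statistically indistinguishable (p ≈ 0.27) — hIL-6 acts on
initial retention, not on long-term loss. The half-life implied by the
median fitted decay rate of this 15-animal simulated cohort is ~128 days,
scattered (as per-cohort estimates are) around the generating truth of
138.6 days.

A single fit prints its estimate with goodness-of-fit and provenance:

```r
fits[["hIL6_01"]]
#> <fit_result> longterm model (nls route)
#>   n0 = 4.094e+05 cells, beta = 0.006069 /day
#>   rss = 7.129e+08 over 9 obs on days [21, 365]; converged: TRUE
```

## Layout

- `R/kinetics.R` — closed-form model, derived quantities, biphasic model
- `R/fitting.R` — per-subject nonlinear least-squares estimation
- `R/synthetic.R` — seeded cohort/culture/ELISPOT generators
- `R/cohort_stats.R`, `R/elispot.R` — statistics layers
- `R/io.R` — CSV/config I/O and the end-to-end pipeline
- `vignettes/plasma-cell-kinetics.Rmd` — model assumptions, parameter
  defaults and their rationale, generator scope, numerical choices
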