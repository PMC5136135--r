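# lionlen

Length-based, age-structured growth modelling for invasive lionfish
(*Pterois volitans/miles*), built for the northeast Florida sampling
design but applicable to any fish population with visible annual cohorts
in its length data.

Direct ageing from otoliths is slow and destructive. When recruitment
happens in a short annual pulse, monthly length-frequency histograms
carry enough signal to estimate growth and age composition by themselves:
each month's histogram is a finite normal mixture over age classes whose
means sit on a von Bertalanffy growth curve. `lionlen` fits that model by
maximum likelihood, with

* traditional and seasonalized (Somers) von Bertalanffy growth,
  `L(t) = L∞[1 − exp(−(K(t−t₀) + S(t) − S(t₀)))]`,
  `S(t) = (CK/2π)·sin 2π(t − t_s)`, winter point `t_w = t_s + 0.5`;
* expected bin counts `n_{a,i,t} = N_t · P_{a,t} · P(bin i | N(L̄_{a,t}, σ_a²))`
  summed over age classes 0–3;
* a 2×2 candidate set (seasonal × variable-σ) compared by AICc and
  Akaike weights;
* multi-start bounded ML with an EM-profiled likelihood, plus ±10%
  sensitivity refits and ±25% random-start robustness diagnostics;
* otolith annulus-age reconciliation (`A = t_w + 1 − t_b` at the first
  annulus) and growth-agreement summaries;
* a synthetic-data generator whose defaults state the study design
  (2,137 fish across six months, summer birth pulse at `t_b = 0.41`),
  so every stage is testable without the original data.

Interfaces are tibble-first and pipe-friendly; fitted objects have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(lionlen)

records  <- simulate_length_records(lf_scenario(), seed = 1)  # 2,137 fish
analysis <- fit_candidates(records, n_starts = 2, seed = 1)
analysis$selection
#>                  model neg_log_lik  K   AIC  AICc delta_AICc     weight
#> 1    seasonal_variable      6706.9 32 13478 13487      0.000 1.0000e+00
#> 2       seasonal_fixed      6728.6 29 13515 13522     35.750 1.7258e-08
#> 3 nonseasonal_variable      6724.0 30 13508 13516     28.921 5.2479e-07
#> 4    nonseasonal_fixed      6748.2 27 13550 13557     69.959 6.4353e-16
```

The seasonal model with age-specific dispersion wins with essentially
all the Akaike weight, as it should — the generator is seasonal with
variable σ. Its estimates sit near the generating values
(K = 0.47, C = 0.61, t_b = 0.41):

```r
round(coef(analysis$fits$seasonal_variable), 3)
#>       K       C     t_s     t_b sigma_0 sigma_1 sigma_2 sigma_3
#>   0.481   0.532   0.166   0.431  27.769  27.568  24.041  44.514
```

K is the annual growth coefficient (1/yr) toward the fixed asymptote
L∞ = 448 mm; C = 0.53 means growth slows strongly — though not to
zero — each winter; t_b = 0.43 puts the recruitment pulse in early
June; the σ's are per-age-class length dispersions in mm. Proportions
at age per month, with the sample-size-weighted mean composition:

```r
proportions_at_age(analysis$fits$seasonal_variable, digits = 2)
#>   label         age_0 age_1 age_2 age_3     n
#> 1 2014-04        0.38  0.60  0.00  0.02   850
#> 2 2014-07        0.00  0.58  0.42  0.00    33
#> ...
#> 7 weighted_mean  0.16  0.56  0.22  0.06  2137
```

`autoplot(analysis$fits$seasonal_variable)` overlays predicted on
observed histograms per month; `plot_growth_curves()` draws both growth
forms with otolith size-at-age points from `growth_agreement()`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from the installed package, the headline growth quantities of
the fitted model — traditional size-at-age at ages 1–3, the seasonal
first-summer length at the age where the traditional curve predicts
80 mm, and the maximum observed age from the 3-annulus reconciliation —
and writes them as JSON.
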