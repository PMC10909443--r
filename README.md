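# transjs

Jolly–Seber (POPAN) mark–recapture models for **translocated
populations** whose initial size is known.

## Why

Post-release monitoring of a conservation translocation produces
capture–recapture data with one unusual feature: the first "survey" is
the release itself, where the number of animals is known exactly and
every individual is recorded (capture probability 1). The unconstrained
POPAN formulation of the Jolly–Seber model ignores this and — especially
for small founder groups of cryptic, hard-to-detect animals — can
substantially overestimate abundance in the critical establishment phase,
which is exactly when managers decide whether to reinforce a population.

`transjs` implements a joint likelihood with a separate component for the
translocated cohort: their entry occasion is known (the release), their
release detection is certain, and only wild-born recruits contribute to
the superpopulation `N` and entry proportions `β`. The unconstrained
POPAN model is included as the comparison baseline, along with
maximum-likelihood fitting, derived abundance trajectories, nonparametric
bootstrap confidence intervals, AIC model selection with occasion
covariates (effort, temperature, moon phase), a capture-history
simulator, and a 12-scenario bias study comparing the two model families.

## The model in brief

For wild-born individual *i* with first capture *f* and last capture *δ*,

Pr(hᵢ) = Σ_{b=τ}^{f} Σ_{d=δ}^{T} β_b · Π_{j=b}^{d−1} φ_j · χ(d) ·
Π_{j=b}^{d} p_j^{x_ij} (1−p_j)^{1−x_ij},

with χ(d) = 1−φ_d for d < T and 1 at d = T. Translocated individuals use
the same sum with b = 1 known and no β factor. The joint likelihood is

L ∝ N!/(N−(D−n₀))! · Π_{i≤n₀} Pr(hᵢ*) · Π_{i>n₀} Pr(hᵢ) ·
Pr(h₀)^{N−(D−n₀)},

where D is the number of observed individuals, n₀ the number released
and Pr(h₀) the probability a wild superpopulation member is never seen.
Abundance follows the recursion N_{t+1} = N_t φ̂_t + N̂ β̂_{t+1} with
N₁ = n₀. Links: log (N), logit (monthly φ and p), multinomial logit (β);
uneven intervals enter as φ_monthly^(months).

## Worked example

```r
library(transjs)

# simulate one replicate of a low-detection translocation scenario:
# 30 released into a superpopulation of 500, p in 0.1–0.3,
# 10 six-month occasions, recruits from occasion 4
sim <- simulate_scenario(tjs_scenario(4), seed = 42)
sim$design
#> Translocation JS study design
#>   occasions: 10 (months 0, 6, 12, 18, 24, 30, 36, 42, 48, 54)
#>   tau (first wild entry occasion): 4
#>   individuals: D = 238 observed, n0 = 26 translocated

fit_t <- fit_mle(sim$histories, sim$design, model = "translocation")
fit_s <- fit_mle(sim$histories, sim$design, model = "standard")
rbind(truth = sim$fates$Nt,
      translocation = round(fit_t$abundance, 1),
      standard = round(fit_s$abundance, 1))[, 1:5]
#>               [,1] [,2] [,3] [,4]  [,5]
#> truth         26.0 23.0 20.0 67.0 130.0
#> translocation 26.0 23.1 20.5 68.4 206.8
#> standard      54.8 46.6 39.6 62.2 186.9
```

The standard model's abundance at the release is more than double the
known 26 animals — the release occasion's perfect detection has been
averaged into a constant capture probability — while the translocation
model starts from the known count by construction and tracks the truth
through the pre-recruitment occasions (both models share the sampling
noise of a single low-detection replicate once recruits arrive, as at
occasion 5 here).

Bootstrap intervals and model selection:

```r
ci <- bootstrap_ci(sim$histories, sim$design, model = "translocation",
                   B = 199, seed = 1)
head(ci$abundance)

aic_select(list(tjs_model_spec(name = "p constant"),
                tjs_model_spec(p = ~time, name = "p time")),
           sim$histories, sim$design, "translocation")
```

A thin command-line front end lives in `inst/scripts/transjs`
(`simulate`, `fit`, `bootstrap`, `study`, `select`).

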