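# tgicomb

Pharmacokinetic–pharmacodynamic modelling of tumor growth inhibition
(TGI) in xenograft mice treated with **two anticancer drugs in
combination**.

## The problem

Preclinical combination studies follow a standard design — a control
arm, each drug alone, and the combination — and ask whether the two
drug *effects* interact: is the combination better (synergy), worse
(antagonism), or exactly what the monotherapies predict (additivity)?
Endpoint ratios depend on dose, schedule and measurement day; a
mechanistic model of the whole growth curve is needed to get
compound-specific, design-independent answers.

## The model

Untreated tumor weight grows exponentially at rate λ₀ and then linearly
at rate λ₁ (switching sharpness Ψ).  Each drug kills proliferating
cells in proportion to its plasma concentration (potency k₂) and sends
them through a three-stage death cascade (transit rate k₁).  For a
combination, cells are tracked on a 4 × 4 damage matrix x_ij (damage
stage i under drug A, j under drug B), and the *entire* interaction is
carried by one parameter γ multiplying the concentration product on the
proliferating cells:

    ẋ₀₀ = f_p(w) − (k₂ₐ·c_a + k₂ᵦ·c_b + γ·c_a·c_b)·x₀₀ ,   w = Σ x_ij

γ > 0 ⇒ synergistic, γ < 0 ⇒ antagonistic, γ ≈ 0 ⇒ additive drug-effect
interaction.  Because γ is confounded with potency and exposure, the
comparable summaries are the time-efficacy indexes

    TEI_comb ≈ (k₂ₐ·AUC_a + k₂ᵦ·AUC_b + γ·AUC_ab)/λ₀ ,
    Δ        ≈ γ·AUC_ab/λ₀ ,
    SC = 100·Δ/TEI_comb (Δ>0) ,   AC = −100·Δ/TEI_add (Δ<0) ,

the percentage of the efficacy delay attributable to the interaction
(AUC_ab is the area under the product of the two concentration curves).

Estimation follows the two-stage strategy used in practice: the seven
single-agent parameters are fitted on the control + monotherapy arms
(weighted least squares, 1/y² weights, per-arm normalization), then γ
alone is fitted on the combination arm.  The fitted model transports to
new doses/schedules of the same drugs by pure simulation.

## Worked example

```r
library(tgicomb)

fx  <- experiment_fixture("c1")       # oral drug days 10-12 & 14-16,
                                      # iv partner days 9, 13, 17
pkl <- synthetic_pk_library()         # synthetic mouse PK parameters
dat <- generate_tumor_dataset(default_truth(gamma = 1), fx$regimens,
                              pkl, cv = 0.1, seed = 7)
fit <- tgi_fit(dat, n_starts = 4, seed = 7)
summary(fit)
```

```
Combination tumor growth inhibition model
Call: tgi_fit(data = dat, n_starts = 4, seed = 7)
Fitting strategy: staged (psi = 20)

        Estimate Std. Error     CV%
w0        0.0509     0.0015  2.9091
lambda0   0.1500     0.0023  1.5019
lambda1   0.1478     0.0029  1.9868
k1a       0.8893     0.0810  9.1128
k2a       0.0202     0.0006  2.9943
k1b       0.4759     0.0978 20.5550
k2b       0.0528     0.0026  4.9761
gamma     0.9950     0.0240  2.4086

RMSE (g): monotherapy = 0.04278, combination = 0.00707 
Drug-effect interaction: synergistic
```

The true γ was 1: the staged fit recovers it within its confidence
interval, and the tumor/drug parameters match the generating values
(w0 = 0.05 g, λ₀ = λ₁ = 0.15, k₂ₐ = 0.02, k₂ᵦ = 0.05).  The interaction
indexes and a no-refit prediction of the +33% dose arm:

```r
predict(fit)$indexes          # fitted c1-style arm
predict(fit, regimens = experiment_fixture("c2")$regimens)$indexes
```

```
Drug-effect interaction indexes (closed_form)
  gamma    = 0.995 /uM^2/day^2
  TEI_comb = 20.87 days   TEI_add = 12.39 days
  Delta    = 8.486 days
  SC = 40.66 % (synergistic contribution to TEI_comb)
  classification: synergistic
```

(Exact numbers vary with the seed; these are from the call shown.)
A command-line front-end is available after install as `exec/tgicomb`
(`simulate-experiment`, `pipeline`, `recover`), and `run_pipeline()`
drives the whole workflow from one YAML configuration.

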