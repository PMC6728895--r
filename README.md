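# lprm

Item-trait pattern recognition for replenished items in multidimensional
computerized adaptive testing (MCAT).

When an adaptive-test item pool is replenished with new pretest items,
each new item must be assigned an item-trait pattern — the subset of the
K latent traits it measures, i.e. the support of its discrimination
vector under the compensatory multidimensional two-parameter logistic
model (M2PLM),

    P(Y = 1 | θ, a, b) = exp(aᵀθ + b) / (1 + exp(aᵀθ + b)).

`lprm` is aimed at psychometricians and measurement researchers studying
this item-replenishment problem. It implements a three-step LASSO-based
recognition procedure and the simulation machinery around it:

1. **MCAT administration** — adaptive selection of operational items by
   D-optimality or Bayesian A-optimality, MAP trait scoring, fixed-length
   or posterior-SE variable-length stopping, and group-wise
   administration of the replenished items (whose responses never enter
   the trait estimates).
2. **L1-penalized logistic fits** — for each replenished item, cyclical
   coordinate descent minimizes −ℓ(b, a; Y, Θ̂) + λ Σₖ|aₖ| along the
   penalty grid λ_w = wT/W (defaults T = 120, W = 80); the support of
   each solution is a candidate pattern.
3. **BIC pattern selection and relaxed refit** — the Bayesian
   information criterion (−2ℓ + df·log n) picks the optimal pattern along
   the path, and the item parameters are re-estimated without penalty
   under the detected pattern.

Evaluation indices cover pattern accuracy (correct specification rate),
ability and item-parameter recovery (AME/RMSE), and operational-item
exposure (chi-square statistic and test overlap ratio). Shipped design
presets reproduce two-dimensional (900 + 30 items) and three-dimensional
(910 + 35 items) study pools with moderate U(0.7, 1.3) or high
U(1.1, 1.7) discriminations and N = 2000 examinees.

## Worked example

```r
library(lprm)

design <- design_preset("study1_high")   # 2D pool, a ~ U(1.1, 1.7)
cfg <- run_config(design, criterion = "D", replications = 3,
                  base_seed = 20190830)
report <- run_study(cfg)
report$aggregate
#>      csr ame_theta rmse_theta   ame_a  ame_b chi_square    tor mean_length
#> 1 0.9889    0.2046     0.2577 0.09211 0.1078      232.3 0.3133          50
```

Reading the row: the procedure recovered 98.9% of the 30 × 2 pattern
entries of the replenished items (`csr`); MAP ability estimates deviate
from the truth by 0.205 on average with RMSE 0.258 over the 2000 × 2
entries; the refitted replenished-item discriminations and intercepts
are off by 0.092 and 0.108 on average; and the exposure chi-square
(232.3) and test overlap ratio (0.313) show the usual concentration of a
greedy deterministic selection rule without exposure control.

The pattern-recognition step can also be run alone on user-supplied
tables with `detect_patterns()` (long response table + trait-score
table), and `inst/scripts/lprm.R` wraps both entry points for shell use:

```sh
Rscript inst/scripts/lprm.R run --design study1_high --criterion D \
    --stopping fixed:50 --grid 120:80 --replications 5 --seed 20190830 \
    --out results/
Rscript inst/scripts/lprm.R detect --responses responses.csv \
    --scores scores.csv --out patterns/
```

## Package layout

- `R/m2plm.R` — model probabilities, likelihoods, Fisher information,
  response simulation, item-pool container and CSV serialization.
- `R/design.R`, `R/generate.R` — study designs, presets, item-pool and
  ability generators, replenished-item group assignment.
- `R/mcat.R`, `src/administer.cpp` — MAP scoring, selection criteria,
  stopping rules; the compiled cohort engine mirrors the pure-R
  reference functions exactly.
- `R/lasso.R` — penalty grid, coordinate-descent L1 solver, KKT
  certificates, path fitting, BIC selection, relaxed refits,
  `detect_patterns()`.
- `R/evaluation.R` — CSR, AME/RMSE, exposure chi-square, overlap ratio.
- `R/study.R` — seeded replications, study aggregation, manifests.

See the vignette
(`vignettes/pattern-recognition-methods.Rmd`) for the model, the
numerical choices and their rationale, and known limitations.
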