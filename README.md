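# mhamfd — health-insurance fraud detection with hierarchical graph attention

Organised health-insurance fraud is hard to see in any single claim but
easy to see in *joint behaviour*: groups of card holders visiting the
same department on the same day, or collecting the same medicines in
lockstep. `mhamfd` is an R package for analysts of claim data that
models a visit table as an attributed heterogeneous information network
(Patient / Time / Medicine / Department), decomposes it into
patient–patient behavioural-relationship graphs, and classifies
patients semi-supervised with a three-tier attention network whose
weights are interpretable.

## The model

Two patients are neighbours under a behavioural relationship
`X ⊆ {D, T, M}` when one visit of each jointly agrees on every entity
type in `X` (same department for D, same date for T, intersecting
medicine sets for M). The seven relationships — PDP, PTP, PMP (single
level), PDTP, PDMP, PTMP (dual), PDTMP (triple) — each yield a patient
graph. Aggregation runs in three tiers:

1. **Neighbour attention** (per relation, K = 8 heads): pair scores
   `e_ij = LeakyReLU(aᵀ[W x_i ‖ W x_j])` (slope 0.2), softmaxed over
   the attended set into `α_ij`; head output `ELU(Σ_j α_ij W x_j)`,
   heads concatenated to a 64-dim relation embedding `x^l`.
2. **Relation attention** (per level): scores
   `ω_l = mean_i q₀ᵀ tanh(W₀ x_i^l + b₀)`, softmaxed within the level
   into weights `β`, level embedding `x_m = Σ β_l x^l`.
3. **Level attention**: the same form with `(W₁, b₁, q₁)` gives level
   weights `γ` and the final embedding `H = Σ γ_m x_m`, classified by a
   small multilayer perceptron trained end-to-end.

Training is transductive full-batch Adam (lr 0.005, L2 weight decay
0.001, dropout 0.6, early-stopping patience 50), with gradients derived
analytically; the per-relation kernels are compiled (RcppArmadillo).
The fitted `β` and `γ` report which relationships and which level of
relationship drive the classification.

Because real claim data of this kind is private, the package includes a
synthetic generator that plants fraud rings through shared co-visit
events on top of uniform background visits, with attribute features
that carry no label signal — so recovered skill is attributable to
graph structure alone.

## Worked example

```r
library(mhamfd)

sim <- simulate_claims(seed = 1)            # 300 patients, 1:2 fraud ratio
X   <- simulate_features(sim$labels, seed = 1)  # pure-noise attributes
fit <- mhamfd(sim$claims, X, seed = 1)
print(fit)
#> Hierarchical-attention fraud detection model
#>   300 patients (100 fraud / 200 non-fraud / 0 unlabelled), 7 relations
#>   trained 292 epochs (best at 242), class weights 1.00/1.00
#>   test: f1 0.9524  accuracy 0.9667  precision 0.9091  recall 1.0000
#>   level attention (gamma):  level1=0.257  level2=0.670  level3=0.073
```

The test F1 of 0.95 is earned from structure alone — a features-only
logistic baseline on the same split reaches F1 0.21
(`baseline_logistic(X, unname(fit$labels), fit$split)`). The level
attention peaks on the dual level (`γ₂ = 0.67`): relationships that
combine two shared entity types (department + date, …) are sparse
enough to be selective and dense enough to be informative, which is
exactly the regime the planted rings occupy. Inspect per-relationship
weights with `coef(fit)`, fitted fraud probabilities with
`predict(fit)`, training curves and attention barplots with
`plot(fit)`, and the fraud-rate lift by fraudulent-neighbour count with
`lift.mhamfd(fit)`.

Lower-level entry points mirror the pipeline stages: `read_claims()` /
`write_claims()`, `build_hetero_graph()`, `build_all_relation_graphs()`,
`split_nodes()`, `train_model()`, `evaluate()`, `fraud_lift_analysis()`.
A command-line front end (`inst/scripts/mhamfd.R`) exposes
`simulate`, `build-graphs`, `train`, `evaluate` and `report`
subcommands with `--config`, `--seed` and `--out-dir`.

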