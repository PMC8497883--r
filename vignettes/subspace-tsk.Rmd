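---
title: "Subspace-clustered TSK fuzzy classifiers: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subspace-clustered TSK fuzzy classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tskfs)
```

## The model

A first-order TSK fuzzy classifier is a set of `K` rules. Rule `k` pairs a
fuzzy antecedent — one Gaussian membership function per feature, with center
`v_i^k` and variance-like spread `σ_i^k` — with a linear consequent
`f^k(x) = p_0^k + Σ_i p_i^k x_i`. An input fires rule `k` with strength
`μ^k(x) = Π_i exp(−(x_i − v_i^k)² / (2 σ_i^k))`, the product running over the
rule's *active* features only; strengths are normalized across rules and the
system output is `y(x) = Σ_k μ̃^k(x) f^k(x)`. For binary classification the
labels are encoded `{−1, +1}` and the sign of `y(x)` is the decision; the
positive class is the lexicographically larger label unless overridden.

Because `y(x)` is linear in the stacked consequent vector once the
antecedents are fixed, consequent learning is a single ridge least-squares
problem over the "design vector" formed by concatenating, per rule, the
normalized firing strength times `(1, x_active)`. The two routes to `y(x)` —
rule-wise weighted sum and design-vector inner product — are algebraically
identical, and the test suite holds them to `1e-10` against one another.

## Antecedent learning by feature-weighted subspace clustering

Antecedents come from a fuzzy clustering with per-cluster feature weights.
The criterion

`J = Σ_c Σ_i μ_ci^m Σ_j w_cj (x_ij − v_cj)² + Σ_c δ_c Σ_j w_cj²`

is minimized under column-stochastic memberships `U` and row-stochastic
weights `W`. The four update rules are coordinate steps: the weight row is a
diagonal quadratic over the simplex (solved exactly; see *Numerical choices*),
memberships follow the familiar inverse-distance form with exponent
`1/(m−1)`, centers are membership-weighted means (the feature weight cancels
between numerator and denominator; the cancelled form avoids 0/0 when a
weight reaches zero), and the per-cluster regularizer `δ_c` is re-calibrated
to the ratio of the cluster's weighted scatter to its squared-weight mass, so
the penalty term tracks the scatter term in magnitude.

After convergence, rule `k`'s Gaussian center is the membership-weighted mean
of the data (membership exponent 1) and its spread is `h` times the
membership-weighted squared deviation. Features whose fitted weight `w_kj`
reaches the threshold `τ` are activated for rule `k`; an empty mask falls
back to the rule's single maximum-weight feature, so every rule keeps at
least one clause.

## Tunable parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `n_rules` (`K = C`) | rules = clusters | 15 | the motivating study's setting |
| `fuzzifier` (`m`) | membership softness | 2 | `m → 1⁺` hardens the partition |
| `tolerance` (`ε`) | stop when `|ΔJ| < ε` | `1e-5` | absolute, on the objective |
| `max_iter` | sweep cap | 300 | rarely reached |
| `spread_scale` (`h`) | antecedent width multiplier | 0.5 | spreads scale linearly in `h` |
| `threshold` (`τ`) | feature activation cutoff | 0.06 | `τ = 0` keeps every feature (the unreduced first-order system) |
| `ridge` (`λ`) | consequent penalty | `1e-4` | the design matrix is rank-deficient when rules overlap heavily |
| `seed` | center initialization | 0 | part of the public contract: same data + config ⇒ identical model |

Model complexity (MC) counts `2 d_k` antecedent parameters plus `d_k + 1`
(reduced mode) or `d + 1` (full mode) consequent parameters per rule.
Reduced mode is the default: it is the accounting under which a 15-rule base
with activated-feature counts `1,3,1,1,5,1,1,1,4,2,1,1,3,5,1` totals 108
parameters, against 690 for the all-active baseline. Full mode is available
to mirror rule tables that print all `d + 1` coefficients per rule
regardless of the antecedent length.

## Algorithmic structure and numerical choices

**Two-phase fitting.** `fit_subspace_clustering()` first runs a plain
fuzzy-c-means warm start — memberships and centers only, weights frozen at
`1/d` — until the objective stabilizes, then calibrates `δ` and begins the
weighted sweeps (order: weights, regularizers, memberships, centers). The
warm start matters: under a diffuse partition the most separating features
have the *largest* apparent within-cluster dispersion, so starting the weight
updates immediately suppresses exactly the features the clusters live on.
Localizing the partition first removes that failure mode; with
`warm_start = FALSE` the raw behavior is available.

**Exact simplex step for the weights.** The analytic weight update can go
negative. The weight subproblem is `min Σ_j w_j b_j + δ Σ_j w_j²` on the
simplex — a diagonal quadratic — whose exact solution is the Euclidean
projection of the unconstrained target onto the simplex (sort-and-threshold).
The package uses that projection rather than clipping-and-renormalizing:
the projected row is the true constrained minimizer, coincides with the
analytic update whenever that is nonnegative, and is what the oracle tests
verify against independent numerical optimization at `1e-6`.

**Transient objective increases.** The `δ` re-calibration is *not* a descent
step on `J` (`J` is increasing in each `δ_c`), so `J` can tick up at sweeps
where the partition reorganizes; on random instances the increases are small
(order `1e-3`) and vanish as the fit settles, and the stopping rule — the
absolute change of `J` between sweeps — is unaffected. The weight, membership
and center steps are exact coordinate minimizers. Tested corollary: with the
weights frozen uniform the membership/center iteration is exactly textbook
fuzzy c-means (agreement to `1e-8` per sweep against an independent
implementation).

**Degenerate inputs.** Zero weighted distance gives crisp membership, split
equally over tied centers (the limit of the update). Empty clusters are
reseeded at the sample farthest from its best current center. `δ` is floored
at `1e-12`, spreads at `1e-8` (constant features within a cluster). Firing
strengths are accumulated in log space and normalized by max-subtraction, so
inputs far from all rules still yield well-defined normalized strengths
(uniform `1/K` in the all-degenerate limit). The unpenalized consequent solve
(`λ = 0`) uses QR; unidentifiable coefficients in a rank-deficient design are
zeroed with a warning.

**Consequent estimation as regression.** Classification fitting regresses the
encoded labels on the design matrix. Because the system is linear in its
consequents, parameter-recovery studies instead regress on a generating
model's real-valued output (`fit_consequents(..., targets = )`); the sign
alone cannot identify the coefficients.

## Linguistic rendering

Rule centers are min–max normalized by each feature's training range and
mapped through five equal-width bins to the terms *Low, Lower, Medium,
Higher, High* (this slightly unusual order is kept deliberately; supply a
custom `linguistic_scale()` to change terms or cut points). Term assignment
is inherently a domain-expert judgment; the package ships this deterministic
default so that rendered rule bases are reproducible, not to claim clinical
semantics. Centers outside the training range clamp to the extreme terms;
zero-range features map to *Medium* with a warning.

## Synthetic data: what it emulates and what it does not

`generate_subspace_clusters()` plants the structure the method assumes: each
cluster is tight (variance 0.01 by default) on its own small feature subset,
with cluster-specific centers displaced from a shared broad noise background
(variance 1, separation 5; offsets `c · separation` with alternating signs so
no planted center coincides with the background mean). Ground truth —
assignments, centers, informative masks — is returned with the data.
`generate_tsk_labeled_data()` draws inputs around a known model's rule
centers and labels them by the sign of the (optionally noise-perturbed)
system output, recording the clean scores for margin filtering.
`generate_adni_like_table()` is a 200 × 15 positive-valued demonstration
table with 15 unequal latent clusters and parity labels, mirroring the shape
of a region-mean intensity table after feature selection.

These generators make recovery tests well-posed (Gaussian families match the
Gaussian membership assumption) but are idealizations: real region-mean
intensity features are correlated across regions, class effects are not
aligned with single clusters, and sample sizes and effect sizes of real
cohort data are not emulated. Passing recovery tests therefore demonstrates
the correctness of the estimation machinery, not expected performance on
clinical data.

## Problem sizes used in the shipped tests

Oracle comparisons run on instances up to `C = 3, d = 4, N = 10`; property
checks use a few hundred samples and up to 15 clusters; the weight-recovery
study uses `N = 300, d = 10, C = 3` over five seeds. These sizes were chosen
so the full suite exercises every code path in well under typical developer
patience while keeping the statistical claims sharp.

## Known limitations

- The adaptive regularizer makes the objective sequence non-monotone at
  reorganization sweeps (see above); convergence is monitored by `|ΔJ|`, not
  by descent.
- With `m = 2` and many clusters on weakly separated data, fuzzy memberships
  can stay diffuse and rule centers collapse toward the grand mean — rules
  then all read "Medium". This is a property of soft partitions, not of the
  implementation; fewer rules or better-separated data sharpen the rule base.
- Only binary classification is supported; rule-count reduction and
  multi-class extensions are out of scope.
- The ROI extractor assumes the volume and atlas are already on the same
  grid; no registration, resampling or smoothing is performed.
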