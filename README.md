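# tskfs — interpretable TSK fuzzy classifiers with subspace-clustered antecedents

`tskfs` trains first-order Takagi–Sugeno–Kang (TSK) fuzzy classifiers for
binary recognition tasks on tabular features — the motivating setting is
dementia recognition from region-mean PET intensities, where each sample is a
vector of atlas ROI averages and the two classes are patients and controls.
Unlike black-box classifiers, a TSK system is a set of human-readable rules

```
Rule k:  If x_1 is A_1^k ∧ … ∧ x_d is A_d^k
         then f^k(x) = p_0^k + p_1^k x_1 + … + p_d^k x_d
```

whose output is the normalized-firing-strength-weighted sum of the per-rule
linear consequents, `y(x) = Σ_k μ̃^k(x) f^k(x)`. With many features the
antecedents become long and the interpretability argument collapses. The
package addresses this with **feature-weighted fuzzy subspace clustering**
for antecedent learning: clusters (one per rule) are fitted by alternating
minimization of

```
J(U, V, W) = Σ_c Σ_i μ_ci^m Σ_j w_cj (x_ij − v_cj)² + Σ_c δ_c Σ_j w_cj²,
             s.t.  Σ_c μ_ci = 1,   Σ_j w_cj = 1
```

so each cluster `c` carries its own feature-weight vector `w_c` on the
probability simplex. Features whose weight reaches a threshold `τ` are
*activated* for the corresponding rule; the rest are dropped from its
antecedent (and, in reduced mode, from its consequent). Antecedents are
Gaussian membership functions with centers and variance-like spreads taken
from the membership-weighted moments of each cluster (spread scale `h`);
consequents are fitted by ridge least squares over normalized firing
strengths. A model-complexity (MC) count — 2 antecedent parameters per
activated feature plus `d_k + 1` consequent parameters per rule — quantifies
the interpretability gain, and the rule base can be rendered with linguistic
terms (*Low, Lower, Medium, Higher, High*) assigned from min–max-normalized
rule centers.

## Worked example

```r
library(tskfs)

tab   <- generate_adni_like_table(seed = 42)       # 200 x 15, two classes
model <- fit_tsk_classifier(tab, n_rules = 15, threshold = 0.09, seed = 0)
model
#> <tsk_classifier> 15 rules, 15 features, tau = 0.09, mode = reduced
#>   classes: case (-1) vs control (+1)
#>   model complexity: 219 parameters

accuracy(classify(tab, model), tab$labels)
#> [1] 0.945

render_rule_base(model, data = tab)
#> Rule 1: If x4 is Lower  then  f(x) = [-11.0130, 0.1624]
#> Rule 2: If x1 is High ∧ x7 is Low  then  f(x) = [-13.0617, 0.1089, -0.0331]
#> Rule 3: If x7 is High ∧ x10 is Low ∧ x13 is Low ∧ x14 is High  then  f(x) = [...]
#> ...
```

At threshold 0 the same pipeline keeps all 15 features in all 15 rules — the
unreduced first-order TSK system with `15·(2·15) + 15·16 = 690` parameters —
and fits the training data perfectly; raising the threshold shrinks the rule
base (here to 219 parameters, rules with 1–8 antecedent clauses) at a small
accuracy cost. `model_complexity()` prints the per-rule accounting,
`write_model()` / `read_model()` round-trip fitted models through JSON at
full float precision, and `fisher_score_select()` and
`extract_roi_features()` cover the table-preparation steps (univariate
feature selection; pooling a NIfTI intensity volume over an integer label
atlas on the same grid).

A command-line wrapper with subcommands `fit`, `predict`, `rules`,
`complexity` and `synth` is installed at `exec/tskfs`; see `?cli_main`.

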