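---
title: "Weighting and scoring hierarchical One Health indicator frameworks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighting and scoring hierarchical One Health indicator frameworks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohindex)
```

## The model

`ohindex` computes weights and composite scores for a three-level indicator
hierarchy: first-level domains (human, animal, environmental health in the
packaged index), second-level indicator groups, and third-level leaf
indicators. Weights are *local*: each node's weight is its share within its
sibling group, so every sibling group sums to 1 and a node's global weight
is the product of the local weights along its path.

Three weighting conventions coexist, mirroring how such indices are built
in practice:

* first- and third-level siblings are weighted **equally** (`1/n`) — at the
  top because the domains are deliberately treated as equal pillars, at the
  bottom because leaf-level expert elicitation would be impractical (the
  packaged index has 61 leaves);
* second-level groups get the **integrated** weight
  $W = \beta\,W^{\mathrm{subj}} + (1-\beta)\,W^{\mathrm{obj}}$.

### Subjective weights: fuzzy AHP by row geometric means

Each expert compares every unordered pair of indicators within a group,
giving a judgment matrix $R = (r_{ie})$ with $r_{ie} r_{ei} = 1$ (ratio
scale). The group weight vector is the normalised row geometric mean

$$\omega_i = \frac{\left(\prod_e r_{ie}\right)^{1/a}}
                  {\sum_k \left(\prod_e r_{ke}\right)^{1/a}},
  \qquad W_i = \frac{\omega_i}{\sum_e \omega_e},$$

where the second normalisation is idempotent after the first (asserted in
the tests) but kept because the two steps are conventionally stated
separately. For a perfectly consistent matrix $r_{ie} = w_i / w_e$ this
recovers $w$ exactly, which is the central correctness oracle of the test
suite.

**Scale.** The elicitation scale is not fixed by the method; the package
defaults to the reciprocal 1–9 (Saaty-style) convention and also accepts
complementary 0.1–0.9 fuzzy-preference matrices ($r_{ie} + r_{ei} = 1$,
diagonal 0.5), which are converted to ratio form by
$b_{ie} = r_{ie}/r_{ei}$ before the row geometric means. Both scales are
tested; nothing downstream depends on which one the questionnaire used.

**Panel pooling.** A panel of judgment matrices is pooled by element-wise
*geometric* mean before weighting. This is the only mean that preserves
reciprocity exactly, and pooling consistent matrices that share a weight
vector returns a consistent matrix with the same weights. An alternative
mode (`panel_weights(..., pool = "weights")`) weights each expert first and
averages the weight vectors; at realistic noise the two agree to a few
thousandths, and the mode exists for exactly that sensitivity check.

**Diagnostics.** `consistency_ratio()` implements the standard principal
eigenvalue index $CI = (\lambda_{\max} - a)/(a - 1)$ scaled by the Saaty
random index. It is defined for the reciprocal form only; order-2 matrices
are always consistent and return 0.

**Numerical guards.** Entries are clipped to $[10^{-6}, 10^{6}]$ before
logs (with a warning) so a malformed questionnaire cannot produce
`-Inf`/`Inf` weights.

### Objective weights: entropy weight method

Given $m \ge 2$ entities and a group of $n$ indicators with raw values
$x_{ij}$, each column is min–max standardised,

$$r_{ij} = \frac{x_{ij} - x_{j\min}}{x_{j\max} - x_{j\min}}
  \quad\text{(benefit)},\qquad
  r_{ij} = \frac{x_{j\max} - x_{ij}}{x_{j\max} - x_{j\min}}
  \quad\text{(cost)},$$

turned into shares $P_{ij} = r_{ij} / \sum_i r_{ij}$, scored by normalised
Shannon entropy $e_j = -\tfrac{1}{\ln m} \sum_i P_{ij} \ln P_{ij}$, and
weighted by $W_j = (1 - e_j) / \sum_k (1 - e_k)$: the less even an
indicator's cross-entity profile, the more it discriminates and the more
weight it earns. Orientation (benefit vs cost) is required metadata — it
cannot be inferred from data.

Conventions for degenerate inputs, chosen so "no variation ⇒ no weight"
holds throughout:

* $0 \ln 0 := 0$ (the entropy limit; no epsilon shift). An optional
  `epsilon = TRUE` mode adds $10^{-12}$ before the shares for comparison
  with implementations that avoid exact zeros; on non-degenerate data the
  two agree to ~$10^{-6}$.
* A constant raw column is standardised to 0.5 everywhere (uniform shares,
  entropy 1, weight 0), with a warning.
* An all-zero standardised column is treated as uniform ($e_j = 1$), with a
  warning.
* If *every* entropy equals 1 the weight formula degenerates; uniform
  weights are returned with a warning.

Entropy weights are computed independently within each first-level sibling
group, matching the per-group weight columns of the packaged index.

**A flagged inconsistency in the published table.** The packaged weight
table prints per-group entropy values between 1.13 and 2.01, which is
impossible for a Shannon entropy normalised by $\ln m$ (bounded by 1).
Whatever scale produced them, applying $W_j = (1-e_j)/\sum(1-e_j)$ to the
printed values *as printed* reproduces the printed entropy weights — all
$1 - e_j$ share a sign, so the normalised weights are positive. The package
therefore implements the entropy formula as written (its outputs are always
in $[0,1]$, asserted property-style in the tests), accepts out-of-range
printed values in `entropy_weight_vector()` without endorsing their scale,
and reproduces the printed weight column within the propagation of the
table's two-decimal rounding. For one group (animal health) that rounding
propagation genuinely exceeds a flat 0.2 percentage points — its
$\sum(1-e_j) \approx -2.17$ is small, so $\pm 0.005$ on each printed
entropy can move a weight by about $\pm 0.25$ pp; the printed table even
assigns two indicators the identical entropy 1.13 but different weights
(5.77 vs 5.81). The tests assert agreement within the *enumerated*
worst-case rounding bound per group and explicitly record the animal-health
deviation rather than hiding it. The raw country dataset behind these
entropies was never published, so the entropy column cannot be regenerated
end-to-end; this is the package's main irreducible gap.

### Integration and the preference coefficient

The integrated weight is the convex combination
$W = \beta W^{\mathrm{subj}} + (1-\beta) W^{\mathrm{obj}}$. $\beta$ is
chosen by minimising

$$Z(\beta) = \sum_i \left(W_i - W^{\mathrm{subj}}_i\right)^2
           + \left(W_i - W^{\mathrm{obj}}_i\right)^2
         = \|W^{\mathrm{subj}} - W^{\mathrm{obj}}\|^2
           \left[(1-\beta)^2 + \beta^2\right],$$

whose minimiser is $\beta = 1/2$ for any two distinct weight vectors. A
*linear* (unsquared) deviation objective is sometimes written down in this
context, but it has no interior minimiser — it is affine in $\beta$ — so
the squared form, which is also what "sum of squared deviations" describes
and what $\beta = 0.5$ requires, is implemented. `optimal_beta()` computes
the minimiser numerically (golden-section search by default, with grid and
closed-form-from-evaluations methods as cross-checks) rather than returning
a constant; identical input vectors make $Z$ flat, in which case 0.5 is
returned by convention with a `flat` attribute.

With $\beta = 0.5$, integration is the plain mean of the two weight
columns, and recomputing the packaged index's integrated column from its
printed subjective and objective columns reproduces it to two decimals for
all 15 groups (half-way cases like 14.265 and 33.915 land within the
$\pm 0.01$ print-rounding band).

### Composite scores

`score_entities()` standardises leaf data (cost indicators reversed, so 1
is always best) and aggregates bottom-up by linear weighted means at each
level. Linear aggregation matches the additive semantics of the weights and
pins the anchors: an entity best on every indicator scores exactly 100, an
entity worst on every indicator exactly 0, and improving any indicator can
never lower a composite. Anchors default to the supplied entity pool
(relative scoring); fixed external anchors can be passed for absolute
benchmarking, in which case out-of-range values are clamped. The original
index publication stops at weights and never scores countries, so this
module is forward-looking plumbing consistent with the framework, not a
reproduction of published scores.

## The framework fixtures and revision semantics

The packaged final framework (3 domains / 15 groups / 61 leaves) is stored
as both JSON and CSV with two-decimal `weight_percent` values exactly as
printed; internal arithmetic uses full-precision fractions, and frameworks
loaded from percentage tables are validated with a sibling-sum tolerance of
$5 \times 10^{-4}$ (groups of sevenths print as $7 \times 14.28 = 99.96$).
Note the printed 14.28 for $1/7 = 14.2857\%$ shows the source table
truncated rather than rounded; `equal_weight_allocation()` always returns
exact fractions and leaves presentation rounding to presentation code.

The pre-review framework (3/19/79) and the revision log connecting the two
are also packaged. The published record names every deleted leaf and every
group-level change but *not* which group each deleted leaf belonged to; the
initial fixture reconstructs plausible placements (e.g. the hepatitis code
under infectious diseases, the eight welfare/law codes under animal
welfare) and is documented as a reconstruction, not a published table. Two
conventions were needed where the record is silent: a merged group inherits
the union of its sources' leaves (re-coded under the destination), and
after revisions every sibling group whose membership changed is reset to
equal weights by default (`reweight = "equal"`), since group weights are
recomputed downstream anyway; `"renormalize"` and `"none"` modes are
available.

## The synthetic world

The simulators state a world and keep it fixed; they are first-class,
tested code, not throwaway fixtures.

**Expert panels.** `expert_panel_spec()` defaults to the published study's
geometry: 42 experts judging three groups of 6, 4 and 5 second-level
indicators, with the published subjective weight columns (normalised) as
the true priorities. Each simulated judgment is the true ratio perturbed by
multiplicative log-normal noise,
$r_{ie} = (w_i/w_e)\,e^{\varepsilon},\ \varepsilon \sim N(0, \sigma^2)$,
which keeps matrices exactly reciprocal — the standard perturbation model
for ratio judgments. The default $\sigma = 0.1$ represents a coherent
panel; at that level a 42-expert consensus recovers the truth with RMSE
about $10^{-3}$, far inside the 0.05 acceptance band, and $\sigma = 0$
recovers it to machine precision. What the generator does *not* emulate:
systematic inter-expert disagreement (bimodal panels), correlated errors
within an expert, or intransitive preference structure — a green recovery
test therefore establishes the estimator's correctness under honest noise,
not robustness to a conflicted panel.

**Indicator data.** `indicator_data_spec()` draws independent columns from
a per-indicator family with stated location and dispersion; the default is
log-normal with $m = 150$ entities, a realistic country-panel size and
skewness. The family choice is load-bearing: for any location-scale family
(normal, uniform), min–max standardisation absorbs location and scale
entirely, so dispersion differences would be *invisible* to the entropy
method by construction — the often-quoted "more dispersion ⇒ more weight"
behaviour is a statement about distributional shape. Log-normal dispersion
changes shape, and with it the entropy, which is why the
dispersion-monotonicity property is tested on the log-normal generator
(and holds across all tested seeds), while exact affine-invariance of the
whole chain is tested separately. Real country data additionally have
missingness, outliers and cross-indicator correlation, none of which the
generator models (imputation and winsorisation are out of scope).

All randomness flows from a single integer seed per spec; generators
restore the global RNG state, and identical specs give byte-identical
output.

## Known limitations

* The published subjective weights cannot be re-derived from raw data (the
  42 questionnaires are unpublished), nor the entropy values (the country
  dataset is unpublished); the package validates those stages by parameter
  recovery on its own simulators and validates the published *integration*
  arithmetic exactly.
* The comparison scale and panel-pooling rule behind the published
  subjective weights are unstated; the package's defaults (reciprocal
  scale, geometric-mean pooling) are documented conventions.
* Composite scoring is pool-relative unless external anchors are supplied;
  scores from different entity pools are not comparable.
* The structure/process/outcome category tags are carried as inert
  metadata; no computation uses them.
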