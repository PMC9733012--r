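# ohindex

Tools for building, weighting and scoring hierarchical composite
health-indicator frameworks — the kind used to track joint human, animal and
environmental ("One Health") development across countries.

Composite health indices face a standard problem: purely expert-driven
weights inherit the panel's subjectivity, while purely data-driven weights
ignore domain judgment. `ohindex` implements the combined approach used for
the global One Health intrinsic-drivers index (GOH-IDI):

* **Framework model.** A three-level indicator tree (domains → indicator
  groups → leaf indicators) with validation, JSON/CSV serialisation, and
  add / delete / merge / rename revision operations of the kind an expert
  review applies. The GOH-IDI framework (3 domains, 15 groups, 61 leaves)
  ships as a fixture, together with its pre-review form (3/19/79) and the
  revision log connecting them.
* **Subjective weights (FAHP).** Expert pairwise-comparison questionnaires
  become reciprocal judgment matrices `R = (r_ie)`; a panel is pooled by
  element-wise geometric mean; group weights are the normalised row
  geometric means `W_i ∝ (∏_e r_ie)^{1/a}`. A complementary (0.1–0.9 fuzzy
  preference) scale and an eigenvalue consistency-ratio diagnostic are
  included.
* **Objective weights (EWM).** Entity × indicator data are min–max
  standardised (cost indicators reversed), turned into cross-entity shares
  `P_ij`, scored by normalised Shannon entropy
  `e_j = −(1/ln m) Σ_i P_ij ln P_ij`, and weighted by
  `W_j = (1 − e_j) / Σ_k (1 − e_k)` — more cross-entity variation, more
  weight.
* **Integration.** `W = β·W_subj + (1 − β)·W_obj`, with β chosen by
  minimising the summed squared deviations of the integrated weights from
  both sources — which yields β = 0.5 for any distinct pair of weight
  vectors.
* **Scoring.** Bottom-up linear weighted means through the three levels,
  anchored so the pool-best entity scores 100 and the pool-worst 0.
* **Simulators.** Seed-controlled generators for expert panels (default: 42
  experts judging groups of 6/4/5 indicators, log-normal judgment noise)
  and for skewed country-style indicator data, so every stage is testable
  against known ground truth.

## Worked example

```r
library(ohindex)

fw <- gohidi_framework("final")
validate_framework(fw)
#> framework validation: PASS
#>   counts: 3/15/61 (first/second/third level)

# integrate the published subjective and objective weight columns at beta 0.5
tab <- integrate_weight_table(gohidi_weight_table(), beta = 0.5)
head(tab[c("code", "fahp_weight", "ewm_weight",
           "integrated_weight", "integrated_recomputed")], 4)
#>   code fahp_weight ewm_weight integrated_weight integrated_recomputed
#> 1 1.1        20.63      17.37             19.00                 19.00
#> 2 1.2        19.53      19.99             19.76                 19.76
#> 3 1.3        15.88      18.16             17.02                 17.02
#> 4 1.4        13.49       9.95             11.72                 11.72
```

The recomputed column reproduces the published integrated weights to two
decimals for all 15 groups: the integrated weight of each indicator group is
exactly the mean of its expert-derived and its entropy-derived weight.

Weight recovery from a simulated 42-expert panel with log-noise 0.1 around a
known priority vector:

```r
spec <- expert_panel_spec(group_sizes = c(animal = 4), n_experts = 42,
                          priorities = list(animal = c(0.32, 0.25, 0.17, 0.26)),
                          noise_sd = 0.1, seed = 42)
panel_weights(simulate_expert_responses(spec))$animal$weights
#> animal.1 animal.2 animal.3 animal.4
#>   0.3187   0.2507   0.1701   0.2605

optimal_beta(c(0.32, 0.25, 0.17, 0.26), c(0.47, 0.06, 0.06, 0.41))
#> [1] 0.5
```

The recovered weights sit within a few thousandths of the truth, and the
squared-deviation-optimal subjective preference coefficient is 0.5.

## Acceptance script

`scripts/acceptance.R` re-derives the pipeline's analytically checkable
quantity from scratch: it simulates a noisy 42-expert panel and an
entity × indicator dataset with the package's generators, computes the
subjective and objective weight vectors, and minimises the
squared-deviation objective numerically to obtain the subjective preference
coefficient. Run it from the repository root against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Further reading

The methods vignette (`vignettes/composite-weighting.Rmd`) documents the
model assumptions, the tunable parameters and their defaults, what the
simulators do and do not emulate, numerical conventions for degenerate
inputs, and known limitations — including why the published entropy values
cannot be regenerated from raw data and how the package treats them.
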