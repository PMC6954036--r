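---
title: "Senescence in clonal and sexual plants from matrix population models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Senescence in clonal and sexual plants from matrix population models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(mpmsen)
```

## The question and the data model

Do plants that reproduce clonally escape senescence? Demographic theory has
often suggested that modular, clonal organisms can maintain constant or even
improving survival with age, while strictly sexual species should senesce.
`mpmsen` implements the comparative pipeline needed to address that question
with stage-based matrix population models (MPMs): per species, a projection
matrix decomposed as

\[ A = U + F + C \]

where `U` holds survival/growth/shrinkage transition probabilities per year,
`F` per-capita sexual recruitment and `C` per-capita clonal (ramet)
recruitment. Matrices are oriented with columns as source stages and rows as
destinations, the standard demographic convention; published matrices vary,
so this is asserted in the I/O layer and tested.

Species fall in three reproduction modes: *only sexual* (`sum(F) > 0`,
`sum(C) = 0`, not clonal per botanical knowledge), *only sexual but clonal
too* (`sum(C) = 0` yet the species is known to be clonal — the study simply
did not quantify ramet production), and *sexual and clonal* (both positive).
Botanical knowledge enters as a per-species boolean supplied with the
metadata, standing in for a clonality trait database lookup.

## Study selection

`apply_selection_criteria()` screens candidate models the way a careful
comparative study must: structural validity (non-negative, irreducible,
primitive, checked on the life-cycle graph of `A` because reproduction arcs
are part of the life cycle), at least 3 study years and 2 annual matrices,
unmanipulated field conditions, an annual time step, growth forms restricted
to epiphytes, herbaceous perennials, succulents and shrubs (annuals lack
clonality almost entirely; trees and palms rarely have below-ground clonal
connections quantified), more than two stages, stage survival strictly below
one, and at least some sexual reproduction (exclusively clonal models would
confound ramet and genet bookkeeping). Replicate matrices for one species are
averaged element-wise beforehand (`average_mpms()`); when several studies
remain, `pick_best_study()` prefers explicit clonality quantification, then
study duration, then the number of annual matrices, then stage count — the
tie-break order beyond the first criterion is this package's choice, applied
deterministically.

Every exclusion is reported with its first failing criterion, so
retained + excluded always equals the input count.

## From stages to ages

Life tables come from the classic age-from-stage construction. The recruit
cohort starts at `c0 ∝ (F + C) w` (`w` = stable stage distribution), with
seed-bank entries zeroed: seed-bank dynamics are poorly known, so life is
counted from *active establishment* (left truncation). Projecting the cohort
through `U` gives survivorship `l_x` (active stages only), and per-capita
reproduction `m_x` (sexual) and `c_x` (clonal).

Stage models with a terminal stasis loop produce artefactual mortality and
fertility plateaus once the cohort structure stops changing. Trajectories
are therefore right-truncated at `QSD90`, the first age where the cohort's
active-stage composition is within 0.10 (Keyfitz's Δ, half the L1 distance)
of the quasi-stationary distribution — the dominant right eigenvector of the
active-stage block of `U`. Using `U` rather than `A` follows the
age-from-stage literature: the QSD describes a *surviving cohort*, which is
what a life table follows; the choice is isolated in one helper and easy to
switch. A species is *eligible* when 99% of its cohort has died
(`l_x < 0.01`) before that convergence age, so that the observed mortality
history is essentially complete; `run_pipeline()` applies the flag as a
filter while the lower-level functions only report it.

## Senescence and iteroparity metrics

Keyfitz (life-table) entropy

\[ H = \frac{-\int_0^\infty \log(l_x)\, l_x\, dx}{\int_0^\infty l_x\, dx} \]

is evaluated by trapezoidal quadrature — on the yearly grid for empirical
models, on fine grids (step 0.01 or finer) for analytic checks, where the
continuous limits are met to 1e-3. `H < 1` indicates mortality rising with
age (senescence, Type I survivorship), `H = 1` constant mortality (Type II),
`H > 1` declining mortality (escape from senescence, Type III). A survivorship
tail that underflows to exactly zero (steep Gompertz hazards) is dropped
before integrating, since \(l \log l \to 0\).

Demetrius entropy quantifies iteroparity as the Shannon entropy of the
growth-discounted age schedule of reproduction:
\(p_x \propto \lambda^{-x} l_x r_x\), renormalized over the truncated window
(the Euler–Lotka normalization only holds for complete schedules), and
\(S = -\sum p_x \log p_x\). `S = 0` is strict semelparity; `log k` is the
maximum for reproduction spread evenly over `k` ages. The schedule defaults
to `r_x = m_x + c_x` (first/last reproduction whether sexual or clonal);
a sexual-only variant is a switch.

Eight traits feed the multivariate analysis: generation time
`T = log(R0)/log(lambda)` with `R0` the dominant eigenvalue of `(F + C) N`
(`N = (I - U)^{-1}`, the fundamental matrix; clonal recruits are counted by
default, switchable, since whole-population replacement is the point of the
definition); mean life expectancy `eta_e` (column sums of `N` weighted by
`c0`); SSD-weighted survival `sigma`, sexual reproduction `phi`, growth
`gamma` and shrinkage `rho` over active stages; the reproductive span
`L_am`; and `S`. Keyfitz `H` is carried alongside as the response variable,
untransformed. Two incompatible published conventions exist for the span:
`eta_e - L_alpha` (used in trait tables, the default here because the trait
matrix feeds the PCA) and `L_omega - L_alpha` (used in life-table figures);
both are implemented and selected by `span_variant`, and neither is asserted
as canonical.

When `lambda` is within 1e-10 of 1 the generation time is undefined and
reported missing (imputable downstream), rather than amplified into a huge
unstable ratio.

## Trait matrix, imputation, ordination, inference

`build_trait_matrix()` log-transforms each trait (traits that can
legitimately be zero — `gamma`, `rho`, `S` — are shifted by half the smallest
positive observed value before logging; the shift is recorded), masks values
outside the 2.5th–97.5th percentile of the log distribution (per trait
value, not per species), and standardizes columns to mean 0, variance 1.
Masking bounds are stored in the object; re-applying them is idempotent,
whereas re-estimating percentiles on masked data would creep inward.

`impute_missing()` is single-dataset multivariate imputation by chained
equations with predictive mean matching: each incomplete column is regressed
on the others over its observed rows, and each missing entry receives an
*observed* donor value whose prediction is among the `donors = 5` closest.
One completed dataset matches the single-ordination workflow; the loop is
deterministic under the supplied seed.

`phylo_pca()` is a phylogenetically corrected PCA under Brownian motion:
with tree covariance `Cmat`, the GLS ancestral mean
\(a = (1'C^{-1}1)^{-1} 1'C^{-1}X\) centres the data, the evolutionary
covariance is \(R = (X-1a)' C^{-1} (X-1a)/(N-1)\), and loadings are its
eigenvectors. On a star tree this reduces exactly to ordinary covariance
PCA, which the tests assert at 1e-8, and the whole routine is cross-checked
against an independent reference implementation. Covariance of standardized
traits (not a correlation variant) is used, with fixed BM scaling — no
branch-length transformation is optimized. Axes are retained by the Kaiser
rule (eigenvalue strictly greater than 1).

Inference mirrors the standard reporting shape: a two-way ANOVA
`H ~ PC1 * PC2` overall and per reproduction mode; three clonality-covariate
models (`H ~ PC1 + PC2 + clonal + PC1:clonal + PC2:clonal`,
`H ~ PC1 * clonal`, `H ~ PC2 * clonal`); one-sample t-tests of each mode's
mean `H` against the threshold 1 (a constant group exactly on the null is
reported as `t = 0, P = 1`); and Tukey HSD per trait across modes with a
compact letter display built from maximal cliques of the non-significance
graph. P-values are reported unadjusted across the model family, matching
common practice for this analysis; a phylogenetic variant of the group
comparisons is out of scope because no defensible specification of it
exists without further assumptions.

## The synthetic study system

No curated plant-matrix database ships with the package, so
`make_collection()` generates collections with known ground truth:

* **Mortality regimes.** Gompertz `mu(x) = a e^{bx}` (Type I, senescent;
  defaults `a = 0.05, b = 0.20`, drawn per species from `a ∈ [0.03, 0.08]`,
  `b ∈ [0.15, 0.25]`), constant `mu ∈ [0.15, 0.30]` (Type II), and
  `mu(x) = a/(1 + bx)` with `a ∈ [0.5, 0.8]`, `b ∈ [0.4, 0.7]` (Type III).
  These are the standard monotone hazard families for the three survivorship
  types, at rates plausible for herbaceous perennials (life expectancies of
  roughly 3–15 years).
* **Age span.** Each species' Leslie model runs until its cohort is
  effectively extinct (cumulative hazard above `-log(1e-6)`, capped at 60
  age classes). This keeps tail survival strictly positive — an underflowed
  zero would disconnect the life-cycle graph and fail the irreducibility
  criterion for a spurious reason.
* **Stage structure.** Ages are pooled into contiguous bins of about two
  years (`aggregate_to_stages()`), weighting within-bin ages by the
  stationary age composition `lambda^{-x} l_x` (uniform fallback when the
  growth rate is degenerate, e.g. periodic semelparous chains). Pooling
  preserves weighted column survival to 1e-6 and the population-level
  reproductive output exactly, and moves the dominant eigenvalue by under
  5% down to five stages. `add_shrinkage()` then re-routes 2–8% of each
  stage's stasis one stage back, because real plant matrices contain
  retrogression and a collection with `rho = 0` everywhere would make that
  trait column untransformable.
* **Reproduction.** Iteroparous schedules start at a first reproductive age
  drawn from 2–5 years with per-capita rates 0.5–2; `clonal_fraction`
  routes 20–50% of recruitment through `C` for sexual-and-clonal species.
  Semelparous specs place the single reproductive age at the last age class
  so the pooled life cycle stays irreducible. About 30% of species get a
  seed-bank stage (stasis 0.2, germination 0.5, half of sexual recruits
  entering the bank).
* **Phylogeny and traits.** Pure-birth (Yule) trees via standard
  birth-death simulation; correlated traits evolve by Brownian motion with
  a specified among-trait covariance (matrix-normal sampling against the
  tree covariance).
* **Planted failures.** Scenarios can append models that each violate
  exactly one selection criterion (annual species, no recorded
  reproduction, stage survival at or above 1, too-short study, tree growth
  form, two-stage model), so the filter can be tested for exactness.

The default scenario's mode counts (124 / 35 / 22) echo the proportions
typical of a large comparative plant dataset. Everything regenerates
bit-identically under a fixed seed.

**What the generator does not emulate.** Real matrices carry estimation
noise, heterogeneous dimensions and stage definitions, biased sampling of
growth forms, and trait–phylogeny correlations; the generator's traits and
demography are phylogeny-free except where Brownian traits are explicitly
simulated. Passing the recovery suites therefore shows the *machinery* is
correct — entropies land on the planted side of 1, regressions recover
planted coefficients, the filter catches planted violations — not that any
particular empirical dataset would yield particular values.

**A genuine property of the eligibility filter.** For pooled Gompertz
(Type I) life cycles, 99% cohort mortality and 90% structural convergence
happen at nearly the same age, so a substantial share of synthetic senescent
species is flagged ineligible — the cohort converges just before it finishes
dying. This mirrors what the criterion does to real fast-senescing species
and is not an implementation artefact; the ground-truth recovery tests
therefore evaluate `H` from the truncated trajectories of all
filter-passing species, while `run_pipeline()` keeps applying the
eligibility flag.

## Numerical choices

* Dominant eigenpairs take the Perron root — among eigenvalues of maximal
  modulus, the real non-negative one — so periodic matrices (ties at
  `±lambda`) resolve correctly; `w` is scaled to sum to 1 and `v` so that
  `v·w = 1`.
* Irreducibility is strong connectivity of the adjacency graph of `A`;
  primitivity uses Wielandt's index-of-primitivity bound
  `(n-1)n + 1` on the boolean adjacency with fast boolean exponentiation.
* The fundamental matrix requires the spectral radius of `U` below
  `1 - 1e-12`; anything at or above signals an immortal life cycle and is
  an error, matching the survival-below-one selection criterion.
* Trajectories stop at survivorship 1e-9 or age 1000, whichever comes
  first; entropy quadrature is trapezoidal on whatever grid the caller
  supplies.
* All randomness (imputation donors, generator draws, tree simulation) sits
  behind explicit integer seeds; stage-local seeds in the pipeline are
  derived deterministically from the master seed.

## Problem sizes in the test suite

The suites run comfortably on one CPU: cohort-simulation oracles use 1e5
individuals in 20 batches on five fixtures (differences bounded by three
Monte-Carlo standard errors, with the batch SE floored at the binomial
resolution); regime recovery uses 108 species (36 per regime); regression
recovery uses 100 replicates of 120 species; subspace recovery uses 20
replicates of 64-tip trees. These sizes were chosen so the whole suite
finishes in well under a minute while keeping Monte-Carlo noise far from
the asserted margins.

## Known limitations

* Transient dynamics, damping ratios and sensitivity/elasticity analyses
  are out of scope.
* The Tukey group comparisons are non-phylogenetic; `H` is modelled on PCA
  scores with ordinary least squares, not GLS against the tree.
* Single imputation understates imputation uncertainty by construction;
  multiple imputation is deliberately not implemented.
* Whether generation time should count clonal recruits is genuinely
  ambiguous for ramet-based models; both variants are exposed
  (`include_clonal`), with the inclusive one as default.
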