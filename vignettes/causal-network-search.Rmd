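---
title: "Searching phenotypic causal networks in pedigreed populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searching phenotypic causal networks in pedigreed populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gensem)
```

## The problem

When several quantitative traits are recorded on the same animals, one
trait's phenotype may directly affect another's (weight affects age at
first egg; age at first egg affects egg number). Structural equation
models (SEMs) quantify such direct effects through structural
coefficients, but require a causal structure — which traits affect which
— to be chosen first. Constraint-based algorithms such as Inductive
Causation (IC) can recover the class of structures compatible with the
conditional independencies of the joint distribution; in a pedigreed
population, however, correlated additive genetic effects confound that
search: two traits can covary through shared genes with no phenotypic
causation at all. The remedy implemented here is to run the search on the
distribution of phenotypes *conditional on genetic effects*, i.e. on the
residual covariance matrix of a multiple-trait animal model (MTAM).

`gensem` implements the full procedure:

1. **Fit** a fully recursive SEM by Gibbs sampling. Because a fully
   recursive SEM (all lower-triangular structural coefficients free,
   diagonal residual covariance) is likelihood-equivalent to an MTAM with
   unstructured residual covariance, posterior samples of the MTAM
   residual covariance are obtained by transforming each draw:
   `R0* = (I - Lambda)^-1 Psi0 (I - Lambda)^-T`.
2. **Search** causal structures with the IC algorithm applied to the
   posterior samples of `R0*`. Every conditional-independence query is a
   Bayesian decision: compute the residual partial correlation at each
   retained draw, form the highest-posterior-density (HPD) interval at a
   chosen probability content, and declare the pair independent when the
   interval contains zero.
3. **Orient** the surviving edges: collider detection and Meek-rule
   propagation first, then (optionally) a temporal override that directs
   edges from earlier-expressed to later-expressed traits.
4. **Compare** SEMs built on the selected structures, and the MTAM,
   with the deviance information criterion (DIC).

## The model

For `t` traits on `n` animals,

    y = (Lambda (x) I_n) y + X beta + Z u + e
    u ~ N(0, G0 (x) A),   e ~ N(0, Psi0 (x) I_n),  Psi0 diagonal

where `Lambda` has zeroes on the diagonal and a free coefficient at
`(j, j')` exactly when the structure has the edge `j' -> j`; `beta` holds
fixed hatch-season effects; `A` is the numerator relationship matrix from
the pedigree; `G0` is the genetic covariance among traits. The diagonal
`Psi0` is the statistical consequence of causal sufficiency: all
cross-trait residual covariance must be explained by the structure or by
the genetic effects. Solving for `y` gives the reduced model
`y = (I - Lambda)^-1 (X beta + Z u + e)`, so SEM dispersion parameters
map to the MTAM scale through the quadratic transform above (and likewise
`G0* = (I - Lambda)^-1 G0 (I - Lambda)^-T`). Heritabilities are reported
on the reduced scale, `h_j^2 = g*_jj / (g*_jj + r*_jj)`.

The conditional likelihood `p(y | Lambda, beta, u, Psi0)` factorizes over
animals because residuals are independent across animals; all likelihood
and deviance code works on `t x t` blocks per animal and never builds an
`(tn) x (tn)` matrix.

## Bayesian fitting

All full conditionals are conjugate, so a plain Gibbs sampler is exact:

* per trait, the season effects and that trait's structural coefficients
  form a joint multivariate-normal block (the trait equation is a linear
  model on season dummies and parent-trait phenotypes, with flat priors);
* genetic effects are updated in per-animal `t`-dimensional blocks
  sweeping the whole pedigree, using the sparse inverse of `A` (assembled
  directly from the pedigree with inbreeding accounted for). Exactness is
  unaffected by the block order; only mixing depends on it;
* `G0` is drawn from its inverse-Wishart conditional
  (`df = nu_G + q`, scale `G0_prior + U' A^-1 U`);
* each residual variance from a scaled inverse-chi-square conditional.

The default hyperparameters for the five quail traits are the published
ones: `s2 = (0.6, 400, 70, 0.7, 40)` with `nu_psi = 3`, and `nu_G = 7`
with diagonal prior scale `(0.3, 200, 30, 0.3, 10)`
(`quail_hyperparameters()`); for other trait sets a weakly informative
data-scaled default is constructed. Default MCMC settings mirror the
published run (300,000 iterations, 100,000 burn-in); the package's own
tests use far smaller profiles (hundreds to a few thousand iterations on
up to ~2,000-animal pedigrees), chosen so the whole suite runs on a
laptop while still giving the sampler enough draws for stable summaries.
Burn-in is a fixed setting, not an adaptive diagnostic: summaries are
computed from everything retained, and convergence is the user's
responsibility at small profiles. The sampler core is compiled
(RcppArmadillo) and uses R's RNG, so chains are reproducible through
`set.seed()` / the `seed` field of `mcmc_settings()`.

## Statistical decisions in the search

* **HPD estimator.** The empirical shortest interval: among all
  contiguous windows of the sorted draws containing `ceiling(content*m)`
  samples, the shortest; ties break to the lowest start. This estimator
  is mode-anchored for skewed posteriors.
* **Boundary rule.** An interval with an endpoint exactly at zero counts
  as containing zero (conservative: favors declaring independence).
* **Singular draws.** A per-draw partial correlation whose submatrix is
  numerically singular is skipped and counted; a query fails loudly if
  more than 1% of draws are skipped, so silent dropping is bounded.
* **Multiple contents.** The search is run at several HPD contents
  (default 70–95%); narrow intervals (low content) find more edges,
  wide intervals fewer. Verdicts are monotone across contents by
  construction: once a query is declared null at some content it stays
  null at every higher content on the same samples, so higher-content
  skeletons are nested in lower-content ones and the edges present at
  every content are flagged as the most stable.
* **Exhaustive conditioning.** With five traits there are at most eight
  conditioning subsets per pair; the search enumerates all of them
  (increasing size, lexicographic within size) rather than pruning
  incrementally, and logs every decision with its interval, so that
  every absent edge has a recorded separating set and every present edge
  has all-subsets-dependent evidence.
* **Orientation.** Collider discovery re-queries all subsets containing
  the middle trait; conflicting collider demands are surfaced as
  flagged edges, never silently resolved. Step-3 propagation uses Meek
  rules R1–R4 to a fixed point; correctness is asserted by an exhaustive
  test: with perfect d-separation decisions the skeleton + collider +
  propagation pipeline must reproduce the brute-force CPDAG on random
  5-node DAGs. Extendability of a partial graph (can its undirected
  edges be oriented acyclically without new unshielded colliders?) is
  decided by sink elimination and cross-checked against exhaustive
  orientation enumeration.
* **Temporal override.** Undirected edges between traits at different
  time points are oriented earlier-to-later even when this creates
  unshielded colliders the data did not support; such colliders are
  detected and reported. Traits tied at the same time point (egg weight
  and egg number are recorded over the same laying window) are never
  auto-oriented; if such an edge survives, the graph is reported as not
  fully oriented and no SEM is fitted to it, because guessing a
  direction would be silent invention.

## Model comparison

`DIC = 2*Dbar - D(theta_bar)` with the *conditional* deviance
`D = -2 log p(y | Lambda, beta, u, Psi0)`: the deviance conditions on the
genetic effects and `theta_bar` includes their posterior means. The
conditional focus is the standard choice for hierarchical animal models
and matches a deviance defined directly on the conditional likelihood;
the marginalized alternative is out of scope. Per-draw deviances are
recorded during sampling, so DIC needs no second pass over the chain.

Two practical properties of this conditional DIC are worth knowing.
First, it is noisy at small scale: the effective-parameter count `pD` is
dominated by the genetic effects, and chain-to-chain variation of a few
DIC units is normal at test profiles. Second, the posterior-mean deviance
`Dbar` of nested structures is *not* monotone in model size: the larger
model's extra fitted deviance and its extra effective parameters cancel
to first order, so `Dbar` comparisons between nested SEMs behave like a
coin flip. The package's tests therefore assert monotone fit where it
genuinely holds (profile least-squares fits given the simulated genetic
effects) and leave ranking to the DIC itself.

## The synthetic-data generator

Real data of this kind (849 hens, a 10,680-animal pedigree) are not
distributable, so `gensem` ships a generator that produces datasets with
exactly the statistical structure the analysis assumes: a
multi-generation random-mating pedigree; additive genetic effects drawn
by sequential Mendelian sampling (founders `N(0, G0)`; offspring receive
the parental mean plus a Mendelian deviation scaled by
`0.5 - 0.25(F_s + F_d)`, which is exactly `N(0, G0 (x) A)`); uniformly
assigned hatch seasons; and reduced-model phenotypes under a configurable
causal structure.

The preset `"paper_model_C"` reproduces the selected quail model:
structure `bw -> aew`, `w35 -> afe -> ne` with coefficients
(-0.408, -0.052, -0.113), residual variances
(0.33, 195.78, 34.65, 0.68, 30.62), the published Model-C genetic
covariance matrix, six hatch seasons, trait means matching the study
population, and 850 phenotyped hens from a 2,000-animal, four-generation
pedigree. Two generator choices are package decisions where the study
reports none: season effects are evenly spaced within ±0.25 phenotypic
standard deviations (estimable but not dominant), and the pedigree is
2,000 animals — deep enough that genetic effects are well separated from
the phenotypic regressions (with a shallow pedigree the fully recursive
model's coefficients can absorb genetic covariance, which distorts
conditional-DIC comparisons), yet far cheaper than the study's full
pedigree. `"null_no_causal"` keeps the dispersions but removes all
edges; `"fully_recursive_demo"` frees all ten coefficients with
moderate unit-aware values.

What passing tests on such data do **not** show: robustness to
non-normal residuals, selection, missing records, genotype-by-environment
trends, or maternal effects — none of which the generator emulates, and
the last of which the model family deliberately omits.

## Numerical and degenerate-input choices

* Pedigrees are validated and topologically sorted (stable by generation
  depth, then input order); cycles and undefined parents are errors
  naming the offending animal. `"0"` and empty fields are unknown-parent
  sentinels; IDs are opaque strings.
* The relationship matrix uses the tabular method with inbreeding
  accumulated; its inverse is assembled sparsely from per-individual
  rules with inbreeding in the Mendelian-sampling variances. These are
  exact inverses of each other (asserted to 1e-8 up to 200 animals).
* `(I - Lambda)` is unit lower-triangular under a causal order, hence
  always invertible; the reduction is the only PSD-preserving reading of
  the transform and keeps source traits' residual variances exactly.
* A singular `G0` is accepted in simulation (degenerate draws via the
  eigendecomposition square root); the sampler requires positive
  definiteness, which the inverse-Wishart conditional maintains.
* Likelihood evaluation fails loudly on a non-PSD reduced covariance
  rather than returning `NaN`.

## Limitations

* The search assumes causal sufficiency, acyclicity and faithfulness;
  violations show up as non-extendable partial graphs (reported, and
  checkable with `has_consistent_extension()`), exactly as observed with
  low-content searches on real data.
* Conditional-DIC comparisons carry a systematic caveat beyond noise:
  because the deviance conditions on the genetic effects, a fully
  recursive structure can lower its conditional deviance by absorbing
  genetic covariance that the pedigree does not fully resolve, by more
  than the effective-parameter penalty grows. On data simulated from the
  sparse quail-like preset this makes the conditional DIC prefer the
  MTAM over the generating structure in most replicates (the package's
  replicate tests measure this). A marginalized deviance would not have
  this behaviour, but is out of scope here; DIC rankings from this
  package should be read with that asymmetry in mind.
* Edge recovery at high HPD contents is only as reproducible as the
  underlying intervals: an edge whose partial-correlation interval
  barely excludes zero (as the weakest quail edge does at 95%) is
  selected in roughly half of replicated datasets of the same size, and
  with ~80 interval decisions per search an occasional spurious edge is
  expected. The multi-content stability report exists precisely to
  expose this.
* Posterior summaries use a fixed burn-in; no convergence gating is
  applied. Trace inspection is recommended for paper-scale runs. The
  reduced-scale partial correlations mix slowly; short chains understate
  their posterior spread, which makes independence decisions
  overconfident. The replicate tests use 10,000-iteration chains for
  this reason.
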