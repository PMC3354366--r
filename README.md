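# gensem

Searching phenotypic causal networks among quantitative traits in
pedigreed populations.

When several traits are measured on related animals, phenotypes can
affect each other directly (weight → age at first egg → egg number), but
shared additive genetic effects confound any attempt to learn that causal
structure from the joint distribution of phenotypes alone. `gensem`
implements the full Bayesian workflow that works around the confounding
by searching on the distribution of phenotypes *conditional on genetic
effects*:

1. **Recursive mixed-effects structural equation model (SEM).** For `t`
   traits on `n` animals,

   ```
   y = (Λ ⊗ Iₙ) y + X β + Z u + e,
   u ~ N(0, G₀ ⊗ A),   e ~ N(0, Ψ₀ ⊗ Iₙ)   (Ψ₀ diagonal),
   ```

   with `Λ` the structural-coefficient matrix (free entries = edges of an
   acyclic causal structure), `β` fixed hatch-season effects, and `A` the
   pedigree relationship matrix. Fitted by an exact conjugate Gibbs
   sampler (compiled core; per-animal block updates of `u` via the sparse
   `A⁻¹`, inverse-Wishart `G₀`, scaled inverse-χ² residual variances).
2. **Reduction to the animal-model scale.** A fully recursive SEM is
   likelihood-equivalent to a multiple-trait animal model (MTAM); each
   posterior draw is transformed by `R₀* = (I−Λ)⁻¹ Ψ₀ (I−Λ)⁻ᵀ` to give
   posterior samples of the residual covariance conditional on genetics.
3. **Inductive Causation (IC) search on the `R₀*` samples.** Each
   conditional-independence query computes the residual partial
   correlation `ρ_{j,j'|S}` at every draw and declares independence when
   the highest-posterior-density (HPD) interval at a chosen probability
   content contains zero; skeleton, collider detection, Meek-rule
   orientation, extendability checking, and temporal-knowledge edge
   orienting follow. Searches run at several HPD contents (70–95%) with
   an edge-stability report.
4. **Model comparison by DIC**, `DIC = 2·D̄ − D(θ̄)` on the conditional
   deviance, between SEMs on the selected structures and the MTAM.

A synthetic-data module generates pedigreed multi-trait datasets with the
exact assumed structure (Mendelian-sampling genetic effects, configurable
causal graph), including a preset emulating the European-quail study the
workflow comes from, so the whole pipeline is testable without the
(undeposited) real data.

## Worked example

Simulate data from the quail-like preset (five traits — bw, w35, afe,
aew, ne — with true graph `bw→aew`, `w35→afe→ne`; 850 phenotyped hens in
a 2,000-animal pedigree; six hatch seasons), fit the fully recursive SEM,
search, orient, and compare:

```r
library(gensem)
sc <- scenario_presets("paper_model_C")
d  <- simulate_dataset(sc, seed = 42)

fr  <- fit_fully_recursive(d, hyper = quail_hyperparameters(),
                           settings = mcmc_settings(10000, 4000, 2, seed = 1))
res <- search_over_contents(fr$r0_star, c(0.70, 0.95), fr$traits)
res$graphs[["0.95"]]
#> partial graph over: bw, w35, afe, aew, ne
#>   undirected: bw - aew, w35 - afe, afe - ne

og <- temporal_orient(res$graphs[["0.95"]], quail_time_order())
og
#> partial graph over: bw, w35, afe, aew, ne
#>   directed:   bw -> aew, w35 -> afe, afe -> ne
```

The 95%-content search recovers the generating skeleton undirected (no
unshielded colliders are detectable in this graph), and the temporal
order of the traits orients it. Fitting the selected structure:

```r
st <- causal_structure(fr$traits, og$directed)
ch <- fit_sem(d, st, hyper = quail_hyperparameters(),
              settings = mcmc_settings(10000, 4000, 2, seed = 2))
posterior_summary(ch, "^lambda")
#>         parameter    mean     sd   lower   upper content
#> 1 lambda:w35->afe -0.0411 0.0223 -0.0856  0.0031    0.95
#> 2  lambda:bw->aew -0.3375 0.1014 -0.5565 -0.1625    0.95
#> 3  lambda:afe->ne -0.1449 0.0589 -0.2526 -0.0349    0.95
```

The posterior means sit near the generating coefficients
(−0.052, −0.408, −0.113): each unit of 35-day weight lowers age at first
egg by ~0.04 days, each day of later first egg costs ~0.14 eggs, and each
gram of hatch weight lowers average egg weight by ~0.34 g conditional on
genetics. `reduced_summaries(ch)` maps the fit back to the animal-model
scale (R₀*, G₀*, heritabilities). Finally,

```r
compare_dic(list(dic(ch, d, label = "selected SEM"),
                 dic(fr, d, label = "MTAM (fully recursive)")))
#>                    label     DIC    Dbar      pD   delta rank within_margin
#> 1 MTAM (fully recursive) 22429.5 21309.7 1119.78   0.000    1          TRUE
#> 2           selected SEM 22545.6 21523.1 1022.47 116.121    2         FALSE
```

Here the conditional DIC ranks the MTAM first even though the sparse
structure generated the data — a documented property of conditioning the
deviance on imperfectly-resolved genetic effects; see the "Model
comparison" section of the methods vignette
(`vignettes/causal-network-search.Rmd`) before reading DIC tables from
this model family.

`run_pipeline(pipeline_config(...))` chains all of the above (fit →
multi-content search → temporal orienting → per-structure fits → DIC →
reduced summaries) and `write_report()` serializes graphs (DOT, GraphML,
edge lists), tables (CSV) and a JSON summary.

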