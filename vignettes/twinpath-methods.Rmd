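---
title: "Biometric models for the direction of causality between paired childhood traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biometric models for the direction of causality between paired childhood traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinpath)
```

## The scientific problem

Two childhood traits — say, a child's cognitive development and the amount of
cognitive stimulation the child receives at home — are usually positively
correlated. Three mechanisms can produce that correlation: stimulation may
causally foster development, development may causally evoke stimulation (a
brighter child elicits more books, games and conversation), or both traits may
share common causes, genetic or environmental, without any direct effect in
either direction. Ordinary longitudinal regressions cannot separate these,
because the "environmental" measure is itself partly heritable and familially
confounded.

Twin data can. Monozygotic (MZ) co-twins share their full genome; dizygotic
(DZ) co-twins share on average half their segregating genes; both share their
family environment. Contrasting MZ with DZ resemblance identifies additive
genetic (A), shared environmental (C) and non-shared environmental (E)
variance, and — more importantly here — lets several structural designs
distinguish direct causal paths from confounded covariance. `twinpath`
implements that full modelling chain:

1. **Univariate ACE decomposition** of each trait (observed score or a latent
   factor with two indicators).
2. **Bivariate Cholesky decomposition**, the non-causal baseline that
   partitions all covariance into A/C/E routes.
3. **Direction-of-Causation (DoC) models**, which infer the direction of a
   causal path from the pattern of cross-twin cross-trait correlations —
   feasible only when the two traits' modes of inheritance differ enough.
4. **MRDoC**, the Mendelian-randomization extension that adds a polygenic
   score as an instrument for a unidirectional path.
5. **Cross-lagged twin models** over two assessment ages, and the **extended
   cross-lagged model** that additionally frees cross-time genetic (`rA`) and
   shared-environment (`rC`) confound correlations, testing whether apparent
   cross-lagged effects are really common-cause artefacts.

## Model representation and likelihood

All models are expressed in reticular (RAM) form. For each zygosity group,
one-headed paths live in a matrix $A$, two-headed (co)variances in $S$, and a
filter $F$ selects observed variables; the implied covariance is

$$\Sigma = F\,(I - A)^{-1}\, S\, (I - A)^{-\top} F^\top .$$

Every matrix cell is either a constant or *multiplier × parameter*, so the
twin-design structural constants (DZ additive-genetic sharing 0.5, shared
environment 1.0 in both groups, E uncorrelated across twins, polygenic-score
sharing 1.0/0.5) and all cross-group equality constraints are encoded by
construction. Latent A/C/E factors have unit variance and free loadings;
variance components are therefore squared loadings, estimated unconstrained
and standardized afterwards (`standardized_ace()`), which avoids boundary
non-convergence at zero variance. All phenotypes are assumed residualized (for
age and sex, `residualize()`) and standardized (`standardize()`) upstream, so
model means are fixed at zero.

Fitting is full-information maximum likelihood: each pair contributes the
multivariate-normal log density of its observed subvector, missing entries
marginalized by dropping rows/columns of the implied moments. Rows are grouped
by missingness pattern with per-pattern sufficient statistics, so an
evaluation costs $O(\text{patterns} \times p^3)$ rather than
$O(n \times p^3)$. Optimization is box-constrained quasi-Newton (`nlminb`)
with up to ten seeded jittered restarts on failure; standard errors come from
a central-difference Hessian of the deviance (step $10^{-5}\max(|\theta|,1)$),
with the parameter covariance $2 H^{-1}$. Worked examples whose inputs are
printed correlation matrices rather than raw data use the normal-theory
discrepancy fit to per-group covariance inputs (`fit_twin_moments()`), which
preserves chi-square differences.

**Identification** is checked locally (`check_identification()`): the Jacobian
of the stacked unique implied-covariance entries of both groups with respect
to the free parameters is computed by central differences (step $10^{-6}$);
the model is identified iff the Jacobian has full column rank (singular values
below $10^{-8}$ of the largest count as zero), and the null-space basis names
the deficient parameter combinations otherwise.

## Design choices in the causal models

**DoC.** The causal variants carry the whole cross-trait covariance through
the causal path(s); cross-trait factor correlations are fixed at zero. Default
start values give the two traits different ACE profiles because the perfectly
symmetric point is itself rank-deficient — DoC needs the modes of inheritance
to differ, and the pipeline warns when the univariate h² intervals of the two
traits overlap.

**MRDoC.** The instrument (a polygenic score) is shared exactly by MZ and half
by DZ co-twins. Because MZ co-twins' scores are identical, the MZ implied
covariance with both score columns present is singular; `dedupe_mz_instrument()`
sets the second twin's score missing so FIML marginalizes the redundant
column. A structural fact uncovered while validating the builder with the
rank checker, and worth stating plainly: *pleiotropy (`p2`) and the
non-shared-environment confound correlation (`re`) cannot both be free* — the
instrument's moments only pin the combination `p2 + d·p1`, leaving one null
direction. `build_mrdoc()` therefore exposes the trade-off explicitly:
with `free_pleiotropy = TRUE` (default) `p2` is free and `re` is fixed at
zero, the restriction conventional in causal twin modelling; with
`free_pleiotropy = FALSE` there is no pleiotropic path, all three confound
correlations are free, and the score is then the *sole* source of
identification of the causal path `d` — at `p1 = 0` the model is
rank-deficient with `d` in the null space, the structural counterpart of a
polygenic score that "is not a valid instrument".

**Cross-lagged models.** Observed scores of two traits at two ages; per-trait
ACE at time 1, residual ACE at time 2, free within-time cross-trait A/C/E
correlations at both times, stability paths, and cross-lags `f` (trait 2 at T1
→ trait 1 at T2) and `g` (the reverse). The extended model adds four
cross-time correlations between the T1 *common* factors and the T2 *residual*
factors of the other trait (`h1`, `h2` genetic; `j1`, `j2` shared
environment). Cross-time transmission within a trait flows only through the
stability path, because the T2 totals already contain transmitted T1 variance;
correlating T1 factors with T2 *totals* would double-count it. E cross-time
correlations are fixed at zero: freeing them makes the model locally
unidentified (the package's rank checker demonstrates this, and a test guards
it), which is why causal twin models conventionally restrict them.

**Trek decomposition.** For any acyclic (recursive) model,
`decompose_cross_covariance()` enumerates every Wright path-tracing trek — a
backward chain of one-headed paths, exactly one two-headed arc, a forward
chain — connecting two variables within a twin, and groups the trek values
into: direct cross-lag, cross-time `rA`, cross-time `rC`, and the remainder
(within-time correlations plus stability). Direct-path treks cannot carry a
cross-time arc (the code asserts this rather than assuming it), so the groups
partition the implied covariance exactly; the partition identity against the
reticular formula is property-tested to $10^{-10}$. Percentages are *signed*:
a negative group (possible, e.g., with a negative cross-lag) can push another
group above 100%. Shares are computed on the covariance scale of standardized
variables, which coincides with the correlation scale when all variances
are 1.

**Model comparison and pruning.** `compare_models()` implements the
chi-square difference test and AIC preference for nested fits.
`prune_nonsignificant()` fixes to zero, *simultaneously*, all structural
paths and correlations with two-sided Wald `p ≥ α` (loadings and variances
are never pruned), refits, and reports the difference test — matching the
practice of reporting one restricted, parsimonious model rather than a
stepwise search.

## The synthetic cohort generator

`simulate_structural()` draws the latent factors of the full two-trait,
two-timepoint design directly — A with cross-twin correlation 1.0/0.5, C
shared, E independent, a polygenic score with genetic sharing — and builds
phenotypes by the cross-lagged recursion, so it is an *independent* route to
the same distribution the reticular engine describes. `config_to_spec()`
maps a configuration onto an equivalent fixed-parameter spec, and a test
verifies that empirical group covariances at n = 20,000 pairs/group match the
engine's implied moments within Monte-Carlo error; this dual-route agreement
is the package's core cross-validation.

Defaults describe an early-childhood parent-report setting: per-trait shares
a² = 0.3, c² = 0.6, e² = 0.1 (strong shared environment, modest genetics,
little unique environment — the profile typical of parent-rated measures at
ages 3–4); within-time cross-trait correlations `ra = 0.35`, `rc = 0.60`,
`re = 0.20`, under which roughly three quarters of the cross-trait covariance
travels through C and about a fifth through A; stability 0.45; zero true
cross-lags with cross-time confounds `h = 0.25`, `j = 0.35`, so that the
generator's default world is one where naive cross-lagged estimates are
spurious. These are illustrative study conditions chosen once, not fitted
values. The polygenic-score paths default to zero; when set, the instrument's
contribution is carved out of the trait's genetic share so `p1`/`p2` act as
direct path coefficients and total variance shares are preserved.

What the generator does *not* emulate: non-normal phenotypes, ordinal items,
assortative mating (DZ genetic sharing is fixed at 0.5), sibling interaction,
informative (non-MCAR) missingness, and measurement structure beyond the
two-indicator latent option. Passing tests therefore certify the estimators
under the models' own assumptions, not robustness to their violation —
in particular FIML's tolerance of missingness is exercised only under MCAR.

## Numerical conventions

* Deviance convergence: optimizer success or a residual gradient below
  $10^{-4}\max(100, |{-2\ln L}|)$, far below one likelihood-ratio unit.
* PSD checks precede all sampling (eigenvalue floor $-10^{-8}$); FIML raises
  an error naming the missingness pattern if an implied submatrix is not
  positive definite.
* Identification rank tolerance $10^{-8}$, finite-difference steps as above;
  all configurable through function arguments.
* Correlation parameters are bounded in $[-0.99, 0.99]$; a parameter within
  $10^{-6}$ of a bound flags the fit as a boundary solution.
* Ties in pruning are not an issue: all non-significant paths are pruned in
  one step.

## Problem sizes used by the test-suite

Parameter-recovery checks run at 5,000 pairs per zygosity group, one seeded
dataset per family, asserting recovery within 3 standard errors. The
confound-absorption property (zero true cross-lags, `h = 0.25`, `j = 0.35`)
uses 100 replicates of 1,000 pairs/group, scoring a replicate as successful
when both naive cross-lags are spuriously positive (more than 3 SE above
zero) while both extended-model cross-lags are near zero (within 3 SE of
zero). Dual-route moment agreement uses 20,000 pairs/group. These sizes were
chosen once as adequate for the properties being demonstrated.

## Known limitations

Wald intervals only (no profile or likelihood-based intervals); no ordinal
liability-threshold likelihoods; no sex-limitation, rater-bias or
definition-variable moderation; one instrument and unidirectional causality
in MRDoC (no MRDoC2); means fixed at zero rather than a saturated means
model. The within-time residual correlations at T2 are kept free in the
extended cross-lagged model for nesting coherence with the naive model.

## A worked session

```{r example, eval = FALSE}
cfg <- sim_config(n_mz = 2000, n_dz = 2000,
                  crosslag = c(f = 0, g = 0),
                  crosstime = c(h1 = 0.25, h2 = 0.25, j1 = 0.35, j2 = 0.35),
                  seed = 1)
cohort <- simulate_structural(cfg)

naive <- fit_twin_model(cohort, build_crosslag("cd", "cs"))
extended <- fit_twin_model(cohort, build_extended_crosslag("cd", "cs"))

compare_models(naive, extended)       # does controlling rA/rC fit better?
tidy(extended)                        # Wald table
prune_nonsignificant(extended, cohort)$pruned
decompose_cross_covariance(extended, "cd_t1", "cs_t2")
```
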