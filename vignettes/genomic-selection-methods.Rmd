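---
title: "Models and methods behind peagain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind peagain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`peagain` implements the statistical machinery of a genomic-selection (GS)
programme for connected recombinant inbred line (RIL) populations evaluated
in multi-environment trials, of the kind run in autumn-sown pea breeding:
three populations of roughly one hundred F6 lines each, derived from paired
crosses among three elite parents, genotyped with several thousand biallelic
SNPs and phenotyped in randomized complete block (RCB) trials across three
environments. This vignette states the models, the assumptions they make,
the tunable parameters that matter, and the numerical and design choices
taken where the problem was genuinely open. No empirical claim is made here
that the package's tests or the acceptance script do not themselves compute.

## Phenotypic analysis of balanced trials

All phenotypic statistics assume a *balanced* RCB design: every line in
every block of every environment. Within one environment the model is
`Y = m + G_i + B_r + e`; across environments it is
`Y = m + E_j + B_r(E_j) + G_i + GE_ij + e`, with genotype and interaction
random. Variance components come from equating observed to expected mean
squares (method of moments): `S_e2 = MS_e`,
`S_GE2 = (MS_GE - MS_e)/r`, `S_G2 = (MS_G - MS_GE)/(re)` with `r`
replicates and `e` environments. For balanced data this equals the REML
solution; the equivalence is *tested* against lme4 rather than shipped,
which keeps the estimator exact, transparent and dependency-free. Negative
estimates are clamped to zero and flagged — a clamped component is a
warning sign, not a silent zero. Unbalanced data are rejected with an error
instead of being patched by ad-hoc imputation.

Broad-sense heritability on a genotype-mean basis is
`H2 = S_G2/(S_G2 + S_e2/n)` per environment and
`H2 = S_G2/(S_G2 + S_GE2/e + S_e2/(e n))` across environments. The genetic
coefficient of variation is `CV_g = 100 sqrt(S_G2)/m`. The genetic
correlation between two environments rescales the phenotypic correlation of
genotype values by the heritability roots, `r_g = r/(H1 H2)`; sampling noise
can push `|r_g|` past 1, in which case the value is returned as-is with a
flag rather than truncated. The phenotypic correlation `r` is computed on
raw line means; using BLUPs instead is a switch, since the original
protocol does not pin this down.

Line values entering all GS modelling are shrunken means:
`BLUP_i = m + H2 (ybar_i - m)`. The exact shrinkage formula used in the
original protocol is cited but not printed; for balanced data this
one-parameter shrinkage toward the environment grand mean is the textbook
BLUP of a genotype effect and is adopted as the package's documented choice.

## AMMI

Genotype-by-environment interaction (GEI) of the cell-mean matrix is
decomposed as `Y_ij = m + G_i + L_j + sum_n (u_in sqrt(l_n))(v_jn sqrt(l_n))
+ d_ij`: main effects by row/column centering, then an SVD of the
double-centered residual. Axis scores are unit-norm; the full set of axes
reconstructs the matrix to machine precision, and the axis sums of squares
partition the interaction sum of squares exactly — both are pinned by
tests at 1e-10.

Axes are retained by the F_R residual test, iterated from zero axes: the
residual interaction SS (times `n_reps`, to return to the plot scale)
divided by its degrees of freedom `(g-1-n)(e-1-n)` is referred to the
plot-level error mean square. The df convention is the Cornelius form and is
test-pinned, because the source protocol names the test only by citation.
SVD sign indeterminacy is resolved deterministically: the lexicographically
first environment scores nonnegative on every axis, so plots are
reproducible. "Percent of GEI explained" is the axis SS share of the
double-centered matrix SS (error SS not removed) — again a documented
choice where the original is ambiguous.

Nominal values exclude the environment main effect,
`m + G_i + (u sqrt(l))(v sqrt(l))`, and are returned against the
environment axis score, which is the standard adaptation plot.

## Whole-genome regression models

All three models consume line-level BLUPs and a dosage matrix coded 0/1/2,
column-centered by *training-set* means and not variance-scaled (matching
the plain dosage coding). Population structure, when requested, enters as a
populations-by-lines incidence matrix of fixed effects estimated jointly by
generalized least squares inside the mixed model — never as a
pre-correction of the phenotype.

**rrBLUP.** `Y = mu + G u + e`, `u ~ N(0, I sigma_u^2)`. Marker effects use
the ridge closed form `u = G'(GG' + lambda I)^{-1}(Y - mu)` with
`lambda = sigma_e^2/sigma_u^2`. The estimator of `lambda` is not printed in
the source protocol; the package profiles the restricted likelihood on the
spectrum of `GG'` (one eigendecomposition, then 1-D optimization — the
EMMA device). A fixed-`lambda` entry point exists purely so that tests can
compare against a generic penalized-least-squares oracle at 1e-8.

**G-BLUP.** The animal model with genomic covariance `K = ZZ'/c`,
`c = 2 sum p_j(1-p_j)` (VanRaden scaling; the exact constant used in the
original study is not printed, so this standard choice is documented).
Breeding values are `K (K + delta I)^{-1} (y - X beta)`; new lines are
predicted through the cross-kinship block. With `K = G_c G_c'/c` and
`lambda` mapped by the same `c`, G-BLUP reproduces rrBLUP predictions to
1e-6 — a pinned equivalence test, not an assumption.

**Bayesian Lasso.** Park–Casella scale-mixture Gibbs sampler: marker
effects `u_j | tau_j^2 ~ N(0, sigma^2 tau_j^2)`, `tau_j^2` exponential,
`lambda^2 ~ Gamma(1, 1e-4)` (weakly informative), Jeffreys prior on
`sigma^2`. Effects are updated single-site with residual maintenance
(O(np) per sweep, compiled), on R's RNG stream so a seed fixes the chain
bit-for-bit. Defaults are 12,000 iterations, 2,000 burn-in, thinning 5;
the original hyperparameters are deferred to a reference and not printed,
so these defaults are configurable and make no claim of equivalence.
Cross-validation uses shorter chains (stated where done); the three models'
predictive abilities agree within far less than the 0.1 acceptance band on
the synthetic trait, so chain length is not the binding constraint.

## Cross-validation scenarios

The evaluation protocol is 10-fold cross-validation *stratified by RIL
population*, repeated 50 times (tests and examples scale repetitions down
and say so). Predictive ability `r_Ab` is always computed within each
population and then averaged unweighted across populations, *before*
averaging over repetitions — pooling populations would inflate correlations
through population mean differences, so population-mean-first averaging is
mandatory, not optional. Four scenarios:

* intra-environment, intra-population: plain repeated stratified CV;
* inter-environment, intra-population: the model trained on one
  environment's values predicts, for held-out lines, their values in each
  *other* environment (same folds as the intra case, so a duplicated
  validation environment reproduces the intra result exactly — a pinned
  degenerate-case test);
* inter-population (intra- or inter-environment): the model trains on *all*
  lines of one population (no CV inside the training population, as in the
  original protocol) and predicts the other populations, averaging r across
  validation populations, and across validation environments for the
  inter-environment scope. Training environments are weighted equally when
  averaged, resolving an ambiguity in the original description.

Configuration choice across models and marker missing-data thresholds uses
RMSD over traits between each configuration's predictive ability and the
per-trait best, ascending; ties break by mean predictive ability, then by
the stricter (lower) missing threshold.

## Selection-gain calculus

Truncation-selection intensity is the infinite-population form
`i = phi(z)/p` — no finite-sample correction, because that form reproduces
the printed reference values (2.421, 1.755, 2.154, 1.400) exactly. Expected
genetic gains per year are `dG_G' = i_G r_Ac s_A / t_G` for GS and
`dG_P' = i_P H s_A / t_P` for phenotypic selection, with accuracy
`r_Ac = r_Ab/H`. The GS/PS efficiency ratio for equal budgets,
`(1.46 r_Ac / t_G)/(H / t_P)`, uses the intensity ratio 1.46 — the midpoint
of the 1.379–1.539 range implied by five-fold cheaper GS evaluations at PS
selected fractions of 10% and 20% — and cancels `s_A`.
`intensity_ratio_from_costs()` derives scenario-specific ratios for other
cost structures.

## Association scan

Markers are tested within each population (stratum) after residualizing
phenotype and dosage on the stratum's leading principal components (2 by
default — three connected populations leave little finer structure). The
per-stratum statistic is the squared residual correlation referred to its
*exact* null law, Beta(1/2, (m-1)/2) in the m-dimensional residual space,
then mapped back to a 1-df chi-square. The exact form matters: the
asymptotic sigma-hat-scaled score statistic is conservative in the far tail
at stratum sizes near 100, and would undershoot the nominal 0.001 rate at
the score-3 threshold by a factor of about three. Per-stratum statistics
are corrected for genomic inflation (`lambda_GC` = median over 0.4549,
floored at 1 — deflation is never applied) and combined by summation with
one df per contributing stratum; the combination rule is not printed in the
original and summation is the documented choice, with per-stratum outputs
preserved so alternatives can be applied. Markers monomorphic within a
stratum contribute zero statistic and zero df there, and are flagged.
Benjamini–Yekutieli adjustment (the BH step-up inflated by the harmonic
penalty, valid under arbitrary dependence) is reported alongside raw
scores; the significance flag is `score = -log10 p >= 3`, i.e. P < 0.001.
LD is plain squared Pearson correlation of dosages over complete pairs.

## The synthetic world

The generator exists so every stage is testable without field data. It
emulates: three (configurable) fully homozygous parents; paired crosses
selfed for five meioses (F6), with crossovers Poisson per linkage group
along seven abstract chromosomes of 1.5 Morgans with equally spaced
markers — residual heterozygosity `0.5^5` is retained, not forced to zero;
~100 lines per cross; several thousand SNPs segregating in at least one
cross (so MAF >= 0.05 is achievable after crossing); an additive polygenic
trait (default 100 QTL, standard-normal effects rescaled to unit genetic
SD); environment/block structure of a 3-environment, 3-block RCB with
block SD 0.25; and per-environment residual SD calibrated so the
*plot-basis* heritability `S_G2/(S_G2+S_e2)` hits the `h2_per_env` target
(default 0.5, a grain-yield-like value). The default GEI SD ratio 1.6
corresponds to a genotypic-to-GEI variance ratio near 0.39, the
yield-like, GEI-dominated preset.

Two GEI generators are provided, and the reason is a genuine statistical
conflict. A rank-1 interaction (QTL-driven line score times random
environment loadings) makes the AMMI PC1 dominate, as in strongly
patterned real GEI — but with only three environments, a single shared
loading vector makes the EMS interaction component an erratic function of
three random draws, and any deterministic centering of the loadings
instead biases `S_G2` down by `V_GE/e`. No rank-1 construction can satisfy
an iid-model variance-recovery criterion at e = 3. Hence
`gei_model = "rank1"` (default; used for the AMMI dominance properties) and
`gei_model = "iid"` (independent N(0, V_GE) cell effects; EMS-faithful;
the scenario preset under which the S_G2/S_GE2 recovery test runs, passing
within 7% of the 0.39 target over 20 seeds where 25% is allowed).

What a green test does *not* establish: the generator has no epistasis, no
dominance, no selection during inbreeding, no recombination hotspots, no
genotyping error, and its GEI is either exactly rank-1 or exactly
unstructured. Real GBS data add call-rate structure correlated with MAF,
and real GEI sits between those extremes. Parameter-recovery results on
this world therefore validate the estimators' algebra and calibration, not
field performance; the study's real-data predictive abilities are
deliberately out of scope.

## Numerical choices and degenerate inputs

* REML profiling optimizes over `log(delta)` on a 60-point grid refined by
  golden-section search; eigenvalues are floored at zero.
* Constant phenotypes yield zero-effect fits with a warning, not an error;
  constant populations are excluded from predictive-ability averages with
  a warning.
* A kinship matrix failing PSD by more than 1e-8 relative is rejected with
  a suggestion to jitter, rather than silently regularized.
* `J_AB = 0` in Nei's distance returns `Inf`, not an error.
* All seeded generators run under a local RNG that restores the caller's
  state; per-repetition and per-stage seeds derive from one master seed by
  a documented 32-bit string hash, so the whole pipeline is bit-reproducible
  and stage order cannot perturb downstream draws.
* Mode imputation breaks ties toward the smaller dosage; the iterative
  random-forest imputation (100 trees per marker, at most 10 sweeps,
  categorical encoding, 30 most-correlated companion markers as predictors)
  stops when imputed values stop changing or start oscillating.

## Known limitations

Only balanced designs are supported (by design). The F_R test assumes the
plot-level error MS is available from a replicated ANOVA. The Bayesian
Lasso reports posterior means only, not full chains. Inter-population
prediction assumes validation populations share the training marker panel.
The association scan does not model kinship within strata (the original
protocol used PCA correction, not a mixed model), and no genetic map is
shipped — map-anchored interpretation of hits is out of scope.
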