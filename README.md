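# peagain

Genomic selection (GS) analysis for **connected RIL populations in
multi-environment trials**, as used in pea (*Pisum sativum*) breeding
programmes.

Breeding programmes that phenotype a few hundred recombinant inbred lines
(RILs) from paired crosses among elite parents face two linked questions:
how much of the observed variation is genetic rather than
genotype-by-environment interaction (GEI), and whether selecting on
marker-predicted breeding values beats selecting on phenotypes once cost
and cycle length are accounted for. `peagain` implements the full analysis
chain for that setting, for breeders and quantitative geneticists:

* **Marker QC** — missing-rate and minor-allele-frequency filters, mode /
  rounded-mean / iterative random-forest imputation, VanRaden kinship
  `K = ZZ'/(2 Σ p_j(1−p_j))`, Nei's standard genetic distance; VCF and CSV
  input/output.
* **Trial statistics** — balanced-ANOVA variance components (`S_G²`,
  `S_GE²`, `S_e²`, and the population-factor split), broad-sense
  heritability `H² = S_G²/(S_G² + S_GE²/e + S_e²/(e·n))`, genetic
  coefficient of variation `CV_g = 100·S_G/m`, genetic correlations
  `r_g = r/(H₁H₂)`, shrunken (BLUP) line means.
* **AMMI** — `Y_ij = m + G_i + L_j + Σ_n (u_in√l_n)(v_jn√l_n) + d_ij`,
  axis retention by the F_R residual test, nominal yields for adaptation
  plots.
* **Three GS models** — rrBLUP (`û = G'(GG'+λI)⁻¹(Y−μ)`, spectral-REML λ),
  G-BLUP via genomic kinship, and a compiled Bayesian Lasso Gibbs sampler;
  optional population-structure fixed effects.
* **Evaluation** — population-stratified 10-fold × 50-repetition
  cross-validation; intra/inter-environment × intra/inter-population
  prediction scenarios; predictive ability `r_Ab` averaged within
  populations first; RMSD-based model/configuration selection.
* **GS vs PS efficiency** — truncation-selection intensities `i = φ(z)/p`,
  accuracy `r_Ac = r_Ab/H`, gains per year `i·r_Ac·s_A/t_G` vs `i·H·s_A/t_P`,
  and the budget-matched efficiency ratio `(1.46·r_Ac/t_G)/(H/t_P)`.
* **Association scan** — stratified, PCA-corrected exact score test with
  genomic-control inflation correction, Benjamini–Yekutieli FDR, score
  threshold 3 (P < 0.001), and LD r².
* **Synthetic data** — a generator for connected F6 RIL populations
  (Poisson crossovers on 7 abstract linkage groups, residual
  heterozygosity 0.5⁵) with controllable heritability and GEI, so the whole
  pipeline is testable without field data.

## Worked example

```r
library(peagain)

cfg <- sim_config(n_markers = 500, lines_per_pop = 50, n_qtl = 50, seed = 2026)
sim <- simulate_populations(cfg)          # 3 crosses of 3 parents, 150 RILs
tm  <- make_trait_model(sim$genotypes, cfg)
ph  <- simulate_phenotypes(sim$genotypes, tm, cfg)

estimate_vc_multi_env(ph, "trait")
#> <variance_components>
#>   S_G2     0.68085
#>   S_GE2    0.85806
#>   S_e2     1.5122
#>   mean     0.087167

vc <- estimate_vc_multi_env(ph, "trait")
h2_multi_env(vc$S_G2, vc$S_GE2, vc$S_e2, 3, 3)
#> [1] 0.6

y <- blup_line_means(ph, "E1", "trait")   # shrunken line means, environment 1
run_cv(gs_model("rrblup"), sim$genotypes, y, k = 10, repetitions = 5, seed = 7)
#> <cv_result:intra_env_intra_pop> r_Ab = 0.604 (5 reps, k = 10)

efficiency_ratio(r_Ac = 0.390, H = 0.632, t_G = 0.5, t_P = 1)
#> [1] 1.801899
```

Reading the numbers: the simulated trait has genotypic variance 0.68
against interaction variance 0.86 (a GEI-dominated, grain-yield-like
trait), giving `H² = 0.60` on a genotype-mean basis across the three
environments. Ridge-regression BLUP predicts held-out lines with
`r_Ab ≈ 0.60` under population-stratified cross-validation. With accuracy
0.390 and comparator heritability root 0.632, genomic selection at two
cycles per year is 1.80× as efficient per year as one-year phenotypic
selection for the same budget — i.e. an 80% predicted advantage.

The full study pipeline (QC grid → variance components → AMMI → model grid
CV → scenarios → gains → association scan) runs from one config:

```r
bundle <- run_study(list(simdata = list(n_markers = 500, lines_per_pop = 50),
                         models = c("rrblup", "gblup"),
                         cv = list(k = 10, repetitions = 5), seed = 1))
writeLines(make_report(bundle))
```

or from the shell: `Rscript inst/cli/peagain.R run --config study.yaml`.

## Scope

Balanced designs only; no SNP calling or alignment (upstream of this
package); no GGE biplots, BayesA/B/Cπ, or mixed-model GWAS; the original
study's field-data results are represented by parameter-recovery properties
on synthetic data, not reproduced. See
`vignettes/genomic-selection-methods.Rmd` for the models, assumptions,
defaults and design decisions.
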