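---
title: "Mendelian randomization of adult height on head and neck cancer risk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mendelian randomization of adult height on head and neck cancer risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`heightMR` re-implements, as a tested pipeline, a one-sample Mendelian
randomization (MR) analysis of adult height on head and neck cancer (HNC)
risk in a European case-control sample: genotype quality control of a height
instrument panel, a weighted genetic risk score (GRS) used as instrumental
variable, summary-statistics IVW and MR-Egger estimators, a confounder
screen, and an analytic power calculation. Because the original
individual-level data are not publicly deposited, the package ships a
first-class cohort simulator whose defaults encode the study's conditions;
every downstream stage is exercised and tested against it.

# The causal model and its estimators

Write $X$ for adult height in SD units (1 SD = 6.9 cm), $Y$ for HNC case
status, and $G_1,\dots,G_m$ for independent height-associated SNPs with
per-allele height effects $\beta_{GP,i}$ (SD units, from an external GWAS).
The instrumental-variable logic requires each $G_i$ to (i) associate with
height, (ii) be independent of confounders of the height-HNC relation, and
(iii) affect HNC only through height.

Three estimators of the causal log odds ratio per SD of height are
implemented:

* **Weighted GRS** (individual level): $\mathrm{GRS} = \sum_i
  \beta_{GP,i}\,d_i$ with $d_i \in [0,2]$ the effect-allele dosage. Because
  the weights are per-allele effects in SD units, one GRS unit corresponds
  to one SD of genetically predicted height, and the coefficient of the GRS
  in the adjusted logistic model
  `case ~ GRS + age + sex + country + smoking + drinking + PCs`
  is reported as the log-OR per SD. An optional rescaling through the
  measured-height regression (`sd_height_cm / cm_per_grs_unit`) is exposed
  in `grs_outcome_estimate()` for comparison but is not the default, since
  the per-unit and per-SD scales already coincide under SD-unit weights.
* **IVW** (summary level): per-SNP Wald ratios
  $\hat\theta_i = \hat\beta_{GD,i}/\beta_{GP,i}$ (outcome log-OR over height
  effect) are combined by fixed-effect meta-analysis with weights
  $w_i = \beta_{GP,i}^2/\mathrm{se}(\hat\beta_{GD,i})^2$, equivalently a
  weighted regression of $\hat\beta_{GD}$ on $\beta_{GP}$ through the
  origin. Both routes are computed and must agree to $10^{-8}$; the
  meta-analytic form is returned.
* **MR-Egger**: the same weighted regression with a free intercept, after
  orienting every instrument so $\beta_{GP,i} > 0$. The slope is a
  pleiotropy-adjusted causal estimate; the intercept estimates average
  directional pleiotropy, and a nonzero intercept flags violation of the
  exclusion restriction. Standard errors are scaled by the multiplicative
  overdispersion estimate floored at 1, and tests use a $t$ reference with
  $m - 2$ degrees of freedom — the conventional random-effects treatment for
  MR-Egger. With the intercept constrained to zero the estimator reduces
  exactly to IVW, which the test suite asserts.

The per-SNP outcome effects $\hat\beta_{GD,i}$ come from one adjusted
logistic regression per SNP
(`case ~ dosage + age + sex + country + smoking + drinking + PCs`), run by a
compiled batch IRLS (RcppArmadillo) that matches `stats::glm` to $10^{-6}$;
an equivalent pure-R engine is kept for cross-checking. Logistic likelihoods
are declared converged on the same relative-deviance criterion as
`stats::glm` (tolerance $10^{-8}$, at most 50 iterations); fits that do not
converge, or SNPs with degenerate dosages, are dropped from the summary set
with a recorded reason rather than aborting the scan.

## Power

`mr_power_binary()` gives the closed-form asymptotic power of the two-sided
Wald test of the IV log-OR. Two published non-centrality formulations are
implemented and the choice is an explicit argument:

* `linear_probability` (default): the binary-outcome formula of the mRnd MR
  power calculator (Brion, Shakhbazov & Visscher 2013). With case fraction
  $K$ and total $N$, the probability-scale effect is
  $b = K\,(\mathrm{OR}/(1 + K(\mathrm{OR}-1)) - 1)$, its variance
  $(K(1-K) - b^2)/(N R^2)$, and power is read from a noncentral
  $\chi^2_1$.
* `log_odds`: the log-odds-scale approximation (Burgess 2014),
  $\Phi\!\big(\sqrt{N R^2 K (1-K)}\,|\log \mathrm{OR}| - z_{1-\alpha/2}\big)$
  plus the opposite tail.

Both have size exactly $\alpha$ at $\mathrm{OR} = 1$ and are strictly
increasing in $N$, $R^2$ and $|\log \mathrm{OR}|$. At the study's inputs
(2,082 cases, 3,477 controls, $R^2 = 0.16$, OR 1.24, $\alpha = 0.05$) they
give **89.2%** and **87.4%** respectively. The figure published for this
design is 81.5%; neither standard formulation reproduces it — working
backwards, 81.5% corresponds to OR $\approx$ 1.21-1.22 or $R^2 \approx$
0.13-0.14 under these formulas. The package reports what its formulas
compute and documents the gap rather than adjusting either formulation
toward the published number; both alternatives are exposed so the
discrepancy can be examined.

# The synthetic cohort

The generator (`sim_config()`, `simulate_cohort()`) encodes the study
conditions as defaults: 599 instruments, $h^2_{snp} = 0.16$, 2,082 cases /
3,477 controls, sex-specific mean heights 161.8 / 173.7 cm, SD 6.9 cm,
causal OR 1.24 per SD.

* **Panel.** Effect-allele frequencies are uniform on (0.05, 0.95); raw
  effects are zero-mean normal, rescaled so
  $\sum_i 2p_i(1-p_i)\beta_{GP,i}^2 = h^2_{snp}$ *exactly* — only this
  variance sum matters downstream, so the shape of the effect-size
  distribution is immaterial. GWAS standard errors are back-filled from
  z-scores uniform on (6, 15), keeping every instrument genome-wide
  significant. Imputation quality is uniform on (0.4, 1.0) so that both the
  0.7 and the 0.9 sensitivity filters genuinely bite; a consequence visible
  in the demo workflow is that roughly half the panel survives the 0.7
  filter.
* **Genotypes** are hard dosages drawn binomially (Hardy-Weinberg
  proportions), with missingness completely at random (default 1%).
* **True score and height.** $G^* = \sum_i \beta_{GP,i}(g_i - 2p_i)$ has
  variance $h^2_{snp}$ exactly under HWE independence (the panel rescaling
  guarantees it), so no empirical rescaling is applied. Height in SD units
  is $G^*$ plus $N(0, 1 - h^2_{snp})$ noise; height in cm adds the
  sex-specific mean.
* **Behavioural covariates.** Ever-smoking propensity is logistic in a
  sex-by-study base rate (women 0.35/0.42, men 0.72/0.78 for CE/ARCAGE)
  plus `grs_smoking_log_or` $\times G^*/\mathrm{sd}(G^*)$; the default
  -0.09 per SD plants the inverse height-smoking association (about OR 0.8
  per GRS unit at full panel strength). Drinking uses sex base rates (0.76
  women, 0.95 men) with no genetic channel; age ($N(59.5, 10.8^2)$,
  rounded, truncated to 18-94), country and study are independent of
  genotype. These base rates and the 75% male fraction were chosen once to
  mimic the published descriptive table of this hospital-based sample; they
  are conditions, not tuning knobs.
* **Disease.** Liability is additive-logistic:
  $\mathrm{logit}\,P(\mathrm{case}) = a + \log(1.24)\,X +
  \log(3.0)\,\mathrm{smoke} + \log(1.5)\,\mathrm{drink} + \text{direct SNP
  effects}$. When pleiotropy is requested, a fraction of SNPs receives
  direct log-ORs drawn around `pleiotropy_mean` and applied to the
  *height-increasing* allele, so a nonzero mean is directional in the frame
  MR-Egger orients to — with sign-symmetric assignment the planted effects
  would cancel on orientation and no intercept signal would exist.
* **Case-control sampling.** The intercept $a$ is tuned by bisection so the
  *expected* population case count is `case_oversample` (default 1.3)
  $\times$ `n_cases`; exactly `n_cases` cases and `n_controls` controls are
  then drawn from the realized population (default size
  $2.2\,(n_\mathrm{cases}+n_\mathrm{controls})$). The oversampling margin
  exists because targeting the expected count exactly would leave the
  realized count short of the target in about half of all runs; 1.3 keeps
  the shortfall probability negligible while preserving a realistic
  population prevalence.
* **QC-challenge channels** (both default 0, i.e. the default cohort is the
  analysis-ready instrument set): `n_hwe_violating` SNPs are *appended* with
  70% of heterozygotes converted to homozygotes — the classic
  genotyping-error signature — at moderate allele frequencies (0.25-0.75),
  where the exact test has the counts to reach $P < 10^{-7}$ in a few
  thousand controls; `n_ld_duplicates` SNPs are appended as noisy copies
  (5% per-genotype resampling, pairwise $R^2 \approx 0.9$) with inflated
  GWAS p-values so pruning deterministically keeps the original. Appending
  keeps the clean instrument count at `n_snps`.

What the generator does *not* emulate: haplotype structure and
recombination (LD exists only as injected duplicates), genotype imputation
(quality scores are simulated attributes), population stratification
(single homogeneous population, so PCs are pure noise controls), study-
or center-specific height distributions, age-matching of controls, and HNC
subtypes. Passing tests therefore demonstrate correctness of the estimators
and filters under the assumed data-generating model, not robustness to real
LD, ancestry structure or imputation artefacts.

# Quality control

Filters run in a fixed order — call rate, HWE, imputation quality, LD
pruning — with exact accounting (`run_qc()` reports reconcile input =
output + removals at every step):

* Call rate: variants with non-missing fraction strictly below 0.95 are
  removed first, then individuals over the remaining variants. The boundary
  is read strictly, so a SNP at exactly 95% stays.
* HWE: dosages of *controls* are hardened to genotype classes
  ($>1.5 \to 2$, $<0.5 \to 0$, else 1 — the exact test is defined on
  counts) and tested with a Wigginton-style exact conditional test, plain
  (no mid-p); SNPs at $P < 10^{-7}$ are removed. Cases are ignored.
* Imputation: `imputation_r2` strictly greater than 0.7 retained (0.9 for
  the sensitivity set).
* LD pruning: greedy, visiting SNPs by ascending GWAS p-value (ties by
  chromosome, position), keeping a SNP iff its $R^2$ with all kept SNPs is
  below 0.01. A zero-variance (monomorphic) vector has undefined
  correlation; it is assigned $R^2 = 1$ against everything and is never
  kept, since it carries no instrument information.
* PCs: columns are mean-imputed, centered and scaled by
  $\sqrt{2\hat p(1-\hat p)}$; scores are the top-$k$ (default 15) left
  singular vectors of the standardized matrix. In synthetic runs the PCs
  are computed on the analysis SNPs themselves; the original study's
  separate 12,898-variant set is an artefact of real-data scale.

# Numerical choices

* HWE tie handling: configurations whose probability is within a relative
  $10^{-7}$ of the observed configuration's probability are included in the
  two-sided sum, so floating-point ties cannot flip inclusion; with this
  guard the implementation agrees with an independent log-factorial
  enumeration oracle to $10^{-12}$ over all tested count triples.
* `fit_linear` reports Wald p-values against the normal reference (not
  $t$), with the unbiased residual-variance estimator; rank-deficient
  designs raise an error naming the aliased columns.
* `fit_logistic` flags perfect separation (boundary fitted probabilities
  with coefficients beyond $\pm 12$) as an error, and never returns an
  unconverged fit silently.
* Missing dosages are mean-imputed: at $2\,\mathrm{eaf}$ inside the GRS
  (preserves the expected score) and at the sample column mean in the
  per-SNP scan and PCA. Covariate missingness is handled complete-case per
  model, with `n_used` recorded exactly.
* Height standardization in the observed phenotypic model uses the
  control-sample SD by default (controls approximate the source
  population); `overall` and `external` (6.9 cm) conventions are exposed.
  Note that the pooled control SD includes the between-sex height gap, so
  the "per SD" scale of this observational estimate is larger than the 6.9
  cm within-sex SD — one reason the phenotypic and genetic estimates are
  not numerically interchangeable.
* Pipeline determinism: every stochastic stage derives its seed from the
  configuration seed plus a stage offset; identical configuration and seed
  give byte-identical output files (numeric TSV fields are serialized at 17
  significant digits so files round-trip bit-exactly).

# Validation experiments and their sizes

The suite's heavier, statistical checks (in `tests/testthat/`) use sizes
chosen to balance statistical resolution against runtime on a single CPU:

* Parameter recovery at study scale: 100 replicates of the full cohort
  (599 SNPs, 2,082/3,477) with causal OR 1.24 and the nuisance channels
  (pleiotropy, genetic confounding of smoking) off, so the experiment
  isolates the causal channel the estimators target; mean GRS and IVW
  estimates must sit within 0.02 of $\log 1.24$ and 95% CI coverage within
  [0.90, 0.99]. 60 null replicates (OR 1) check the 5% size. The
  confounding channel is evaluated by its own experiment (30 replicates
  planted, 60 null at reduced scale) because adjusting for a
  genetically-influenced binary mediator leaves a small residual
  attenuation that is a property of the data-generating model, not of the
  estimators.
* Masking direction: with a strong negative score-smoking channel, the
  smoking-*unadjusted* GRS estimate falls below the adjusted one in paired
  per-replicate comparisons — the one-sample caution that a
  height-decreasing pathway into smoking biases the naive estimate
  downward.
* Egger power/size: 10 replicates with directional pleiotropy planted
  (30% of SNPs, mean direct log-OR 0.03) must reject the zero-intercept
  hypothesis in a majority; estimator-equivalence and null behaviour are
  covered separately.
* The HWE implementation-versus-oracle suite uses 500 random triples with
  $n \le 200$; IVW route-equivalence uses 1,000 random summary sets.

# Known limitations

* One-sample MR throughout: exposure weights are taken as known external
  quantities, so weak-instrument bias from estimated weights and
  winner's-curse effects are out of scope, as are two-sample overlap
  corrections, weighted-median/modal estimators and MR-PRESSO.
* The logistic non-collapsibility of odds ratios means per-SNP and GRS
  conditional estimates are attenuated by a fraction of a percent relative
  to the liability-scale parameter; at the study's effect sizes this is an
  order of magnitude below sampling noise.
* The power calculation reproduces its published formulations, not the
  single published percentage (see above).
* No relatedness, sex-check, or batch-effect modelling in QC.
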