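---
title: "Methods: joint analysis of genetically opposed diseases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint analysis of genetically opposed diseases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ccspectrum` analyses two case-control GWAS of disorders whose common-variant
architectures point in opposite directions — the dilated-versus-hypertrophic
cardiomyopathy situation. This vignette documents the models, the conventions
that tie the modules together, the tunable parameters, and the choices made
where the design was genuinely open. All empirical statements below are the
ones the package's test suite and acceptance script themselves compute.

## The liability-threshold model and the package's scale conventions

Each disorder is modelled as a thresholded latent liability: an individual is
a case when a standard-normal liability exceeds `tau = qnorm(1 - K)` for
prevalence `K`. A standardized (per genotype-SD) causal liability effect `b`
then shifts standardized genotype means by

* `b * phi(tau) / K` in cases versus the population, and
* `b * phi(tau) / (K (1 - K))` in cases versus controls.

Three scales recur:

1. **Liability scale.** Heritabilities (`h2_liability`, defaults 0.142 and
   0.18) and the genetic correlation `rg` (default −0.58) are defined here.
2. **Observed scale at effective sample size.** GWAS z-scores are modelled as
   `z = sqrt(n_eff) * a + e` with `n_eff = 4 / (1/n_case + 1/n_control)`,
   `a` the marginal (LD-smeared) observed-scale effect, and unit-variance
   noise. The liability-to-observed factor is the standard Lee conversion at
   sample prevalence 1/2 (the `n_eff` convention):
   `a = b * phi(tau) / (K(1-K)) * sqrt(P(1-P))`, `P = 0.5`.
   `estimate_h2(..., pop_prev = K)` inverts exactly this conversion, so
   observed-scale slopes map back to liability heritabilities.
3. **Delta (standardized frequency-difference) scale.** The case-case module
   converts log-odds effects by `delta = beta * sqrt(2 p (1-p)) * (1 - K)`,
   `var = se^2 * 2p(1-p) * (1-K)^2`. The factor `2p(1-p)` is the allele-dosage
   variance; the `(1 - K)` factor rescales case-versus-control to
   case-versus-population, so a liability effect `b` has delta-scale
   expectation `b * phi(tau) / K`. This convention is pinned down by an
   individual-level oracle test: the summary-level delta matches the directly
   computed standardized case-group dosage shift in a simulated cohort that
   shares the same causal truth.

Reported standard errors on the log-odds scale follow
`se = 2 / sqrt(n_eff * 2p(1-p))`, the standard logistic-information
approximation for a balanced effective design. These conventions are a single
self-consistent system; each is checked against either a closed form or an
individual-level simulation rather than assumed.

## The synthetic-data generator

`simulate_paired_sumstats()` draws causal liability effects for the two
disorders from a bivariate normal with per-trait variance `h2 / m_causal` and
correlation `rg`, converts to the observed scale, applies block LD, and adds
sampling noise whose cross-trait correlation is
`shared_controls / sqrt(n_control_a * n_control_b)` — exactly the quantity the
bivariate LD score intercept estimates. Defaults mirror the study conditions:
prevalences 0.004/0.002, liability heritabilities 0.142/0.18, `rg = -0.58`,
1223 causal variants, and the published case/control counts (9,365/1,199,156
and 5,900/68,359). Endophenotypes are generated with causal effects correlated
to the standardized case-case axis at configurable `rg_axis`
(`default_endophenotypes()` uses 0.793, 0.711 and −0.668, with h² 0.3 — a
typical value for imaging-derived traits, which the source data do not pin
down).

**LD is block-diagonal compound-symmetric**, so LD scores are available in
closed form, `l = 1 + (block_size - 1) * rho^2`. Blocks receive correlations
spread evenly over `[0, within_block_corr]`: a constant correlation would make
every LD score identical and the LD score regression slope unidentifiable, so
the spread is what gives the regression leverage. The default block size is 50
with maximum correlation 0.5, chosen to give LD scores a realistic range
(1–13) at desk scale.

What the generator does *not* emulate: realistic human LD maps (no long-range
or inter-block correlation), allele-frequency–dependent architecture,
population stratification in the summary statistics, imputation error, and
X-chromosome inheritance. Tests passing on this generator therefore establish
the *statistical* correctness of the estimators under their stated model, not
robustness to the full texture of real data.

`simulate_cohort()` draws independent binomial dosages (LD is a
summary-statistics-level device here), computes liabilities from the same
causal truth, and can ascertain fixed numbers of cases of each disorder by
batched rejection sampling — necessary because at prevalence 0.4% an
unascertained desk-scale cohort contains almost no cases. An optional ancestry
gradient loads logit allele frequencies on a latent axis carried by PC1.

## LD score regression

`estimate_h2` regresses `chi^2` on `N l_j / M` with the usual
heteroskedasticity weights `1/(l_j (intercept + slope x_j)^2)`, iterated
twice and switchable to unweighted for oracle checks. `estimate_rg` regresses
`z_a z_b` on `sqrt(N_a N_b) l_j / M`; the slope is the genetic covariance, the
intercept the overlap covariance, and `rg = gencov / sqrt(h2_a h2_b)`.
Standard errors come from a delete-one block jackknife over LD blocks (at
most 200 groups). Averaged over seeds the estimators are unbiased at the
study conditions (the test suite asserts recovery within 2 jackknife SEs for
single draws).

The regional scan is deliberately a *simplified stand-in* for full regional
bivariate decomposition: it whitens each region with the known block
correlation (`R^{-1/2}` has a closed form for compound symmetry), tests the
summed chi-square of both traits against its exact null distribution
(stage 1, Bonferroni over all regions), and in retained regions computes
method-of-moments heritabilities `(sum(u^2) - M_r)/N`, covariance
`(sum(u_a u_b) - c M_r)/sqrt(N_a N_b)`, and a plug-in normal test (stage 2,
Bonferroni over retained regions). The two-stage multiplicity scheme — both
traits must pass stage 1, with stage-2 correction over the retained count —
matches the workflow it stands in for.

A practical rule adopted throughout the pipeline: the bivariate intercept is
always *estimated*, but it is only fed downstream (as the case-case
`error_covariance`) when it is resolved from zero (|estimate| > 2 SE). At
desk scale the intercept estimate can be wildly noisy, and feeding an
unresolved estimate into the overlap term degrades the case-case variances;
`casecase_stats` additionally clamps the overlap correlation to (−0.95, 0.95)
with a warning.

## Case-case reconstruction

The ordinary statistic is `delta_a - delta_b` with variance
`var_a + var_b - 2 c sqrt(var_a var_b)`. It tests equality of standardized
case-group frequencies, and is therefore biased away from zero at variants
whose causal *liability* effects are equal but whose prevalence/heritability
configurations differ — the stress scenario.

The exact statistic rescales each disorder by the inverse of its
liability-to-delta factor, `w_t = K_t / phi(tau_t)`, before differencing.
Under the package's conventions this gives *exactly* zero expectation for
equal-liability-effect variants; since the reference method's closed form is
not published in the source for this pipeline, correctness is defined
behaviourally and enforced by a stress-calibration test: over ≥2,000
simulated equal-effect variants at large sample size, the exact path's
rejection rate stays within 1.5× nominal while the ordinary path inflates
severalfold. Both paths are emitted side by side with a `flag_stress` marker
(ordinary significant, exact not); downstream locus definition consumes the
exact path by default, and the sample-size attenuation scalar defaults to 1
and is recorded in the output metadata.

`fst_causal` is the expected squared standardized case-group frequency
difference per causal variant,
`(h2d_a + h2d_b - 2 rg sqrt(h2d_a h2d_b)) / m_causal` with
`h2d = h2_liability * (phi(tau)/K)^2`; it is validated against a
forward-simulation oracle that draws causal effect pairs and averages the
realized squared differences.

## Multi-trait combination

`estimate_omega_sigma` assembles the sampling covariance from pairwise
bivariate intercepts (unit diagonal) and the genetic covariance from the
pairwise regression slopes; an indefinite moment estimate is projected to the
nearest PSD matrix by eigenvalue clipping, with the Frobenius distance
reported. `mtag_combine` is the GLS update
`(w' V^{-1} beta)/(w' V^{-1} w)` with `w = omega[,t]/omega[t,t]` and
`V = Omega_j - w omega[t,]' + S`; it reduces exactly to the input for a
single trait or diagonal matrices, and to inverse-variance meta-analysis
under perfect proportionality (both checked against closed forms). The
effective-sample-size gain is reported as the excess mean chi-square ratio —
an approximation, labelled as such. The false-discovery grid computation of
the reference multi-trait tool is out of scope. Secondary traits are selected
at `|rg| >= 0.65`, and each trait's sign convention is whatever its input
table carries — no silent sign flipping.

## Shared-effect meta-analysis

Stage one removes precision outliers — variants whose log SE-ratio deviates
from the median by more than `k = 3` MAD-scaled robust SDs (the published
filter's exact form is not recoverable from the main text; the MAD rule is a
documented, brute-force-checkable stand-in with configurable `k`) — then
pools by fixed-effects inverse variance. Stage two recomputes every variant
with first-stage `P < 1e-4` under a two-study DerSimonian–Laird
random-effects model and keeps the more conservative p-value
(`p_final = max(p_fe, p_re)`), so `p_final >= p_fe` always. The DL values are
cross-checked against `metafor::rma(method = "DL")` in the tests.

## Loci, credible sets, gene scores

Credible sets use Wakefield approximate Bayes factors under a
single-causal-variant model with prior SD 0.2 on the log-odds scale (a
standard binary-trait prior), coverage 0.95; a region yields a set only if
something is genome-wide significant (`P < 5e-8`), and a numerical failure
falls back to a flagged single-variant set. Multi-signal regions therefore
yield one set per region — a documented divergence from multi-signal
fine-mapping. Top-variant tie-breaks: pip, then p, then position (the last is
invented purely for determinism).

Locus definition merges index variants within 1 Mb by single linkage
(transitive), with bounds at member positions and ids `chrom:start-end`
assigned in genomic order; ids are deterministic per input but not stable
across different inputs. Gene nominations contribute 0.5 points per method
per study; leads are the maximal-score genes, with runners-up within 1.0
retained as joint candidates.

## Polygenic scores

The score builder is a deliberately simple clumping-and-thresholding
stand-in for genome-wide Bayesian weight fitting. For the synthetic
end-to-end evaluation, an inclusive configuration (`p_threshold = 0.01`,
50 kb clumping) is used: at desk scale most of the discriminating signal
lives below genome-wide significance, exactly as genome-wide scoring methods
assume. Standardization follows the ancestry-robust recipe: residualise on
PCs, model the squared residuals log-linearly on the PCs (positivity
guaranteed), divide by the predicted SD, then centre/scale. Metrics: OR/SD
with Wald CI from the logistic model (PCs always adjusted; age/sex when
supplied, except in the univariate AUC/AUPRC); bootstrap percentile CIs
(default 2,000 resamples) for AUC/AUPRC; Nagelkerke gain full-minus-covariate;
liability R² via the Lee ascertainment-corrected transformation with the
population prevalence as configured (sample versus population prevalence is
an explicit argument). One note on that transformation: it does *not* reduce
to the observed-scale R² at prevalence 1/2 (the scale factor is π/2 there),
so no such identity is asserted. Score orientation is never flipped
silently; the end-to-end tests compare orientation-free discrimination
(`max(AUC, 1 - AUC)`).

## Replication statistics

Binomial tails are computed exactly (`P(X >= k)` by summation) and match
exhaustive enumeration to machine precision for n ≤ 25. One-sided replication
p-values are `1 - pnorm(z_repl * sign(beta_disc))`. The allele-frequency
enrichment test is a one-sided Fisher exact test on the 2×2 allele-count
table. Untestable variants are counted, never imputed, and `n` is always the
testable count.

## Problem sizes and numerical choices

The test suite runs at reduced sizes chosen so the whole suite completes in
about a minute while every statistical assertion retains its stated
resolution: 20,000 variants for parameter-recovery checks (50,000 with the
full 1,223-variant causal architecture in the acceptance run), ≥2,000
variants/replicates for calibration rates, 800-case ascertained cohorts for
the score evaluation, and a mean over three replicates for the end-to-end
AUC ordering (whose single-draw margin is a few AUC points). Degenerate
inputs are handled explicitly: empty intersections, constant LD scores,
constant score vectors, rank-deficient PC matrices, zero margins and empty
regions all raise informative errors or flags rather than propagating NaNs.

## Known limitations

* The regional estimator is method-of-moments under known block correlation,
  not a full local decomposition; its p-values rely on the whitening being
  exact, which holds only for the block-compound-symmetric LD of the
  generator (or user-supplied references of the same form).
* The exact case-case weights satisfy the zero-expectation contract under
  the package's delta conventions; they are not a byte-compatible
  re-implementation of the published case-case tool.
* The score builder ignores LD between clumps and shrinks nothing; absolute
  AUCs from it are stand-in quality, though orderings are stable.
* The simulator's independence of cohort genotypes across variants means
  individual-level analyses see no LD; summary-level and individual-level
  results are tied together only through the shared causal truth.
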