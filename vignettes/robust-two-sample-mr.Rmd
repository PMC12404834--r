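---
title: "Robust two-sample Mendelian randomization: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust two-sample Mendelian randomization: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Two-sample Mendelian randomization treats genetic variants as instrumental
variables for a modifiable exposure. For variant $j$ the exposure GWAS
reports $\hat\gamma_j \sim N(\gamma_j, \sigma_{Xj}^2)$ and the outcome GWAS,
measured in a different cohort, reports
$\hat\Gamma_j \sim N(\beta\gamma_j + \alpha_j, \sigma_{Yj}^2)$, independent
of the exposure estimates. $\beta$ is the causal effect of interest (on the
log-odds scale for binary outcomes) and $\alpha_j$ is the variant's direct
(pleiotropic) effect on the outcome, zero for a valid instrument. Everything
in this package operates on these per-variant summary pairs after allele
harmonization; no individual-level data are touched.

Three well-known failure modes drive the design:

* **weak instruments** — when $\gamma_j$ is comparable to $\sigma_{Xj}$, the
  ratio and IVW estimators are attenuated toward zero;
* **pleiotropy** — nonzero $\alpha_j$, either balanced, directional, or
  *correlated* with instrument strength (a shared confounder pathway), the
  last of which breaks the assumption that instrument strength is
  independent of direct effects;
* **winner's curse** — selecting instruments by significance in the same
  sample that supplies $\hat\gamma_j$ inflates the selected estimates and
  worsens the attenuation.

## Estimators

**IVW** is the weighted zero-intercept regression of $\hat\Gamma$ on
$\hat\gamma$ with weights $1/\sigma_Y^2$. The default standard error is
multiplicative random effects: the fixed-effect SE inflated by
$\max(1, \sqrt{Q/(p-1)})$.

**Debiased IVW** replaces the denominator $\sum\hat\gamma_j^2/\sigma_{Yj}^2$
with $\sum(\hat\gamma_j^2 - \sigma_{Xj}^2)/\sigma_{Yj}^2$, removing the
expectation of the squared measurement error, and stays consistent with
many weak instruments. Its standard error is the estimating-equation
sandwich with per-variant score variance
$[(\hat\gamma^2-\sigma_X^2)(\sigma_Y^2+\beta^2\sigma_X^2)
+ \sigma_X^2\sigma_Y^2 + 2\beta^2\sigma_X^4]/\sigma_Y^4$, validated against
the empirical sampling SD in the test suite (agreement within 10% over 500
replicates at 1000 weak instruments). The companion *condition number*
$\hat\kappa = \sum_j(\hat\gamma_j^2-\sigma_{Xj}^2)/\sigma_{Xj}^2 / \sqrt p$
measures effective instrument strength; estimates are flagged weak below a
configurable floor (default 20).

**Robust adjusted profile score (RAPS).** The profile of the joint
likelihood over the nuisance $\gamma_j$ reduces inference to the
standardized residuals
$t_j(\beta,\tau^2) = (\hat\Gamma_j - \beta\hat\gamma_j) /
\sqrt{\sigma_{Yj}^2 + \beta^2\sigma_{Xj}^2 + \tau^2}$.
The estimate maximizes $-\sum_j \rho(t_j)$ where $\rho$ is squared error,
Huber ($k = 1.345$) or Tukey biweight ($k = 4.685$) — the standard
95%-efficiency constants, exposed as arguments. The bounded losses cap any
single variant's influence, which is the robustness to sporadic pleiotropy.
With overdispersion enabled, a systematic-pleiotropy variance $\tau^2$ is
solved jointly from $\sum_j [\psi(t_j)t_j - \delta]/s_j^2 = 0$ with
$\delta = E[\psi(Z)Z]$ under $Z\sim N(0,1)$ (computed by quadrature), the
consistency correction that makes the equation unbiased under the robust
loss; $\tau^2$ is constrained to $[0,\infty)$ and reported as 0 when the
boundary is attained. Optimization alternates a safeguarded scalar search
for $\beta$ (started at the debiased-IVW estimate, whose consistency under
weak instruments provides a good basin) with a monotone root-solve for
$\tau^2$; for bounded losses a coarse scan over the search interval first
locates the best basin and a fine 10^-3^ grid is the fallback when the
alternation fails to settle, in which case the `converged` flag is honest.
Standard errors are M-estimator sandwiches over the one- or two-equation
system; at the $\tau^2=0$ boundary the overdispersion equation is inactive
and the one-parameter sandwich is used.

**Profile-curve diagnostics.** Evaluating the Tukey-loss objective over a
$\beta$ grid (default $[-2,2]$, step 0.001 — wide enough for plausible
log-odds effects) exposes the pathway structure: instruments sharing one
causal pathway produce a single mode; a subset routed through a confounder
adds a second mode at the confounded apparent slope. Modes are strict local
maxima refined by bounded optimization, then filtered by prominence
(default 2 objective units, roughly a likelihood ratio of 2) and pairwise
separation (default 0.05); both defaults are package choices since no
standard filter exists, and both are arguments. Marker variants for a mode
are those with $|t_j| < 1$ at the mode; because $t_j$ is approximately
standard normal at a variant's own mode, only about two thirds of a
pathway's variants can fall inside any unit cutoff — attribution is
therefore sharpest for variants marking exactly one mode. A multimodal
curve with a mode near zero is flagged as the reverse-causation signature.
The package interprets the flag as *any* near-zero mode of a multimodal
curve rather than only a secondary one: which peak dominates depends solely
on how many of the selected instruments truly belong to the outcome, which
is not informative about direction. Note that the signature requires the
true outcome to have genetic signal of its own; a system in which every
variant instruments the exposure produces a single-sloped reverse scatter
and no zero mode, and the bundled reverse-direction fixture therefore
includes outcome-specific variants.

**Multivariable MR** generalizes the residual to K exposures,
$t_j = (\hat\Gamma_j - \sum_k \beta_k\hat\gamma_{jk}) /
\sqrt{\sigma_{Yj}^2 + \sum_k \beta_k^2\sigma_{Xjk}^2}$, assuming
independent exposure measurement errors (the bundled sources are
non-overlapping cohorts; an error-correlation matrix is out of scope). The
covariance is the full sandwich $A^{-1}BA^{-\top}$ rather than the inverse
information alone, which is anticonservative under bounded losses.
Per-exposure Wald tests carry Bonferroni flags at $0.05/K$ (the divisor is
the number of exposures in the model). An exposure whose instrument column
is identically zero is pinned at coefficient 0 — a vacuous adjustment — and
excluded from the optimization, rather than being treated as a rank
failure; genuinely collinear exposures are an error. The modified
conditional Cochran's $Q = \sum_j t_j^2$ with $p-K$ degrees of freedom is
the instrument-validity heterogeneity test.

**BESIDE-MR** puts the profile-form likelihood inside a Bayesian model
average over instrument-inclusion vectors: included variants contribute
$N(\beta_c\hat\gamma_j,\ \sigma_{Yj}^2+\beta_c^2\sigma_{Xj}^2+\tau^2)$,
excluded variants nothing, with one or two effect components. Priors are
deliberately vague on the log-odds scale: $N(0, 10^2)$ on each $\beta$,
half-normal(0.5) on $\tau$, and inclusion prior
$\propto \exp(\lambda\sum_j I_j)$ with minimum model size 2 per component.
The sampler is Metropolis-within-Gibbs (single-bit inclusion flips,
random-walk $\beta$ and reflected random-walk $\tau$, component
reassignment), with the two-component label switching resolved by the
ordering constraint $\beta_1<\beta_2$ enforced through rejection.
Random-walk steps adapt toward acceptance rates in $[0.15, 0.6]$ during
burn-in only and are frozen afterwards, so the post-burn-in chain is a
fixed Markov kernel and a fixed seed reproduces draws bit for bit. The
per-variant posterior probability of inclusion (PPI) is the fraction of
post-burn-in draws retaining the variant. Defaults of 50,000 iterations
with 10,000 burn-in give stable PPIs at $p \le 100$; the bundled analyses
use 20,000/5,000, which the effective-sample-size diagnostic shows is ample
at their scale. A "DL" companion estimate — the l2 profile fit with
overdispersion on the PPI>0.5 subset — is provided as a deterministic
summary and explicitly labelled an interpretation in its metadata. Note
that the posterior mode differs slightly from the RAPS maximizer because
the full normal likelihood keeps the $-\tfrac12\log s_j^2$ term that the
profile score drops; with strong instruments the difference is well inside
one posterior SD.

**Mediation by difference in coefficients.** The total effect comes from
the primary univariable estimator (Tukey RAPS by default), the direct
effect is the exposure's coefficient in the multivariable fit adjusting for
the mediator, and indirect = total − direct holds as an exact identity.
The indirect SE defaults to the independence approximation
$\sqrt{se_T^2 + se_D^2}$ (the two estimates come from separate fits); a
parametric bootstrap alternative is provided and the two are reported when
they disagree by more than 20%. The proportion mediated uses a delta-method
interval that accounts for the dependence between indirect and total, and
is suppressed when $|total| < 2\,se_T$, where a ratio interval is
meaningless.

**Drug-target proxy.** The inhibition exposure orients every cis-eQTL lead
variant to its expression-lowering allele, harmonizes with the downstream
biomarker, retains only variants whose oriented biomarker effect is
strictly negative (a sign test on point estimates, deliberately without any
p-value filter — suitable variants are scarce and the downstream debiased
IVW tolerates weak instruments), and LD-prunes the joined set greedily
(default $r^2 < 0.001$, with 0.8 as the relaxed sensitivity preset). Lead
variants pooled across tissues are deduplicated by the smallest eQTL
p-value. Whether pruning should happen per table or on the joined set is
not standardized; the package prunes the joined set, where the instrument
actually lives. Two-variant instrument sets are a supported path — the
estimator runs and the condition number plus a loud weak-instrument warning
carry the caveat.

## The synthetic-data generator

Every fixture is generated in code from a seeded configuration; the
generator is a first-class, tested module. Defaults mirror the cohort
scale the pipeline targets: exposure GWAS of n = 31,684, binary outcome
GWAS of n = 443,107 on the log-odds scale, allele frequencies uniform on
[0.05, 0.5], and per-variant standard errors following the GWAS scaling
$1/\sqrt{2n\,\mathrm{maf}(1-\mathrm{maf})}$. Instrument strengths are
normal (sd 0.03 by default, a mixed strong/weak regime around the 10^-4^
screen) or spike-and-slab. Pleiotropy options: balanced, directional, or
correlated — a fraction $\pi$ of variants routed through a confounder so
their apparent slope is a second fixed value, which is exactly what makes
the profile curve bimodal. Selection can be none, same-sample (the selected
estimates are reused downstream — winner's curse present) or three-sample
(selection on an independent replicate — curse absent). Binary outcomes are
generated directly on the log-odds summary scale; no individual-level
simulation is performed, matching the two-sample summary paradigm.

What the generator does *not* emulate: linkage disequilibrium between
instruments (the LD module is exercised by a separate block-structured cis
fixture), allele-frequency-dependent effect sizes, sample overlap between
exposure and outcome cohorts, and population stratification. Passing tests
therefore validate the estimators under the stated sampling model, not
against every pathology of real GWAS data.

## Validation design

The test suite validates each operation against an independent oracle:
IVW against weighted least squares ($10^{-10}$), each RAPS loss against an
exhaustive $10^{-4}$ grid search of its own objective, clumping against a
brute-force greedy pass, mode locations against fine-grid scans near the
generating slopes, and the samplers against planted ground truth.
Recovery experiments use 500 seeded replicates at p = 100 with strong
cis-scale instruments (per-variant F around 400) and, for the univariable
cell, an outcome cohort of 5,000 — sized so that per-replicate standard
errors sit at the scale of published MR studies and the Monte-Carlo error
dominates the estimators' genuine second-order biases (which scale as the
square of the noise, while Monte-Carlo error is linear in it; with extreme
per-replicate precision no finite-bias estimator can sit "within Monte-Carlo
error"). The weak-instrument experiment uses 1000 instruments at mean
per-variant F ≈ 2. The analysis scripts run a 300-variant study with
20,000-iteration chains; the whole suite completes in a few minutes on one
CPU.

## Known limitations

* Exposure-error correlations across exposures in the multivariable fit are
  assumed zero unless supplied; overlapping-cohort corrections are out of
  scope.
* The profile-likelihood direction diagnostic is informative only when the
  outcome trait has genetic instruments of its own.
* The BESIDE-MR sampler is single-chain; the ESS diagnostic should be
  checked, and the exported draw table supports external convergence
  tooling.
* No LD reference handling beyond a user-supplied r² matrix: no clumping
  from genotypes, no liftover or rsID resolution.
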