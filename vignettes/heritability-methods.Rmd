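---
title: "Pedigree- and marker-based heritability: models, priors, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree- and marker-based heritability: models, priors, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gherit)
```

## The scientific question

In a multi-generation family study, the narrow-sense heritability of a
quantitative trait can be estimated two ways: from the *expected* genetic
resemblance of relatives, encoded in the pedigree-derived additive
relationship matrix **A** (twice the kinship coefficients), or from the
*realized* resemblance measured at genome-wide SNPs, encoded in the genomic
relationship matrix **G**. Because meiosis samples alleles at random
(Mendelian sampling), realized sharing scatters around its pedigree
expectation: G~ij~ = A~ij~ + d~ij~ with E[d~ij~] = 0. gherit implements both
routes behind a common model so the two estimates — and the predicted
genetic values they produce — can be compared on equal footing.

## The model

Phenotypes are first pre-adjusted: the analysis outcome $y_i$ is the
residual of an ordinary least-squares regression of the trait on sex, age,
two ancestry principal components, and cohort (dummy-coded against its
first level). The genetic model is then

$$\mathbf{y} = \mathbf{1}\beta_0 + \mathbf{u} + \boldsymbol{\varepsilon},
\qquad \mathbf{u} \sim N(\mathbf{0}, K\sigma^2_u), \qquad
\boldsymbol{\varepsilon} \sim N(\mathbf{0}, I\sigma^2_\varepsilon),$$

with $K = A$ (pedigree kernel) or $K = G$ (genomic kernel). Narrow-sense
heritability is $h^2 = \sigma^2_u / (\sigma^2_u + \sigma^2_\varepsilon)$.
The two-stage analysis (pre-adjust, then fit the genetic model on
residuals) is deliberate: it mirrors the standard workflow in family-based
heritability studies, keeps the coefficient table interpretable on the
trait's original scale, and makes the same residuals available to both
kernels. A joint fit would be statistically tidier but would entangle the
comparison we care about; the fixed-effect fitted values are retained so
predicted values can combine both parts.

The G matrix entries are

$$G_{ik} = \frac{1}{p}\sum_{j=1}^{p}
\frac{(x_{ij} - 2\theta_j)(x_{kj} - 2\theta_j)}{2\theta_j(1-\theta_j)},$$

where $x_{ij} \in \{0,1,2\}$ counts the coded allele and $\theta_j$ is its
estimated frequency. The diagonal uses the same formula (no special case),
so mean diag(G) ≈ 1 when frequencies are estimated in-sample. G is
invariant to allele-coding flips ($x \to 2-x$, $\theta \to 1-\theta$),
which is enforced by a unit test.

## Genotype quality control and imputation

QC follows the standard order for marker panels: individuals with call
rate below 90% are removed first; SNP call rates and allele frequencies
are recomputed on the survivors; SNPs with call rate below 90% or minor
allele frequency below 0.5% are then removed. Every removal is logged with
its token, reason and value. The recompute-after-individual-removal order
matters — a SNP that failed only because of a badly genotyped individual
is retained once that individual is gone — and is covered by a dedicated
test.

After filtering, the allele frequencies are **frozen**. Remaining missing
genotypes are imputed by sampling from Binomial(2, $\theta_j$) — the
Hardy-Weinberg draw — and $\theta$ is *not* re-estimated afterwards, so
imputation and standardization share one estimate. At ~1% missingness the
alternative (re-estimating after imputation) moves G entries only in the
third decimal, but the frozen convention makes the pipeline a pure
function of the filtered data and the seed.

## Priors and the Gibbs sampler

Both variance components get a scaled inverse chi-square prior with scale
$S = 2$ and degrees of freedom $\nu = 5$, fixed in the parameterization

$$p(\sigma^2) \propto (\sigma^2)^{-(\nu/2+1)} e^{-S/(2\sigma^2)},$$

i.e. $\sigma^2 = S/\chi^2_\nu$ with prior mean $S/(\nu-2) = 2/3$. "Scale
2, df 5" is ambiguous across software parameterizations; we adopt the
convention above (that of the Bayesian regression packages this model
family comes from) and document the prior mean it implies. The intercept
gets an improper flat prior; its full conditional is Gaussian.

The sampler exploits the spectral decomposition $K = UDU^\top$, computed
once per kernel. In rotated coordinates ($z = U^\top y$, $o = U^\top
\mathbf{1}$) every update is $O(n)$:

1. $\beta_0 \mid \cdot \sim N\!\big(\sum_m o_m(z_m - u^*_m)/n,\;
   \sigma^2_\varepsilon/n\big)$;
2. each rotated genetic effect independently,
   $u^*_m \mid \cdot \sim N\!\big(v_m (z_m - o_m\beta_0)/\sigma^2_\varepsilon,\, v_m\big)$
   with $v_m = (1/(D_m\sigma^2_u) + 1/\sigma^2_\varepsilon)^{-1}$;
3. $\sigma^2_u \mid \cdot \sim \text{scaled-inv-}\chi^2(\nu + r,\;
   S + \sum_m u^{*2}_m / D_m)$ with $r$ the kernel rank;
4. $\sigma^2_\varepsilon \mid \cdot \sim \text{scaled-inv-}\chi^2(\nu + n,\;
   S + \text{RSS})$.

Eigenvalues below $10^{-10}\times\max(D)$ carry no genetic signal and
their $u^*_m$ are pinned at 0, avoiding division blow-ups. If the minimum
eigenvalue of a kernel falls below $10^{-10}$, a jitter of $10^{-8}$ is
added to the diagonal (logged in the fit's notes); a kernel indefinite
beyond that is refused. Heritability is computed per draw and summarized
by its posterior mean and SD — the "±" reported in the summary tables is
the posterior SD, labelled as such. Default chain settings are 30 000
iterations, 5 000 burn-in, thinning 5; they were sized so the effective
sample size of $h^2$ comfortably exceeds 400 on studies of about a
thousand individuals, and everything is configurable. Fits warn when
ESS($h^2$) drops below 100.

The model "log likelihood" reported alongside the estimates deserves a
caveat: for a Bayesian fit this quantity has no single definition. We
compute the Gaussian *marginal* log-likelihood of y at the posterior-mean
$(\beta_0, \sigma^2_u, \sigma^2_\varepsilon)$ — a well-defined, reproducible
summary — and label it accordingly.

### Independent oracles

Two deterministic cross-checks guard the sampler. `gridMLOracle()`
profiles the Gaussian marginal likelihood over a heritability grid
(intercept and total variance profiled analytically), and
`gridPosteriorSurface()` evaluates the exact likelihood-times-prior
surface over a 2-D variance grid with the genetic values and intercept
integrated out — the density the Gibbs chain targets. The test suite
requires the chain's most probable draw to land within one grid cell of
the surface's maximum, and the zero-data full conditional to reproduce
the prior mean 2/3.

## The synthetic family study

The generator provides every downstream stage with truth-bearing input.
Its defaults are the study conditions the package is validated under:

* **Pedigree**: founders with balanced sexes; within each later
  generation, random non-overlapping monogamous matings (no selfing;
  full-sib pairings avoided when a swap can fix them), a configurable
  number of offspring per mating, cohort = generation. Three generations
  by default, matching the classic long-running family-cohort design.
* **Genotypes**: founder allele frequencies drawn Uniform(0.05, 0.5) so
  every SNP is polymorphic and survives QC; gene dropping transmits one
  uniformly chosen allele per parent per SNP. SNPs segregate
  independently — see limitations.
* **Covariates**: sex from the pedigree (effect coded on a female
  indicator), age Uniform(19, 92) — the adult span of such cohorts —
  PC1/PC2 standard normal ancestry proxies, cohort = generation.
  Default effects (−0.96 for the female indicator, −0.032 per year of
  age, cohort shifts 0.28 and 0.44) are of the size seen for lung
  volumes in litres in adult cohort studies, so the fixed-effect share of
  variance is realistic.
* **Phenotype**: total variance 1 split as $\sigma^2_u = h^2$ and
  $\sigma^2_\varepsilon = 1 - h^2$, default $h^2 = 0.5$. In
  `marker_effects` mode the genetic value is
  $u_i = \sum_j (x_{ij} - 2\theta_j) a_j$ with
  $a_j \sim N(0, \sigma^2_u / \sum_j 2\theta_j(1-\theta_j))$, aligning
  the generative variance with the standardized-G denominator; in
  `infinitesimal` mode $u \sim N(0, A\sigma^2_u)$.
* **Missingness**: 1% of entries masked completely at random.
* **Determinism**: every stage seed derives from the single master seed,
  so a rerun of the same spec is byte-identical.

A separate, purely phenotypic helper (`simulateSpirometry()`) generates
FEV1/FVC-style traits from a shared lung-size factor and an independent
airway-patency ratio, reproducing the canonical pattern that the two
volumes correlate highly while each correlates only weakly with their
ratio.

### What the generator does *not* emulate

* **Linkage.** Real chromosomes segregate in large chunks, which inflates
  Var(G~ij~ | A~ij~) at higher relationship levels. With independently
  dropped SNPs E[G] = A still holds (and is tested), but the dispersion
  of G around A is understated, so the characteristic fanning of the
  G-vs-A scatter at close relationships is reproduced only qualitatively.
  The per-bin variance of G is therefore *reported*, not asserted to be
  monotone in A.
* **Shared environment.** Residuals are i.i.d., so the generator cannot
  produce the confounding of familial environment with pedigree
  relatedness that inflates pedigree-based estimates in real data.
* **Real LD and allele-frequency spectra**, genotyping error, X-linked or
  non-additive variance.

Consequently, passing tests demonstrate internal correctness and
calibration of the estimators under the additive model's own assumptions
— not robustness to the violations above.

## Validation design and problem sizes

The suite validates each stage against an independent route: the tabular
A against a memoized recursive-kinship oracle on randomized pedigrees up
to n = 200; G against a naive double-loop evaluation of its formula and a
hand substitution; the gene dropper against the E[G] = A identity over
200 replicates of 5 000 unlinked SNPs for every classic relationship
class; the covariate adjustment against exact interpolation,
orthogonality and parameter-recovery checks; and the sampler against the
analytic posterior surface at n = 200, parameter recovery over ten
replicates at n ≈ 500, and the pedigree-vs-SNP agreement study at
n ≈ 1000 with p = 5000 (ten replicates; the two kernels must agree within
0.1 on $h^2$ in at least 80% of them, with predicted-value correlations
averaging at least 0.8). Short chains (4 000 iterations) are used inside
the tests because the rotated sampler mixes quickly at these sample
sizes; the chain-length defaults remain conservative for real use.

## Degenerate inputs and tie-breaks

* An unknown parent contributes nothing to the tabular recursion — it is
  treated as an unrelated, non-inbred founder; founders are assumed
  non-inbred. How partially missing pedigrees were handled in any
  particular historical dataset is rarely stated, so this convention is
  documented rather than guessed at.
* `trueH2 = 1` yields $\sigma^2_\varepsilon = 0$; the generator permits it
  but flags the degenerate residual.
* With $K = I$ the two variance components are not identifiable; the
  profile likelihood is flat in $h^2$ (covered by a test) and the
  posterior follows the prior along the flat direction.
* Monomorphic SNPs make the G standardization divide by zero;
  `computeG()` refuses them and points at the QC filter.
* Zero-variance phenotype columns make correlations undefined; they are
  flagged rather than silently dropped.

## Known limitations

Dense matrices throughout: the implementation targets study sizes up to
roughly 10^4 individuals, where an n × n eigendecomposition is cheap;
no sparse A-inverse machinery is included because the sampler works with
the kernel directly. One trait and one kernel per fit — multi-trait and
multi-kernel (A + G) models are out of scope. REML is provided only as a
grid-based test oracle, not as a production fitting route. And the
pedigree-vs-SNP comparison inherits the generator's idealizations listed
above: on real data, the two estimates can differ for reasons the
synthetic study cannot produce.
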