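---
title: "Estimating gene-to-trait effects with allelic heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating gene-to-trait effects with allelic heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

An eQTL study reports, per SNP, an estimated effect of genotype on a gene's
expression; a GWAS reports the effect of the same SNPs on a downstream trait.
If expression of the gene *mediates* the trait, SNPs that perturb expression
should perturb the trait in proportion, and the proportionality constant — the
gene-to-trait slope $\alpha$ — is the causal effect of a unit change of
(standardized) expression on the (standardized) trait. This is the logic of
two-sample Mendelian randomization with cis-eQTLs as instruments.

`hetmr` estimates $\alpha$ from summary statistics alone (coefficients,
standard errors, p-values, allele codes) plus an LD matrix, for loci with
*allelic heterogeneity*: two or more nearly-LD-independent eQTL signals.
Alongside $\alpha$ it estimates a dispersion $\sigma$, the SD of per-signal
trait effects around the fitted line, which quantifies how variable the
mediated effect is across regulatory elements at the locus — information that
matters when choosing whether to perturb a gene directly or through one of
its enhancers.

## Pipeline

1. **Harmonization.** The two studies are joined on SNP id and study B is
   re-oriented to study A's effect alleles (a swapped coding negates the
   coefficient). No strand inference is attempted: pairs that only match
   after complementation are dropped, as are swapped palindromic (A/T, C/G)
   SNPs, where a swap cannot be distinguished from a strand flip. SNPs with
   MAF below 0.01 (in either study) are removed.
2. **Clumping.** Greedy clumping on eQTL p-values (index p < 0.001, members
   with $r^2 \ge 0.1$ to the index within 500 kb) yields signal clusters;
   clusters are then trimmed so that all retained key SNPs are pairwise
   nearly independent ($r^2 < 0.05$), dropping weaker-index clusters first.
   Trimming runs twice: on clump index SNPs before colocalization and on
   candidate causal SNPs after.
3. **Orientation and collapsing.** Within each cluster all SNPs are flipped
   into positive correlation with an index whose eQTL coefficient is
   positive (so results always refer to expression-increasing alleles), and
   SNPs correlated above r = 0.95 are collapsed to a representative (the
   smallest eQTL p-value in the group). A representative therefore stands
   for a set of statistically indistinguishable SNPs.
4. **Colocalization.** Per cluster, a shrinkage model proposes one candidate
   causal SNP (below).
5. **Slope fitting.** The candidates' posterior effect summaries form one
   instrument per cluster, and a hierarchical errors-in-variables regression
   estimates $\alpha$ and $\sigma$.

## The colocalization model

For study $S \in \{A, B\}$ and the $n$ representatives of a cluster with
signed LD matrix $R_S$, observed coefficients $\hat\beta_{i}$ with standard
errors $se_i$:

$$\hat\beta_i \sim \mathrm{N}\big((R_S \beta)_i,\; se_i\big), \qquad
\beta_i = \tau \lambda_i z_i,\; z_i \sim \mathrm{N}(0,1),\;
\lambda_i \sim \mathrm{C}^+(0,1),\; \tau \sim \mathrm{C}^+(0,\tau_0).$$

The likelihood is univariate per SNP — LD enters only through the mean
$R_S\beta$ — which keeps the model fast and robust compared to a full
multivariate-normal likelihood on z-scores. The horseshoe prior on the true
effects $\beta$ pushes all but a few coordinates to zero, so when a single
SNP drives both studies its posterior means are large in both, and a SNP
driving only the eQTL signal keeps a GWAS posterior mean near zero — exactly
the quantity the slope step needs. The candidate causal SNP is the member
with the largest posterior mean eQTL effect (ties broken by smaller eQTL
p-value, then position).

The global scale adapts to the cluster. The default rule is
$\tau_0 = \mathrm{median}(se)/n$: the noise scale times the expected nonzero
fraction when one causal SNP is expected among $n$ representatives. An
alternative rule `tau0_rule = "scale"` uses $\max|\hat\beta|/n$, adapting to
the coefficient scale instead; both are exposed, and the default was chosen
because it gave near-zero slope bias in the package's own mediated-locus
simulations. Each study gets an independent horseshoe (no sharing of local
scales across studies). The slope step consumes, per study, the posterior
mean and SD of the candidate's **fitted marginal effect** $(R\beta)_{cand}$
as instrument coefficient and SE. The fitted-marginal functional matters:
the posterior of the joint effect $\beta$ itself is asymmetrically resolved
when one study is far better powered than the other (a GWAS with $10^5$
samples pins its joint effect, while the eQTL posterior mean is diluted by
model averaging over correlated members), which inflates the slope; on the
fitted-marginal scale both studies are commensurate and LD between the
candidate and the underlying causal SNP cancels in the ratio. The joint
posterior (`instrument_mode = "posterior"`) and pass-through observed
coefficients (`"raw"`, for externally chosen candidates) remain available,
as does a `"marginal"` likelihood that drops $R$ from the mean entirely and
behaves almost identically to the default.

Because every conditional distribution of this model is available in closed
form (the half-Cauchy scales admit an inverse-gamma augmentation), the
posterior is sampled by an exact Gibbs sampler rather than a generic
gradient-based sampler; draws are reproducible given the seed. Before use,
the LD diagonal receives a ridge of $10^{-3}$ for conditioning; the
conditional precision matrix of $\beta$ is positive definite by construction.

## The slope model

With one instrument per cluster $j = 1..J$:

$$\hat\beta_{jA} \sim \mathrm{N}(\beta_{jA}, se_{jA}), \quad
\hat\beta_{jB} \sim \mathrm{N}(\beta_{jB}, se_{jB}), \quad
\beta_{jA} \sim \mathrm{N}(0, SD_\beta), \quad
\beta_{jB} \sim \mathrm{N}(\alpha\,\beta_{jA}, \sigma).$$

All scale parameters are standard deviations. There is no intercept: the
mediation line passes through the origin, encoding the assumption that
instruments affect the trait only through the gene. Unlike a plain
inverse-variance-weighted regression, the latent $\beta_{jA}$ carry their
own uncertainty, which propagates into the interval for $\alpha$; in the
degenerate limit ($\sigma \to 0$, $se_{jA} \to 0$, diffuse $SD_\beta$) the
posterior mean of $\alpha$ collapses onto the IVW fixed-effects estimate,
and the test suite verifies this against an independent quadrature oracle.

Hyperprior scales adapt to the data and are all overridable via the `prior`
argument of `fit_slope()`:

* $SD_\beta \sim \mathrm{N}^+(0, \max_j|\hat\beta_{jA}|)$ — the instrument
  effects live at the scale of the largest observed exposure coefficient;
* $\alpha \sim \mathrm{N}(0, 2\,\mathrm{rms}(\hat\beta_B)/\mathrm{rms}(\hat\beta_A))$
  — twice the crude scale ratio of the two studies, weakly informative;
* $\sigma \sim \mathrm{N}^+(0, s)$ with
  $s = 2\sqrt{\max\big(\mathrm{mean}(r^2) - \mathrm{mean}(se_B^2) -
  \hat\alpha_0^2\,\mathrm{mean}(se_A^2),\; \mathrm{mean}(se_B^2)/4\big)}$,
  where $r$ are the residuals of a preliminary weighted least-squares fit —
  a moment-matched estimate of the *excess* dispersion beyond the stated
  observation noise. Subtracting the noise keeps the prior from absorbing
  pure measurement scatter into $\sigma$ (which would widen the slope
  interval and make null-slope detection conservative); the factor 2 keeps
  prior mass above the point estimate, and the floor prevents degeneracy on
  perfectly collinear input.

Sampling is again Gibbs: the latent effects and $\alpha$ have conjugate
normal conditionals, and the two scale parameters are updated by univariate
slice sampling on the log scale. Defaults are 4 chains of 1000 warmup + 1000
retained iterations; split-$\hat R$ above 1.05 attaches a convergence
warning to the fit. Reported intervals for $\alpha$ and $\sigma$ are
empirical quantiles of the draws at the requested level (default 0.80,
the level used throughout the package's figures).

With a single signal cluster ($J = 1$) the dispersion is not identified and
`fit_slope()` refuses to run (an `insufficient allelic heterogeneity`
warning) unless forced.

Two derived summaries make fits comparable across loci: the **mean mediated
effect**, $\bar m = \hat\alpha \cdot \mathrm{mean}_j(\hat\beta_{jA})$ (the
typical trait change delivered through the gene), and the **dispersion
ratio** $\hat\sigma / |\bar m|$ (how much individual signal clusters deviate
from the line, relative to the typical mediated effect).

## What the synthetic data emulates

The generator reproduces the structure of a TWAS-style locus simulation:

* **Genotypes** (`simulate_genotypes`): two latent Gaussian haplotypes per
  individual with AR(1) correlation `rho` (default 0.9) across SNPs,
  thresholded at MAF-matched quantiles (MAF uniform on [0.05, 0.5]) and
  summed to dosages, then standardized. Two cohorts simulated with shared
  `maf` share population LD, mimicking eQTL and GWAS samples from one
  population.
* **Studies** (`simulate_study`): a causal set of 1% of SNPs; eQTL effects
  $\beta_j \sim \mathrm{N}(0, h^2_g/n_{causal})$; expression built as
  $y = Z\beta + \varepsilon$ with the error variance set from the realized
  genetic variance so the target heritability is met, then standardized.
  The trait is built the same way at heritability $h^2_{med}$. In mediated
  mode the GWAS effects are the eQTL effects rescaled by
  $\sqrt{h^2_{med}/h^2_g}$ — the printed trait construction admits a single
  slope only under a deterministic rescale, and the resulting true slope
  satisfies $h^2_{med} \approx h^2_g\,\alpha^2$ exactly up to the
  realized-versus-target variance gap. In null mode the trait is an
  independent second draw (own causal set, heritability $h^2_g$), so the
  locus carries trait-only association signals and the true slope is 0. The
  horizontal-pleiotropy mode adds three trait-only signals of SD
  $\sqrt{h^2_{med}}$ on top of mediation.
* **Defaults** mirror the study design: $N_{eQTL} = 500$,
  $N_{GWAS} = 100{,}000$, 1% causal SNPs, 1000-SNP loci.
* **Correlated instruments** (`simulate_correlated_instruments`): direct
  multivariate-normal coefficient draws with eQTL means 10, GWAS means 0
  (true slope 0), adjacent-cluster correlation $\sqrt{r^2}$, unit SEs. For
  adjacent $r^2 = 0.5$ the banded matrix loses positive-definiteness and is
  eigen-clipped and rescaled to unit diagonal.

What it does **not** emulate: real haplotype block structure and long-range
LD (AR(1) correlation decays geometrically, so leakage between distant
signals is rarer than in real reference panels), population structure,
relatedness, allele-frequency-dependent effect sizes, and winner's-curse
ascertainment across many real loci. Calibration results on this generator
therefore speak to the model's statistical behavior under short-range-LD
loci, not to every property of real-data analyses.

## Problem sizes and numerical choices

The test suite and the acceptance script run reduced-but-faithful problem
sizes chosen as the package's own benchmark configuration: 400-SNP loci,
2 MCMC chains of 300 warmup + 600 retained iterations, 20 (tests) to 60
(benchmark script) mediated loci and 15-30 null loci per heritability setting, 100 correlated-instrument iterations
per cluster count, and 200 replicates for slope-model recovery. One large
GWAS genotype panel is drawn per simulation setting and reused across locus
replicates (fresh eQTL panels, causal sets and phenotypes per locus), which
leaves the per-locus randomness in the quantities that matter. Monte-Carlo
tolerances in tests are set from binomial or MCSE error at those sizes.

Degenerate inputs are handled explicitly: monomorphic simulated SNPs are
redrawn (bounded retries); p-values are floored at the smallest positive
double; an empty study intersection or an all-zero exposure is an error;
ties in candidate selection, clumping and collapsing break deterministically
(smaller p-value, then smaller position).

## Known limitations

* The dispersion $\sigma$ is only informative with several clusters; at
  $J = 2$–3 its posterior is prior-dominated and its interval wide.
* No MR-Egger-style intercept: directional pleiotropy shared across all
  instruments biases $\alpha$ (the dispersion absorbs only heterogeneous
  pleiotropy).
* Candidate SNPs are identified up to the collapsed high-correlation group;
  the method deliberately does not claim single-variant resolution.
* Strand-ambiguous harmonization drops data rather than guessing; studies
  coded on opposite strands lose their palindromic and complement-coded
  SNPs.
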