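---
title: "Inferring birth and death rates from particle snapshots"
author: "snapBDD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring birth and death rates from particle snapshots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snapBDD)
```

## The model and its assumptions

Single-molecule imaging of fixed cells (smFISH and relatives) resolves the
positions of individual RNA molecules at one instant, but fixation destroys
the dynamics that produced them. snapBDD models the simplest mechanistic
account of such data in one dimension: particles are born at a gene site
$z$ at rate $\kappa_+$, diffuse with diffusivity $D$ inside a domain
$[0, L]$ whose ends absorb (instantaneous nuclear export), and are degraded
at rate $\kappa_-$. Only the ratios

$$\lambda = \frac{\kappa_+ L_0^2}{D}, \qquad \mu = \frac{\kappa_- L_0^2}{D}$$

are identifiable from a snapshot, so the package works throughout in
nondimensional coordinates (diffusivity 1, lengths in units of the typical
cell size $L_0$); `nondimensionalize()` performs the conversion.

If births have been running since long before the observation (the process
is stationary), the set of observed positions in one cell is an
inhomogeneous spatial Poisson point process: counts in disjoint regions are
independent and Poisson, with intensity $u$ solving the boundary-value
problem

$$0 = u''(x) + \lambda\,\delta(x - z) - \mu\,u(x), \qquad u(0) = u(L) = 0,$$

whose closed form is

$$u(x) = \frac{\lambda}{\sqrt{\mu}}\,
  \operatorname{csch}(\sqrt{\mu}\,L)\,
  \sinh(\sqrt{\mu}\,\min(x,z))\,\sinh(\sqrt{\mu}\,(L - \max(x,z))),$$

with expected count
$E[N] = \frac{\lambda}{\mu}\bigl[1 - \operatorname{sech}(\sqrt{\mu}L/2)
\cosh(\sqrt{\mu}(L - 2z)/2)\bigr]$. Every hyperbolic argument carries
$\sqrt{\mu}$; this is verified in the test suite against an independent
second-order finite-difference solve of the boundary-value problem
(`solveIntensityNumeric()`) and against a time-dependent occupation-measure
integration, and the closed-form $E[N]$ is checked against adaptive
quadrature of $u$ across a parameter sweep.

The assumptions that matter: a *point* source (not a spatially extended
one), zero drift, perfectly absorbing walls, first-order decay, and
stationarity at the observation time. None of bursty transcription,
gated export (Robin boundaries), subdiffusion, or dimensions above one are
modelled.

## Likelihood and information

For cell $m$ with geometry $\vartheta_m = (z_m, L_m)$ and observed
positions $x^m$, the exact point-process log-likelihood is
$\ell(\theta) = \sum_m \bigl[\sum_i \log u(x^m_i;\theta,\vartheta_m) -
E[N_m]\bigr]$ (`logLikelihood()`). Binning positions into $K$ spatial bins
gives independent Poisson counts with means $\int_{A_k} u$
(`binnedLogLikelihood()`); as the mesh is refined the binned likelihood
recovers the exact one, and for any finite partition the binned Fisher
information for $\mu$ is strictly smaller (a Cauchy–Schwarz argument,
checked numerically by `binnedInformation()`), while the scale parameter
$\lambda$ loses nothing to binning. This is the quantitative sense in which
keeping exact positions beats count-based summaries.

The Fisher information matrix
$I_{ij} = \int_0^L \partial_{\theta_i} u\,\partial_{\theta_j} u / u \,dx$
(`fisherInformation()`) uses $\partial_\lambda u = u/\lambda$ exactly, so
$I_{\lambda\lambda} = E[N]/\lambda^2$, and an analytic
$\partial_\mu u$ (finite differences serve only as a test oracle, since
quadrature of near-singular integrands amplifies their noise). Quadrature
is adaptive Gauss–Kronrod applied separately on $[0, z]$ and $[z, L]$
(tolerance $10^{-10}$) because the kink at the source degrades single-panel
schemes. $\det I$ is the D-optimality score: at large $\mu$ it is maximised
by a central source, while for small $\mu$ two symmetric off-centre optima
appear; `optimalSourceLocation()` evaluates the $z$-profile on a fixed
201-point grid with ties broken toward smaller $z$ so results are
deterministic.

Cell-to-cell heterogeneity is modelled by $z/L \mid L \sim
\mathrm{Beta}(1/\sigma_z, 1/\sigma_z)$ (mean $L/2$; $\sigma_z = 1$ is
spatially uniform) and $L \sim \Gamma(1/\sigma_L^2,
\mathrm{scale}=\sigma_L^2)$ (mean 1, variance $\sigma_L^2$).
`heterogeneousInformation()` averages $I$ over these laws with tensorised
Gauss quadrature — Gauss–Jacobi in $z/L$ and generalized Gauss–Laguerre in
$L$, 32 nodes per dimension by Golub–Welsch — with a seeded Monte Carlo
fallback for diagnostics. $\sigma_z = 0$ and $\sigma_L = 0$ are treated as
exact point masses (the Beta/Gamma parameterisations are undefined there),
which the static baseline of the experiment driver needs. In the low-$\mu$
regime geometric heterogeneity *increases* $\det E_\vartheta[I]$; at large
$\mu$ it decreases it.

## Simulators: the stated world

`simulateSnapshotTrajectories()` is the ground-truth generator: a Poisson
number of births on a finite history window $(-T_0, 0]$, Euler–Maruyama
steps $x \mathrel{+}= \sqrt{2\,dt}\,\eta$, exponential lifetimes drawn once
at birth (exact, cheaper than per-step thinning), and absorbing walls.
Numerical choices:

* **History horizon.** $T_0 = -\log(\texttt{burnInTol})/(\mu + \pi^2/L^2)$
  with default tolerance $10^{-7}$: $\mu + \pi^2/L^2$ is the slowest decay
  rate of the survival probability (death rate plus the leading Dirichlet
  eigenvalue of the Laplacian), so births before $-T_0$ contribute less
  than the tolerance. This implements the pullback of the birth process to
  $-\infty$ at finite cost.
* **Within-step absorption.** A step that lands outside kills the
  particle; a step that stays inside may still have crossed. The
  Brownian-bridge crossing probability for a step of variance
  $\sigma^2 = 2\,dt$ with endpoint distances $d_1, d_2$ to a wall is
  $\exp(-2 d_1 d_2/\sigma^2) = \exp(-d_1 d_2/dt)$, applied independently
  per wall. (Note the $2\,dt$ in the denominator sometimes quoted for unit
  diffusivity does not apply here because the nondimensional process has
  generator $\partial_{xx}$, i.e. step variance $2\,dt$; with the
  correction in this form the simulated mean count matches the closed-form
  $E[N]$ even at coarse $dt$, while the $2\,dt$ variant measurably
  over-absorbs.) Default $dt = 10^{-4}$.
* **Observation time** is exactly $t = 0$; the "experimental time" of a
  snapshot experiment is identified with the equilibration horizon $T_0$.

`sampleSnapshotDirect()` generates from the Poisson-process description
directly (count from `expectedCount()`, positions by inverse CDF of
$u/\int u$ on a 4096-point grid) and is the fast generator used in the
inference experiments; the test suite checks that the two routes agree
(per-bin Poisson counts, independence across disjoint bins, KS tests on
positions). What a green trajectory-vs-theory test establishes is that the
point-process description holds for this stated world — stationary births,
a point source, memoryless decay; it does not validate the model against
features real smFISH data have and the model lacks (bursting, nonstationary
induction, 2D/3D geometry, localisation error).

Per-cell reproducibility uses substreams: the master seed draws one
integer seed per cell, so a fixed master seed reproduces a `SnapshotSet`
bit-identically regardless of how many cells are generated.

## Bayesian inference

A Gamma$(\alpha, \beta)$ prior on $\lambda$ is conjugate given $\mu$:
with $u = \lambda v$,
$\lambda \mid x, \mu \sim \mathrm{Gamma}(\alpha + \sum_m n_m,\;
\beta + \sum_m \int v_m)$. The sampler (`samplePosterior()`) alternates
this exact Gibbs draw with a Gaussian random-walk Metropolis update of
$\mu$ under a Uniform$(0, \mu_{max})$ prior. Defaults — $\alpha = 2$,
$\beta = 0.004$ (prior mean 500, weakly informative on the scale of the
experiments here), $\mu_{max} = 100$ — are deliberate choices in the
absence of published values, and everything is configurable. The proposal
scale adapts every 50 burn-in iterations toward 30% acceptance and is
frozen afterwards, preserving detailed balance for retained draws. Four
chains from dispersed $\mu$ starts are pooled; $\lambda$ is initialised at
its conditional MLE so no chain starts at $-\infty$. Because $\lambda$ and
$\mu$ are strongly correlated along the curve of constant $E[N]$, the
random walk diffuses slowly along that ridge; default chain lengths
(12000 with 2000 burn-in, four chains) are chosen so the pooled effective
sample size exceeds 200 on $M = 100$ data.

The 89% highest-density posterior region (`hdpr()`) follows the
top-density-samples construction: evaluate the unnormalised posterior at
every pooled draw, keep the top 89%, and take the convex hull (area by the
shoelace formula). For banana-shaped small-$M$ posteriors the hull
overestimates the region; it is kept because the hull area is the measured
quantity of record in this framework. Per-draw likelihood terms are cached
in the chains object so the hull step costs $O(\text{draws})$, which is
what makes the repeated-inference experiment (400 fits) affordable.
The HDPR area scales like $M^{-1}$, each parameter contributing a
central-limit $M^{-1/2}$.

`runHeterogeneityExperiment()` repeats the full pipeline (sample
geometries, simulate, fit, measure HDPR area) across the four scenarios
static / random-$z$ / random-$L$ / both. Repeats are *paired*: one seed per
repeat drives all scenarios, so scenario contrasts are within-repeat (the
original design leaves this unstated; pairing was chosen because it removes
between-repeat noise from the comparison). Relative source positions
within $10^{-4}$ of a wall are resampled and counted, since they produce
near-empty snapshots and $-\infty$-prone likelihoods. The default 100
repeats (rather than 1000) keeps the experiment at desk scale; the median
ordering — heterogeneous scenarios beat the static one at $\mu = 1$ — is
robust at that size.

## Degenerate inputs and numerical edges

* $\sqrt{\mu}\,a$ overflows $\sinh$ near 710, so all evaluation is in log
  space via $\log\sinh(y) = y + \log(1 - e^{-2y}) - \log 2$; results stay
  finite to $\sqrt{\mu}L \approx 700$ and beyond.
* $\mu < 10^{-10}$ switches to the analytic limits
  $u = \lambda \min(x,z)(L - \max(x,z))/L$ and $E[N] = \lambda z(L-z)/2$
  (the hyperbolic form is $0/0$ at $\mu = 0$).
* Positions exactly at $0$ or $L$ are rejected as invalid data — the model
  puts zero intensity at absorbing walls, so such points indicate a
  preprocessing error, and the readers name the offending rows.
* $\lambda = 0$ with particles present returns a $-\infty$ log-likelihood
  sentinel rather than an error.

## Known limitations

One-dimensional, point-source, drift-free, perfectly absorbing model only;
no inference of the heterogeneity hyperparameters $(\sigma_z, \sigma_L)$;
the convex-hull HDPR overestimates credible area for strongly curved
posteriors; and the Metropolis step is a plain random walk — efficient
enough here, but slow if extended to posteriors with much heavier
$\lambda$–$\mu$ curvature.

## A worked call

```{r example, eval = FALSE}
theta <- NondimParams(lam = 500, mu = 10)
geom <- CellGeometry(L = 1, z = 0.5)
data <- simulateSnapshotSet(theta, rep(list(geom), 100), seed = 1)
fit <- samplePosterior(data, PriorSpec(), seed = 2)
posteriorSummary(fit)
hdpr(fit, prior = PriorSpec())
```
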