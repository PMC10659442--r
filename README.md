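# snapBDD

Inference of birth and death rates of diffusing particles from fixed-time
**snapshots** of their positions.

## The problem

Imaging of fixed cells (for example single-molecule FISH of nuclear RNA)
reports the exact positions of individual molecules in each cell at one
instant — and nothing about their history. Yet those positions are shaped
by the production rate at the gene site, the degradation rate, and
diffusion to the absorbing nuclear boundary. snapBDD is for researchers who
want to turn per-cell point patterns like these into estimates of the
underlying demographic rates, with honest joint uncertainty, across
hundreds of cells that differ in size and gene-site position.

## The model

Particles are born at rate κ₊ at a source z inside a 1D domain [0, L],
diffuse with diffusivity D, are degraded at rate κ₋, and are removed on
contact with the absorbing ends. Only the nondimensional combinations

    λ = κ₊L₀²/D,   μ = κ₋L₀²/D

are identifiable. At stationarity, the observed positions form an
inhomogeneous spatial Poisson point process whose intensity u solves

    0 = u″(x) + λ δ(x − z) − μ u(x),   u(0) = u(L) = 0,

with closed form u(x) = (λ/√μ) csch(√μ L) sinh(√μ min(x,z))
sinh(√μ (L − max(x,z))) and expected count
E[N] = (λ/μ)[1 − sech(√μ L/2) cosh(√μ (L − 2z)/2)].

On top of this the package provides:

* the exact point-process likelihood and its binned counterpart, plus the
  proof-by-computation that binning loses Fisher information for μ and
  none for λ;
* the 2×2 Fisher information matrix, D-optimality maps over source
  location and cell size, and its average over Beta/Gamma models of
  cell-to-cell geometric heterogeneity;
* a Gibbs-within-Metropolis sampler (Gamma conjugacy in λ, random-walk
  Metropolis in μ) with 89% highest-density posterior regions measured by
  convex-hull area;
* two synthetic-data generators — a trajectory-level simulator of the
  particle process (with Brownian-bridge absorption correction) and a fast
  direct sampler from the Poisson process — that the test suite plays
  against each other.

## Worked example

```r
library(snapBDD)

theta <- NondimParams(lam = 500, mu = 10)   # truth
geom  <- CellGeometry(L = 1, z = 0.5)
expectedCount(theta, geom)
#> [1] 30.26145

data <- simulateSnapshotSet(theta, rep(list(geom), 100), seed = 1)
data
#> SnapshotSet: 100 cells, 2962 particles (mean 29.62 per cell)

fit <- samplePosterior(data, PriorSpec(), seed = 2)
fit
#> PosteriorChains: 40000 draws (4 chains), accept = 0.30
#>   mean lambda = 443.5, mean mu = 8.206; ESS = (222, 217)

region <- hdpr(fit, prior = PriorSpec())
region
#> HDPRegion: level 0.89, 72 vertices, area = 187.915
hdprContains(region, theta)
#> [1] TRUE
```

Each snapshot of ~30 particles narrows (λ, μ) along the curve of constant
expected count. At M = 100 the posterior still rides that ridge — this
seed's means sit about one posterior standard deviation below the truth,
which the 89% region (area ≈ 188 in λ×μ units) duly covers — and the area
shrinks like 1/M as cells are added. `runHeterogeneityExperiment()` repeats this pipeline across
heterogeneity scenarios and shows that, at low μ, variable gene-site
positions and cell sizes *reduce* posterior uncertainty.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package: the nondimensional
rate pair implied by the reference dimensional parameters; the log–log
slope of the 89% HDPR area against the number of snapshots M ∈ {10, 50,
100, 500} (3 seeded repeats each); and the posterior means of λ and μ
recovered from M = 500 synthetic snapshots at the reference truth. Results
are written as JSON keyed by target id.

## Command line

A thin dispatcher over the same functions ships in
`inst/scripts/snapbdd`:

```sh
Rscript inst/scripts/snapbdd simulate --config sim.cfg
Rscript inst/scripts/snapbdd fit --config fit.cfg
```

with subcommands `simulate`, `fit`, `info`, `experiment`; every run writes
a manifest (config echo + seed + package version) sufficient to reproduce
its outputs bit-exactly.
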