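## Central S4 containers. All parameters are nondimensional: rates are
## scaled by L0^2/D and lengths by 1/L0, so the diffusivity is 1 throughout.

#' Nondimensional birth and death rates
#'
#' The inference target \eqn{\theta = (\lambda, \mu)}: the particle birth
#' rate and death (state-switch) rate after nondimensionalising by
#' \eqn{L_0^2/D}, so that the diffusivity is 1.
#'
#' @slot lam non-negative dimensionless birth rate \eqn{\lambda}
#' @slot mu non-negative dimensionless death rate \eqn{\mu}
#' @export
setClass("NondimParams",
    representation(lam = "numeric", mu = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(object@lam) != 1L || !is.finite(object@lam) ||
            object@lam < 0)
            msg <- c(msg, "'lam' must be a single finite value >= 0")
        if (length(object@mu) != 1L || !is.finite(object@mu) ||
            object@mu < 0)
            msg <- c(msg, "'mu' must be a single finite value >= 0")
        if (length(msg)) msg else TRUE
    })

#' @param lam non-negative dimensionless birth rate
#' @param mu non-negative dimensionless death rate
#' @return `NondimParams()` returns a validated \linkS4class{NondimParams}.
#' @examples
#' NondimParams(lam = 500, mu = 10)
#' @rdname NondimParams-class
#' @export
NondimParams <- function(lam, mu) {
    new("NondimParams", lam = as.numeric(lam), mu = as.numeric(mu))
}

#' Dimensional (physical) model parameters
#'
#' Physical birth rate \eqn{\kappa_+}, death rate \eqn{\kappa_-} (1/time),
#' diffusivity `D` (length^2/time) and reference length `L0` used for
#' nondimensionalisation.
#'
#' @slot kappaPlus physical birth rate (1/time)
#' @slot kappaMinus physical death rate (1/time)
#' @slot D diffusivity (length^2/time), strictly positive
#' @slot L0 reference length, strictly positive
#' @export
setClass("DimensionalParams",
    representation(kappaPlus = "numeric", kappaMinus = "numeric",
                   D = "numeric", L0 = "numeric"),
    validity = function(object) {
        msg <- character()
        num1 <- function(x) length(x) == 1L && is.finite(x)
        if (!num1(object@kappaPlus) || object@kappaPlus < 0)
            msg <- c(msg, "'kappaPlus' must be a single finite value >= 0")
        if (!num1(object@kappaMinus) || object@kappaMinus < 0)
            msg <- c(msg, "'kappaMinus' must be a single finite value >= 0")
        if (!num1(object@D) || object@D <= 0)
            msg <- c(msg, "'D' must be a single finite value > 0")
        if (!num1(object@L0) || object@L0 <= 0)
            msg <- c(msg, "'L0' must be a single finite value > 0")
        if (length(msg)) msg else TRUE
    })

#' @param kappaPlus,kappaMinus,D,L0 physical parameters (see slots)
#' @return `DimensionalParams()` returns a validated
#'   \linkS4class{DimensionalParams}.
#' @rdname DimensionalParams-class
#' @export
DimensionalParams <- function(kappaPlus, kappaMinus, D, L0 = 1) {
    new("DimensionalParams", kappaPlus = as.numeric(kappaPlus),
        kappaMinus = as.numeric(kappaMinus), D = as.numeric(D),
        L0 = as.numeric(L0))
}

#' Geometry of a single cell domain
#'
#' The heterogeneity vector \eqn{\vartheta = (z, L)}: nondimensional domain
#' length `L` and source (gene site) position `z`, with \eqn{0 < z < L}.
#'
#' @slot L dimensionless domain length, strictly positive
#' @slot z source position, strictly inside (0, L)
#' @export
setClass("CellGeometry",
    representation(L = "numeric", z = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(object@L) != 1L || !is.finite(object@L) || object@L <= 0)
            msg <- c(msg, "'L' must be a single finite value > 0")
        if (length(object@z) != 1L || !is.finite(object@z) ||
            object@z <= 0 || object@z >= object@L)
            msg <- c(msg, "'z' must satisfy 0 < z < L")
        if (length(msg)) msg else TRUE
    })

#' @param L dimensionless domain length
#' @param z source position in (0, L)
#' @return `CellGeometry()` returns a validated \linkS4class{CellGeometry}.
#' @examples
#' CellGeometry(L = 1, z = 0.5)
#' @rdname CellGeometry-class
#' @export
CellGeometry <- function(L, z) {
    new("CellGeometry", L = as.numeric(L), z = as.numeric(z))
}

#' Gridded intensity profile
#'
#' The point-process intensity \eqn{u(x)} (expected particles per unit
#' length) evaluated on an ordered grid spanning \eqn{[0, L]}; `u` vanishes
#' at both absorbing endpoints.
#'
#' @slot grid strictly increasing positions in `[0, L]`
#' @slot values non-negative intensity values at `grid`
#' @export
setClass("IntensityProfile",
    representation(grid = "numeric", values = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(object@grid) != length(object@values))
            msg <- c(msg, "'grid' and 'values' lengths differ")
        if (any(diff(object@grid) <= 0))
            msg <- c(msg, "'grid' must be strictly increasing")
        if (any(object@values < 0))
            msg <- c(msg, "intensity values must be >= 0")
        if (length(msg)) msg else TRUE
    })

#' Options for the trajectory-level simulator
#'
#' @slot dt Euler-Maruyama time step (nondimensional time)
#' @slot burnInTol survival-probability tolerance used to choose the finite
#'   history horizon standing in for the pullback of birth times to
#'   \eqn{-\infty}
#' @slot bridgeCorrection apply the Brownian-bridge within-step absorption
#'   correction
#' @slot seed optional RNG seed
#' @export
setClass("SimOptions",
    representation(dt = "numeric", burnInTol = "numeric",
                   bridgeCorrection = "logical", seed = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(object@dt) != 1L || !is.finite(object@dt) ||
            object@dt <= 0)
            msg <- c(msg, "'dt' must be a single finite value > 0")
        if (length(object@burnInTol) != 1L ||
            !is.finite(object@burnInTol) ||
            object@burnInTol <= 0 || object@burnInTol >= 1)
            msg <- c(msg, "'burnInTol' must lie strictly in (0, 1)")
        if (length(object@bridgeCorrection) != 1L ||
            is.na(object@bridgeCorrection))
            msg <- c(msg, "'bridgeCorrection' must be TRUE or FALSE")
        if (length(msg)) msg else TRUE
    })

#' @param dt time step (default 1e-4)
#' @param burnInTol history-horizon tolerance (default 1e-7)
#' @param bridgeCorrection logical (default TRUE)
#' @param seed optional integer seed
#' @return `SimOptions()` returns a validated \linkS4class{SimOptions}.
#' @rdname SimOptions-class
#' @export
SimOptions <- function(dt = 1e-4, burnInTol = 1e-7, bridgeCorrection = TRUE,
                       seed = NULL) {
    new("SimOptions", dt = as.numeric(dt), burnInTol = as.numeric(burnInTol),
        bridgeCorrection = as.logical(bridgeCorrection),
        seed = if (is.null(seed)) numeric() else as.numeric(seed))
}

#' A single-cell snapshot of particle positions
#'
#' The observed data for one cell: positions of all active particles at the
#' observation instant, each strictly inside the open domain `(0, L)`.
#'
#' @slot cellId character identifier
#' @slot geom the cell's \linkS4class{CellGeometry}
#' @slot positions numeric vector of particle positions, strictly interior
#' @export
setClass("Snapshot",
    representation(cellId = "character", geom = "CellGeometry",
                   positions = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(object@cellId) != 1L || is.na(object@cellId))
            msg <- c(msg, "'cellId' must be a single non-NA string")
        L <- object@geom@L
        p <- object@positions
        if (length(p) && (any(!is.finite(p)) || any(p <= 0) || any(p >= L)))
            msg <- c(msg,
                "all positions must be finite and strictly inside (0, L)")
        if (length(msg)) msg else TRUE
    })

#' @param cellId identifier
#' @param geom a \linkS4class{CellGeometry}
#' @param positions numeric positions in (0, L)
#' @return `Snapshot()` returns a validated \linkS4class{Snapshot}.
#' @rdname Snapshot-class
#' @export
Snapshot <- function(cellId, geom, positions = numeric()) {
    new("Snapshot", cellId = as.character(cellId), geom = geom,
        positions = as.numeric(positions))
}

#' A collection of per-cell snapshots
#'
#' The full data set of an experiment: `M` independent cells, each with its
#' own geometry and observed particle positions.
#'
#' @slot snapshots list of \linkS4class{Snapshot} with unique cell ids
#' @export
setClass("SnapshotSet",
    representation(snapshots = "list"),
    validity = function(object) {
        msg <- character()
        ok <- vapply(object@snapshots, is, logical(1), "Snapshot")
        if (!all(ok))
            msg <- c(msg, "'snapshots' must be a list of Snapshot objects")
        else {
            ids <- vapply(object@snapshots, function(s) s@cellId,
                          character(1))
            if (anyDuplicated(ids))
                msg <- c(msg, "cell ids must be unique")
        }
        if (length(msg)) msg else TRUE
    })

#' @param snapshots list of \linkS4class{Snapshot}
#' @return `SnapshotSet()` returns a validated \linkS4class{SnapshotSet}.
#' @rdname SnapshotSet-class
#' @export
SnapshotSet <- function(snapshots) {
    new("SnapshotSet", snapshots = unname(snapshots))
}

#' A spatial partition of a cell domain
#'
#' Bin edges `0 = e_0 < e_1 < ... < e_K = L` defining `K` bins used for the
#' binned likelihood and binned-information comparisons.
#'
#' @slot edges strictly increasing edges from 0 to L
#' @export
setClass("Partition",
    representation(edges = "numeric"),
    validity = function(object) {
        e <- object@edges
        msg <- character()
        if (length(e) < 2L || any(!is.finite(e)))
            msg <- c(msg, "'edges' needs at least two finite values")
        else {
            if (e[1L] != 0) msg <- c(msg, "first edge must be 0")
            if (any(diff(e) <= 0))
                msg <- c(msg, "'edges' must be strictly increasing")
        }
        if (length(msg)) msg else TRUE
    })

#' @param edges strictly increasing edges starting at 0 and ending at L
#' @return `Partition()` returns a validated \linkS4class{Partition}.
#' @rdname Partition-class
#' @export
Partition <- function(edges) new("Partition", edges = as.numeric(edges))

#' 2x2 Fisher information matrix in (lambda, mu)
#'
#' @slot entries symmetric positive-semidefinite 2x2 matrix with dimnames
#'   `c("lam", "mu")`
#' @export
setClass("InfoMatrix",
    representation(entries = "matrix"),
    validity = function(object) {
        E <- object@entries
        msg <- character()
        if (!is.numeric(E) || !all(dim(E) == c(2L, 2L)) ||
            any(!is.finite(E)))
            msg <- c(msg, "'entries' must be a finite numeric 2x2 matrix")
        else {
            if (abs(E[1, 2] - E[2, 1]) >
                1e-8 * max(abs(E)) + .Machine$double.eps)
                msg <- c(msg, "'entries' must be symmetric")
            ev <- eigen((E + t(E)) / 2, symmetric = TRUE,
                        only.values = TRUE)$values
            if (min(ev) < -1e-8 * max(abs(ev), 1))
                msg <- c(msg, "'entries' must be positive semidefinite")
        }
        if (length(msg)) msg else TRUE
    })

InfoMatrix <- function(entries) {
    entries <- (entries + t(entries)) / 2
    dimnames(entries) <- list(c("lam", "mu"), c("lam", "mu"))
    new("InfoMatrix", entries = entries)
}

#' Prior specification for Bayesian inference
#'
#' A Gamma(shape, rate) prior on the birth rate \eqn{\lambda} (conjugate to
#' the point-process likelihood) and a Uniform(0, `muMax`) prior on the
#' death rate \eqn{\mu}.
#'
#' @slot priorShape Gamma shape for lambda, > 0
#' @slot priorRate Gamma rate for lambda, > 0
#' @slot muMax upper bound of the uniform prior on mu, > 0
#' @export
setClass("PriorSpec",
    representation(priorShape = "numeric", priorRate = "numeric",
                   muMax = "numeric"),
    validity = function(object) {
        msg <- character()
        pos1 <- function(x) length(x) == 1L && is.finite(x) && x > 0
        if (!pos1(object@priorShape))
            msg <- c(msg, "'priorShape' must be a single value > 0")
        if (!pos1(object@priorRate))
            msg <- c(msg, "'priorRate' must be a single value > 0")
        if (!pos1(object@muMax))
            msg <- c(msg, "'muMax' must be a single value > 0")
        if (length(msg)) msg else TRUE
    })

#' @param priorShape Gamma shape for lambda (default 2)
#' @param priorRate Gamma rate for lambda (default 0.004, a weakly
#'   informative prior with mean 500)
#' @param muMax uniform upper bound for mu (default 100)
#' @return `PriorSpec()` returns a validated \linkS4class{PriorSpec}.
#' @rdname PriorSpec-class
#' @export
PriorSpec <- function(priorShape = 2, priorRate = 0.004, muMax = 100) {
    new("PriorSpec", priorShape = as.numeric(priorShape),
        priorRate = as.numeric(priorRate), muMax = as.numeric(muMax))
}

#' MCMC posterior samples for (lambda, mu)
#'
#' Post-burn-in, thinned draws of the Gibbs-within-Metropolis sampler,
#' pooled across chains, together with cached per-draw likelihood terms
#' (`slv` = sum of log v over particles, `siv` = sum over cells of the
#' integral of v) so posterior densities can be re-evaluated cheaply.
#'
#' @slot lam,mu posterior draws
#' @slot chain chain index per draw
#' @slot slv,siv cached likelihood terms per draw
#' @slot nTotal total particle count of the fitted data
#' @slot acceptanceRate post-burn-in Metropolis acceptance rate for mu
#' @slot ess effective sample sizes, named `c(lam, mu)`
#' @slot seed,nIter,nBurn,thin run metadata
#' @export
setClass("PosteriorChains",
    representation(lam = "numeric", mu = "numeric", chain = "integer",
                   slv = "numeric", siv = "numeric", nTotal = "integer",
                   acceptanceRate = "numeric", ess = "numeric",
                   seed = "integer", nIter = "integer", nBurn = "integer",
                   thin = "integer"),
    validity = function(object) {
        msg <- character()
        n <- length(object@lam)
        if (length(object@mu) != n || length(object@chain) != n ||
            length(object@slv) != n || length(object@siv) != n)
            msg <- c(msg, "sample vectors must have equal length")
        if (any(object@lam <= 0))
            msg <- c(msg, "all lambda samples must be > 0")
        if (any(object@mu <= 0))
            msg <- c(msg, "all mu samples must be > 0")
        if (length(msg)) msg else TRUE
    })

#' Highest-density posterior region
#'
#' Convex hull of the top-`level` fraction of posterior samples ranked by
#' unnormalised posterior density, with its (shoelace) area.
#'
#' @slot level credibility mass (default 0.89)
#' @slot vertices two-column matrix of hull vertices in the (lambda, mu)
#'   plane, in counter-clockwise order
#' @slot area polygon area, >= 0
#' @export
setClass("HDPRegion",
    representation(level = "numeric", vertices = "matrix", area = "numeric"),
    validity = function(object) {
        msg <- character()
        if (object@level <= 0 || object@level > 1)
            msg <- c(msg, "'level' must lie in (0, 1]")
        if (ncol(object@vertices) != 2L)
            msg <- c(msg, "'vertices' must have two columns")
        if (object@area < 0) msg <- c(msg, "'area' must be >= 0")
        if (length(msg)) msg else TRUE
    })

#' Cell-to-cell geometric heterogeneity model
#'
#' Relative source position \eqn{z/L \mid L \sim
#' \mathrm{Beta}(1/\sigma_z, 1/\sigma_z)} (so \eqn{E[z|L] = L/2}, with
#' \eqn{\sigma_z = 1} giving spatially uniform sources) and cell size
#' \eqn{L \sim \Gamma(\mathrm{shape} = 1/\sigma_L^2, \mathrm{scale} =
#' \sigma_L^2)} (so \eqn{E[L] = 1}, \eqn{\mathrm{Var}[L] = \sigma_L^2}).
#' `sigmaZ = 0` and `sigmaL = 0` are admitted as exact degenerate cases
#' (fixed `z = L/2`, fixed `L = 1`).
#'
#' @slot sigmaZ source-location spread in \[0, 1\]
#' @slot sigmaL cell-size spread >= 0
#' @export
setClass("HeterogeneityModel",
    representation(sigmaZ = "numeric", sigmaL = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(object@sigmaZ) != 1L || !is.finite(object@sigmaZ) ||
            object@sigmaZ < 0 || object@sigmaZ > 1)
            msg <- c(msg, "'sigmaZ' must lie in [0, 1]")
        if (length(object@sigmaL) != 1L || !is.finite(object@sigmaL) ||
            object@sigmaL < 0)
            msg <- c(msg, "'sigmaL' must be >= 0")
        if (length(msg)) msg else TRUE
    })

#' @param sigmaZ source-location spread in \[0, 1\] (0 = fixed z = L/2)
#' @param sigmaL cell-size spread >= 0 (0 = fixed L = 1)
#' @return `HeterogeneityModel()` returns a validated
#'   \linkS4class{HeterogeneityModel}.
#' @rdname HeterogeneityModel-class
#' @export
HeterogeneityModel <- function(sigmaZ = 0, sigmaL = 0) {
    new("HeterogeneityModel", sigmaZ = as.numeric(sigmaZ),
        sigmaL = as.numeric(sigmaL))
}
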