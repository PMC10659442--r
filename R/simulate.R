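## Two synthetic-data generators: a trajectory-level simulator of the
## underlying birth-death-diffusion process (the oracle that validates the
## Poisson point-process representation), and a direct sampler from the
## Poisson process with intensity u (fast generator for inference work).

# history horizon standing in for the pullback of birth times to -infinity:
# mu + pi^2/L^2 is the slowest decay rate of the survival probability (death
# plus the leading Dirichlet eigenvalue of d^2/dx^2 on (0, L))
.historyHorizon <- function(mu, L, tol) -log(tol) / (mu + pi^2 / L^2)

#' Trajectory-level simulation of one snapshot
#'
#' Simulates the particle process directly: births form a Poisson process of
#' rate \eqn{\lambda} on \eqn{(-T_0, 0]} with horizon
#' \eqn{T_0 = -\log(\mathrm{burnInTol})/(\mu + \pi^2/L^2)}; each particle
#' starts at the source `z`, carries an independent Exp(\eqn{\mu}) lifetime,
#' and follows Euler-Maruyama steps \eqn{x \leftarrow x + \sqrt{2\,dt}\,\eta}
#' (unit diffusivity in nondimensional coordinates). A particle is removed
#' when its lifetime expires, when a step lands outside \eqn{(0, L)}, or --
#' with the Brownian-bridge correction on -- with within-step absorption
#' probability \eqn{\exp(-d_1 d_2 / dt)} per wall (the bridge crossing
#' probability \eqn{\exp(-2 d_1 d_2/\sigma^2)} for step variance
#' \eqn{\sigma^2 = 2\,dt}), where \eqn{d_1, d_2} are the distances to that
#' wall at the step ends. Survivors' positions at
#' time 0 form the snapshot.
#'
#' @param theta a \linkS4class{NondimParams}
#' @param geom a \linkS4class{CellGeometry}
#' @param opts a \linkS4class{SimOptions}; `opts@seed`, when non-NULL, seeds
#'   the RNG
#' @param cellId identifier for the returned snapshot
#' @return a \linkS4class{Snapshot}
#' @examples
#' simulateSnapshotTrajectories(NondimParams(10, 1.5),
#'     CellGeometry(L = 3, z = 1), SimOptions(dt = 1e-3, seed = 1))
#' @export
simulateSnapshotTrajectories <- function(theta, geom, opts = SimOptions(),
                                         cellId = "cell_1") {
    stopifnot(is(theta, "NondimParams"), is(geom, "CellGeometry"),
              is(opts, "SimOptions"))
    validObject(opts)
    if (length(opts@seed)) set.seed(opts@seed)
    lam <- theta@lam; mu <- theta@mu
    L <- geom@L; z <- geom@z; dt <- opts@dt
    if ((mu > 0 && dt >= 1 / mu) || dt >= (L / 10)^2)
        warning("time step 'dt' is coarse relative to 1/mu or (L/10)^2; ",
                "absorption and death may be poorly resolved")
    if (lam == 0)
        return(Snapshot(cellId, geom, numeric()))
    T0 <- .historyHorizon(mu, L, opts@burnInTol)
    nBirth <- rpois(1L, lam * T0)
    if (nBirth == 0L)
        return(Snapshot(cellId, geom, numeric()))
    tb <- runif(nBirth, 0, T0)                 # age at the snapshot instant
    life <- if (mu > 0) rexp(nBirth, mu) else rep(Inf, nBirth)
    alive <- life > tb                         # survived degradation
    surv <- numeric(0)
    for (k in which(alive)) {
        nst <- floor(tb[k] / dt)
        rem <- tb[k] - nst * dt
        dts <- c(rep(dt, nst), if (rem > 0) rem)
        if (!length(dts)) { surv <- c(surv, z); next }
        pos <- z + cumsum(rnorm(length(dts), 0, sqrt(2 * dts)))
        out <- pos <= 0 | pos >= L
        if (any(out)) next                     # stepped outside: absorbed
        if (opts@bridgeCorrection) {
            prev <- c(z, pos[-length(pos)])
            # crossing probability exp(-2 d1 d2 / sigma^2) with step
            # variance sigma^2 = 2 dt
            pl <- exp(-prev * pos / dts)
            pr <- exp(-(L - prev) * (L - pos) / dts)
            if (any(runif(length(dts)) > (1 - pl) * (1 - pr))) next
        }
        surv <- c(surv, pos[length(pos)])
    }
    Snapshot(cellId, geom, surv)
}

#' Direct sampling from the Poisson point process
#'
#' Samples a snapshot from its exact statistical description: the total
#' count is Poisson with mean [expectedCount()], and positions are iid draws
#' from the normalised intensity \eqn{u/\int u}, generated by numerical
#' inverse-CDF on a fine grid.
#'
#' @inheritParams simulateSnapshotTrajectories
#' @param seed optional RNG seed
#' @param nGridCDF grid size for the inverse-CDF table (default 4096)
#' @return a \linkS4class{Snapshot}
#' @examples
#' sampleSnapshotDirect(NondimParams(500, 10), CellGeometry(1, 0.5),
#'                      seed = 1)
#' @export
sampleSnapshotDirect <- function(theta, geom, seed = NULL,
                                 cellId = "cell_1", nGridCDF = 4096L) {
    stopifnot(is(theta, "NondimParams"), is(geom, "CellGeometry"))
    if (!is.null(seed)) set.seed(seed)
    if (theta@lam == 0)
        return(Snapshot(cellId, geom, numeric()))
    n <- rpois(1L, expectedCount(theta, geom))
    if (n == 0L)
        return(Snapshot(cellId, geom, numeric()))
    Snapshot(cellId, geom, .sampleIntensityPositions(n, theta, geom,
                                                     nGridCDF))
}

# iid positions from u / int u via inverse CDF on a fixed grid
.sampleIntensityPositions <- function(n, theta, geom, nGridCDF = 4096L) {
    L <- geom@L
    grid <- seq(0, L, length.out = as.integer(nGridCDF) + 1L)
    u <- .intensity(grid, theta@lam, theta@mu, L, geom@z)
    cdf <- cumsum(c(0, (u[-1] + u[-length(u)]) / 2 * diff(grid)))
    cdf <- cdf / cdf[length(cdf)]
    x <- approx(cdf, grid, xout = runif(n), ties = "ordered")$y
    eps <- L * 1e-12
    pmin(pmax(x, eps), L - eps)
}

#' Simulate a multi-cell snapshot set
#'
#' Generates `M` independent per-cell snapshots, one per geometry, using
#' per-cell RNG substreams derived from the master seed so that results are
#' reproducible and independent of evaluation order.
#'
#' @param theta a \linkS4class{NondimParams}
#' @param geoms list of \linkS4class{CellGeometry} (names, when present,
#'   become cell ids)
#' @param mode `"direct"` (Poisson sampler) or `"trajectories"`
#' @param opts a \linkS4class{SimOptions} used in trajectory mode
#' @param seed master RNG seed
#' @return a \linkS4class{SnapshotSet}
#' @examples
#' geoms <- rep(list(CellGeometry(1, 0.5)), 5)
#' simulateSnapshotSet(NondimParams(500, 10), geoms, seed = 1)
#' @export
simulateSnapshotSet <- function(theta, geoms,
                                mode = c("direct", "trajectories"),
                                opts = SimOptions(), seed = NULL) {
    mode <- match.arg(mode)
    if (is(geoms, "CellGeometry")) geoms <- list(geoms)
    stopifnot(length(geoms) >= 1L)
    M <- length(geoms)
    ids <- names(geoms)
    if (is.null(ids)) ids <- sprintf("cell_%04d", seq_len(M))
    if (anyDuplicated(ids)) stop("duplicate cell ids")
    if (!is.null(seed)) set.seed(seed)
    cellSeeds <- sample.int(.Machine$integer.max - 1L, M)
    snaps <- vector("list", M)
    for (m in seq_len(M)) {
        snaps[[m]] <- if (mode == "direct") {
            sampleSnapshotDirect(theta, geoms[[m]], seed = cellSeeds[m],
                                 cellId = ids[m])
        } else {
            o <- opts
            o@seed <- as.numeric(cellSeeds[m])
            simulateSnapshotTrajectories(theta, geoms[[m]], o,
                                         cellId = ids[m])
        }
    }
    SnapshotSet(snaps)
}
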