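## Closed-form and numerical evaluation of the birth-death-diffusion
## intensity u solving  0 = u'' + lambda * delta(x - z) - mu * u  on (0, L)
## with absorbing (Dirichlet) ends. All evaluation goes through a log-space
## form so that sqrt(mu) * L up to ~700 stays finite.

# threshold below which the mu -> 0 Green's-function limit is used;
# the hyperbolic form is 0/0 at mu = 0
.MU_EPS <- 1e-10

# log(sinh(y)) for y >= 0, exact and overflow-safe for all y
# (y + log1p(-exp(-2 y)) - log 2); returns -Inf at y = 0
.logsinh <- function(y) y + log1p(-exp(-2 * y)) - log(2)

# coth(y) for y > 0, stable for large y
.coth <- function(y) {
    out <- 1 + 2 * exp(-2 * y) / (-expm1(-2 * y))
    small <- y < 1e-4
    if (any(small)) out[small] <- 1 / tanh(y[small])
    out
}

# scalar-parameter intensity, vectorised over x; the workhorse behind
# intensity()
.intensity <- function(x, lam, mu, L, z) {
    a <- pmin(x, z)
    b <- L - pmax(x, z)
    out <- numeric(length(x))
    inside <- a > 0 & b > 0
    if (!any(inside)) return(out)
    if (mu < .MU_EPS) {
        out[inside] <- lam * a[inside] * b[inside] / L
    } else {
        s <- sqrt(mu)
        out[inside] <- lam * exp(-0.5 * log(mu) + .logsinh(s * a[inside]) +
                                 .logsinh(s * b[inside]) - .logsinh(s * L))
    }
    out
}

# d log u / d mu at interior points (vectorised over x); analytic derivative
# of the stable log-space form
.dlogu_dmu <- function(x, mu, L, z) {
    s <- sqrt(mu)
    a <- pmin(x, z)
    b <- L - pmax(x, z)
    -1 / (2 * mu) +
        (a * .coth(s * a) + b * .coth(s * b) - L * .coth(s * L)) / (2 * s)
}

# du/dmu, zero at the endpoints
.du_dmu <- function(x, lam, mu, L, z) {
    u <- .intensity(x, lam, mu, L, z)
    d <- numeric(length(x))
    inside <- u > 0
    d[inside] <- u[inside] * .dlogu_dmu(x[inside], mu, L, z)
    d
}

# E[N] at lambda = 1, i.e. the integral of v = u / lambda; stable form of
# (1/mu) [1 - sech(s L / 2) cosh(s (L - 2 z) / 2)]
.int_v <- function(mu, L, z) {
    n <- max(length(mu), length(L), length(z))
    mu <- rep_len(mu, n); L <- rep_len(L, n); z <- rep_len(z, n)
    out <- numeric(length(mu))
    small <- mu < .MU_EPS
    out[small] <- 0.5 * z[small] * (L[small] - z[small])
    if (any(!small)) {
        s <- sqrt(mu[!small]); Lb <- L[!small]; zb <- z[!small]
        cc <- abs(Lb / 2 - zb)
        g <- exp(-s * (Lb / 2 - cc)) * (1 + exp(-2 * s * cc)) /
            (1 + exp(-s * Lb))
        out[!small] <- (1 - g) / mu[!small]
    }
    out
}

#' Nondimensionalise physical parameters
#'
#' Converts physical rates \eqn{\kappa_\pm} (1/time) with diffusivity `D`
#' and reference length `L0` into the identifiable nondimensional rates
#' \eqn{\lambda = \kappa_+ L_0^2 / D} and \eqn{\mu = \kappa_- L_0^2 / D}.
#' Physical lengths rescale by the factor `1/L0` (returned as attribute
#' `"lengthScale"`).
#'
#' @param p a \linkS4class{DimensionalParams}
#' @return a \linkS4class{NondimParams} with attribute `lengthScale = 1/L0`
#' @examples
#' nondimensionalize(DimensionalParams(kappaPlus = 5, kappaMinus = 0.75,
#'                                     D = 0.5, L0 = 1))
#' @export
nondimensionalize <- function(p) {
    stopifnot(is(p, "DimensionalParams"))
    validObject(p)
    out <- NondimParams(lam = p@kappaPlus * p@L0^2 / p@D,
                        mu = p@kappaMinus * p@L0^2 / p@D)
    attr(out, "lengthScale") <- 1 / p@L0
    out
}

#' Point-process intensity of the snapshot model
#'
#' Evaluates the intensity \eqn{u(x)} (expected particles per unit length)
#' of the Poisson spatial point process describing snapshot observations:
#' the solution of \eqn{0 = u'' + \lambda\delta(x - z) - \mu u} on
#' \eqn{(0, L)} with absorbing ends,
#' \deqn{u(x) = \frac{\lambda}{\sqrt\mu}\,
#'   \mathrm{csch}(\sqrt\mu L)\,\sinh(\sqrt\mu \min(x, z))\,
#'   \sinh(\sqrt\mu (L - \max(x, z))).}
#' For \eqn{\mu < 10^{-10}} the analytic limit
#' \eqn{u = \lambda \min(x,z)(L - \max(x,z))/L} is used.
#'
#' @param x position(s) in `[0, L]`
#' @param theta a \linkS4class{NondimParams}
#' @param geom a \linkS4class{CellGeometry}
#' @return intensity values, zero at both endpoints
#' @examples
#' intensity(0.5, NondimParams(500, 10), CellGeometry(L = 1, z = 0.5))
#' @export
intensity <- function(x, theta, geom) {
    stopifnot(is(theta, "NondimParams"), is(geom, "CellGeometry"))
    if (any(!is.finite(x)) || any(x < 0) || any(x > geom@L))
        stop("positions 'x' must lie in [0, L]")
    .intensity(x, theta@lam, theta@mu, geom@L, geom@z)
}

#' Expected particle count of a snapshot
#'
#' The mean of the Poisson-distributed total count,
#' \deqn{E[N] = \int_0^L u\,dx = \frac{\lambda}{\mu}\left[1 -
#'   \mathrm{sech}(\sqrt\mu L/2)\cosh(\sqrt\mu (L - 2z)/2)\right],}
#' evaluated in an overflow-safe form; for \eqn{\mu < 10^{-10}} the limit
#' \eqn{\lambda z (L - z)/2} (birth rate times mean Brownian exit time) is
#' used.
#'
#' @inheritParams intensity
#' @return the expected number of observed particles
#' @examples
#' expectedCount(NondimParams(500, 10), CellGeometry(L = 1, z = 0.5))
#' @export
expectedCount <- function(theta, geom) {
    stopifnot(is(theta, "NondimParams"), is(geom, "CellGeometry"))
    theta@lam * .int_v(theta@mu, geom@L, geom@z)
}

#' Finite-difference solution of the intensity boundary-value problem
#'
#' Independent numerical oracle for [intensity()]: a second-order centred
#' finite-difference discretisation of
#' \eqn{0 = u'' + \lambda\delta(x - z) - \mu u} with homogeneous Dirichlet
#' ends, the point source deposited on the grid by linear (hat-function)
#' mass splitting between the two nodes bracketing `z`. Converges to the
#' closed form at rate \eqn{O(h^2)}.
#'
#' @inheritParams intensity
#' @param nGrid number of grid intervals (>= 16)
#' @return an \linkS4class{IntensityProfile} on `nGrid + 1` equispaced nodes
#' @export
solveIntensityNumeric <- function(theta, geom, nGrid = 1024L) {
    stopifnot(is(theta, "NondimParams"), is(geom, "CellGeometry"))
    nGrid <- as.integer(nGrid)
    if (nGrid < 16L) stop("'nGrid' must be at least 16")
    L <- geom@L; z <- geom@z
    h <- L / nGrid
    grid <- seq(0, L, length.out = nGrid + 1L)
    # interior nodes 1..nGrid-1
    n <- nGrid - 1L
    # hat-function deposition of the unit point mass at z
    j <- min(max(floor(z / h), 0L), nGrid - 1L)   # left bracketing node
    w <- z / h - j
    f <- numeric(n)
    depos <- function(node, mass) {
        if (node >= 1L && node <= n) f[node] <<- f[node] + mass / h
    }
    depos(j, theta@lam * (1 - w))
    depos(j + 1L, theta@lam * w)
    # tridiagonal system: (u[i-1] - 2 u[i] + u[i+1])/h^2 - mu u[i] = -f[i]
    dmain <- rep(-2 / h^2 - theta@mu, n)
    doff <- rep(1 / h^2, n - 1L)
    sol <- .thomas(doff, dmain, doff, -f)
    if (any(!is.finite(sol)))
        stop("finite-difference system produced non-finite solution")
    vals <- c(0, pmax(sol, 0), 0)
    new("IntensityProfile", grid = grid, values = vals)
}

# Thomas algorithm for a tridiagonal system (lower, diag, upper, rhs)
.thomas <- function(lo, dg, up, rhs) {
    n <- length(dg)
    cp <- numeric(n); dp <- numeric(n)
    cp[1] <- if (n > 1L) up[1] / dg[1] else 0
    dp[1] <- rhs[1] / dg[1]
    if (n > 1L) {
        for (i in 2:n) {
            m <- dg[i] - lo[i - 1L] * cp[i - 1L]
            if (i < n) cp[i] <- up[i] / m
            dp[i] <- (rhs[i] - lo[i - 1L] * dp[i - 1L]) / m
        }
    }
    x <- numeric(n)
    x[n] <- dp[n]
    if (n > 1L) for (i in (n - 1L):1L) x[i] <- dp[i] - cp[i] * x[i + 1L]
    x
}

#' Export an intensity profile as a two-column table
#'
#' @param profile an \linkS4class{IntensityProfile}
#' @param file path of the tab-separated output (columns
#'   `position`, `intensity`)
#' @return the file path, invisibly
#' @export
writeIntensityProfile <- function(profile, file) {
    stopifnot(is(profile, "IntensityProfile"))
    df <- data.frame(position = format(profile@grid, digits = 17),
                     intensity = format(profile@values, digits = 17))
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}
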