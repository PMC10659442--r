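## Fisher information for theta = (lambda, mu), its determinant
## (D-optimality score), the heterogeneity-averaged information, and the
## binned information used to show that binning loses information.

#' Fisher information matrix for (lambda, mu)
#'
#' Computes the 2x2 information matrix of the point-process likelihood for
#' one cell,
#' \deqn{I_{ij} = \int_0^L \frac{\partial_{\theta_i} u\,
#'   \partial_{\theta_j} u}{u}\,dx,}
#' using \eqn{\partial_\lambda u = u/\lambda} exactly (so
#' \eqn{I_{\lambda\lambda} = E[N]/\lambda^2}, which has the closed form
#' \eqn{(\lambda\mu)^{-1}[1 - \mathrm{sech}(\sqrt\mu L/2)
#' \cosh(\sqrt\mu(L-2z)/2)]}) and the analytic \eqn{\partial_\mu u} with
#' adaptive quadrature split at the source kink \eqn{x = z}.
#'
#' @param theta a \linkS4class{NondimParams} with `lam > 0`, `mu > 0`
#' @param geom a \linkS4class{CellGeometry}
#' @return an \linkS4class{InfoMatrix}
#' @examples
#' fisherInformation(NondimParams(500, 10), CellGeometry(1, 0.5))
#' @export
fisherInformation <- function(theta, geom) {
    stopifnot(is(theta, "NondimParams"), is(geom, "CellGeometry"))
    lam <- theta@lam; mu <- theta@mu
    if (lam <= 0 || mu <= 0)
        stop("fisherInformation requires lam > 0 and mu > 0")
    L <- geom@L; z <- geom@z
    Ill <- .int_v(mu, L, z) / lam            # E[N] / lambda^2 with E[N]=lam*intv
    f12 <- function(x) .du_dmu(x, lam, mu, L, z) / lam
    f22 <- function(x) {
        u <- .intensity(x, lam, mu, L, z)
        u * .dlogu_dmu(x, mu, L, z)^2
    }
    I12 <- tryCatch(.binIntegral(f12, 0, L, z),
                    error = function(e) stop(
                        "quadrature for I[lam,mu] failed: ",
                        conditionMessage(e)))
    I22 <- tryCatch(.binIntegral(f22, 0, L, z),
                    error = function(e) stop(
                        "quadrature for I[mu,mu] failed: ",
                        conditionMessage(e)))
    InfoMatrix(matrix(c(Ill, I12, I12, I22), 2, 2))
}

#' D-optimality score
#'
#' Determinant of [fisherInformation()], used as a proxy for the inverse
#' area of the joint uncertainty region of \eqn{(\lambda, \mu)}.
#'
#' @inheritParams fisherInformation
#' @return `det I >= 0`
#' @export
detInformation <- function(theta, geom) {
    det(infoEntries(fisherInformation(theta, geom)))
}

#' Information of the binned likelihood
#'
#' Scalar information for one parameter under spatial binning,
#' \deqn{I_{bin}(\theta_i) = \sum_j
#'   \frac{\left(\int_{A_j}\partial_{\theta_i} u\right)^2}
#'        {\int_{A_j} u\,dx}.}
#' By the Cauchy-Schwarz inequality this never exceeds the unbinned
#' information; for the scale parameter \eqn{\lambda} (where
#' \eqn{\partial_\lambda u \propto u}) equality holds for every partition.
#'
#' @inheritParams fisherInformation
#' @param part a \linkS4class{Partition} of `[0, L]`
#' @param whichParam `"lam"` or `"mu"`
#' @return the scalar binned information
#' @export
binnedInformation <- function(theta, part, geom,
                              whichParam = c("mu", "lam")) {
    stopifnot(is(theta, "NondimParams"), is(part, "Partition"),
              is(geom, "CellGeometry"))
    whichParam <- match.arg(whichParam)
    lam <- theta@lam; mu <- theta@mu
    L <- geom@L; z <- geom@z
    e <- part@edges
    m <- .binIntensityIntegrals(theta, part, geom)
    if (any(m <= 0)) stop("partition contains a bin of zero intensity mass")
    if (whichParam == "lam") {
        # int dlam u = m / lam exactly
        return(sum((m / lam)^2 / m))
    }
    dm <- vapply(seq_len(length(e) - 1L), function(k) {
        .binIntegral(function(x) .du_dmu(x, lam, mu, L, z),
                     e[k], e[k + 1L], z)
    }, numeric(1))
    sum(dm^2 / m)
}

# Gauss quadrature w.r.t. Beta(a, a) on (0, 1): Golub-Welsch on the
# symmetric Jacobi weight (1-t)^(a-1) (1+t)^(a-1) on (-1, 1)
.gaussBetaSym <- function(n, a) {
    al <- a - 1
    k <- seq_len(n - 1)
    b <- numeric(n - 1)
    b[1] <- 4 * (1 + al)^2 / ((2 + 2 * al)^2 * (3 + 2 * al))
    if (n > 2) {
        kk <- k[-1]
        b[-1] <- 4 * kk * (kk + al)^2 * (kk + 2 * al) /
            ((2 * kk + 2 * al)^2 * (2 * kk + 2 * al + 1) *
             (2 * kk + 2 * al - 1))
    }
    J <- diag(0, n)
    idx <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
    J[idx] <- sqrt(b)
    J[idx[, 2:1, drop = FALSE]] <- sqrt(b)
    ev <- eigen(J, symmetric = TRUE)
    nodes <- (ev$values + 1) / 2              # map (-1,1) -> (0,1)
    w <- ev$vectors[1, ]^2
    list(nodes = nodes, weights = w / sum(w))
}

# Gauss quadrature w.r.t. Gamma(shape, scale): generalized Gauss-Laguerre
.gaussGamma <- function(n, shape, scale) {
    al <- shape - 1
    dg <- 2 * seq(0, n - 1) + al + 1
    k <- seq_len(n - 1)
    b <- k * (k + al)
    J <- diag(dg)
    idx <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
    J[idx] <- sqrt(b)
    J[idx[, 2:1, drop = FALSE]] <- sqrt(b)
    ev <- eigen(J, symmetric = TRUE)
    w <- ev$vectors[1, ]^2
    list(nodes = ev$values * scale, weights = w / sum(w))
}

#' Heterogeneity-averaged Fisher information
#'
#' Expected information \eqn{E_\vartheta[I(\theta;\vartheta)]} over the
#' cell-to-cell geometry distribution (relative source position
#' \eqn{z/L \sim} Beta, cell size \eqn{L \sim} Gamma; see
#' \linkS4class{HeterogeneityModel}), computed entry-wise by tensorised
#' Gauss quadrature (Gauss-Jacobi in \eqn{z/L}, generalized Gauss-Laguerre
#' in \eqn{L}), or by seeded Monte Carlo as a diagnostic fallback.
#'
#' @param theta a \linkS4class{NondimParams}
#' @param het a \linkS4class{HeterogeneityModel}
#' @param nNodes quadrature nodes per dimension (default 32)
#' @param method `"quadrature"` or `"montecarlo"`
#' @param nMC Monte Carlo sample size (method `"montecarlo"`)
#' @param seed Monte Carlo seed
#' @return an \linkS4class{InfoMatrix}
#' @examples
#' heterogeneousInformation(NondimParams(500, 1),
#'                          HeterogeneityModel(sigmaZ = 0.75))
#' @export
heterogeneousInformation <- function(theta, het, nNodes = 32L,
                                     method = c("quadrature", "montecarlo"),
                                     nMC = 2000L, seed = 1L) {
    stopifnot(is(theta, "NondimParams"), is(het, "HeterogeneityModel"))
    method <- match.arg(method)
    if (method == "montecarlo") {
        geoms <- sampleGeometries(nMC, het, seed = seed)
        Es <- matrix(0, 2, 2)
        for (g in geoms)
            Es <- Es + infoEntries(fisherInformation(theta, g))
        return(InfoMatrix(Es / length(geoms)))
    }
    # degenerate directions collapse to a single node
    qz <- if (het@sigmaZ == 0) list(nodes = 0.5, weights = 1)
          else .gaussBetaSym(nNodes, 1 / het@sigmaZ)
    qL <- if (het@sigmaL == 0) list(nodes = 1, weights = 1)
          else .gaussGamma(nNodes, 1 / het@sigmaL^2, het@sigmaL^2)
    Es <- matrix(0, 2, 2)
    for (iL in seq_along(qL$nodes)) {
        L <- qL$nodes[iL]
        for (iz in seq_along(qz$nodes)) {
            p <- qz$nodes[iz]
            # clip relative positions indistinguishable from the walls
            p <- min(max(p, 1e-12), 1 - 1e-12)
            w <- qL$weights[iL] * qz$weights[iz]
            Es <- Es + w * infoEntries(fisherInformation(
                theta, CellGeometry(L = L, z = p * L)))
        }
    }
    if (any(!is.finite(Es)))
        stop("heterogeneity quadrature diverged")
    InfoMatrix(Es)
}

#' Optimal source location on a z-grid
#'
#' Evaluates [detInformation()] on a 201-point grid of source positions and
#' returns the argmax, breaking ties toward smaller `z`.
#'
#' @param theta a \linkS4class{NondimParams}
#' @param L domain length
#' @param nGrid grid resolution (default 201)
#' @return list with elements `z` (maximiser), `detI` (values), `zGrid`
#' @export
optimalSourceLocation <- function(theta, L = 1, nGrid = 201L) {
    zg <- seq(0, L, length.out = nGrid)[-c(1, nGrid)]
    d <- vapply(zg, function(z)
        detInformation(theta, CellGeometry(L = L, z = z)), numeric(1))
    list(z = zg[which.max(d)], detI = d, zGrid = zg)
}
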