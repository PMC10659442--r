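## Exact point-process likelihood and the binned (per-bin Poisson count)
## likelihood. The per-evaluation work for a new mu is a single pass over
## pooled particle terms, done in C++ (see src/bdd_terms.cpp).

# precompute mu-independent per-particle terms for a SnapshotSet:
# a = min(x, z), b = L - max(x, z), Lp = L of the particle's cell,
# plus per-cell geometry vectors and the total count
.dataTerms <- function(data) {
    stopifnot(is(data, "SnapshotSet"))
    Lg <- vapply(data@snapshots, function(s) s@geom@L, numeric(1))
    zg <- vapply(data@snapshots, function(s) s@geom@z, numeric(1))
    nPer <- vapply(data@snapshots, function(s) length(s@positions),
                   integer(1))
    x <- unlist(lapply(data@snapshots, function(s) s@positions),
                use.names = FALSE)
    if (is.null(x)) x <- numeric()
    Lp <- rep(Lg, nPer)
    zp <- rep(zg, nPer)
    if (length(x) && (any(x <= 0) || any(x >= Lp)))
        stop("invalid data: positions on or outside the absorbing ",
             "boundary, where the model intensity vanishes")
    list(a = pmin(x, zp), b = Lp - pmax(x, zp), Lp = Lp,
         Lg = Lg, zg = zg, n = sum(nPer))
}

# (sum_i log v(x_i; mu), sum_m int v_m(mu)) for precomputed terms
.muTerms <- function(mu, terms) {
    bdd_mu_terms(mu, terms$a, terms$b, terms$Lp, terms$Lg, terms$zg)
}

#' Exact point-process log-likelihood
#'
#' The log of the Poisson point-process likelihood over `M` independent
#' cells,
#' \deqn{\ell(\theta; x) = \sum_m\Big[\sum_i \log u(x_i^m;\theta,
#'   \vartheta_m) - E[N_m]\Big],}
#' where \eqn{u} is the closed-form intensity and \eqn{E[N_m]} its integral
#' over cell `m`. Positions exactly on a boundary (where \eqn{u = 0}) are
#' rejected as invalid data. For \eqn{\lambda = 0} with any particle present
#' the likelihood is zero and `-Inf` is returned.
#'
#' @param theta a \linkS4class{NondimParams}
#' @param data a \linkS4class{SnapshotSet}
#' @return the log-likelihood value
#' @examples
#' d <- simulateSnapshotSet(NondimParams(500, 10),
#'         rep(list(CellGeometry(1, 0.5)), 10), seed = 1)
#' logLikelihood(NondimParams(500, 10), d)
#' @export
logLikelihood <- function(theta, data) {
    stopifnot(is(theta, "NondimParams"))
    terms <- .dataTerms(data)
    if (theta@lam == 0)
        return(if (terms$n > 0) -Inf else 0)
    mt <- .muTerms(theta@mu, terms)
    terms$n * log(theta@lam) + mt[1] - theta@lam * mt[2]
}

#' Closed-form conditional maximum-likelihood estimate of lambda
#'
#' Because the intensity is linear in \eqn{\lambda} (\eqn{u = \lambda v}),
#' the profile likelihood over \eqn{\lambda} at fixed \eqn{\mu} is maximised
#' at \eqn{\hat\lambda = \sum_m n_m / \sum_m \int v_m\,dx}.
#'
#' @param mu death rate at which to profile
#' @param data a \linkS4class{SnapshotSet}
#' @return the conditional MLE of lambda
#' @export
lambdaMLE <- function(mu, data) {
    terms <- .dataTerms(data)
    siv <- .muTerms(mu, terms)[2]
    terms$n / siv
}

# integral of u over [lo, hi] by adaptive quadrature, split at the source
# kink when it falls inside the bin
.binIntegral <- function(f, lo, hi, z, ...) {
    tol <- 1e-10
    if (z > lo && z < hi) {
        integrate(f, lo, z, ..., rel.tol = tol, abs.tol = tol)$value +
            integrate(f, z, hi, ..., rel.tol = tol, abs.tol = tol)$value
    } else {
        integrate(f, lo, hi, ..., rel.tol = tol, abs.tol = tol)$value
    }
}

# per-bin integrals of the intensity over a partition
.binIntensityIntegrals <- function(theta, part, geom) {
    e <- part@edges
    vapply(seq_len(length(e) - 1L), function(k) {
        .binIntegral(function(x) .intensity(x, theta@lam, theta@mu,
                                            geom@L, geom@z),
                     e[k], e[k + 1L], geom@z)
    }, numeric(1))
}

#' Binned Poisson log-likelihood
#'
#' Log-likelihood of per-bin counts under the Poisson point process: counts
#' in the bins of a partition are independent Poisson with means
#' \eqn{\int_{A_k} u\,dx}, so
#' \deqn{\ell_{bin} = \sum_k \left[-\textstyle\int_{A_k} u + n_k \log
#'   \int_{A_k} u - \log n_k!\right].}
#'
#' @param theta a \linkS4class{NondimParams}
#' @param counts non-negative integer counts, one per bin
#' @param part a \linkS4class{Partition} spanning `[0, L]`
#' @param geom a \linkS4class{CellGeometry}
#' @return the binned log-likelihood
#' @export
binnedLogLikelihood <- function(theta, counts, part, geom) {
    stopifnot(is(theta, "NondimParams"), is(part, "Partition"),
              is(geom, "CellGeometry"))
    e <- part@edges
    if (abs(e[length(e)] - geom@L) > 1e-12 * max(1, geom@L))
        stop("partition must span [0, L]")
    K <- length(e) - 1L
    if (length(counts) != K)
        stop("length of 'counts' (", length(counts),
             ") does not match number of bins (", K, ")")
    if (any(counts < 0) || any(counts != round(counts)))
        stop("'counts' must be non-negative integers")
    m <- .binIntensityIntegrals(theta, part, geom)
    # guard 0 * log(0): bins with zero count contribute only -m
    contrib <- -m - lgamma(counts + 1)
    pos <- counts > 0
    contrib[pos] <- contrib[pos] + counts[pos] * log(m[pos])
    sum(contrib)
}

#' Bin a snapshot's positions into partition counts
#'
#' @param snap a \linkS4class{Snapshot}
#' @param part a \linkS4class{Partition}
#' @return integer vector of per-bin counts
#' @export
binCounts <- function(snap, part) {
    stopifnot(is(snap, "Snapshot"), is(part, "Partition"))
    e <- part@edges
    idx <- findInterval(snap@positions, e, rightmost.closed = TRUE,
                        left.open = TRUE)
    tabulate(idx, nbins = length(e) - 1L)
}
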