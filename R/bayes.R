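## Gibbs-within-Metropolis posterior sampling for (lambda, mu): exact
## conjugate Gamma draws for lambda, Gaussian random-walk Metropolis for mu
## with a uniform prior on (0, muMax). The proposal scale is adapted during
## burn-in toward ~30% acceptance and frozen afterwards so detailed balance
## holds for the retained draws.

#' Conjugate conditional posterior of lambda
#'
#' Because the intensity is linear in \eqn{\lambda} (\eqn{u = \lambda v}),
#' a Gamma(\eqn{\alpha, \beta}) prior is conjugate: given \eqn{\mu} and `M`
#' snapshots,
#' \deqn{\lambda \mid x, \mu \sim \mathrm{Gamma}\Big(\alpha + \sum_m n_m,\;
#'   \beta + \sum_m \int_{\Omega_m} v(x;\mu)\,dx\Big).}
#'
#' @param mu death rate (> 0)
#' @param data a \linkS4class{SnapshotSet}
#' @param prior a \linkS4class{PriorSpec}
#' @return named numeric `c(shape, rate)` of the Gamma conditional
#' @examples
#' d <- simulateSnapshotSet(NondimParams(500, 10),
#'         rep(list(CellGeometry(1, 0.5)), 5), seed = 1)
#' conditionalLambdaPosterior(10, d, PriorSpec())
#' @export
conditionalLambdaPosterior <- function(mu, data, prior = PriorSpec()) {
    stopifnot(is(prior, "PriorSpec"), mu > 0)
    terms <- .dataTerms(data)
    siv <- if (length(terms$Lg)) .muTerms(mu, terms)[2] else 0
    c(shape = prior@priorShape + terms$n, rate = prior@priorRate + siv)
}

#' Gibbs-within-Metropolis posterior sampler for (lambda, mu)
#'
#' Alternates (i) an exact Gamma draw of \eqn{\lambda \mid \mu, x} using the
#' conjugacy of [conditionalLambdaPosterior()] with (ii) a Gaussian
#' random-walk Metropolis update of \eqn{\mu \mid \lambda, x}, proposals
#' outside \eqn{(0, \mu_{max})} being rejected. The proposal scale adapts
#' during burn-in toward 30% acceptance, then is frozen. Multiple chains are
#' run from dispersed starting points and pooled; per-draw likelihood terms
#' are cached so [hdpr()] needs no further passes over the data.
#'
#' @param data a \linkS4class{SnapshotSet}
#' @param prior a \linkS4class{PriorSpec}
#' @param nIter iterations per chain (including burn-in)
#' @param nBurn burn-in iterations per chain (< `nIter`)
#' @param thin keep every `thin`-th post-burn-in draw
#' @param proposalScale initial random-walk sd for mu (adapted in burn-in)
#' @param nChains number of chains (default 4)
#' @param seed master RNG seed
#' @return a \linkS4class{PosteriorChains}
#' @examples
#' d <- simulateSnapshotSet(NondimParams(500, 10),
#'         rep(list(CellGeometry(1, 0.5)), 20), seed = 1)
#' fit <- samplePosterior(d, nIter = 500, nBurn = 100, seed = 1)
#' fit
#' @export
samplePosterior <- function(data, prior = PriorSpec(), nIter = 12000L,
                            nBurn = 2000L, thin = 1L, proposalScale = 0.5,
                            nChains = 4L, seed = NULL) {
    stopifnot(is(prior, "PriorSpec"))
    nIter <- as.integer(nIter); nBurn <- as.integer(nBurn)
    thin <- as.integer(thin); nChains <- as.integer(nChains)
    if (nIter <= nBurn) stop("'nIter' must exceed 'nBurn'")
    terms <- .dataTerms(data)
    if (terms$n == 0 && length(terms$Lg) == 0)
        stop("empty SnapshotSet: nothing to fit")
    muMax <- prior@muMax
    if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
    seed <- as.integer(seed)
    set.seed(seed)
    chainSeeds <- sample.int(.Machine$integer.max - 1L, nChains)

    keepPer <- length(seq.int(nBurn + 1L, nIter, by = thin))
    lamAll <- muAll <- slvAll <- sivAll <- numeric(keepPer * nChains)
    chainAll <- integer(keepPer * nChains)
    accPost <- 0L; nPost <- 0L

    for (ch in seq_len(nChains)) {
        set.seed(chainSeeds[ch])
        mu <- runif(1, 0.5, 2)
        mt <- .muTerms(mu, terms)
        lam <- if (terms$n > 0) terms$n / mt[2] else
            prior@priorShape / prior@priorRate
        g <- mt[1] - lam * mt[2]      # log target for mu given lam (+const)
        if (!is.finite(g) || !is.finite(lam) || lam <= 0)
            stop("non-finite log-posterior at initialization; ",
                 "re-initialize with different starting values or check ",
                 "the data for boundary positions")
        scale <- proposalScale
        accWin <- 0L; winLen <- 50L
        k <- 0L
        for (it in seq_len(nIter)) {
            # Gibbs: lambda | mu, x
            lam <- rgamma(1, shape = prior@priorShape + terms$n,
                          rate = prior@priorRate + mt[2])
            g <- mt[1] - lam * mt[2]
            # Metropolis: mu | lambda, x
            muProp <- mu + rnorm(1, 0, scale)
            accepted <- FALSE
            if (muProp > 0 && muProp < muMax) {
                mtProp <- .muTerms(muProp, terms)
                gProp <- mtProp[1] - lam * mtProp[2]
                if (is.finite(gProp) && log(runif(1)) < gProp - g) {
                    mu <- muProp; mt <- mtProp; g <- gProp
                    accepted <- TRUE
                }
            }
            if (it <= nBurn) {
                accWin <- accWin + accepted
                if (it %% winLen == 0L) {
                    scale <- scale * exp(accWin / winLen - 0.3)
                    scale <- min(max(scale, 1e-4), muMax / 2)
                    accWin <- 0L
                }
            } else {
                nPost <- nPost + 1L
                accPost <- accPost + accepted
                if ((it - nBurn - 1L) %% thin == 0L) {
                    k <- k + 1L
                    i <- (ch - 1L) * keepPer + k
                    lamAll[i] <- lam; muAll[i] <- mu
                    slvAll[i] <- mt[1]; sivAll[i] <- mt[2]
                    chainAll[i] <- ch
                }
            }
        }
    }
    essLam <- sum(vapply(seq_len(nChains), function(ch)
        .essGeyer(lamAll[chainAll == ch]), numeric(1)))
    essMu <- sum(vapply(seq_len(nChains), function(ch)
        .essGeyer(muAll[chainAll == ch]), numeric(1)))
    new("PosteriorChains", lam = lamAll, mu = muAll, chain = chainAll,
        slv = slvAll, siv = sivAll, nTotal = as.integer(terms$n),
        acceptanceRate = accPost / max(nPost, 1L),
        ess = c(lam = essLam, mu = essMu),
        seed = seed, nIter = nIter, nBurn = nBurn, thin = thin)
}

# effective sample size by Geyer's initial monotone positive sequence
.essGeyer <- function(x) {
    n <- length(x)
    if (n < 10L || sd(x) == 0) return(as.numeric(n))
    maxLag <- min(n - 2L, 2000L)
    rho <- stats::acf(x, lag.max = maxLag, plot = FALSE,
                      demean = TRUE)$acf[-1]
    nPairs <- floor(length(rho) / 2)
    if (nPairs < 1L) return(as.numeric(n))
    gam <- rho[2 * seq_len(nPairs) - 1L] + rho[2 * seq_len(nPairs)]
    m <- which(gam <= 0)
    if (length(m)) gam <- gam[seq_len(m[1L] - 1L)]
    if (length(gam) > 1L) gam <- cummin(gam)       # enforce monotonicity
    tau <- 1 + 2 * sum(gam)
    max(1, n / max(tau, 1e-10))
}

# unnormalised log posterior density at the cached draws
.logPosterior <- function(chains, prior) {
    dgamma(chains@lam, shape = prior@priorShape, rate = prior@priorRate,
           log = TRUE) +
        chains@nTotal * log(chains@lam) + chains@slv -
        chains@lam * chains@siv
}

#' Highest-density posterior region
#'
#' Evaluates the unnormalised log posterior at each pooled draw, retains the
#' top `level` fraction by density, and returns the convex hull of the
#' retained \eqn{(\lambda, \mu)} points with its shoelace area. Cached
#' likelihood terms stored in the chains are used; `data` is only needed if
#' those are absent.
#'
#' @param chains a \linkS4class{PosteriorChains} (>= 100 draws)
#' @param data optional \linkS4class{SnapshotSet} (unused when cached terms
#'   are present)
#' @param prior the \linkS4class{PriorSpec} used in fitting
#' @param level credibility mass (default 0.89)
#' @return an \linkS4class{HDPRegion}
#' @export
hdpr <- function(chains, data = NULL, prior = PriorSpec(), level = 0.89) {
    stopifnot(is(chains, "PosteriorChains"), is(prior, "PriorSpec"))
    n <- length(chains@lam)
    if (n < 100L) stop("need at least 100 post-burn-in samples")
    lp <- .logPosterior(chains, prior)
    keep <- order(lp, decreasing = TRUE)[seq_len(ceiling(level * n))]
    pts <- cbind(chains@lam[keep], chains@mu[keep])
    hull <- chull(pts)
    verts <- pts[hull, , drop = FALSE]
    area <- .shoelace(verts)
    if (area == 0)
        warning("retained samples are degenerate (collinear); ",
                "zero-area region")
    colnames(verts) <- c("lam", "mu")
    new("HDPRegion", level = level, vertices = verts, area = area)
}

# polygon area by the shoelace formula (vertex order irrelevant up to sign)
.shoelace <- function(v) {
    if (nrow(v) < 3L) return(0)
    x <- v[, 1]; y <- v[, 2]
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    abs(sum(x * yn - xn * y)) / 2
}

#' Test whether a parameter point lies inside an HDPR
#'
#' Point-in-convex-polygon test used, e.g., for coverage calibration.
#'
#' @param region an \linkS4class{HDPRegion}
#' @param theta a \linkS4class{NondimParams}
#' @return logical
#' @export
hdprContains <- function(region, theta) {
    stopifnot(is(region, "HDPRegion"), is(theta, "NondimParams"))
    v <- region@vertices
    if (nrow(v) < 3L) return(FALSE)
    p <- c(theta@lam, theta@mu)
    nv <- nrow(v)
    cr <- vapply(seq_len(nv), function(i) {
        j <- if (i == nv) 1L else i + 1L
        (v[j, 1] - v[i, 1]) * (p[2] - v[i, 2]) -
            (v[j, 2] - v[i, 2]) * (p[1] - v[i, 1])
    }, numeric(1))
    all(cr >= 0) || all(cr <= 0)
}

#' Posterior summary table
#'
#' @param chains a \linkS4class{PosteriorChains}
#' @param probs quantile probabilities (default 5.5% and 94.5%, the
#'   equal-tailed 89% interval)
#' @return a data.frame with one row per parameter
#' @export
posteriorSummary <- function(chains, probs = c(0.055, 0.945)) {
    stopifnot(is(chains, "PosteriorChains"))
    mk <- function(x, nm) {
        q <- quantile(x, probs, names = FALSE)
        data.frame(param = nm, mean = mean(x), sd = sd(x),
                   lower = q[1], upper = q[2])
    }
    out <- rbind(mk(chains@lam, "lam"), mk(chains@mu, "mu"))
    out$ess <- chains@ess[c("lam", "mu")]
    out$acceptanceRate <- chains@acceptanceRate
    rownames(out) <- NULL
    out
}
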