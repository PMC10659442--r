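# Shared fixtures: reference parameter points used across the suite and a
# slow-but-independent quadrature of the intensity (never the package's
# closed-form integral) for cross-checks.

thetaRef <- function() NondimParams(500, 10)
geomRef <- function() CellGeometry(L = 1, z = 0.5)

# independent numerical integral of u over [lo, hi] (split at the kink)
quadIntensity <- function(theta, geom, lo = 0, hi = domainLength(geom)) {
    f <- function(x) intensity(x, theta, geom)
    z <- sourcePosition(geom)
    if (z > lo && z < hi) {
        integrate(f, lo, z, rel.tol = 1e-12, abs.tol = 1e-14)$value +
            integrate(f, z, hi, rel.tol = 1e-12, abs.tol = 1e-14)$value
    } else {
        integrate(f, lo, hi, rel.tol = 1e-12, abs.tol = 1e-14)$value
    }
}

# chi-square goodness-of-fit of integer counts against a Poisson pmf,
# pooling tail categories so every expected count is >= 5
poissonGofPvalue <- function(counts, mean) {
    tb <- table(factor(counts, levels = 0:max(counts)))
    obs <- as.numeric(tb)
    exp <- dpois(0:max(counts), mean) * length(counts)
    exp[length(exp)] <- exp[length(exp)] +
        ppois(max(counts), mean, lower.tail = FALSE) * length(counts)
    # pool from the right, then from the left, until expected >= 5
    while (length(exp) > 2 && exp[length(exp)] < 5) {
        n <- length(exp)
        exp[n - 1] <- exp[n - 1] + exp[n]; exp <- exp[-n]
        obs[n - 1] <- obs[n - 1] + obs[n]; obs <- obs[-n]
    }
    while (length(exp) > 2 && exp[1] < 5) {
        exp[2] <- exp[2] + exp[1]; exp <- exp[-1]
        obs[2] <- obs[2] + obs[1]; obs <- obs[-1]
    }
    stat <- sum((obs - exp)^2 / exp)
    df <- length(exp) - 1
    list(stat = stat, df = df,
         p = pchisq(stat, df, lower.tail = FALSE))
}
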