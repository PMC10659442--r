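# Fisher information: closed-form checks, derivative oracles, D-optimality
# structure, heterogeneity averaging, and the binning inequality.

test_that("I[lam,lam] matches its closed form and E[N]/lambda^2 across a
           sweep, and all entries stay finite and positive", {
    for (lam in c(10, 500))
        for (mu in c(0.1, 1, 10, 100))
            for (zf in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
                th <- NondimParams(lam, mu)
                g <- CellGeometry(1, zf)
                I <- infoEntries(fisherInformation(th, g))
                s <- sqrt(mu)
                closed <- (1 / (lam * mu)) *
                    (1 - (1 / cosh(s * 1 / 2)) * cosh(s * (1 - 2 * zf) / 2))
                expect_equal(I[1, 1], closed, tolerance = 1e-8)
                expect_equal(I[1, 1], expectedCount(th, g) / lam^2,
                             tolerance = 1e-10)
                expect_true(all(is.finite(I)))
                expect_true(I[1, 1] > 0 && I[2, 2] > 0)
            }
})

test_that("analytic d u/d mu matches central finite differences away from
           the kink and the walls", {
    lam <- 500; mu <- 10
    g <- CellGeometry(L = 1.5, z = 0.6)
    x <- setdiff(seq(0.05, 1.45, by = 0.05), 0.6)
    h <- mu * 1e-6
    fd <- (intensity(x, NondimParams(lam, mu + h), g) -
           intensity(x, NondimParams(lam, mu - h), g)) / (2 * h)
    an <- snapBDD:::.du_dmu(x, lam, mu, 1.5, 0.6)
    expect_equal(an, fd, tolerance = 1e-6)
})

test_that("full information matrix agrees with a Monte Carlo score
           estimate over direct-sampled snapshots", {
    th <- NondimParams(500, 10); g <- geomRef()
    I <- infoEntries(fisherInformation(th, g))
    EN <- expectedCount(th, g)
    set.seed(100)
    reps <- 2000L
    dENdmu <- integrate(function(x) snapBDD:::.du_dmu(x, 500, 10, 1, 0.5),
                        0, 0.5)$value +
        integrate(function(x) snapBDD:::.du_dmu(x, 500, 10, 1, 0.5),
                  0.5, 1)$value
    sc <- matrix(0, reps, 2)
    for (r in seq_len(reps)) {
        p <- positions(sampleSnapshotDirect(th, g))
        # score: (n/lam - E[N]/lam, sum dlogu/dmu - d E[N]/dmu)
        sc[r, 1] <- length(p) / 500 - EN / 500
        sc[r, 2] <- sum(snapBDD:::.dlogu_dmu(p, 10, 1, 0.5)) - dENdmu
    }
    Imc <- crossprod(sc) / reps
    # elementwise within 3 SE of the Monte Carlo estimate
    for (i in 1:2) for (j in 1:2) {
        se <- sd(sc[, i] * sc[, j]) / sqrt(reps)
        expect_lt(abs(Imc[i, j] - I[i, j]), 3 * se)
    }
})

test_that("information is additive over iid cells through the likelihood
           curvature", {
    # numerical Hessian of the M-cell log-likelihood expectation equals
    # M times the single-cell information for the lam-lam entry (exact
    # through E[N]/lam^2)
    th <- thetaRef(); g <- geomRef()
    I1 <- infoEntries(fisherInformation(th, g))[1, 1]
    M <- 7
    ENs <- M * expectedCount(th, g)
    expect_equal(ENs / 500^2, M * I1, tolerance = 1e-12)
})

test_that("D-optimal source location is central for large mu and
           bifurcates off-centre for small mu, and det I saturates in L", {
    oBig <- optimalSourceLocation(NondimParams(500, 100))
    expect_equal(oBig$z, 0.5, tolerance = 1e-9)
    oSmall <- optimalSourceLocation(NondimParams(500, 1))
    zc <- oSmall$detI[which.min(abs(oSmall$zGrid - 0.5))]
    expect_true(oSmall$z < 0.5)               # tie-break toward smaller z
    expect_gt(max(oSmall$detI), zc)
    # reflection symmetry of the z-profile
    expect_equal(oSmall$detI, rev(oSmall$detI), tolerance = 1e-6)
    # saturation in L at large mu
    th <- NondimParams(500, 100)
    d8 <- detInformation(th, CellGeometry(8, 4))
    d16 <- detInformation(th, CellGeometry(16, 8))
    expect_lt(abs(d16 - d8) / d8, 0.01)
})

test_that("heterogeneous information reduces to the fixed geometry in the
           degenerate limit and reproduces the small/large mu contrast", {
    thLow <- NondimParams(500, 1)
    fixed <- infoEntries(fisherInformation(thLow, geomRef()))
    degen <- infoEntries(heterogeneousInformation(thLow,
        HeterogeneityModel(0, 0)))
    expect_equal(degen, fixed, tolerance = 1e-6)
    # low mu: source-location spread increases det E[I]
    dz <- vapply(c(0, 0.75), function(s) det(infoEntries(
        heterogeneousInformation(thLow, HeterogeneityModel(s, 0)))),
        numeric(1))
    expect_gt(dz[2], dz[1])
    # high mu: spread decreases det E[I], monotonically on a sweep to 1
    thHigh <- NondimParams(500, 100)
    dzh <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(s) det(infoEntries(
        heterogeneousInformation(thHigh, HeterogeneityModel(s, 0)))),
        numeric(1))
    expect_true(all(diff(dzh) < 0))
    # quadrature agrees with seeded Monte Carlo within its noise
    q <- infoEntries(heterogeneousInformation(thLow,
        HeterogeneityModel(0.75, 0.25)))
    mc <- infoEntries(heterogeneousInformation(thLow,
        HeterogeneityModel(0.75, 0.25), method = "montecarlo",
        nMC = 2000, seed = 8))
    expect_lt(max(abs(q - mc) / abs(q)), 0.1)
})

test_that("binned information never exceeds the exact information, with
           equality for the scale parameter lambda", {
    th <- thetaRef(); g <- geomRef()
    I <- infoEntries(fisherInformation(th, g))
    set.seed(40)
    parts <- c(
        lapply(c(2L, 4L, 8L, 16L), function(K)
            Partition(seq(0, 1, length.out = K + 1))),
        lapply(c(2L, 4L, 8L, 16L), function(K)
            Partition(c(0, sort(runif(K - 1)), 1))))
    for (p in parts) {
        expect_equal(binnedInformation(th, p, g, "lam"), I[1, 1],
                     tolerance = 1e-12)
        expect_lte(binnedInformation(th, p, g, "mu"), I[2, 2] + 1e-10)
    }
    # K = 2 equal bins loses mu-information strictly
    p2 <- Partition(c(0, 0.5, 1))
    expect_lt(binnedInformation(th, p2, g, "mu"), I[2, 2])
    # refinement approaches the unbinned value
    pFine <- Partition(seq(0, 1, length.out = 257))
    expect_equal(binnedInformation(th, pFine, g, "mu"), I[2, 2],
                 tolerance = 1e-3)
})
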