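# Closed-form intensity u, its integral E[N], nondimensionalisation, and
# the finite-difference oracle for the boundary-value problem.

test_that("nondimensionalization applies the L0^2/D rescaling", {
    th <- nondimensionalize(DimensionalParams(kappaPlus = 5,
                                              kappaMinus = 0.75,
                                              D = 0.5, L0 = 1))
    expect_identical(birthRate(th), 10)
    expect_identical(deathRate(th), 1.5)
    expect_equal(attr(th, "lengthScale"), 1)

    # identity scaling at D = L0 = 1
    th1 <- nondimensionalize(DimensionalParams(3.2, 0.7, 1, 1))
    expect_equal(c(birthRate(th1), deathRate(th1)), c(3.2, 0.7))

    # quadratic in L0: doubling L0 multiplies both rates by 4
    a <- nondimensionalize(DimensionalParams(3.2, 0.7, 2, 1))
    b <- nondimensionalize(DimensionalParams(3.2, 0.7, 2, 2))
    expect_equal(birthRate(b) / birthRate(a), 4)
    expect_equal(deathRate(b) / deathRate(a), 4)

    expect_error(DimensionalParams(1, 1, 0, 1), "D")
    expect_error(DimensionalParams(1, 1, 1, 0), "L0")
})

test_that("intensity vanishes at absorbing ends, is linear in lambda, and
           reflects across the domain midpoint with the source", {
    th <- thetaRef()
    g <- CellGeometry(L = 2, z = 0.6)
    expect_identical(intensity(c(0, 2), th, g), c(0, 0))
    x <- seq(0.05, 1.95, by = 0.1)
    u1 <- intensity(x, NondimParams(1, 10), g)
    u5 <- intensity(x, NondimParams(5, 10), g)
    expect_equal(u5, 5 * u1, tolerance = 1e-14)
    # u(x; z) = u(L - x; L - z)
    gRef <- CellGeometry(L = 2, z = 2 - 0.6)
    expect_equal(intensity(x, th, g), intensity(2 - x, th, gRef),
                 tolerance = 1e-12)
    expect_true(all(u1 >= 0))
    expect_error(intensity(2.5, th, g), "0, L")
})

test_that("closed form agrees with the finite-difference BVP oracle at
           second order", {
    th <- NondimParams(500, 10)
    g <- CellGeometry(L = 1, z = 0.5)
    errAt <- function(n) {
        pr <- solveIntensityNumeric(th, g, n)
        max(abs(intensity(pr@grid, th, g) - pr@values))
    }
    e1 <- errAt(512); e2 <- errAt(1024)
    order <- log2(e1 / e2)
    expect_gt(order, 1.9)
    expect_lt(errAt(10000), 1e-5)
    # value check at the source
    pr <- solveIntensityNumeric(th, g, 10000)
    i <- which.min(abs(pr@grid - 0.5))
    expect_equal(intensity(0.5, th, g), pr@values[i], tolerance = 1e-6)
    # off-grid source retains second order (hat-function deposition)
    g2 <- CellGeometry(L = 1, z = 1 / 3)
    err2 <- vapply(c(512L, 1024L), function(n) {
        pr <- solveIntensityNumeric(th, g2, n)
        max(abs(intensity(pr@grid, th, g2) - pr@values))
    }, numeric(1))
    expect_gt(log2(err2[1] / err2[2]), 1.9)
    # lambda = 0 gives the zero profile
    pr0 <- solveIntensityNumeric(NondimParams(0, 10), g, 64)
    expect_identical(max(pr0@values), 0)
})

test_that("expected count equals the integral of the intensity across a
           parameter sweep", {
    for (lam in c(1, 500))
        for (mu in c(0.1, 1, 10, 100))
            for (L in c(0.5, 1, 2))
                for (zf in c(0.1, 0.5, 0.9)) {
                    th <- NondimParams(lam, mu)
                    g <- CellGeometry(L = L, z = zf * L)
                    expect_equal(expectedCount(th, g),
                                 quadIntensity(th, g),
                                 tolerance = 1e-8)
                }
})

test_that("expected count has the lambda*z*(L-z)/2 small-mu limit and
           vanishes as the source approaches a wall", {
    g <- CellGeometry(L = 2, z = 0.7)
    EN <- expectedCount(NondimParams(50, 1e-6), g)
    expect_lt(abs(EN - 50 * 0.7 * (2 - 0.7) / 2) / EN, 1e-4)
    # exactly-zero mu uses the analytic limit
    expect_equal(expectedCount(NondimParams(50, 0), g),
                 50 * 0.7 * 1.3 / 2)
    # source on the boundary kills the count
    for (z in c(1e-9, 2 - 1e-9))
        expect_lt(expectedCount(NondimParams(50, 1), CellGeometry(2, z)),
                  1e-6)
})

test_that("evaluation is overflow-safe up to sqrt(mu)*L ~ 700", {
    th <- NondimParams(500, 700^2)
    g <- CellGeometry(L = 1, z = 0.5)
    u <- intensity(seq(0, 1, by = 0.05), th, g)
    expect_true(all(is.finite(u)))
    expect_true(is.finite(expectedCount(th, g)))
    expect_equal(expectedCount(th, g), 500 / 700^2, tolerance = 1e-10)
})

test_that("time-dependent occupation-measure oracle reproduces the
           stationary profile", {
    # integrate the survival density rho_t = rho_xx - mu*rho forward in
    # time (Crank-Nicolson) from a hat-function delta at z, accumulate
    # int rho dt, multiply by lambda: this occupation measure solves the
    # same BVP as the intensity
    th <- NondimParams(500, 10)
    g <- CellGeometry(L = 1, z = 0.5)
    n <- 400L; h <- 1 / n; dt <- 5e-4
    x <- seq(0, 1, length.out = n + 1)
    j <- floor(0.5 / h); w <- 0.5 / h - j
    rho <- numeric(n - 1)
    rho[j] <- (1 - w) / h
    if (w > 0) rho[j + 1] <- rho[j + 1] + w / h
    A <- diag(-2 / h^2 - 10, n - 1)
    A[cbind(1:(n - 2), 2:(n - 1))] <- 1 / h^2
    A[cbind(2:(n - 1), 1:(n - 2))] <- 1 / h^2
    Iright <- diag(n - 1) + dt / 2 * A
    Mleft <- solve(diag(n - 1) - dt / 2 * A)
    occ <- numeric(n - 1)
    for (k in 1:4000) {   # T = 2: survival ~ exp(-(mu + pi^2) T) ~ 1e-17
        rhoNew <- Mleft %*% (Iright %*% rho)
        occ <- occ + dt * (rho + rhoNew) / 2
        rho <- rhoNew
    }
    u <- intensity(x[2:n], th, g)
    expect_lt(max(abs(500 * occ - u)) / max(u), 5e-3)
})
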