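# Trajectory-level and direct Poisson samplers: determinism, boundary
# behaviour, Poisson statistics, and the scaling invariance of the
# nondimensionalised system.

test_that("zero birth rate yields empty snapshots in both modes", {
    g <- CellGeometry(1, 0.5)
    s1 <- simulateSnapshotTrajectories(NondimParams(0, 1), g,
                                       SimOptions(dt = 1e-3, seed = 1))
    s2 <- sampleSnapshotDirect(NondimParams(0, 1), g, seed = 1)
    expect_identical(positions(s1), numeric())
    expect_identical(positions(s2), numeric())
})

test_that("fixed master seed reproduces a SnapshotSet bit-identically and
           cell ids must be unique", {
    th <- thetaRef()
    geoms <- rep(list(geomRef()), 4)
    a <- simulateSnapshotSet(th, geoms, seed = 99)
    b <- simulateSnapshotSet(th, geoms, seed = 99)
    expect_identical(positions(a), positions(b))
    expect_identical(cellIds(a), cellIds(b))
    c2 <- simulateSnapshotSet(th, geoms, seed = 100)
    expect_false(identical(positions(a), positions(c2)))
    names(geoms) <- c("a", "a", "b", "c")
    expect_error(simulateSnapshotSet(th, geoms, seed = 1), "duplicate")
    # M = 1 reduces to the single-cell sampler
    one <- simulateSnapshotSet(th, list(geomRef()), seed = 7)
    expect_identical(nCells(one), 1L)
})

test_that("direct sampler counts are Poisson-dispersed and disjoint halves
           are uncorrelated", {
    th <- NondimParams(500, 10)   # E[N] ~ 30
    g <- geomRef()
    set.seed(314)
    reps <- 5000L
    left <- right <- integer(reps)
    for (r in seq_len(reps)) {
        p <- positions(sampleSnapshotDirect(th, g))
        left[r] <- sum(p < 0.5); right[r] <- sum(p >= 0.5)
    }
    n <- left + right
    expect_gt(var(n) / mean(n), 0.9)
    expect_lt(var(n) / mean(n), 1.1)
    expect_lt(abs(mean(n) - expectedCount(th, g)),
              3 * sd(n) / sqrt(reps))
    expect_lt(abs(cor(left, right)), 3 / sqrt(reps))
})

test_that("direct-sampled positions follow the normalized intensity", {
    th <- NondimParams(500, 10)
    g <- geomRef()
    set.seed(2718)
    pool <- unlist(lapply(1:200, function(r)
        positions(sampleSnapshotDirect(th, g))))
    cdf <- function(q) vapply(q, function(qq)
        quadIntensity(th, g, 0, qq), numeric(1)) / expectedCount(th, g)
    ks <- suppressWarnings(ks.test(pool, cdf))
    expect_gt(ks$p.value, 0.01)
})

test_that("trajectory simulator matches the expected count and intensity
           shape at fine dt", {
    th <- NondimParams(10, 1.5)
    g <- CellGeometry(L = 3, z = 1)
    set.seed(11)
    opts <- SimOptions(dt = 1e-3)
    reps <- 400L
    snaps <- lapply(seq_len(reps), function(r)
        simulateSnapshotTrajectories(th, g, opts))
    counts <- vapply(snaps, particleCounts, integer(1))
    EN <- expectedCount(th, g)
    expect_lt(abs(mean(counts) - EN), 3 * sd(counts) / sqrt(reps))
    pool <- unlist(lapply(snaps, positions))
    cdf <- function(q) vapply(q, function(qq)
        quadIntensity(th, g, 0, qq), numeric(1)) / EN
    ks <- suppressWarnings(ks.test(pool, cdf))
    expect_gt(ks$p.value, 0.01)
})

test_that("skipping the bridge correction biases counts high at coarse dt
           and the bias shrinks with dt", {
    th <- NondimParams(200, 1)
    g <- CellGeometry(L = 1, z = 0.25)   # strong absorption regime
    EN <- expectedCount(th, g)
    meanCount <- function(dt, bridge, reps, seed) {
        set.seed(seed)
        opts <- SimOptions(dt = dt, bridgeCorrection = bridge)
        mean(vapply(seq_len(reps), function(r)
            particleCounts(simulateSnapshotTrajectories(th, g, opts)),
            integer(1)))
    }
    coarse <- suppressWarnings(meanCount(4e-3, FALSE, 150, 21))
    finer <- meanCount(5e-4, FALSE, 150, 22)
    corrected <- meanCount(4e-3, TRUE, 150, 23)
    expect_gt(coarse, EN * 1.05)            # missed absorptions inflate N
    expect_lt(finer - EN, coarse - EN)      # bias shrinks as dt -> 0
    expect_lt(abs(corrected - EN) / EN, 0.05)
})

test_that("nondimensional rescaling leaves count and position distributions
           invariant", {
    # same physical system nondimensionalised with L0 = 1 vs L0 = 3:
    # (lam, mu, L) = (10, 1.5, 3) vs (90, 13.5, 1), lengths scaled by 3
    thA <- NondimParams(10, 1.5); gA <- CellGeometry(3, 1)
    thB <- NondimParams(90, 13.5); gB <- CellGeometry(1, 1 / 3)
    expect_equal(expectedCount(thA, gA), expectedCount(thB, gB),
                 tolerance = 1e-12)
    set.seed(33)
    reps <- 400L
    sA <- lapply(seq_len(reps), function(r) sampleSnapshotDirect(thA, gA))
    sB <- lapply(seq_len(reps), function(r) sampleSnapshotDirect(thB, gB))
    nA <- vapply(sA, particleCounts, integer(1))
    nB <- vapply(sB, particleCounts, integer(1))
    expect_gt(suppressWarnings(
        ks.test(unlist(lapply(sA, positions)),
                3 * unlist(lapply(sB, positions)))$p.value), 0.01)
    expect_gt(suppressWarnings(ks.test(nA, nB)$p.value), 0.01)
})

test_that("coarse time steps trigger a warning", {
    th <- NondimParams(5, 10)
    g <- CellGeometry(1, 0.5)
    expect_warning(
        simulateSnapshotTrajectories(th, g, SimOptions(dt = 0.5, seed = 1)),
        "coarse")
})
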