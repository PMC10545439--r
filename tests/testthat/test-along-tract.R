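# Uniform resampling, the along-tract median with its support-count
# termination rule, smoothing and the pointwise group test.

test_that("uniform resampling places points at integer arc lengths", {
    b <- streamlineSet(list(straightStreamline(c(0, 0, 0), c(0, 0, 1), 10,
                                               step = 2.5)))
    r <- resampleUniform(b, 1)
    m <- streamlines(r)[[1]]
    expect_equal(nrow(m), 11L)
    expect_equal(m[, 3], 0:10)
    # idempotent on already-uniform input
    r2 <- resampleUniform(r, 1)
    expect_equal(streamlines(r2), streamlines(r))
    # a streamline shorter than one step keeps its endpoints
    tiny <- streamlineSet(list(rbind(c(0, 0, 0), c(0, 0, 0.4))))
    expect_equal(nrow(streamlines(resampleUniform(tiny, 1))[[1]]), 2L)
    expect_error(resampleUniform(b, 0), "step > 0")
})

test_that("resampling preserves total length within one step and endpoints within half", {
    withSeed(20, {
        g <- scalarVolume(array(0, c(30, 30, 30)))
        s <- randomStreamlineSet(g, n = 10, npts = 12)
        r <- resampleUniform(s, 1)
        for (i in seq_len(10)) {
            L0 <- sum(sqrt(rowSums(diff(streamlines(s)[[i]])^2)))
            m <- streamlines(r)[[i]]
            L1 <- sum(sqrt(rowSums(diff(m)^2)))
            expect_lt(abs(L0 - L1), 1)
            ends0 <- streamlines(s)[[i]][c(1, nrow(streamlines(s)[[i]])), ]
            expect_lt(max(abs(m[1, ] - ends0[1, ])), 1e-9)
            expect_lt(sqrt(sum((m[nrow(m), ] - ends0[2, ])^2)), 0.5 + 1e-9)
        }
    })
})

test_that("profile medians follow the odd/even conventions and the termination rule", {
    # five streamlines at x = 1..5 in a field equal to x: position-0 values
    # {1,2,3,4,5} -> median 3
    lin <- linearFieldVolume(c(10, 10, 12), coef = c(1, 0, 0))
    b5 <- streamlineSet(lapply(1:5, function(i)
        straightStreamline(c(i, 4, 1), c(0, 0, 1), 9)))
    p <- profileMedian(b5, lin, minSupport = 5)
    expect_equal(profileValues(p)[1], 3)
    expect_equal(profilePositions(p), 0:9)
    expect_equal(profileSupport(p), rep(5L, 10))

    # point counts {10,10,10,10,4}: profile stops after 4 positions
    mixed <- streamlineSet(c(lapply(1:4, function(i)
        straightStreamline(c(i, 4, 1), c(0, 0, 1), 9)),
        list(straightStreamline(c(5, 4, 1), c(0, 0, 1), 3))))
    p2 <- profileMedian(mixed, lin, minSupport = 5)
    expect_equal(length(profilePositions(p2)), 4L)
    expect_equal(profilePositions(p2), 0:3)

    # even contributor count {1,2,3,4} -> mean-of-middle-two 2.5
    b4 <- streamlineSet(lapply(1:4, function(i)
        straightStreamline(c(i, 4, 1), c(0, 0, 1), 9)))
    p3 <- profileMedian(b4, lin, minSupport = 4)
    expect_equal(profileValues(p3)[1], 2.5)

    expect_error(profileMedian(b4, lin, minSupport = 5), "fewer than")
})

test_that("profile medians equal the per-index oracle on random bundles", {
    withSeed(22, {
        for (i in 1:40) {
            v <- randomVolume(c(9, 9, 9), affine = diag(4))
            npts <- sample(3:8, 6, replace = TRUE)
            sl <- lapply(npts, function(np) {
                m <- randomStreamlineSet(v, n = 1, npts = np)
                streamlines(m)[[1]]
            })
            b <- streamlineSet(sl)
            p <- profileMedian(b, v, minSupport = 3)
            samples <- lapply(sl, function(m) sampleMetric(v, m))
            ref <- oracleProfileMedian(samples, minSupport = 3)
            expect_equal(profileValues(p), ref$values)
            expect_equal(profileSupport(p), as.integer(ref$support))
        }
    })
})

test_that("profiles of a constant field are constant, and support never increases", {
    cst <- scalarVolume(array(4.2, c(12, 12, 12)))
    withSeed(23, {
        sl <- lapply(sample(4:9, 7, replace = TRUE), function(np)
            straightStreamline(c(runif(2, 2, 9), 1), c(0, 0, 1), np - 1))
        b <- streamlineSet(sl)
        p <- profileMedian(b, cst, minSupport = 4)
        expect_true(all(profileValues(p) == 4.2))
        expect_true(all(diff(profileSupport(p)) <= 0))
        # removing a streamline never lengthens the profile
        p2 <- profileMedian(streamlineSet(sl[-1]), cst, minSupport = 4)
        expect_lte(length(profileValues(p2)), length(profileValues(p)))
    })
})

test_that("profile of a distance-increasing field increases monotonically", {
    lin <- linearFieldVolume(c(8, 8, 20), coef = c(0, 0, 1))
    b <- streamlineSet(lapply(1:6, function(i)
        straightStreamline(c(2 + 0.3 * i, 4, 1), c(0, 0, 1), 15)))
    p <- profileMedian(b, lin, minSupport = 5)
    expect_true(all(diff(profileValues(p)) > 0))
})

test_that("smoothing is the identity on constants, window-1 and linear interiors", {
    mkProfile <- function(vals) new("TractProfile",
                                    positions = seq_along(vals) - 1,
                                    values = vals,
                                    support = rep(9L, length(vals)),
                                    metric = "AFD")
    cst <- mkProfile(rep(3, 25))
    expect_equal(profileValues(smoothProfile(cst, 10)), rep(3, 25))
    withSeed(24, {
        ran <- mkProfile(rnorm(25))
        expect_equal(profileValues(smoothProfile(ran, 1)),
                     profileValues(ran))
    })
    ramp <- mkProfile(0.5 * (0:24))
    sm <- profileValues(smoothProfile(ramp, 10))
    # symmetric windows leave a linear sequence unchanged in the interior
    expect_equal(sm[6:19], profileValues(ramp)[6:19], tolerance = 1e-12)
    # support untouched
    expect_equal(profileSupport(smoothProfile(ramp, 10)),
                 profileSupport(ramp))
})

test_that("the pointwise H-test runs per position without correction", {
    # three groups of flat profiles at distinct levels: H = 7.2 everywhere
    mk <- function(level) lapply(level, function(l) rep(l, 5))
    groups <- list(TD = mk(1:3), HP = mk(4:6), DP = mk(7:9))
    ht <- pointwiseHTest(groups)
    expect_equal(nrow(ht), 5L)
    expect_equal(ht$H, rep(7.2, 5), tolerance = 1e-12)
    expect_equal(ht$position_mm, 0:4)
    # identical distributions: H ~ 0, p ~ 1
    same <- list(a = mk(c(1, 2, 3)), b = mk(c(1, 2, 3)))
    ht2 <- pointwiseHTest(same)
    expect_true(all(ht2$p > 0.95))
    # permuting subjects within groups changes nothing
    perm <- list(TD = mk(c(3, 1, 2)), HP = mk(c(6, 4, 5)), DP = mk(c(8, 9, 7)))
    expect_equal(pointwiseHTest(perm)$H, ht$H)
    # positions missing group coverage are skipped
    ragged <- list(a = list(rep(1, 6), rep(2, 2)), b = mk(c(3, 4)))
    ht3 <- pointwiseHTest(ragged)
    expect_equal(nrow(ht3), 2L)
    expect_error(pointwiseHTest(list(a = mk(1:3))), "2 groups")
})
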