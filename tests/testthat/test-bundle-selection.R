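# Bundle selection: midline rule, terminal-ROI membership, orientation,
# the minimum-count exclusion, density images, masks and outlier removal.

test_that("midline filtering keeps strictly one-sided streamlines only", {
    s <- streamlineSet(list(
        cbind(c(1, 2, 3), 0, c(0, 1, 2)),        # all x > 0: kept
        cbind(c(1, 2, -1), 0, c(0, 1, 2)),       # crosses: removed
        cbind(c(-1, -5, -2), 0, c(0, 1, 2)),     # all x < 0: kept
        cbind(c(1, 0, 2), 0, c(0, 1, 2))))       # touches plane: removed
    f <- filterMidline(s, 0)
    expect_equal(nStreamlines(f), 2L)
    expect_true(all(sapply(streamlines(f), function(m)
        all(m[, 1] > 0) || all(m[, 1] < 0))))
    # configurable plane position
    expect_equal(nStreamlines(filterMidline(s, -10)), 4L)
})

test_that("ROI filtering keeps streamlines by cortical terminal point", {
    g <- scalarVolume(array(0, c(15, 15, 15)))
    surf <- scalarVolume(array(1, c(15, 15, 15)))
    roi <- manualROI(c(7, 7, 10), "upper", "left", surf, radius = 3)
    inOrigin <- straightStreamline(c(7, 7, 0), c(0, 0, 1), 10)   # ends in origin
    inDilation <- straightStreamline(c(7, 9, 0), c(0, 0, 1), 10) # ends 2 mm off
    out <- straightStreamline(c(2, 2, 0), c(0, 0, 1), 4)         # ends far away
    f <- filterToROI(streamlineSet(list(inOrigin, inDilation, out)), roi, g)
    expect_equal(nStreamlines(f), 2L)
    # a SeedROI always contains its origin, so the voxel set is never empty
    expect_gte(nrow(roiVoxels(roi)), 1L)
})

test_that("midline and ROI filters commute", {
    withSeed(31, {
        g <- scalarVolume(array(0, c(21, 21, 21)))
        surf <- scalarVolume(array(1, c(21, 21, 21)))
        roi <- manualROI(c(14, 10, 16), "upper", "left", surf, radius = 3)
        s <- randomStreamlineSet(g, n = 40, npts = 7)
        a <- filterToROI(filterMidline(s, 10), roi, g)
        b <- filterMidline(filterToROI(s, roi, g), 10)
        expect_equal(streamlines(a), streamlines(b))
    })
})

test_that("orientation flips streamlines thalamus-first and is involutive", {
    thal <- scalarVolume(array(0, c(11, 11, 11)))
    thal@data[2, 6, 6] <- 1
    toward <- straightStreamline(c(1, 5, 5), c(1, 0, 0), 8)   # starts at thalamus
    away <- toward[nrow(toward):1, ]
    s <- streamlineSet(list(toward, away, toward, away))
    o <- orientBundle(s, thal)
    for (m in streamlines(o)) expect_equal(m, toward)
    # applying twice changes nothing
    o2 <- orientBundle(o, thal)
    expect_equal(streamlines(o2), streamlines(o))
    # equidistant endpoints: original order kept with a warning
    thalC <- scalarVolume(array(0, c(11, 11, 11)))
    thalC@data[2, 6, 6] <- 1
    symm <- rbind(c(0, 5, 5), c(1, 6, 5), c(2, 5, 5))  # ends equidistant from (1,5,5)
    expect_warning(orientBundle(streamlineSet(list(symm)), thalC),
                   "equidistant")
    expect_error(orientBundle(s, scalarVolume(array(0, c(5, 5, 5)))), "empty")
})

test_that("the minimum streamline count rule excludes below 5 and keeps 5", {
    mk <- function(n) tractBundle(lapply(seq_len(n), function(i)
        straightStreamline(c(i, 0, 0), c(0, 0, 1), 5)))
    expect_s4_class(enforceMinCount(mk(5)), "TractBundle")
    expect_true(isExcluded(enforceMinCount(mk(4))))
    ex <- enforceMinCount(mk(2))
    expect_true(isExcluded(ex))
    expect_match(ex@reason, "<5")
    expect_s4_class(enforceMinCount(mk(3), minN = 3), "TractBundle")
})

test_that("tract density counts each streamline once per visited voxel", {
    g <- scalarVolume(array(0, c(9, 9, 9)))
    one <- straightStreamline(c(4, 4, 2), c(0, 0, 1), 4)   # crosses 5 centers
    tdi <- tractDensity(streamlineSet(list(one)), g)
    expect_identical(volumeUnits(tdi), "count")
    expect_equal(sum(voxelData(tdi)), 5)
    expect_true(all(voxelData(tdi)[5, 5, 3:7] == 1))
    # duplicated streamline doubles every visited voxel
    tdi2 <- tractDensity(streamlineSet(list(one, one)), g)
    expect_equal(voxelData(tdi2), 2 * voxelData(tdi))
    expect_error(tractDensity(streamlineSet(list()), g), "empty")
})

test_that("tract density matches the brute-force visitation oracle", {
    withSeed(17, {
        for (i in 1:6) {
            g <- scalarVolume(array(0, c(8, 8, 8)))
            s <- randomStreamlineSet(g, n = 3, npts = 5)
            tdi <- tractDensity(s, g)
            expect_equal(voxelData(tdi), oracleTDI(s, g),
                         info = paste("fixture", i))
        }
    })
})

test_that("tract mask marks exactly the non-zero density voxels", {
    counts <- array(0, c(3, 3, 3))
    counts[1, 1, 1] <- 1; counts[2, 2, 2] <- 7
    tdi <- scalarVolume(counts, units = "count")
    m <- tractMask(tdi)
    expect_equal(sort(unique(as.vector(voxelData(m)))), c(0, 1))
    expect_equal(sum(voxelData(m)), sum(counts > 0))
    expect_equal(sum(voxelData(tractMask(scalarVolume(array(0, c(3, 3, 3)))))),
                 0)
})

test_that("outlier filtering removes displaced streamlines, never the medoid", {
    parallel <- lapply(1:10, function(i)
        straightStreamline(c(i * 0.3, 0, 0), c(0, 0, 1), 10))
    displaced <- straightStreamline(c(50, 50, 0), c(0, 0, 1), 10)
    b <- streamlineSet(c(parallel, list(displaced)))
    f <- outlierFilter(b, zMax = 3)
    expect_equal(nStreamlines(f), 10L)
    expect_true(all(sapply(streamlines(f), function(m) max(m[, 1]) < 10)))
    # identical streamlines: nothing removed
    same <- streamlineSet(lapply(1:5, function(i)
        straightStreamline(c(1, 1, 0), c(0, 0, 1), 10)))
    expect_equal(nStreamlines(outlierFilter(same, 3)), 5L)
    # infinite threshold is the identity
    expect_equal(nStreamlines(outlierFilter(b, Inf)), 11L)
    expect_error(outlierFilter(streamlineSet(parallel[1:2]), 3), "at least 3")
})

test_that("selectBundle output satisfies the bundle invariants", {
    withSeed(5, {
        spec <- tinyPhantomSpec()
        thal <- thalamusMask(spec)
        surf <- surfaceMask(spec)
        roi <- manualROI(seedVoxel(spec, "upper", "right"), "upper", "right",
                         surf, 3)
        s <- generateBundle(spec, "upper", "right")
        g <- generateMetricVolume(spec, "TD", "MD", limbs = "upper")
        b <- selectBundle(s, thal, roi, g)
        expect_s4_class(b, "TractBundle")
        expect_gte(nStreamlines(b), 5L)
        roiKey <- apply(roiVoxels(roi), 1, paste, collapse = ",")
        tW <- which(voxelData(thal) != 0)
        for (m in streamlines(b)) {
            expect_true(all(m[, 1] > 0))                     # right hemisphere
            endVox <- round(worldToVoxel(g, m[nrow(m), ]))
            expect_true(paste(endVox, collapse = ",") %in% roiKey)
        }
        # provenance records every filter
        ops <- sapply(provenance(b), `[[`, "op")
        expect_true(all(c("orientBundle", "filterMidline", "filterToROI",
                          "enforceMinCount") %in% ops))
    })
})
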