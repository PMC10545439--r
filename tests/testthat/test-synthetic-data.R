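# The phantom generator: determinism, geometry, painted ground truth and
# cohort structure.

test_that("bundles are deterministic and collapse to the control arc at zero jitter", {
    spec <- tinyPhantomSpec(jitterSd = 0)
    withSeed(50, b1 <- generateBundle(spec, "upper", "left"))
    withSeed(50, b2 <- generateBundle(spec, "upper", "left"))
    expect_identical(streamlines(b1), streamlines(b2))
    # zero jitter: all streamlines identical
    for (m in streamlines(b1))
        expect_equal(m, streamlines(b1)[[1]])
    # left-hemisphere bundles stay strictly left of the midline
    expect_true(all(sapply(streamlines(b1), function(m) all(m[, 1] < 0))))
    spec2 <- tinyPhantomSpec()
    withSeed(51, b3 <- generateBundle(spec2, "upper", "right"))
    expect_true(all(sapply(streamlines(b3), function(m) all(m[, 1] > 0))))
})

test_that("generated bundles pass the selection filters with full retention", {
    spec <- tinyPhantomSpec()          # jitter 0.5 mm default
    withSeed(52, {
        thal <- thalamusMask(spec)
        surf <- surfaceMask(spec)
        for (hemi in c("left", "right")) {
            s <- generateBundle(spec, "upper", hemi)
            roi <- manualROI(seedVoxel(spec, "upper", hemi), "upper", hemi,
                             surf, 3)
            g <- generateMetricVolume(spec, "TD", "MD", limbs = "upper")
            b <- selectBundle(s, thal, roi, g, zMax = Inf)
            expect_s4_class(b, "TractBundle")
            expect_equal(nStreamlines(b), spec@nStreamlines)
        }
    })
})

test_that("metric volumes encode the painted group effects exactly at zero noise", {
    spec <- tinyPhantomSpec(noiseSd = 0, jitterSd = 0, subjectSd = 0)
    vHP <- generateMetricVolume(spec, "HP", "MD", dominantHemisphere = "left",
                                limbs = "upper")
    arcL <- limbtract:::.controlArc(spec, "upper", "left")
    arcR <- limbtract:::.controlArc(spec, "upper", "right")
    mid <- function(v, arc) sampleMetric(v, arc[round(nrow(arc) / 2), ])
    # non-dominant (right) painted MD exceeds dominant by exactly delta_HP
    expect_equal(mid(vHP, arcR) / mid(vHP, arcL) - 1, spec@mdDelta[["HP"]],
                 tolerance = 1e-9)
    # DP: bilateral increase
    vDP <- generateMetricVolume(spec, "DP", "MD", dominantHemisphere = "left",
                                limbs = "upper")
    expect_equal(mid(vDP, arcR) / spec@baseline[["MD"]] - 1,
                 spec@mdDelta[["DP"]], tolerance = 1e-9)
    expect_equal(mid(vDP, arcL), mid(vDP, arcR), tolerance = 1e-12)
    # TD: no offset anywhere
    vTD <- generateMetricVolume(spec, "TD", "MD", limbs = "upper")
    expect_equal(mid(vTD, arcL), spec@baseline[["MD"]], tolerance = 1e-9)
})

test_that("FA volumes are clipped to [0, 1] even under heavy noise", {
    spec <- tinyPhantomSpec(noiseSd = 2)
    withSeed(53, v <- generateMetricVolume(spec, "TD", "FA", limbs = "upper"))
    expect_gte(min(voxelData(v)), 0)
    expect_lte(max(voxelData(v)), 1)
})

test_that("activation maps lead the seeding rule back to the true seed", {
    spec <- tinyPhantomSpec()
    surf <- surfaceMask(spec)
    amap <- generateActivationMap(spec, "upper", "left")
    roi <- roiFromActivation(amap, "upper", "left", surf)
    expect_equal(roiOrigin(roi), seedVoxel(spec, "upper", "left"))
    # a lower-peaked decoy does not hijack the selection
    decoyCtr <- spec@seeds$upper$right    # far outside the 8 mm sphere
    amap2 <- generateActivationMap(spec, "upper", "left",
                                   decoy = list(center = decoyCtr, peak = 4))
    roi2 <- roiFromActivation(amap2, "upper", "left", surf)
    expect_equal(roiOrigin(roi2), seedVoxel(spec, "upper", "left"))
    # threshold above the peak: seeding error
    amap3 <- generateActivationMap(spec, "upper", "left", peak = 3,
                                   threshold = 10)
    expect_error(roiFromActivation(amap3, "upper", "left", surf),
                 "suprathreshold")
})

test_that("cohort tables are reproducible and respect the declared vocabularies", {
    spec <- tinyPhantomSpec()
    c1 <- generateCohort(spec, seed = 7)
    c2 <- generateCohort(spec, seed = 7)
    expect_identical(c1$subjects, c2$subjects)
    df <- c1$subjects
    expect_equal(nrow(df), sum(spec@nSubjects))
    expect_equal(unname(table(df$group)[c("TD", "HP", "DP")]),
                 unname(spec@nSubjects[c("TD", "HP", "DP")]),
                 ignore_attr = TRUE)
    expect_true(all(df$age >= spec@ageRange[1] & df$age <= spec@ageRange[2]))
    expect_true(all(df$dominance[df$group == "TD"] == "right"))
    expect_false(anyDuplicated(df$id) > 0)
    # subject data regenerate bit-identically from the stored seed
    d1 <- generateSubjectData(spec, df[3, ], metrics = "MD", limbs = "upper")
    d2 <- generateSubjectData(spec, df[3, ], metrics = "MD", limbs = "upper")
    expect_identical(voxelData(d1$volumes$MD), voxelData(d2$volumes$MD))
    expect_identical(streamlines(d1$bundles$upper$left),
                     streamlines(d2$bundles$upper$left))
})

test_that("zero missingness makes imputation a no-op on the cohort", {
    spec <- tinyPhantomSpec()
    spec@behavior$missingRate <- 0
    cohort <- generateCohort(spec, seed = 11)
    sv <- buildSumVariables(cohort$subjects, spec@behavior$defs)
    expect_true(all(sv$scores$hand_imputed == 0))
    expect_true(all(sv$scores$stability_imputed == 0))
    expect_equal(nrow(sv$imputationLog), 0L)
    expect_false(anyNA(sv$scores$hand))
})

test_that("simulated cohorts round-trip through the on-disk layout", {
    spec <- tinyPhantomSpec()
    dir <- tempfile("cohortdir")
    on.exit(unlink(dir, recursive = TRUE))
    # a 2/2/2 mini cohort keeps the file tree small
    spec@nSubjects[] <- c(2L, 2L, 2L)
    cohort <- simulateCohort(spec, dir, seed = 21, metrics = "MD",
                             limbs = "upper")
    expect_true(file.exists(file.path(dir, "cohort.csv")))
    expect_true(file.exists(file.path(dir, "thalamus.nii.gz")))
    loaded <- loadCohort(dir, spec)
    expect_equal(loaded$subjects$id, cohort$subjects$id)
    # per-subject files agree with in-memory regeneration
    row <- cohort$subjects[1, ]
    onDisk <- readStreamlines(file.path(dir, row$id, "upper_left.tck"))
    mem <- generateSubjectData(spec, row, metrics = "MD", limbs = "upper")
    err <- max(mapply(function(a, b) max(abs(a - b)),
                      streamlines(onDisk),
                      streamlines(mem$bundles$upper$left)))
    expect_lt(err, 1e-4)
    vol <- readVolume(file.path(dir, row$id, "md.nii.gz"))
    expect_equal(voxelData(vol), voxelData(mem$volumes$MD), tolerance = 1e-6)
})
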