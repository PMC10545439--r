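# NIfTI / TCK / TRK round trips and the voxel-world coordinate contract.

test_that("NIfTI volumes round-trip through write/read", {
    f <- tempfile(fileext = ".nii.gz")
    on.exit(unlink(f))

    v1 <- scalarVolume(array(1, c(3, 3, 3)))
    writeVolume(v1, f)
    r1 <- readVolume(f)
    expect_equal(voxelData(r1), array(1, c(3, 3, 3)))
    expect_equal(affine(r1), diag(4), tolerance = 1e-6)

    withSeed(11, {
        A <- diag(4); diag(A)[1:3] <- c(1, 1.5, 2); A[1:3, 4] <- c(-4, 3, 7)
        v2 <- scalarVolume(array(rnorm(60), c(3, 4, 5)), affine = A,
                           units = "mm^2/s")
        writeVolume(v2, f)
        r2 <- readVolume(f, units = "mm^2/s")
        expect_identical(voxelData(r2), voxelData(v2))
        expect_equal(affine(r2), A, tolerance = 1e-6)
        expect_identical(volumeUnits(r2), "mm^2/s")
    })
})

test_that("garbled or missing NIfTI input raises a format error naming the path", {
    f <- tempfile(fileext = ".nii")
    writeBin(as.raw(1:40), f)
    on.exit(unlink(f))
    suppressWarnings(expect_error(readVolume(f), basename(f), fixed = TRUE))
    expect_error(readVolume("/nonexistent/vol.nii"), "not found")
})

test_that("TCK files round-trip and record length correctly", {
    f <- tempfile(fileext = ".tck")
    on.exit(unlink(f))
    s1 <- streamlineSet(list(rbind(c(0, 0, 0), c(0, 0, 10))))
    writeStreamlines(s1, f)
    r1 <- readStreamlines(f)
    expect_equal(nStreamlines(r1), 1L)
    expect_equal(sum(sqrt(rowSums(diff(streamlines(r1)[[1]])^2))), 10)

    withSeed(42, {
        s2 <- streamlineSet(lapply(1:100, function(i)
            matrix(runif(3 * (2 + i %% 7), -50, 50), ncol = 3) +
                outer(seq_len(2 + i %% 7), c(0, 0, 2))))
        writeStreamlines(s2, f)
        r2 <- readStreamlines(f)
        expect_equal(nStreamlines(r2), 100L)
        err <- max(mapply(function(a, b) max(abs(a - b)),
                          streamlines(s2), streamlines(r2)))
        expect_lt(err, 1e-4)
    })
})

test_that("TRK files round-trip through the voxel-corner convention", {
    f <- tempfile(fileext = ".trk")
    on.exit(unlink(f))
    withSeed(7, {
        A <- diag(4); diag(A)[1:3] <- c(2, 1, 1.25); A[1:3, 4] <- c(-10, 4, 2)
        s <- randomStreamlineSet(scalarVolume(array(0, c(20, 20, 20)),
                                              affine = A), n = 20, npts = 9)
        writeStreamlines(s, f, affine = A)
        r <- readStreamlines(f)
        err <- max(mapply(function(a, b) max(abs(a - b)),
                          streamlines(s), streamlines(r)))
        expect_lt(err, 1e-4)
    })
})

test_that("TCK and TRK describe identical world geometry", {
    # cross-format check: the same streamlines written in both dialects
    # must read back to the same world coordinates
    ftck <- tempfile(fileext = ".tck")
    ftrk <- tempfile(fileext = ".trk")
    on.exit(unlink(c(ftck, ftrk)))
    withSeed(13, {
        A <- diag(4); diag(A)[1:3] <- c(1, 2, 0.5); A[1:3, 4] <- c(3, -7, 1)
        s <- randomStreamlineSet(scalarVolume(array(0, c(15, 15, 15)),
                                              affine = A), n = 10, npts = 6)
        writeStreamlines(s, ftck)
        writeStreamlines(s, ftrk, affine = A)
        rt <- readStreamlines(ftck)
        rk <- readStreamlines(ftrk)
        err <- max(mapply(function(a, b) max(abs(a - b)),
                          streamlines(rt), streamlines(rk)))
        expect_lt(err, 1e-3)
    })
})

test_that("malformed streamline files are rejected", {
    f <- tempfile(fileext = ".tck")
    on.exit(unlink(f))
    writeLines("not a tck", f)
    expect_error(readStreamlines(f), "bad magic|truncated")
    expect_error(readStreamlines("x.xyz"), "not found")
    f2 <- tempfile(fileext = ".xyz")
    file.create(f2)
    on.exit(unlink(f2), add = TRUE)
    expect_error(readStreamlines(f2), "unknown streamline format")
    # header/body count mismatch
    s <- streamlineSet(list(rbind(c(0, 0, 0), c(0, 0, 1))))
    writeStreamlines(s, f)
    txt <- readBin(f, "raw", file.size(f))
    txt[which(rawToChar(txt, multiple = TRUE) == "1")[1]] <- charToRaw("7")
    writeBin(txt, f)
    expect_error(readStreamlines(f), "does not match")
})

test_that("world/voxel transforms satisfy the inverse contract", {
    v <- scalarVolume(array(0, c(5, 5, 5)))
    expect_equal(worldToVoxel(v, c(1.5, 2, 0)), c(1.5, 2, 0))
    A <- diag(4); A[1, 4] <- 10
    vt <- scalarVolume(array(0, c(5, 5, 5)), affine = A)
    expect_equal(worldToVoxel(vt, c(10, 0, 0)), c(0, 0, 0))
    withSeed(3, {
        for (i in 1:20) {
            A <- diag(4)
            A[1:3, 1:3] <- matrix(rnorm(9), 3) + diag(3) * 3
            A[1:3, 4] <- rnorm(3, 0, 10)
            vr <- scalarVolume(array(0, c(4, 4, 4)), affine = A)
            p <- rnorm(3, 0, 20)
            expect_lt(max(abs(voxelToWorld(vr, worldToVoxel(vr, p)) - p)), 1e-9)
        }
    })
})

test_that("subject tables parse empty strings and NA as missing, and are validated", {
    f <- tempfile(fileext = ".csv")
    on.exit(unlink(f))
    writeLines(c("id,group,dominance,age,bbt",
                 "S1,TD,right,12.5,33",
                 "S2,HP,left,14.0,",
                 "S3,DP,right,11.2,NA"), f)
    df <- readSubjectTable(f)
    expect_identical(is.na(df$bbt), c(FALSE, TRUE, TRUE))
    writeLines(c("id,group,dominance,age", "S1,XX,right,12"), f)
    expect_error(readSubjectTable(f), "group")
    writeLines(c("id,group,dominance,age", "S1,TD,right,12", "S1,TD,left,13"), f)
    expect_error(readSubjectTable(f), "unique")
})

test_that("class validity catches malformed objects", {
    expect_error(scalarVolume(array(0, c(2, 2)), diag(4)), "3-D")
    expect_error(scalarVolume(array(0, c(2, 2, 2)), matrix(0, 4, 4)),
                 "invertible")
    expect_error(streamlineSet(list(matrix(0, 1, 3))), ">= 2 rows")
    expect_error(streamlineSet(list(rbind(c(0, 0, 0), c(0, 0, 0)))),
                 "distinct")
})
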