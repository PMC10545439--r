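# Filtering a streamline set down to a limb-specific thalamocortical bundle
# and deriving its density image and mask. The midline rule plus a
# geometric outlier filter stand in for surface-based sulcus-jump removal,
# which requires a cortical reconstruction; users with surfaces can
# substitute their own cleanup between the filters.

.logFilter <- function(b, op, before, after, extra = list()) {
    b@provenance <- c(b@provenance,
                      list(c(list(op = op, kept = after, removed = before - after),
                             extra)))
    b
}

.asBundle <- function(s, template = NULL) {
    if (is(s, "TractBundle")) return(s)
    if (!is.null(template))
        tractBundle(s, limb = template@limb, hemisphere = template@hemisphere,
                    seedROI = template@seedROI,
                    provenance = template@provenance, step = template@step)
    else tractBundle(s)
}

.keepStreamlines <- function(b, keep, op, extra = list()) {
    n0 <- length(b@streamlines)
    out <- b
    out@streamlines <- b@streamlines[keep]
    if (is(out, "TractBundle"))
        out <- .logFilter(out, op, n0, sum(keep), extra)
    out
}

#' Remove streamlines touching or crossing the mid-sagittal plane
#'
#' Retains exactly those streamlines whose x coordinates lie strictly on
#' one side of the plane \code{x = midlineX}; a point exactly on the plane
#' disqualifies the streamline (treated as touching both sides).
#'
#' @param s a [StreamlineSet-class] or [TractBundle-class].
#' @param midlineX world-mm x position of the mid-sagittal plane (default 0).
#' @return The filtered set, same class as the input.
#' @export
filterMidline <- function(s, midlineX = 0) {
    stopifnot(is(s, "StreamlineSet"))
    keep <- vapply(s@streamlines, function(m)
        all(m[, 1L] > midlineX) || all(m[, 1L] < midlineX), logical(1))
    .keepStreamlines(s, keep, "filterMidline", list(midlineX = midlineX))
}

#' Retain streamlines terminating in a dilated seed ROI
#'
#' A streamline joins the limb-specific bundle when its cortical terminal
#' point — the last point of the (thalamus-oriented) polyline — falls in a
#' voxel of the dilated seed ROI. Orient the bundle with [orientBundle()]
#' first so the last point is the cortex-side endpoint.
#'
#' @param s a [StreamlineSet-class] or [TractBundle-class], thalamus-oriented.
#' @param roi a [SeedROI-class].
#' @param grid the [ScalarVolume-class] whose voxel grid defines membership.
#' @return The filtered set, same class as the input.
#' @export
filterToROI <- function(s, roi, grid) {
    stopifnot(is(s, "StreamlineSet"), is(roi, "SeedROI"),
              is(grid, "ScalarVolume"))
    if (nrow(roi@voxels) == 0L) stop("seed ROI has no voxels")
    roiKey <- paste(roi@voxels[, 1L], roi@voxels[, 2L], roi@voxels[, 3L])
    keep <- vapply(s@streamlines, function(m) {
        end <- m[nrow(m), ]
        v <- round(worldToVoxel(grid, end))
        paste(v[1L], v[2L], v[3L]) %in% roiKey
    }, logical(1))
    out <- .keepStreamlines(s, keep, "filterToROI",
                            list(limb = roi@limb, hemisphere = roi@hemisphere))
    if (is(out, "TractBundle")) out@seedROI <- roi
    out
}

#' Orient every streamline thalamus-first
#'
#' Flips each streamline's point order if needed so that point 0 is the
#' endpoint nearer the thalamus mask (nearest thalamus-voxel distance).
#' Position 0 of along-tract profiles then sits on the thalamus surface.
#' Streamlines with equidistant endpoints keep their original order with a
#' warning.
#'
#' @param s a [StreamlineSet-class] or [TractBundle-class].
#' @param thalamus binary [ScalarVolume-class] thalamus mask (nonempty).
#' @return The oriented set, same class as the input.
#' @export
orientBundle <- function(s, thalamus) {
    stopifnot(is(s, "StreamlineSet"), is(thalamus, "ScalarVolume"))
    tIdx <- which(thalamus@data != 0)
    if (length(tIdx) == 0L) stop("thalamus mask is empty")
    tW <- .applyAffine(thalamus@affine, arrayInd(tIdx, dim(thalamus@data)) - 1L)
    ambiguous <- 0L
    out <- s
    out@streamlines <- lapply(s@streamlines, function(m) {
        ends <- m[c(1L, nrow(m)), , drop = FALSE]
        d <- .minDistToSet(ends, tW)
        if (d[2L] < d[1L]) m[nrow(m):1L, , drop = FALSE]
        else {
            if (d[2L] == d[1L]) ambiguous <<- ambiguous + 1L
            m
        }
    })
    if (ambiguous > 0L)
        warning(ambiguous, " streamline(s) had equidistant endpoints; ",
                "original order kept")
    if (is(out, "TractBundle"))
        out <- .logFilter(out, "orientBundle", length(s@streamlines),
                          length(s@streamlines),
                          list(ambiguous = ambiguous))
    out
}

#' Enforce the minimum streamline count for a usable tract
#'
#' Tracts supported by fewer than \code{minN} streamlines (default 5,
#' matching the "<5" exclusion rule) are replaced by a
#' [TractExclusion-class] marker; otherwise the bundle is returned
#' unchanged apart from a provenance note.
#'
#' @param b a [TractBundle-class].
#' @param minN minimum streamline count (a bundle with exactly \code{minN}
#'   passes).
#' @return \code{b}, or a [TractExclusion-class].
#' @export
enforceMinCount <- function(b, minN = 5) {
    stopifnot(is(b, "TractBundle"))
    n <- length(b@streamlines)
    if (n < minN)
        return(new("TractExclusion", limb = b@limb, hemisphere = b@hemisphere,
                   nStreamlines = n,
                   reason = sprintf("low (<%d) streamline count", minN)))
    .logFilter(b, "enforceMinCount", n, n, list(minN = minN))
}

#' Tract density image
#'
#' Counts, per voxel of the metric grid, the number of streamlines whose
#' polyline enters the voxel at least once (each streamline contributes at
#' most 1 per voxel). Traversal is determined by walking every segment at a
#' tenth of the smallest voxel spacing, endpoints included.
#'
#' @param b a nonempty [StreamlineSet-class] or [TractBundle-class].
#' @param grid the [ScalarVolume-class] defining the voxel grid.
#' @return A [ScalarVolume-class] of counts (units \code{"count"}).
#' @export
tractDensity <- function(b, grid) {
    stopifnot(is(b, "StreamlineSet"), is(grid, "ScalarVolume"))
    if (length(b@streamlines) == 0L) stop("cannot compute TDI of an empty bundle")
    dm <- dim(grid@data)
    step <- min(.voxelSpacing(grid@affine)) / 10
    counts <- array(0, dm)
    inv <- .affineInverse(grid@affine)
    for (m in b@streamlines) {
        pts <- .walkSegments(m, step)
        vox <- round(.applyAffine(inv, pts))
        vox <- vox[.insideGrid(vox, dm), , drop = FALSE]
        if (nrow(vox) == 0L) next
        lin <- unique(.linearIndex(vox, dm))
        counts[lin] <- counts[lin] + 1
    }
    scalarVolume(counts, affine = grid@affine, units = "count")
}

#' Binary tract mask from a tract density image
#'
#' Marks all non-zero voxels of the density image as 1.
#'
#' @param tdi a [ScalarVolume-class] of streamline counts.
#' @return A binary [ScalarVolume-class].
#' @export
tractMask <- function(tdi) {
    stopifnot(is(tdi, "ScalarVolume"))
    scalarVolume((tdi@data > 0) * 1, affine = tdi@affine, units = "")
}

#' Remove geometric outlier streamlines
#'
#' Scores each streamline by its mean closest-point distance to the
#' bundle's medoid streamline (the streamline minimizing the summed
#' symmetric mean closest-point distance to all others) and removes those
#' exceeding \code{zMax} robust z-scores (median/MAD). The medoid itself is
#' never removed. This geometric cleanup stands in for manual/visual
#' spurious-streamline removal.
#'
#' @param b a [StreamlineSet-class] or [TractBundle-class] with >= 3
#'   streamlines.
#' @param zMax robust z-score threshold (default 3; \code{Inf} keeps all).
#' @return The filtered set, same class as the input.
#' @export
outlierFilter <- function(b, zMax = 3) {
    stopifnot(is(b, "StreamlineSet"))
    n <- length(b@streamlines)
    if (n < 3L) stop("outlier filtering needs at least 3 streamlines")
    sl <- b@streamlines
    npts <- vapply(sl, nrow, integer(1))
    D <- matrix(0, n, n)
    if (sum(npts) <= 4000L) {
        # one pooled squared-distance matrix, then slice per pair
        pts <- do.call(rbind, sl)
        sq <- rowSums(pts^2)
        d2 <- outer(sq, sq, "+") - 2 * tcrossprod(pts)
        ends <- cumsum(npts)
        starts <- ends - npts + 1L
        mc <- function(i, j) {
            sub <- d2[starts[i]:ends[i], starts[j]:ends[j], drop = FALSE]
            best <- max.col(-sub, ties.method = "first")
            mean(sqrt(pmax(0, sub[cbind(seq_len(nrow(sub)), best)])))
        }
        for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
            d <- (mc(i, j) + mc(j, i)) / 2
            D[i, j] <- d; D[j, i] <- d
        }
        medoid <- which.min(rowSums(D))
        d <- vapply(seq_len(n), function(i) mc(i, medoid), numeric(1))
    } else {
        for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
            d <- (.meanClosestDist(sl[[i]], sl[[j]]) +
                  .meanClosestDist(sl[[j]], sl[[i]])) / 2
            D[i, j] <- d; D[j, i] <- d
        }
        medoid <- which.min(rowSums(D))
        d <- vapply(sl, function(m) .meanClosestDist(m, sl[[medoid]]),
                    numeric(1))
    }
    med <- stats::median(d)
    scale <- stats::mad(d)
    if (scale < 1e-12) scale <- mean(abs(d - med))
    z <- if (scale < 1e-12) rep(0, n) else (d - med) / scale
    keep <- z <= zMax
    keep[medoid] <- TRUE
    .keepStreamlines(b, keep, "outlierFilter", list(zMax = zMax))
}

#' Run the full bundle-selection chain
#'
#' Orientation, midline filtering, terminal-point ROI filtering, geometric
#' outlier removal and the minimum-count rule, in that order, with every
#' decision recorded in the bundle's provenance.
#'
#' @param s a [StreamlineSet-class] of candidate thalamocortical streamlines.
#' @param thalamus binary thalamus mask [ScalarVolume-class].
#' @param roi the limb-specific [SeedROI-class].
#' @param grid metric-grid [ScalarVolume-class].
#' @param midlineX mid-sagittal plane position (world mm).
#' @param zMax outlier threshold ([outlierFilter()]); \code{Inf} disables.
#' @param minN minimum streamline count.
#' @return A [TractBundle-class] or [TractExclusion-class].
#' @export
selectBundle <- function(s, thalamus, roi, grid, midlineX = 0, zMax = 3,
                         minN = 5) {
    b <- tractBundle(s, limb = roi@limb, hemisphere = roi@hemisphere)
    b <- orientBundle(b, thalamus)
    b <- filterMidline(b, midlineX)
    if (length(b@streamlines) == 0L)
        return(new("TractExclusion", limb = roi@limb,
                   hemisphere = roi@hemisphere, nStreamlines = 0L,
                   reason = "no streamlines on one side of the midline"))
    b <- filterToROI(b, roi, grid)
    if (length(b@streamlines) >= 3L && is.finite(zMax))
        b <- outlierFilter(b, zMax)
    enforceMinCount(b, minN)
}
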