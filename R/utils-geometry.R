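# Shared geometry primitives. The coordinate contract: voxel indices are
# 0-based with the voxel center at the integer index; the affine maps those
# indices to world mm (RAS). Only world coordinates cross module boundaries.

.applyAffine <- function(A, pts) {
    pts <- if (is.matrix(pts)) pts else matrix(pts, ncol = 3L)
    out <- pts %*% t(A[1:3, 1:3, drop = FALSE])
    sweep(out, 2L, A[1:3, 4L], "+")
}

.affineInverse <- function(A) solve(A)

.voxelSpacing <- function(A) sqrt(colSums(A[1:3, 1:3, drop = FALSE]^2))

# world coords of voxel centers for an n x 3 matrix of 0-based indices
.voxelCenters <- function(vol, idx) .applyAffine(vol@affine, idx)

.polylineLength <- function(m) {
    sum(sqrt(rowSums((m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2)))
}

# cumulative arc length, starting at 0
.cumArc <- function(m) {
    c(0, cumsum(sqrt(rowSums((m[-1L, , drop = FALSE] -
                              m[-nrow(m), , drop = FALSE])^2))))
}

# linearly interpolate a polyline at arc-length positions s (clamped to range)
.interpPolyline <- function(m, s) {
    arc <- .cumArc(m)
    s <- pmin(pmax(s, 0), arc[length(arc)])
    cbind(stats::approx(arc, m[, 1L], xout = s, ties = "ordered")$y,
          stats::approx(arc, m[, 2L], xout = s, ties = "ordered")$y,
          stats::approx(arc, m[, 3L], xout = s, ties = "ordered")$y)
}

# resample a polyline at a fixed spatial step for voxel-visitation purposes
.densifyPolyline <- function(m, step) {
    L <- .polylineLength(m)
    s <- seq(0, L, by = step)
    if (s[length(s)] < L) s <- c(s, L)
    .interpPolyline(m, s)
}

# walk every segment at a fixed step (restarting at each vertex) and
# include both segment endpoints; used for voxel-visitation counting
.walkSegments <- function(m, step) {
    out <- vector("list", nrow(m) - 1L)
    for (i in seq_len(nrow(m) - 1L)) {
        a <- m[i, ]; b <- m[i + 1L, ]
        L <- sqrt(sum((b - a)^2))
        s <- seq(0, L, by = step)
        if (s[length(s)] < L) s <- c(s, L)
        out[[i]] <- matrix(a, length(s), 3L, byrow = TRUE) +
            outer(s / L, b - a)
    }
    do.call(rbind, out)
}

# 1-based linear array index from an n x 3 matrix of 0-based voxel indices
.linearIndex <- function(idx, dm) {
    1L + idx[, 1L] + dm[1L] * (idx[, 2L] + dm[2L] * idx[, 3L])
}

.insideGrid <- function(idx, dm) {
    idx[, 1L] >= 0L & idx[, 1L] < dm[1L] &
    idx[, 2L] >= 0L & idx[, 2L] < dm[2L] &
    idx[, 3L] >= 0L & idx[, 3L] < dm[3L]
}

# minimum distance from each point in pts to the point set ref (both n x 3)
.minDistToSet <- function(pts, ref) {
    # split to cap memory for large reference sets
    n <- nrow(pts)
    out <- numeric(n)
    block <- max(1L, floor(2e6 / max(1L, nrow(ref))))
    refSq <- rowSums(ref^2)
    for (i0 in seq(1L, n, by = block)) {
        i1 <- min(n, i0 + block - 1L)
        p <- pts[i0:i1, , drop = FALSE]
        d2 <- outer(rowSums(p^2), refSq, "+") - 2 * (p %*% t(ref))
        best <- max.col(-d2, ties.method = "first")
        out[i0:i1] <- sqrt(pmax(0, d2[cbind(seq_len(nrow(d2)), best)]))
    }
    out
}

# mean over points of a's minimum distance to points of b
.meanClosestDist <- function(a, b) mean(.minDistToSet(a, b))
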