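# Sampling scalar metric maps along streamlines, whole-tract summaries and
# the hemispheric Asymmetry Index.

#' Trilinearly sample a scalar volume at world-mm points
#'
#' Interpolates the 8 surrounding voxel values at the continuous voxel
#' coordinate of each point. A point at a voxel center returns that voxel's
#' value exactly, and affine-linear fields are reproduced exactly in the
#' grid interior.
#'
#' @param v a [ScalarVolume-class].
#' @param p world-mm point (length-3 vector) or n x 3 matrix.
#' @return Sampled value(s); error if any point falls outside the grid.
#' @export
sampleMetric <- function(v, p) {
    stopifnot(is(v, "ScalarVolume"))
    pm <- if (is.matrix(p)) p else matrix(p, ncol = 3L)
    vox <- .applyAffine(.affineInverse(v@affine), pm)
    dm <- dim(v@data)
    eps <- 1e-9
    bad <- vox[, 1L] < -eps | vox[, 1L] > dm[1L] - 1L + eps |
           vox[, 2L] < -eps | vox[, 2L] > dm[2L] - 1L + eps |
           vox[, 3L] < -eps | vox[, 3L] > dm[3L] - 1L + eps
    if (any(bad))
        stop("out-of-field sample: ", sum(bad), " point(s) fall outside the grid")
    vox <- pmin(pmax(vox, 0), matrix(dm - 1L, nrow(vox), 3L, byrow = TRUE))
    i0 <- floor(vox)
    w <- vox - i0
    i1 <- pmin(i0 + 1, matrix(dm - 1L, nrow(vox), 3L, byrow = TRUE))
    gather <- function(ix, iy, iz)
        v@data[1L + ix + dm[1L] * (iy + dm[2L] * iz)]
    val <-
        gather(i0[,1], i0[,2], i0[,3]) * (1-w[,1]) * (1-w[,2]) * (1-w[,3]) +
        gather(i1[,1], i0[,2], i0[,3]) *    w[,1]  * (1-w[,2]) * (1-w[,3]) +
        gather(i0[,1], i1[,2], i0[,3]) * (1-w[,1]) *    w[,2]  * (1-w[,3]) +
        gather(i0[,1], i0[,2], i1[,3]) * (1-w[,1]) * (1-w[,2]) *    w[,3]  +
        gather(i1[,1], i1[,2], i0[,3]) *    w[,1]  *    w[,2]  * (1-w[,3]) +
        gather(i1[,1], i0[,2], i1[,3]) *    w[,1]  * (1-w[,2]) *    w[,3]  +
        gather(i0[,1], i1[,2], i1[,3]) * (1-w[,1]) *    w[,2]  *    w[,3]  +
        gather(i1[,1], i1[,2], i1[,3]) *    w[,1]  *    w[,2]  *    w[,3]
    if (is.matrix(p)) val else drop(val)
}

#' Whole-tract mean of a metric over a bundle
#'
#' In \code{"streamline"} mode (the default, matching averaging over all
#' streamlines) the value is the mean over streamlines of each streamline's
#' mean sampled value, so every streamline carries equal weight; resample
#' the bundle uniformly first ([resampleUniform()]) so points along each
#' streamline are equally spaced. In \code{"mask"} mode the value is the
#' mean of the voxel values inside the bundle's tract mask.
#'
#' @param b a [TractBundle-class] (or [StreamlineSet-class]).
#' @param v the metric [ScalarVolume-class].
#' @param mode \code{"streamline"} or \code{"mask"}.
#' @return The summary value (a length-1 numeric with \code{"mode"} and
#'   \code{"units"} attributes).
#' @export
bundleMean <- function(b, v, mode = c("streamline", "mask")) {
    mode <- match.arg(mode)
    stopifnot(is(b, "StreamlineSet"), is(v, "ScalarVolume"))
    if (length(b@streamlines) == 0L) stop("empty bundle")
    if (mode == "streamline") {
        perStreamline <- vapply(b@streamlines,
                                function(m) mean(sampleMetric(v, m)),
                                numeric(1))
        out <- mean(perStreamline)
    } else {
        mask <- tractMask(tractDensity(b, v))
        out <- mean(v@data[mask@data > 0])
    }
    structure(out, mode = mode, units = v@units)
}

#' Hemispheric Asymmetry Index
#'
#' AI = 100 * (nd - d) / ((nd + d) / 2): the percent difference between the
#' non-dominant and dominant tract values normalized by their mean.
#' Positive values mean the non-dominant tract value is larger. For
#' positive inputs the index is bounded by +/-200 (attained only when one
#' input is 0). A zero-valued pair is an error rather than 0, so degenerate
#' bundles are not silently masked.
#'
#' @param nd non-dominant tract value(s).
#' @param d dominant tract value(s).
#' @return AI in percent (vectorized).
#' @examples
#' asymmetryIndex(1.1, 0.9)  # +20
#' @export
asymmetryIndex <- function(nd, d) {
    s <- nd + d
    if (any(s == 0))
        stop("asymmetry index undefined: non-dominant + dominant value is 0")
    100 * (nd - d) / (s / 2)
}

#' Absolute asymmetry index
#'
#' Correlation analyses use the magnitude of the asymmetry, discarding its
#' direction.
#'
#' @param ai asymmetry index value(s) in percent.
#' @return \code{abs(ai)}.
#' @export
absAI <- function(ai) abs(ai)
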