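#' @import methods
NULL

#' ScalarVolume: a 3-D scalar grid with a voxel-to-world affine
#'
#' Container for any scalar map the pipeline touches: diffusion metrics
#' (MD in mm^2/s, FA and AFD unitless), binary masks, activation statistic
#' maps, and tract density images. The affine maps 0-based voxel indices to
#' world millimetres (RAS); a voxel's center sits at an integer index.
#'
#' @slot data 3-D numeric array of voxel values.
#' @slot affine 4x4 matrix mapping 0-based voxel index (homogeneous) to
#'   world mm.
#' @slot units free-text unit tag, e.g. \code{"mm^2/s"} for MD, \code{""}
#'   for FA/AFD, \code{"count"} for tract density images.
#'
#' @seealso [scalarVolume()], [readVolume()], [worldToVoxel()]
#' @export
setClass("ScalarVolume",
         representation(data = "array", affine = "matrix", units = "character"))

setValidity("ScalarVolume", function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 3L)
        msg <- c(msg, "data must be a 3-D array")
    if (any(dim(object@data) < 1L))
        msg <- c(msg, "every data dimension must be >= 1")
    if (!identical(dim(object@affine), c(4L, 4L)))
        msg <- c(msg, "affine must be a 4x4 matrix")
    else {
        d <- try(det(object@affine), silent = TRUE)
        if (inherits(d, "try-error") || !is.finite(d) || abs(d) < 1e-12)
            msg <- c(msg, "affine must be invertible")
    }
    if (length(object@units) != 1L)
        msg <- c(msg, "units must be a single string")
    if (is.null(msg)) TRUE else msg
})

#' Construct a ScalarVolume
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices, world mm).
#' @param units unit tag (default empty).
#' @return A [ScalarVolume-class] object.
#' @examples
#' v <- scalarVolume(array(0, c(4, 4, 4)), diag(4))
#' dim(voxelData(v))
#' @export
scalarVolume <- function(data, affine = diag(4), units = "") {
    storage.mode(data) <- "double"
    new("ScalarVolume", data = data,
        affine = structure(as.numeric(affine), dim = c(4L, 4L)),
        units = as.character(units))
}

#' StreamlineSet: ordered 3-D polylines in world millimetres
#'
#' Each streamline is an n x 3 matrix of world-mm points (n >= 2, no
#' zero-length steps). All modules exchange world coordinates; voxel indices
#' never cross a module boundary.
#'
#' @slot streamlines list of numeric matrices, one polyline each.
#' @slot space world coordinate frame identifier (default \code{"RAS"}).
#' @seealso [streamlineSet()], [readStreamlines()]
#' @export
setClass("StreamlineSet",
         representation(streamlines = "list", space = "character"))

.validPolyline <- function(m) {
    if (!is.matrix(m) || ncol(m) != 3L || nrow(m) < 2L || !is.numeric(m))
        return("each streamline must be a numeric matrix with 3 columns and >= 2 rows")
    if (any(!is.finite(m)))
        return("streamline points must be finite")
    step <- sqrt(rowSums((m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))
    if (any(step <= 0))
        return("consecutive streamline points must be distinct")
    TRUE
}

setValidity("StreamlineSet", function(object) {
    for (m in object@streamlines) {
        v <- .validPolyline(m)
        if (!isTRUE(v)) return(v)
    }
    if (length(object@space) != 1L) return("space must be a single string")
    TRUE
})

#' Construct a StreamlineSet
#'
#' @param streamlines list of n x 3 numeric matrices (world mm).
#' @param space coordinate frame tag.
#' @return A [StreamlineSet-class] object.
#' @examples
#' s <- streamlineSet(list(cbind(0, 0, c(0, 5, 10))))
#' nStreamlines(s)
#' @export
streamlineSet <- function(streamlines, space = "RAS") {
    streamlines <- lapply(streamlines, function(m) {
        m <- as.matrix(m); storage.mode(m) <- "double"; dimnames(m) <- NULL; m
    })
    new("StreamlineSet", streamlines = streamlines, space = space)
}

#' SeedROI: a single cortical seed voxel plus its spherical dilation
#'
#' The seed is a single 1 mm^3 voxel on the white-matter surface (placed
#' manually or derived from an activation map); for streamline filtering it
#' is dilated with a spherical kernel (3 mm by default) to absorb
#' registration error.
#'
#' @slot limb \code{"upper"} or \code{"lower"}.
#' @slot hemisphere \code{"left"} or \code{"right"}.
#' @slot origin 0-based voxel index triple of the seed voxel.
#' @slot dilationRadius dilation radius in mm.
#' @slot voxels integer matrix (n x 3) of 0-based voxel indices: origin plus
#'   all voxels whose centers lie within \code{dilationRadius}.
#' @seealso [manualROI()], [roiFromActivation()], [dilateROI()]
#' @export
setClass("SeedROI",
         representation(limb = "character", hemisphere = "character",
                        origin = "integer", dilationRadius = "numeric",
                        voxels = "matrix"))

setValidity("SeedROI", function(object) {
    msg <- NULL
    if (!object@limb %in% c("upper", "lower"))
        msg <- c(msg, "limb must be 'upper' or 'lower'")
    if (!object@hemisphere %in% c("left", "right"))
        msg <- c(msg, "hemisphere must be 'left' or 'right'")
    if (length(object@origin) != 3L)
        msg <- c(msg, "origin must be an index triple")
    if (ncol(object@voxels) != 3L || nrow(object@voxels) < 1L)
        msg <- c(msg, "voxels must be an n x 3 index matrix")
    else if (!any(apply(object@voxels, 1L, function(v) all(v == object@origin))))
        msg <- c(msg, "origin must be contained in voxels")
    if (object@dilationRadius < 0)
        msg <- c(msg, "dilationRadius must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' ActivationMap: a statistic volume with a cutoff
#'
#' Wraps a contrast-statistic map (e.g. a GLM t-map following proprioceptive
#' limb stimulation) and the threshold above which activation is considered
#' visible. Used to derive seed ROIs via the 8 mm sphere / center-of-mass
#' rule.
#'
#' @slot stat [ScalarVolume-class] of statistic values.
#' @slot threshold finite statistic cutoff (inclusive).
#' @seealso [roiFromActivation()], [generateActivationMap()]
#' @export
setClass("ActivationMap",
         representation(stat = "ScalarVolume", threshold = "numeric"))

setValidity("ActivationMap", function(object) {
    if (length(object@threshold) != 1L || !is.finite(object@threshold))
        return("threshold must be a single finite number")
    TRUE
})

#' @rdname ActivationMap-class
#' @param stat a [ScalarVolume-class] of statistic values.
#' @param threshold inclusive statistic cutoff.
#' @export
activationMap <- function(stat, threshold) {
    new("ActivationMap", stat = stat, threshold = as.numeric(threshold))
}

#' TractBundle: a filtered, thalamus-oriented limb-specific streamline bundle
#'
#' A [StreamlineSet-class] whose streamlines run thalamus-to-cortex, carry a
#' limb and hemisphere label and the seed ROI they were filtered against,
#' plus a provenance log of every filter applied. The uniform resampling
#' step (mm) is recorded once [resampleUniform()] has been applied.
#'
#' @slot limb,hemisphere labels as in [SeedROI-class].
#' @slot seedROI the [SeedROI-class] used for filtering, or \code{NULL}.
#' @slot provenance list of filter-log entries.
#' @slot step uniform arc-length step in mm (\code{NA} before resampling).
#' @seealso [filterMidline()], [filterToROI()], [orientBundle()],
#'   [enforceMinCount()]
#' @export
setClass("TractBundle", contains = "StreamlineSet",
         representation(limb = "character", hemisphere = "character",
                        seedROI = "ANY", provenance = "list", step = "numeric"))

#' Construct a TractBundle
#'
#' @param streamlines a [StreamlineSet-class] or list of polyline matrices.
#' @param limb,hemisphere bundle labels.
#' @param seedROI optional [SeedROI-class].
#' @param provenance list of log entries.
#' @param step resampling step mm, \code{NA} if not uniformly resampled.
#' @return A [TractBundle-class].
#' @export
tractBundle <- function(streamlines, limb = "upper", hemisphere = "left",
                        seedROI = NULL, provenance = list(), step = NA_real_) {
    if (is(streamlines, "StreamlineSet")) {
        sl <- streamlines@streamlines
        sp <- streamlines@space
    } else {
        ss <- streamlineSet(streamlines)
        sl <- ss@streamlines
        sp <- ss@space
    }
    new("TractBundle", streamlines = sl, space = sp, limb = limb,
        hemisphere = hemisphere, seedROI = seedROI,
        provenance = provenance, step = as.numeric(step))
}

#' TractExclusion: marker for a bundle excluded by a selection rule
#'
#' Returned by [enforceMinCount()] in place of a bundle that has fewer than
#' the minimum number of streamlines (the analysis excludes tracts with
#' fewer than 5).
#'
#' @slot limb,hemisphere labels of the excluded tract.
#' @slot nStreamlines streamline count at exclusion time.
#' @slot reason human-readable exclusion reason.
#' @seealso [enforceMinCount()], [isExcluded()]
#' @export
setClass("TractExclusion",
         representation(limb = "character", hemisphere = "character",
                        nStreamlines = "integer", reason = "character"))

#' Is this object an exclusion marker?
#' @param x any object.
#' @return \code{TRUE} for a [TractExclusion-class].
#' @export
isExcluded <- function(x) is(x, "TractExclusion")

#' TractProfile: per-position median metric values along a bundle
#'
#' Holds the along-tract profile: at each arc-length position from the
#' thalamus surface (position 0) toward the cortex, the median of the
#' sampled metric over all streamlines still reaching that distance, plus
#' the number of contributing streamlines. Positions are retained only while
#' at least \code{minSupport} (default 5) streamlines contribute, so support
#' is non-increasing.
#'
#' @slot positions strictly increasing arc-length positions in mm
#'   (constant step), position 0 at the thalamus surface.
#' @slot values median metric value per position.
#' @slot support number of streamlines contributing per position.
#' @slot metric metric name (\code{"MD"}, \code{"FA"}, \code{"AFD"}, ...).
#' @seealso [profileMedian()], [smoothProfile()], [pointwiseHTest()]
#' @export
setClass("TractProfile",
         representation(positions = "numeric", values = "numeric",
                        support = "integer", metric = "character"))

setValidity("TractProfile", function(object) {
    n <- length(object@positions)
    msg <- NULL
    if (length(object@values) != n || length(object@support) != n)
        msg <- c(msg, "positions, values and support must have equal length")
    if (n > 1L) {
        st <- diff(object@positions)
        if (any(st <= 0))
            msg <- c(msg, "positions must be strictly increasing")
        else if (max(st) - min(st) > 1e-6 * max(st))
            msg <- c(msg, "positions must have a constant step")
        if (any(diff(object@support) > 0L))
            msg <- c(msg, "support must be non-increasing along the tract")
    }
    if (is.null(msg)) TRUE else msg
})

## ---- accessors -------------------------------------------------------------

#' @describeIn ScalarVolume-class voxel data array.
#' @param x object.
#' @export
voxelData <- function(x) x@data

#' @describeIn ScalarVolume-class 4x4 voxel-to-world affine.
#' @export
affine <- function(x) x@affine

#' @describeIn ScalarVolume-class unit tag.
#' @export
volumeUnits <- function(x) x@units

#' @describeIn StreamlineSet-class list of polyline matrices (world mm).
#' @export
streamlines <- function(x) x@streamlines

#' @describeIn StreamlineSet-class number of streamlines.
#' @export
nStreamlines <- function(x) length(x@streamlines)

#' @describeIn TractProfile-class arc-length positions (mm).
#' @export
profilePositions <- function(x) x@positions

#' @describeIn TractProfile-class median values per position.
#' @export
profileValues <- function(x) x@values

#' @describeIn TractProfile-class streamline support per position.
#' @export
profileSupport <- function(x) x@support

#' @describeIn SeedROI-class the dilated voxel set (0-based indices).
#' @export
roiVoxels <- function(x) x@voxels

#' @describeIn SeedROI-class the seed voxel index (0-based).
#' @export
roiOrigin <- function(x) x@origin

#' @describeIn TractBundle-class provenance log of filter decisions.
#' @export
provenance <- function(x) x@provenance

## ---- show methods ----------------------------------------------------------

setMethod("show", "ScalarVolume", function(object) {
    d <- dim(object@data)
    sp <- sqrt(colSums(object@affine[1:3, 1:3, drop = FALSE]^2))
    cat(sprintf("ScalarVolume %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm%s\n",
                d[1], d[2], d[3], sp[1], sp[2], sp[3],
                if (nzchar(object@units)) paste0(", units ", object@units) else ""))
    r <- range(object@data, na.rm = TRUE)
    cat(sprintf("  value range [%.4g, %.4g]\n", r[1], r[2]))
})

setMethod("show", "StreamlineSet", function(object) {
    n <- length(object@streamlines)
    cat(sprintf("StreamlineSet with %d streamline%s (space %s)\n",
                n, if (n == 1L) "" else "s", object@space))
    if (n > 0L) {
        len <- vapply(object@streamlines, .polylineLength, numeric(1))
        cat(sprintf("  length %.1f-%.1f mm (median %.1f)\n",
                    min(len), max(len), stats::median(len)))
    }
})

setMethod("show", "TractBundle", function(object) {
    cat(sprintf("TractBundle: %s limb, %s hemisphere, %d streamlines%s\n",
                object@limb, object@hemisphere, length(object@streamlines),
                if (is.finite(object@step))
                    sprintf(", resampled at %.2g mm", object@step) else ""))
    if (length(object@provenance))
        cat("  filters applied:",
            paste(vapply(object@provenance, function(p) p$op, character(1)),
                  collapse = ", "), "\n")
})

setMethod("show", "SeedROI", function(object) {
    cat(sprintf("SeedROI: %s limb, %s hemisphere, origin (%d,%d,%d), %d voxels (r = %.3g mm)\n",
                object@limb, object@hemisphere, object@origin[1],
                object@origin[2], object@origin[3], nrow(object@voxels),
                object@dilationRadius))
})

setMethod("show", "TractProfile", function(object) {
    n <- length(object@positions)
    cat(sprintf("TractProfile (%s): %d positions", object@metric, n))
    if (n > 0L)
        cat(sprintf(", 0-%.1f mm, support %d-%d",
                    max(object@positions), min(object@support),
                    max(object@support)))
    cat("\n")
})

setMethod("show", "TractExclusion", function(object) {
    cat(sprintf("TractExclusion: %s limb, %s hemisphere, n = %d (%s)\n",
                object@limb, object@hemisphere, object@nStreamlines,
                object@reason))
})
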