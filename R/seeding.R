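# Limb-specific cortical seed ROIs: a single 1 mm^3 voxel on the
# white-matter surface, placed manually or derived from an activation
# statistic map, then dilated with a spherical kernel for streamline
# filtering.

#' Spherical dilation of a voxel on a grid
#'
#' Returns every voxel whose center lies within \code{radius} world mm
#' (closed ball, so radius 0 returns the origin alone) of the origin
#' voxel's center, clipped to the grid. On a 1 mm isotropic grid a 3 mm
#' kernel gives 123 voxels and a 1 mm kernel 7 (origin plus face
#' neighbors).
#'
#' @param origin 0-based voxel index triple, inside the grid.
#' @param radius dilation radius in mm, >= 0.
#' @param grid a [ScalarVolume-class] supplying dimensions and affine.
#' @return Integer matrix (n x 3) of 0-based voxel indices.
#' @examples
#' g <- scalarVolume(array(0, c(11, 11, 11)))
#' nrow(dilateROI(c(5, 5, 5), 3, g))  # 123
#' @export
dilateROI <- function(origin, radius, grid) {
    stopifnot(is(grid, "ScalarVolume"), radius >= 0)
    origin <- as.integer(round(origin))
    dm <- dim(grid@data)
    if (any(origin < 0L) || any(origin >= dm))
        stop("ROI origin (", paste(origin, collapse = ","),
             ") lies outside the grid")
    sp <- .voxelSpacing(grid@affine)
    reach <- pmin(ceiling(radius / sp), dm - 1L)
    off <- as.matrix(expand.grid(-reach[1L]:reach[1L],
                                 -reach[2L]:reach[2L],
                                 -reach[3L]:reach[3L]))
    cand <- sweep(off, 2L, origin, "+")
    keep <- .insideGrid(cand, dm)
    cand <- cand[keep, , drop = FALSE]
    d <- .applyAffine(grid@affine, cand) -
        matrix(.applyAffine(grid@affine, matrix(origin, 1L)),
               nrow(cand), 3L, byrow = TRUE)
    cand <- cand[sqrt(rowSums(d^2)) <= radius + 1e-9, , drop = FALSE]
    storage.mode(cand) <- "integer"
    dimnames(cand) <- NULL
    cand
}

#' Place a manual seed ROI on the white-matter surface
#'
#' Mirrors manual seed placement on the post-central sulcus white-matter
#' surface: the origin must lie on the supplied surface mask (placement
#' fails over lesions where no surface voxel is available), and the ROI is
#' dilated with a spherical kernel (3 mm by default) to absorb registration
#' error.
#'
#' @param origin 0-based voxel index triple on the surface mask.
#' @param limb \code{"upper"} or \code{"lower"}.
#' @param hemisphere \code{"left"} or \code{"right"}.
#' @param surface binary [ScalarVolume-class] white-matter surface mask.
#' @param radius dilation radius in mm (default 3).
#' @return A [SeedROI-class].
#' @export
manualROI <- function(origin, limb, hemisphere, surface, radius = 3) {
    stopifnot(is(surface, "ScalarVolume"))
    origin <- as.integer(round(origin))
    dm <- dim(surface@data)
    if (any(origin < 0L) || any(origin >= dm))
        stop("seed placement error: origin outside the grid")
    if (surface@data[origin[1L] + 1L, origin[2L] + 1L, origin[3L] + 1L] == 0)
        stop("seed placement error: origin (", paste(origin, collapse = ","),
             ") is not on the white-matter surface mask")
    new("SeedROI", limb = limb, hemisphere = hemisphere, origin = origin,
        dilationRadius = as.numeric(radius),
        voxels = dilateROI(origin, radius, surface))
}

#' Derive a seed ROI from an activation statistic map
#'
#' Implements the activation-seeding rule: (1) locate the suprathreshold
#' global maximum, (2) restrict suprathreshold voxels to those within
#' \code{sphereRadius} (default 8 mm) of it, (3) take the statistic-weighted
#' center of mass of that set, (4) project it to the nearest white-matter
#' surface voxel (ties broken by lowest index triple). The resulting single
#' voxel becomes the ROI origin and is dilated as in [manualROI()].
#'
#' @param map an [ActivationMap-class].
#' @param limb,hemisphere ROI labels.
#' @param surface binary [ScalarVolume-class] surface mask (same grid as the
#'   statistic map).
#' @param sphereRadius restriction sphere radius in mm (default 8).
#' @param radius dilation radius in mm (default 3).
#' @return A [SeedROI-class].
#' @export
roiFromActivation <- function(map, limb, hemisphere, surface,
                              sphereRadius = 8, radius = 3) {
    stopifnot(is(map, "ActivationMap"), is(surface, "ScalarVolume"),
              sphereRadius > 0)
    stat <- map@stat@data
    dm <- dim(stat)
    supra <- which(stat >= map@threshold)
    if (length(supra) == 0L)
        stop("no suprathreshold voxels at threshold ", map@threshold)
    surfIdx <- which(surface@data != 0)
    if (length(surfIdx) == 0L)
        stop("white-matter surface mask is empty")
    idx <- arrayInd(supra, dm) - 1L                        # 0-based triples
    vals <- stat[supra]
    # (1) global suprathreshold maximum; arrayInd order breaks exact ties
    # deterministically by lowest linear (hence lowest index triple) index
    peak <- idx[which.max(vals), ]
    # (2) restrict to the sphere around the peak (closed ball, world mm)
    world <- .applyAffine(map@stat@affine, idx)
    peakW <- drop(.applyAffine(map@stat@affine, matrix(peak, 1L)))
    d <- sqrt(rowSums(sweep(world, 2L, peakW, "-")^2))
    inSphere <- d <= sphereRadius + 1e-9
    # (3) statistic-weighted center of mass (world mm)
    w <- vals[inSphere]
    com <- colSums(world[inSphere, , drop = FALSE] * w) / sum(w)
    # (4) nearest surface voxel, ties by lowest index triple
    sIdx <- arrayInd(surfIdx, dim(surface@data)) - 1L
    ord <- order(sIdx[, 1L], sIdx[, 2L], sIdx[, 3L])
    sIdx <- sIdx[ord, , drop = FALSE]
    sW <- .applyAffine(surface@affine, sIdx)
    dist2 <- rowSums(sweep(sW, 2L, com, "-")^2)
    origin <- sIdx[which.min(round(dist2, 9)), ]
    new("SeedROI", limb = limb, hemisphere = hemisphere,
        origin = as.integer(origin), dilationRadius = as.numeric(radius),
        voxels = dilateROI(origin, radius, surface))
}
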