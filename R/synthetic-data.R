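# Phantom cohorts: curved streamline bundles from a thalamus blob to a
# cortical seed patch on a 1 mm grid, scalar metric volumes whose values
# vary along the tract with group-specific offsets (bilateral MD increase
# for DP, non-dominant-lateralized increase for HP), activation maps, and
# behavioral scores with group effects and missingness. Bundles are
# painted into the volumes (metric follows geometry), so every stage of
# the pipeline has a known ground truth.

#' PhantomSpec: parameters of the synthetic cohort generator
#'
#' Holds the geometry (grid, thalamus blobs, per-limb seed locations,
#' bundle arcs), the metric model (baselines, along-tract AFD peak shape,
#' group MD effect sizes, noise), and the behavioral score model. Defaults
#' follow the study regime being emulated: a 96^3 grid at 1 mm, 50
#' streamlines per bundle, MD increased by 15% in the non-dominant
#' hemisphere for HP and 10% bilaterally for DP, 5% voxel noise, AFD peaks
#' ~10 and ~45 mm from the thalamus surface, and group sizes 19/15/10
#' (TD/HP/DP).
#'
#' @slot dim grid dimensions (voxels).
#' @slot spacing isotropic voxel size (mm).
#' @slot thalamusCenter named list (left/right) of world-mm blob centers.
#' @slot thalamusRadius blob radius (mm).
#' @slot seeds nested list seeds[[limb]][[hemisphere]] of world-mm seed
#'   locations on the cortical surface.
#' @slot bow lateral bow (mm) of the quadratic arc between thalamus and
#'   seed.
#' @slot tubeRadius bundle tube radius (mm).
#' @slot nStreamlines streamlines per bundle.
#' @slot jitterSd per-streamline offset / point jitter sd (mm).
#' @slot baseline named baselines: MD (mm^2/s), FA, AFD.
#' @slot afdPeakPos,afdPeakAmp,afdPeakWidth two-peak AFD profile shape:
#'   positions (mm from the thalamus surface), relative amplitudes, and
#'   common Gaussian width (mm).
#' @slot mdDelta named relative MD increases: HP (non-dominant side only)
#'   and DP (bilateral).
#' @slot noiseSd voxel noise sd relative to each metric's baseline.
#' @slot subjectSd sd of the per-subject global metric scale factor
#'   (between-subject biological variability; cancels in the asymmetry
#'   index).
#' @slot nSubjects named group sizes (TD/HP/DP).
#' @slot ageRange uniform age range in years.
#' @slot domRightProb named probability of right-hand dominance per group.
#' @slot behavior list with \code{defs} ([testDefinitions()]), per-group
#'   \code{means}/\code{sds} matrices and \code{missingRate}.
#' @seealso [phantomSpec()], [reducedPhantomSpec()]
#' @export
setClass("PhantomSpec",
         representation(dim = "integer", spacing = "numeric",
                        thalamusCenter = "list", thalamusRadius = "numeric",
                        seeds = "list", bow = "numeric",
                        tubeRadius = "numeric", nStreamlines = "integer",
                        jitterSd = "numeric", baseline = "numeric",
                        afdPeakPos = "numeric", afdPeakAmp = "numeric",
                        afdPeakWidth = "numeric", mdDelta = "numeric",
                        noiseSd = "numeric", subjectSd = "numeric",
                        nSubjects = "integer", ageRange = "numeric",
                        domRightProb = "numeric", behavior = "list"))

setValidity("PhantomSpec", function(object) {
    msg <- NULL
    if (any(object@dim < 8L)) msg <- c(msg, "grid too small")
    if (object@noiseSd < 0 || object@jitterSd < 0 || object@subjectSd < 0)
        msg <- c(msg, "noise/jitter sds must be >= 0")
    if (any(object@nSubjects < 1L)) msg <- c(msg, "group sizes must be >= 1")
    if (!all(c("MD", "FA", "AFD") %in% names(object@baseline)))
        msg <- c(msg, "baseline must name MD, FA and AFD")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf("PhantomSpec: %dx%dx%d grid at %g mm, %d streamlines/bundle\n",
                object@dim[1], object@dim[2], object@dim[3], object@spacing,
                object@nStreamlines))
    cat(sprintf("  MD delta: HP %.0f%% (non-dominant), DP %.0f%% (bilateral); voxel noise %.0f%%\n",
                100 * object@mdDelta[["HP"]], 100 * object@mdDelta[["DP"]],
                100 * object@noiseSd))
    cat(sprintf("  cohort: TD %d / HP %d / DP %d\n",
                object@nSubjects[["TD"]], object@nSubjects[["HP"]],
                object@nSubjects[["DP"]]))
})

.defaultBehaviorModel <- function() {
    defs <- testDefinitions(
        name = c("bbt_dom", "bbt_nd", "nhp_dom", "nhp_nd",
                 "sway_eo", "sway_ec", "gait_ent", "gait_dt"),
        domain = c(rep("hand", 4L), rep("stability", 4L)),
        higherIsBetter = c(TRUE, TRUE, FALSE, FALSE,
                           FALSE, FALSE, TRUE, TRUE))
    means <- rbind(
        TD = c(62, 60, 17, 18,  9, 12, 1.9, 1.7),
        HP = c(48, 30, 24, 40, 14, 18, 1.5, 1.3),
        DP = c(52, 48, 21, 24, 16, 21, 1.4, 1.2))
    sds <- rbind(
        TD = c(7, 7, 2.5, 2.5, 2, 3, 0.20, 0.20),
        HP = c(9, 10, 6, 10,   4, 5, 0.25, 0.25),
        DP = c(8, 8, 4, 5,     4, 5, 0.25, 0.25))
    colnames(means) <- colnames(sds) <- defs$name
    list(defs = defs, means = means, sds = sds, missingRate = 0.08)
}

#' Construct a phantom specification
#'
#' All arguments default to the emulated study conditions; see
#' [PhantomSpec-class] for their meaning.
#'
#' @param dim,spacing grid shape and voxel size.
#' @param thalamusRadius,bow,tubeRadius,nStreamlines,jitterSd bundle
#'   geometry.
#' @param baseline,afdPeakPos,afdPeakAmp,afdPeakWidth metric model.
#' @param mdDelta,noiseSd,subjectSd group effects and noise.
#' @param nSubjects,ageRange,domRightProb cohort composition.
#' @param behavior behavioral model list (see [PhantomSpec-class]).
#' @param thalamusCenter,seeds optional geometry overrides (world mm).
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(dim = c(96L, 96L, 96L), spacing = 1,
                        thalamusRadius = 6, bow = 8, tubeRadius = 2,
                        nStreamlines = 50L, jitterSd = 0.5,
                        baseline = c(MD = 8e-4, FA = 0.5, AFD = 0.3),
                        afdPeakPos = c(10, 45), afdPeakAmp = c(0.5, 0.35),
                        afdPeakWidth = 5,
                        mdDelta = c(HP = 0.15, DP = 0.10),
                        noiseSd = 0.05, subjectSd = 0.03,
                        nSubjects = c(TD = 19L, HP = 15L, DP = 10L),
                        ageRange = c(10.5, 18.1),
                        domRightProb = c(TD = 1, HP = 0.4, DP = 0.6),
                        behavior = .defaultBehaviorModel(),
                        thalamusCenter = NULL, seeds = NULL) {
    ext <- (dim - 1) * spacing / 2          # half extent; centers at +/- ext
    if (is.null(thalamusCenter))
        thalamusCenter <- list(left = c(-0.19, 0, -0.30) * ext,
                               right = c(0.19, 0, -0.30) * ext)
    if (is.null(seeds))
        seeds <- list(
            upper = list(left = c(-0.65, -0.12, 0.78) * ext,
                         right = c(0.65, -0.12, 0.78) * ext),
            lower = list(left = c(-0.16, -0.22, 0.88) * ext,
                         right = c(0.16, -0.22, 0.88) * ext))
    new("PhantomSpec", dim = as.integer(dim), spacing = as.numeric(spacing),
        thalamusCenter = thalamusCenter, thalamusRadius = thalamusRadius,
        seeds = seeds, bow = bow, tubeRadius = tubeRadius,
        nStreamlines = as.integer(nStreamlines), jitterSd = jitterSd,
        baseline = baseline, afdPeakPos = afdPeakPos,
        afdPeakAmp = afdPeakAmp, afdPeakWidth = afdPeakWidth,
        mdDelta = mdDelta, noiseSd = noiseSd, subjectSd = subjectSd,
        nSubjects = structure(as.integer(nSubjects), names = names(nSubjects)),
        ageRange = ageRange, domRightProb = domRightProb,
        behavior = behavior)
}

#' Reduced phantom for replicated experiments
#'
#' Same effect sizes, noise and cohort composition as [phantomSpec()], on
#' a 48^3 grid with 12 streamlines per bundle and proportionally shorter
#' arcs, so that 100-replicate recovery experiments run in minutes.
#'
#' @param ... overrides passed on to [phantomSpec()].
#' @return A [PhantomSpec-class].
#' @export
reducedPhantomSpec <- function(...) {
    phantomSpec(dim = c(48L, 48L, 48L), nStreamlines = 12L, bow = 4,
                thalamusRadius = 3, tubeRadius = 1.5, ...)
}

.phantomAffine <- function(spec) {
    A <- diag(4)
    diag(A)[1:3] <- spec@spacing
    A[1:3, 4L] <- -(spec@dim - 1) * spec@spacing / 2
    A
}

.emptyVolume <- function(spec, units = "") {
    scalarVolume(array(0, spec@dim), affine = .phantomAffine(spec),
                 units = units)
}

#' Binary thalamus mask of the phantom
#'
#' @param spec a [PhantomSpec-class].
#' @return Binary [ScalarVolume-class] marking both thalamus blobs.
#' @export
thalamusMask <- function(spec) {
    v <- .emptyVolume(spec)
    dm <- spec@dim
    idx <- arrayInd(seq_len(prod(dm)), dm) - 1L
    w <- .applyAffine(v@affine, idx)
    inside <- rep(FALSE, nrow(w))
    for (ctr in spec@thalamusCenter)
        inside <- inside |
            rowSums(sweep(w, 2L, ctr, "-")^2) <= spec@thalamusRadius^2
    v@data[inside] <- 1
    v
}

#' White-matter surface mask of the phantom
#'
#' Marks the voxels within 2 mm of each limb-specific cortical seed
#' location; serves as the surface for manual placement and for projecting
#' activation-derived seeds.
#'
#' @param spec a [PhantomSpec-class].
#' @return Binary [ScalarVolume-class].
#' @export
surfaceMask <- function(spec) {
    v <- .emptyVolume(spec)
    for (limb in names(spec@seeds))
        for (hemi in names(spec@seeds[[limb]])) {
            origin <- round(worldToVoxel(v, spec@seeds[[limb]][[hemi]]))
            vox <- dilateROI(origin, 2, v)
            v@data[.linearIndex(vox, spec@dim)] <- 1
        }
    v
}

#' 0-based seed voxel index for a limb and hemisphere
#' @param spec a [PhantomSpec-class].
#' @param limb,hemisphere seed selector.
#' @return Integer index triple.
#' @export
seedVoxel <- function(spec, limb, hemisphere) {
    as.integer(round(worldToVoxel(.emptyVolume(spec),
                                  spec@seeds[[limb]][[hemisphere]])))
}

# control arc (quadratic Bezier) from the thalamus surface to the seed,
# returned as densified points with their arc-length positions
.controlArc <- function(spec, limb, hemisphere, step = 0.5) {
    ctr <- spec@thalamusCenter[[hemisphere]]
    # anchor the seed at the center of its voxel so endpoints are voxel-exact
    seedW <- voxelToWorld(.emptyVolume(spec),
                          round(worldToVoxel(.emptyVolume(spec),
                                             spec@seeds[[limb]][[hemisphere]])))
    u <- seedW - ctr
    u <- u / sqrt(sum(u^2))
    p0 <- ctr + spec@thalamusRadius * u      # start on the thalamus surface
    lateral <- c(sign(ctr[1L]), 0, 0)
    p1 <- (p0 + seedW) / 2 + spec@bow * lateral
    tt <- seq(0, 1, length.out = 120L)
    bez <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), p1) +
        outer(tt^2, seedW)
    .densifyPolyline(bez, step)
}

#' Generate one synthetic streamline bundle
#'
#' Smooth polylines following a jittered quadratic arc from the thalamus
#' blob surface to the cortical seed voxel, all within the declared
#' hemisphere (no midline crossing at zero jitter). Each streamline gets a
#' constant random offset in the plane normal to the arc chord (sd
#' \code{jitterSd}, capped at the tube radius) plus smoothed per-point
#' jitter. Uses the current RNG state; seed the RNG for reproducibility.
#'
#' @param spec a [PhantomSpec-class].
#' @param limb,hemisphere bundle selector.
#' @param n number of streamlines (default \code{spec@nStreamlines}).
#' @return A [StreamlineSet-class].
#' @export
generateBundle <- function(spec, limb, hemisphere, n = spec@nStreamlines) {
    arc <- .controlArc(spec, limb, hemisphere, step = 1)
    npts <- nrow(arc)
    chord <- arc[npts, ] - arc[1L, ]
    chord <- chord / sqrt(sum(chord^2))
    n1 <- c(-chord[2L], chord[1L], 0)
    if (sum(n1^2) < 1e-9) n1 <- c(1, 0, 0)
    n1 <- n1 / sqrt(sum(n1^2))
    n2 <- c(chord[2L] * n1[3L] - chord[3L] * n1[2L],
            chord[3L] * n1[1L] - chord[1L] * n1[3L],
            chord[1L] * n1[2L] - chord[2L] * n1[1L])
    sl <- vector("list", n)
    for (i in seq_len(n)) {
        a <- stats::rnorm(2L, 0, spec@jitterSd)
        nrm <- sqrt(sum(a^2))
        if (nrm > spec@tubeRadius) a <- a * spec@tubeRadius / nrm
        if (spec@jitterSd > 0) {
            wob1 <- stats::filter(stats::rnorm(npts, 0, spec@jitterSd / 2),
                                  rep(1 / 5, 5L), sides = 2L)
            wob2 <- stats::filter(stats::rnorm(npts, 0, spec@jitterSd / 2),
                                  rep(1 / 5, 5L), sides = 2L)
            wob1[is.na(wob1)] <- 0; wob2[is.na(wob2)] <- 0
        } else wob1 <- wob2 <- numeric(npts)
        off <- outer(rep(1, npts), a[1L] * n1 + a[2L] * n2) +
            outer(as.numeric(wob1), n1) + outer(as.numeric(wob2), n2)
        sl[[i]] <- arc + off
    }
    streamlineSet(sl)
}

# along-tract mean value of a metric at arc position s (mm from the
# thalamus surface); the AFD profile carries the two-peak shape
.metricProfileValue <- function(spec, metric, s) {
    base <- spec@baseline[[metric]]
    if (metric == "AFD") {
        shape <- rep(1, length(s))
        for (pk in seq_along(spec@afdPeakPos))
            shape <- shape + spec@afdPeakAmp[pk] *
                exp(-(s - spec@afdPeakPos[pk])^2 / (2 * spec@afdPeakWidth^2))
        base * shape
    } else rep(base, length(s))
}

# paint values along a tube around the centerline into `arr` (nearest-arc
# assignment); assumes the phantom's axis-aligned affine
.paintTube <- function(arr, spec, centerline, arcpos, values, radius) {
    A <- .phantomAffine(spec)
    inv <- .affineInverse(A)
    dm <- spec@dim
    vox <- .applyAffine(inv, centerline)
    reach <- ceiling(radius / spec@spacing + 0.5)
    off <- as.matrix(expand.grid(-reach:reach, -reach:reach, -reach:reach))
    off <- off[rowSums(off^2) <= (radius / spec@spacing + 0.87)^2, ,
               drop = FALSE]
    nP <- nrow(vox); nO <- nrow(off)
    base <- round(vox)
    cand <- base[rep(seq_len(nP), each = nO), ] + off[rep(seq_len(nO), nP), ]
    ptIdx <- rep(seq_len(nP), each = nO)
    d2 <- rowSums((cand - vox[ptIdx, , drop = FALSE])^2) * spec@spacing^2
    keep <- d2 <= radius^2 & .insideGrid(cand, dm)
    cand <- cand[keep, , drop = FALSE]
    ptIdx <- ptIdx[keep]; d2 <- d2[keep]
    lin <- .linearIndex(cand, dm)
    ord <- order(lin, d2)
    first <- !duplicated(lin[ord])
    arr[lin[ord][first]] <- values[ptIdx[ord][first]]
    arr
}

#' Generate a subject's metric volume
#'
#' Baseline plus the along-tract profile painted along each limb bundle's
#' arc, a group/laterality MD offset (HP: non-dominant side only; DP:
#' bilateral), i.i.d. voxel noise, and an optional per-subject global
#' scale. FA is clipped to \eqn{[0, 1]}. Uses the current RNG state.
#'
#' @param spec a [PhantomSpec-class].
#' @param group \code{"TD"}, \code{"HP"} or \code{"DP"}.
#' @param metric \code{"MD"}, \code{"FA"} or \code{"AFD"}.
#' @param dominantHemisphere hemisphere of the dominant-limb tract
#'   (contralateral to the dominant hand).
#' @param subjectScale per-subject global scale factor (default 1).
#' @param limbs which limb bundles to paint (default both).
#' @return A [ScalarVolume-class].
#' @export
generateMetricVolume <- function(spec, group, metric,
                                 dominantHemisphere = "left",
                                 subjectScale = 1,
                                 limbs = names(spec@seeds)) {
    base <- spec@baseline[[metric]]
    mean0 <- array(base * subjectScale, spec@dim)
    paintR <- spec@tubeRadius + 3 * spec@jitterSd + 2
    for (limb in limbs) for (hemi in c("left", "right")) {
        delta <- 0
        if (metric == "MD") {
            if (group == "DP") delta <- spec@mdDelta[["DP"]]
            if (group == "HP" && hemi != dominantHemisphere)
                delta <- spec@mdDelta[["HP"]]
        }
        # flat profiles are insensitive to arc quantization; only the AFD
        # peak shape needs a fine centerline step
        arcFine <- .controlArc(spec, limb, hemi,
                               step = if (metric == "AFD") 0.5 else 1.5)
        arcs <- .cumArc(arcFine)
        # extend 3 mm past both ends so endpoint samples stay in-tube
        d0 <- arcFine[2L, ] - arcFine[1L, ]
        d0 <- d0 / sqrt(sum(d0^2))
        dN <- arcFine[nrow(arcFine), ] - arcFine[nrow(arcFine) - 1L, ]
        dN <- dN / sqrt(sum(dN^2))
        pre <- outer(seq(-3, -0.5, by = 0.5), d0) +
            matrix(arcFine[1L, ], 6L, 3L, byrow = TRUE)
        post <- outer(seq(0.5, 3, by = 0.5), dN) +
            matrix(arcFine[nrow(arcFine), ], 6L, 3L, byrow = TRUE)
        ctrLine <- rbind(pre, arcFine, post)
        pos <- c(rep(0, 6L), arcs, rep(arcs[length(arcs)], 6L))
        vals <- .metricProfileValue(spec, metric, pos) * subjectScale *
            (1 + delta)
        mean0 <- .paintTube(mean0, spec, ctrLine, pos, vals, paintR)
    }
    dat <- mean0
    if (spec@noiseSd > 0)
        dat <- dat + stats::rnorm(length(dat), 0, spec@noiseSd * base)
    if (metric == "FA") dat <- pmin(pmax(dat, 0), 1)
    dim(dat) <- spec@dim
    scalarVolume(dat, affine = .phantomAffine(spec),
                 units = if (metric == "MD") "mm^2/s" else "")
}

#' Generate a synthetic activation statistic map
#'
#' A Gaussian statistic blob centered at the true seed location, an
#' optional lower-peaked decoy blob, and i.i.d. noise. Uses the current
#' RNG state.
#'
#' @param spec a [PhantomSpec-class].
#' @param limb,hemisphere which seed the main blob marks.
#' @param peak main blob peak statistic value.
#' @param sigma blob width (mm).
#' @param threshold statistic cutoff stored in the map.
#' @param noiseSd additive noise sd.
#' @param decoy optional list(center = world mm, peak = value) decoy blob;
#'   its peak should be below \code{peak}.
#' @return An [ActivationMap-class].
#' @export
generateActivationMap <- function(spec, limb, hemisphere, peak = 8,
                                  sigma = 3, threshold = 2, noiseSd = 0,
                                  decoy = NULL) {
    v <- .emptyVolume(spec)
    dm <- spec@dim
    idx <- arrayInd(seq_len(prod(dm)), dm) - 1L
    w <- .applyAffine(v@affine, idx)
    ctr <- voxelToWorld(v, seedVoxel(spec, limb, hemisphere))
    stat <- peak * exp(-rowSums(sweep(w, 2L, ctr, "-")^2) / (2 * sigma^2))
    if (!is.null(decoy))
        stat <- stat + decoy$peak *
            exp(-rowSums(sweep(w, 2L, decoy$center, "-")^2) / (2 * sigma^2))
    if (noiseSd > 0) stat <- stat + stats::rnorm(length(stat), 0, noiseSd)
    v@data[] <- stat
    activationMap(v, threshold)
}

#' Generate a synthetic cohort table
#'
#' Subjects with group labels, dominance side, age ~ uniform over the
#' configured range, behavioral scores from group-specific normal models
#' with missing-at-random cells, and a per-subject RNG seed from which the
#' subject's imaging data ([generateSubjectData()]) are reproducibly
#' derived.
#'
#' @param spec a [PhantomSpec-class].
#' @param nTD,nHP,nDP group sizes (default from the spec).
#' @param seed optional integer seed for full cohort reproducibility.
#' @return list with \code{subjects} (data.frame) and \code{spec}.
#' @export
generateCohort <- function(spec, nTD = spec@nSubjects[["TD"]],
                           nHP = spec@nSubjects[["HP"]],
                           nDP = spec@nSubjects[["DP"]], seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    n <- nTD + nHP + nDP
    group <- rep(c("TD", "HP", "DP"), c(nTD, nHP, nDP))
    df <- data.frame(
        id = sprintf("S%03d", seq_len(n)),
        group = group,
        dominance = ifelse(stats::rbinom(n, 1L, spec@domRightProb[group]) == 1L,
                           "right", "left"),
        age = stats::runif(n, spec@ageRange[1L], spec@ageRange[2L]),
        stringsAsFactors = FALSE)
    bm <- spec@behavior
    for (test in bm$defs$name)
        df[[test]] <- stats::rnorm(n, bm$means[group, test],
                                   bm$sds[group, test])
    if (bm$missingRate > 0) {
        cells <- matrix(stats::runif(n * nrow(bm$defs)) < bm$missingRate,
                        nrow = n)
        for (j in seq_len(nrow(bm$defs)))
            df[[bm$defs$name[j]]][cells[, j]] <- NA_real_
    }
    df$subject_seed <- sample.int(.Machine$integer.max - 1L, n)
    df$subjectScale <- stats::rnorm(n, 1, spec@subjectSd)
    validateSubjectTable(df)
    list(subjects = df, spec = spec)
}

#' Dominant-tract hemisphere for a dominance (hand) side
#'
#' The tract serving a limb runs in the contralateral hemisphere, so a
#' right-dominant subject's dominant tract is the left-hemisphere one. In
#' HP the dominant hand is the less-affected hand.
#'
#' @param dominance \code{"left"} or \code{"right"} (dominant hand).
#' @return Hemisphere (\code{"left"}/\code{"right"}) of the dominant tract.
#' @export
dominantHemisphere <- function(dominance) {
    ifelse(dominance == "right", "left", "right")
}

#' Deterministically generate one subject's imaging data
#'
#' Re-seeds the RNG from the subject's stored seed, so the same subject
#' row always yields bit-identical bundles and volumes.
#'
#' @param spec a [PhantomSpec-class].
#' @param subject one row of the cohort subject table.
#' @param metrics metric volumes to generate.
#' @param limbs limbs to generate bundles for.
#' @return list with \code{bundles[[limb]][[hemisphere]]}
#'   ([StreamlineSet-class]) and \code{volumes[[metric]]}
#'   ([ScalarVolume-class]).
#' @export
generateSubjectData <- function(spec, subject,
                                metrics = c("MD", "FA", "AFD"),
                                limbs = names(spec@seeds)) {
    set.seed(subject$subject_seed)
    domHemi <- dominantHemisphere(subject$dominance)
    bundles <- list()
    for (limb in limbs) {
        bundles[[limb]] <- list()
        for (hemi in c("left", "right"))
            bundles[[limb]][[hemi]] <- generateBundle(spec, limb, hemi)
    }
    volumes <- list()
    for (m in metrics)
        volumes[[m]] <- generateMetricVolume(spec, subject$group, m,
                                             dominantHemisphere = domHemi,
                                             subjectScale = subject$subjectScale,
                                             limbs = limbs)
    list(bundles = bundles, volumes = volumes)
}

#' Write a synthetic cohort to disk
#'
#' Produces the documented phantom layout: \code{cohort.csv},
#' \code{thalamus.nii.gz}, \code{surface.nii.gz}, \code{seeds.yaml} and
#' per-subject directories with TCK bundles and NIfTI metric volumes.
#'
#' @param spec a [PhantomSpec-class].
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param metrics,limbs what to generate.
#' @return The cohort list, invisibly, with \code{dir} recorded.
#' @export
simulateCohort <- function(spec, dir, seed = 42L,
                           metrics = c("MD", "FA", "AFD"),
                           limbs = names(spec@seeds)) {
    cohort <- generateCohort(spec, seed = seed)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeSubjectTable(cohort$subjects, file.path(dir, "cohort.csv"))
    writeVolume(thalamusMask(spec), file.path(dir, "thalamus.nii.gz"))
    writeVolume(surfaceMask(spec), file.path(dir, "surface.nii.gz"))
    seeds <- lapply(names(spec@seeds), function(limb)
        lapply(spec@seeds[[limb]], function(w)
            as.integer(round(worldToVoxel(.emptyVolume(spec), w)))))
    names(seeds) <- names(spec@seeds)
    yaml::write_yaml(list(dilation_mm = 3, seeds = seeds),
                     file.path(dir, "seeds.yaml"))
    aff <- .phantomAffine(spec)
    for (i in seq_len(nrow(cohort$subjects))) {
        row <- cohort$subjects[i, ]
        sdir <- file.path(dir, row$id)
        dir.create(sdir, showWarnings = FALSE)
        dat <- generateSubjectData(spec, row, metrics = metrics,
                                   limbs = limbs)
        for (limb in limbs) for (hemi in c("left", "right"))
            writeStreamlines(dat$bundles[[limb]][[hemi]],
                             file.path(sdir, sprintf("%s_%s.tck", limb, hemi)))
        for (m in metrics)
            writeVolume(dat$volumes[[m]],
                        file.path(sdir, sprintf("%s.nii.gz", tolower(m))))
    }
    cohort$dir <- dir
    invisible(cohort)
}
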