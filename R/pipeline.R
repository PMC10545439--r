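# End-to-end orchestration: per-subject bundle extraction and QC, metric
# and asymmetry tables, along-tract profiles, behavioral sum variables,
# group comparisons and age-corrected correlations, with a machine-readable
# provenance log of every filter decision and exclusion. Subjects failing
# one limb's extraction stay in every other analysis.

#' Pipeline run configuration
#'
#' @param seedingMode \code{"manual"} (seed voxel from the phantom/seed
#'   table) or \code{"activation"} (seed derived from an activation map via
#'   [roiFromActivation()]).
#' @param dilationMm seed dilation radius in mm (default 3).
#' @param minCount minimum streamline count per tract (default 5).
#' @param profileStepMm along-tract position step in mm (default 1).
#' @param averagingMode whole-tract averaging mode (default
#'   \code{"streamline"}).
#' @param alpha global significance level (default 0.05).
#' @param midlineX mid-sagittal plane (world mm).
#' @param zMax outlier-filter threshold ([outlierFilter()]).
#' @param metrics,limbs what to analyze.
#' @return A named list of validated settings.
#' @export
pipelineConfig <- function(seedingMode = c("manual", "activation"),
                           dilationMm = 3, minCount = 5, profileStepMm = 1,
                           averagingMode = c("streamline", "mask"),
                           alpha = 0.05, midlineX = 0, zMax = 3,
                           metrics = c("MD", "FA", "AFD"),
                           limbs = c("upper", "lower")) {
    stopifnot(dilationMm >= 0, minCount >= 1, profileStepMm > 0,
              alpha > 0, alpha < 1)
    list(seedingMode = match.arg(seedingMode), dilationMm = dilationMm,
         minCount = minCount, profileStepMm = profileStepMm,
         averagingMode = match.arg(averagingMode), alpha = alpha,
         midlineX = midlineX, zMax = zMax, metrics = metrics, limbs = limbs,
         fdr = "BH")
}

#' Load a simulated cohort directory
#'
#' Reads the layout written by [simulateCohort()]. The returned cohort
#' reads each subject's bundles and volumes from disk on demand.
#'
#' @param dir cohort directory.
#' @param spec the [PhantomSpec-class] the cohort was simulated from
#'   (supplies seed locations and masks if the mask files are absent).
#' @return A cohort list usable by [runPipeline()].
#' @export
loadCohort <- function(dir, spec) {
    subjects <- readSubjectTable(file.path(dir, "cohort.csv"))
    list(subjects = subjects, spec = spec, dir = dir)
}

.subjectData <- function(cohort, row, cfg) {
    if (!is.null(cohort$dir)) {
        sdir <- file.path(cohort$dir, row$id)
        bundles <- list()
        for (limb in cfg$limbs) {
            bundles[[limb]] <- list()
            for (hemi in c("left", "right")) {
                f <- file.path(sdir, sprintf("%s_%s.tck", limb, hemi))
                bundles[[limb]][[hemi]] <- readStreamlines(f)
            }
        }
        volumes <- list()
        for (m in cfg$metrics)
            volumes[[m]] <- readVolume(file.path(sdir,
                                                 sprintf("%s.nii.gz",
                                                         tolower(m))),
                                       units = if (m == "MD") "mm^2/s" else "")
        list(bundles = bundles, volumes = volumes)
    } else {
        generateSubjectData(cohort$spec, row, metrics = cfg$metrics,
                            limbs = cfg$limbs)
    }
}

.subjectROI <- function(cohort, row, limb, hemi, surface, cfg) {
    spec <- cohort$spec
    if (cfg$seedingMode == "manual") {
        manualROI(seedVoxel(spec, limb, hemi), limb, hemi, surface,
                  radius = cfg$dilationMm)
    } else {
        set.seed((row$subject_seed + 7L * match(limb, c("upper", "lower")) +
                  13L * match(hemi, c("left", "right"))) %%
                 .Machine$integer.max)
        amap <- generateActivationMap(spec, limb, hemi, noiseSd = 0.05)
        roiFromActivation(amap, limb, hemi, surface, radius = cfg$dilationMm)
    }
}

#' Run the full analysis pipeline on a cohort
#'
#' For every subject, limb and hemisphere: derive the seed ROI, run the
#' bundle-selection chain (orientation, midline and terminal-ROI filters,
#' geometric outlier removal, minimum-count rule), then compute whole-tract
#' metric means, asymmetry indices, and along-tract median profiles.
#' Afterwards: behavioral sum variables, Kruskal-Wallis group comparisons
#' with conditional Conover post hoc, pointwise along-tract H-tests, and
#' per-group age-corrected correlations between tract properties and the
#' limb-matched sum variable (9 hypotheses per limb domain, Bonferroni
#' threshold alpha/9). A stage error excludes that subject cell with a
#' logged reason; the run continues.
#'
#' @param cohort list from [generateCohort()] or [loadCohort()].
#' @param cfg configuration from [pipelineConfig()].
#' @return list with \code{qc}, \code{metrics}, \code{ai},
#'   \code{profiles}, \code{profileTests}, \code{behavior},
#'   \code{groupComparisons}, \code{correlations},
#'   \code{bonferroniAlpha} and \code{provenance}.
#' @export
runPipeline <- function(cohort, cfg = pipelineConfig()) {
    spec <- cohort$spec
    subjects <- cohort$subjects
    thal <- thalamusMask(spec)
    surf <- surfaceMask(spec)
    qc <- list(); met <- list(); prof <- list(); logs <- list()
    for (i in seq_len(nrow(subjects))) {
        row <- subjects[i, ]
        dat <- .subjectData(cohort, row, cfg)
        domHemi <- dominantHemisphere(row$dominance)
        for (limb in cfg$limbs) for (hemi in c("left", "right")) {
            role <- if (hemi == domHemi) "dominant" else "nondominant"
            res <- tryCatch({
                roi <- .subjectROI(cohort, row, limb, hemi, surf, cfg)
                b <- selectBundle(dat$bundles[[limb]][[hemi]], thal, roi,
                                  dat$volumes[[cfg$metrics[1L]]],
                                  midlineX = cfg$midlineX, zMax = cfg$zMax,
                                  minN = cfg$minCount)
                b
            }, error = function(e) {
                new("TractExclusion", limb = limb, hemisphere = hemi,
                    nStreamlines = 0L, reason = conditionMessage(e))
            })
            if (isExcluded(res)) {
                qc[[length(qc) + 1L]] <- data.frame(
                    id = row$id, group = row$group, limb = limb,
                    hemisphere = hemi, role = role,
                    n_streamlines = res@nStreamlines, included = FALSE,
                    reason = res@reason, stringsAsFactors = FALSE)
                logs[[length(logs) + 1L]] <- list(
                    event = "exclusion", id = row$id, limb = limb,
                    hemisphere = hemi, reason = res@reason)
                next
            }
            b <- resampleUniform(res, cfg$profileStepMm)
            qc[[length(qc) + 1L]] <- data.frame(
                id = row$id, group = row$group, limb = limb,
                hemisphere = hemi, role = role,
                n_streamlines = length(b@streamlines), included = TRUE,
                reason = "", stringsAsFactors = FALSE)
            logs[[length(logs) + 1L]] <- c(
                list(event = "bundle", id = row$id, limb = limb,
                     hemisphere = hemi),
                list(filters = b@provenance))
            for (m in cfg$metrics) {
                val <- tryCatch(
                    as.numeric(bundleMean(b, dat$volumes[[m]],
                                          mode = cfg$averagingMode)),
                    error = function(e) NA_real_)
                met[[length(met) + 1L]] <- data.frame(
                    id = row$id, group = row$group, limb = limb,
                    hemisphere = hemi, role = role, metric = m,
                    mode = cfg$averagingMode, value = val,
                    stringsAsFactors = FALSE)
                pr <- tryCatch(
                    profileMedian(b, dat$volumes[[m]],
                                  minSupport = cfg$minCount, metric = m),
                    error = function(e) NULL)
                if (!is.null(pr) && length(pr@positions))
                    prof[[length(prof) + 1L]] <- data.frame(
                        id = row$id, group = row$group, limb = limb,
                        hemisphere = hemi, role = role, metric = m,
                        position_mm = pr@positions, value = pr@values,
                        support = pr@support, stringsAsFactors = FALSE)
            }
        }
    }
    qc <- do.call(rbind, qc)
    metrics <- if (length(met)) do.call(rbind, met) else NULL
    profiles <- if (length(prof)) do.call(rbind, prof) else NULL

    ai <- .aiTable(metrics)
    behavior <- buildSumVariables(subjects, spec@behavior$defs)
    comparisons <- .groupComparisonTable(metrics, ai, behavior, cfg)
    profileTests <- .profileTestTable(profiles, cfg)
    correlations <- .correlationTable(metrics, ai, behavior, subjects, cfg)

    list(qc = qc, metrics = metrics, ai = ai, profiles = profiles,
         profileTests = profileTests, behavior = behavior,
         groupComparisons = comparisons, correlations = correlations,
         bonferroniAlpha = bonferroniAlpha(cfg$alpha, 9),
         provenance = logs)
}

# per-subject x limb x metric asymmetry indices (needs both roles)
.aiTable <- function(metrics) {
    if (is.null(metrics)) return(NULL)
    out <- list()
    sp <- split(metrics, list(metrics$id, metrics$limb, metrics$metric),
                drop = TRUE)
    for (d in sp) {
        nd <- d$value[d$role == "nondominant"]
        dd <- d$value[d$role == "dominant"]
        if (length(nd) == 1L && length(dd) == 1L &&
            !is.na(nd) && !is.na(dd) && nd + dd != 0)
            out[[length(out) + 1L]] <- data.frame(
                id = d$id[1L], group = d$group[1L], limb = d$limb[1L],
                metric = d$metric[1L], ai = asymmetryIndex(nd, dd),
                stringsAsFactors = FALSE)
    }
    if (length(out)) do.call(rbind, out) else NULL
}

.groupComparisonTable <- function(metrics, ai, behavior, cfg) {
    rows <- list()
    addRow <- function(varName, values, groups) {
        cmp <- tryCatch(compareGroups(values, groups, cfg$alpha),
                        error = function(e) NULL)
        if (is.null(cmp)) return()
        pw <- cmp$pairwise
        rows[[length(rows) + 1L]] <<- data.frame(
            variable = varName, H = cmp$H, df = cmp$df, p = cmp$p,
            HP_TD_pfdr = .pairP(pw, "HP", "TD"),
            DP_TD_pfdr = .pairP(pw, "DP", "TD"),
            HP_DP_pfdr = .pairP(pw, "HP", "DP"),
            stringsAsFactors = FALSE)
    }
    if (!is.null(metrics))
        for (limb in unique(metrics$limb))
            for (m in unique(metrics$metric)) {
                for (role in c("nondominant", "dominant")) {
                    d <- metrics[metrics$limb == limb &
                                 metrics$metric == m & metrics$role == role, ]
                    addRow(paste(limb, m, role, sep = "_"), d$value, d$group)
                }
                if (!is.null(ai)) {
                    d <- ai[ai$limb == limb & ai$metric == m, ]
                    addRow(paste(limb, m, "AI", sep = "_"), d$ai, d$group)
                }
            }
    for (dom in c("hand", "stability"))
        if (dom %in% names(behavior$scores))
            addRow(paste0("sum_", dom), behavior$scores[[dom]],
                   behavior$scores$group)
    if (length(rows)) do.call(rbind, rows) else NULL
}

.pairP <- function(pw, a, b) {
    if (is.null(pw)) return(NA_real_)
    hit <- (pw$group1 == a & pw$group2 == b) |
           (pw$group1 == b & pw$group2 == a)
    if (any(hit)) pw$p_fdr[hit][1L] else NA_real_
}

.profileTestTable <- function(profiles, cfg) {
    if (is.null(profiles)) return(NULL)
    out <- list()
    for (limb in unique(profiles$limb))
        for (role in unique(profiles$role))
            for (m in unique(profiles$metric)) {
                d <- profiles[profiles$limb == limb & profiles$role == role &
                              profiles$metric == m, ]
                if (nrow(d) == 0L) next
                byGroup <- lapply(split(d, d$group), function(g)
                    lapply(split(g, g$id), function(s)
                        s$value[order(s$position_mm)]))
                byGroup <- byGroup[order(names(byGroup))]
                if (length(byGroup) < 2L) next
                ht <- pointwiseHTest(byGroup, step = cfg$profileStepMm)
                if (nrow(ht) == 0L) next
                ht$limb <- limb; ht$role <- role; ht$metric <- m
                out[[length(out) + 1L]] <- ht
            }
    if (length(out)) do.call(rbind, out) else NULL
}

# age-corrected correlations: per group and limb domain, 9 hypotheses
# (3 metrics x {nondominant, dominant, |AI|}) against the matched sum
# variable, with listwise deletion
.correlationTable <- function(metrics, ai, behavior, subjects, cfg) {
    if (is.null(metrics)) return(NULL)
    domainOf <- c(upper = "hand", lower = "stability")
    rows <- list()
    scores <- behavior$scores
    for (grp in unique(subjects$group))
        for (limb in intersect(cfg$limbs, names(domainOf))) {
            dom <- domainOf[[limb]]
            if (!dom %in% names(scores)) next
            for (m in cfg$metrics) for (what in c("nondominant", "dominant",
                                                  "AI")) {
                if (what == "AI") {
                    d <- ai[!is.null(ai) & ai$limb == limb &
                            ai$metric == m & ai$group == grp, ]
                    if (is.null(d) || nrow(d) == 0L) next
                    x <- absAI(d$ai); ids <- d$id
                } else {
                    d <- metrics[metrics$limb == limb & metrics$metric == m &
                                 metrics$role == what &
                                 metrics$group == grp, ]
                    if (nrow(d) == 0L) next
                    x <- d$value; ids <- d$id
                }
                y <- scores[[dom]][match(ids, scores$id)]
                age <- subjects$age[match(ids, subjects$id)]
                ok <- !is.na(x) & !is.na(y) & !is.na(age)
                res <- tryCatch(pearsonPartialAge(x[ok], y[ok], age[ok]),
                                error = function(e) NULL)
                rows[[length(rows) + 1L]] <- data.frame(
                    group = grp, limb = limb, domain = dom, metric = m,
                    measure = what, n = sum(ok),
                    r = if (is.null(res)) NA_real_ else res$r,
                    p = if (is.null(res)) NA_real_ else res$p,
                    bonferroni_alpha = bonferroniAlpha(cfg$alpha, 9),
                    stringsAsFactors = FALSE)
            }
        }
    if (length(rows)) do.call(rbind, rows) else NULL
}

#' Write pipeline results to a directory
#'
#' Tidy CSV tables plus a JSON-lines provenance log of every filter
#' decision and exclusion.
#'
#' @param results list from [runPipeline()].
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeResults <- function(results, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("qc", "metrics", "ai", "profiles", "profileTests",
                 "groupComparisons", "correlations"))
        if (!is.null(results[[nm]]))
            utils::write.csv(results[[nm]],
                             file.path(dir, paste0(nm, ".csv")),
                             row.names = FALSE)
    if (!is.null(results$behavior))
        utils::write.csv(results$behavior$scores,
                         file.path(dir, "behavior.csv"), row.names = FALSE)
    con <- file(file.path(dir, "provenance.jsonl"), "w")
    for (rec in results$provenance)
        writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
    close(con)
    invisible(dir)
}
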