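# Along-tract profiling: per-position median metric values moving from the
# thalamus surface (position 0) toward the cortex, terminated once fewer
# than five streamlines reach the distance; presentation smoothing; and a
# pointwise Kruskal-Wallis group test without multiplicity correction.

#' Resample every streamline at a uniform arc-length step
#'
#' Replaces each streamline by points at arc lengths 0, step, 2*step, ...
#' along the original polyline. If the last grid point falls more than
#' step/2 short of the original endpoint, the endpoint itself is appended,
#' so both endpoints are preserved within step/2. Uniform resampling makes
#' "distance along the tract" comparable across streamlines and subjects.
#'
#' @param b a [StreamlineSet-class] or [TractBundle-class].
#' @param step arc-length step in mm (default 1).
#' @return The resampled set, same class as the input; a
#'   [TractBundle-class] records the step.
#' @export
resampleUniform <- function(b, step = 1) {
    stopifnot(is(b, "StreamlineSet"), step > 0)
    out <- b
    out@streamlines <- lapply(b@streamlines, function(m) {
        L <- .polylineLength(m)
        s <- seq(0, L, by = step)
        if (L - s[length(s)] > step / 2) s <- c(s, L)
        if (length(s) < 2L) s <- c(0, L)   # shorter than one step: endpoints
        .interpPolyline(m, s)
    })
    if (is(out, "TractBundle")) {
        out@step <- as.numeric(step)
        out <- .logFilter(out, "resampleUniform", length(b@streamlines),
                          length(b@streamlines), list(step = step))
    }
    out
}

#' Along-tract median profile with support-count termination
#'
#' At the first tract point (position 0, on the thalamus surface) the
#' sampled metric value of every streamline is collected and the median
#' taken; moving toward the cortex the same is repeated position by
#' position until the distance is reached by fewer than \code{minSupport}
#' streamlines (default 5), where the profile stops. Even contributor
#' counts use the mean-of-middle-two median convention.
#'
#' @param b a thalamus-oriented, uniformly resampled [TractBundle-class]
#'   (or [StreamlineSet-class]).
#' @param v the metric [ScalarVolume-class].
#' @param minSupport minimum number of contributing streamlines per
#'   position.
#' @param step position step in mm; defaults to the bundle's recorded
#'   resampling step (1 mm if unknown).
#' @param metric metric name stored in the profile.
#' @return A [TractProfile-class].
#' @export
profileMedian <- function(b, v, minSupport = 5, step = NULL, metric = "") {
    stopifnot(is(b, "StreamlineSet"), is(v, "ScalarVolume"))
    if (is.null(step))
        step <- if (is(b, "TractBundle") && is.finite(b@step)) b@step else 1
    n <- length(b@streamlines)
    if (n < minSupport)
        stop("bundle has ", n, " streamlines, fewer than minSupport = ",
             minSupport)
    samples <- lapply(b@streamlines, function(m) sampleMetric(v, m))
    npts <- lengths(samples)
    values <- numeric(0)
    support <- integer(0)
    k <- 0L
    repeat {
        contrib <- npts >= k + 1L
        if (sum(contrib) < minSupport) break
        values <- c(values, stats::median(vapply(samples[contrib],
                                                 `[`, numeric(1), k + 1L)))
        support <- c(support, sum(contrib))
        k <- k + 1L
    }
    new("TractProfile", positions = seq_len(k) * step - step,
        values = values, support = support, metric = metric)
}

#' Moving-average smoothing of a profile (presentation only)
#'
#' Centered moving average over \code{window} points, with the window
#' shrinking symmetrically at the profile ends (at position i the average
#' runs over i +/- min(floor(window/2), distance to the nearer end)).
#' Support counts are unchanged. Smoothing is for display; statistics are
#' computed on raw profiles.
#'
#' @param p a [TractProfile-class].
#' @param window nominal window in points (default 10); 1 is the identity.
#' @return The smoothed [TractProfile-class].
#' @export
smoothProfile <- function(p, window = 10) {
    stopifnot(is(p, "TractProfile"), window >= 1)
    n <- length(p@values)
    h <- floor(window / 2)
    sm <- vapply(seq_len(n), function(i) {
        hi <- min(h, i - 1L, n - i)
        mean(p@values[(i - hi):(i + hi)])
    }, numeric(1))
    new("TractProfile", positions = p@positions, values = sm,
        support = p@support, metric = p@metric)
}

#' Pointwise Kruskal-Wallis test along the tract
#'
#' At each profile position, runs the H-test across groups on the subjects'
#' profile values. Positions where any group contributes fewer than
#' \code{minPerGroup} subjects are skipped. No multiplicity correction is
#' applied (the along-tract analysis is reported pointwise).
#'
#' @param profilesByGroup named list (one element per group, >= 2 groups);
#'   each element a list of [TractProfile-class] objects or numeric value
#'   vectors, one per subject.
#' @param minPerGroup minimum subjects per group per tested position
#'   (default 2).
#' @param step position step in mm used to label positions when raw
#'   numeric vectors are supplied (default 1).
#' @return data.frame with position_mm, H, df, p and per-group n columns.
#' @export
pointwiseHTest <- function(profilesByGroup, minPerGroup = 2, step = 1) {
    if (length(profilesByGroup) < 2L)
        stop("pointwise H-test needs at least 2 groups")
    vals <- lapply(profilesByGroup, function(g)
        lapply(g, function(p) if (is(p, "TractProfile")) p@values else p))
    firstP <- profilesByGroup[[1L]][[1L]]
    if (is(firstP, "TractProfile") && length(firstP@positions) > 1L)
        step <- diff(firstP@positions)[1L]
    maxLen <- max(unlist(lapply(vals, lengths)))
    rows <- list()
    for (k in seq_len(maxLen)) {
        gvals <- lapply(vals, function(g) {
            x <- unlist(lapply(g, function(v) if (length(v) >= k) v[k]))
            if (is.null(x)) numeric(0) else x
        })
        if (any(vapply(gvals, length, integer(1)) < minPerGroup)) next
        kw <- kruskalWallis(gvals)
        rows[[length(rows) + 1L]] <-
            data.frame(position_mm = (k - 1) * step, H = kw$H, df = kw$df,
                       p = kw$p,
                       t(vapply(gvals, length, integer(1))))
    }
    if (length(rows) == 0L)
        return(data.frame(position_mm = numeric(0), H = numeric(0),
                          df = numeric(0), p = numeric(0)))
    out <- do.call(rbind, rows)
    names(out)[-(1:4)] <- paste0("n_", names(profilesByGroup))
    rownames(out) <- NULL
    out
}
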