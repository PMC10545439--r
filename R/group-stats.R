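# Group comparison and structure-function correlation statistics: the
# Kruskal-Wallis H-test with Conover-Iman pairwise post hoc under
# Benjamini-Hochberg FDR, the age-corrected two-tailed Pearson correlation,
# and the Bonferroni threshold.

#' Kruskal-Wallis H-test across groups
#'
#' Wraps \code{stats::kruskal.test} (mid-ranks with the tie-correction
#' factor; p from the chi-square approximation with groups - 1 df). For
#' very small samples a permutation p-value is available: all label
#' permutations are enumerated when the total sample size is at most
#' \code{exactLimit}, otherwise \code{nPerm} random permutations are used.
#'
#' @param groups list of >= 2 numeric vectors.
#' @param method \code{"asymptotic"} (default) or \code{"permutation"}.
#' @param nPerm random permutations when enumeration is infeasible.
#' @param exactLimit maximum total n for full enumeration.
#' @return list with \code{H}, \code{df}, \code{p} and \code{method}.
#' @examples
#' kruskalWallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))$H  # 7.2
#' @export
kruskalWallis <- function(groups, method = c("asymptotic", "permutation"),
                          nPerm = 9999, exactLimit = 9) {
    method <- match.arg(method)
    stopifnot(length(groups) >= 2L)
    groups <- lapply(groups, as.numeric)
    if (length(unique(unlist(groups))) < 2L)
        stop("all values identical: H-test undefined (tie factor 0)")
    kt <- stats::kruskal.test(groups)
    out <- list(H = unname(kt$statistic), df = unname(kt$parameter),
                p = kt$p.value, method = "chi-square approximation")
    if (method == "permutation") {
        x <- unlist(groups)
        g <- rep(seq_along(groups), lengths(groups))
        hstat <- function(gg) unname(stats::kruskal.test(x, gg)$statistic)
        n <- length(x)
        if (n <= exactLimit) {
            perms <- .allPermutations(n)
            hs <- apply(perms, 1L, function(p) hstat(g[p]))
            out$p <- mean(hs >= out$H - 1e-12)
            out$method <- "exact permutation"
        } else {
            hs <- vapply(seq_len(nPerm), function(i) hstat(sample(g)),
                         numeric(1))
            out$p <- (1 + sum(hs >= out$H - 1e-12)) / (nPerm + 1)
            out$method <- sprintf("permutation (%d draws)", nPerm)
        }
    }
    out
}

.allPermutations <- function(n) {
    if (n == 1L) return(matrix(1L))
    sub <- .allPermutations(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i)
        cbind(i, ifelse(sub >= i, sub + 1L, sub))))
}

#' Conover-Iman pairwise post hoc test
#'
#' Pairwise comparisons on the pooled mid-ranks following a significant
#' Kruskal-Wallis test: t_ij = (Rbar_i - Rbar_j) / sqrt(S^2 *
#' ((N - 1 - H) / (N - k)) * (1/n_i + 1/n_j)) with S^2 the pooled rank
#' variance; two-sided p from the t distribution with N - k df;
#' Benjamini-Hochberg adjustment across the pairs. Calling it without a
#' significant global test is a contract violation unless \code{force}.
#'
#' @param groups named list of >= 2 numeric vectors.
#' @param alpha global significance level guarding the post hoc (default
#'   0.05).
#' @param force run even when the global H-test is not significant.
#' @return data.frame with one row per pair: group labels, rank-mean
#'   difference, t statistic, raw and BH-adjusted p.
#' @export
conoverPosthoc <- function(groups, alpha = 0.05, force = FALSE) {
    stopifnot(length(groups) >= 2L)
    if (is.null(names(groups)))
        names(groups) <- paste0("g", seq_along(groups))
    kw <- kruskalWallis(groups)
    if (!force && kw$p >= alpha)
        stop("global Kruskal-Wallis p = ", signif(kw$p, 3),
             " is not below alpha = ", alpha,
             "; post hoc contract violated (use force = TRUE to override)")
    x <- unlist(groups)
    g <- rep(names(groups), lengths(groups))
    N <- length(x)
    k <- length(groups)
    r <- rank(x)
    rbar <- tapply(r, g, mean)[names(groups)]
    n <- lengths(groups)
    S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
    pairs <- utils::combn(names(groups), 2L)
    stat <- p <- dif <- numeric(ncol(pairs))
    for (c0 in seq_len(ncol(pairs))) {
        i <- pairs[1L, c0]; j <- pairs[2L, c0]
        dif[c0] <- rbar[[i]] - rbar[[j]]
        se <- sqrt(S2 * ((N - 1 - kw$H) / (N - k)) * (1 / n[[i]] + 1 / n[[j]]))
        stat[c0] <- dif[c0] / se
        p[c0] <- 2 * stats::pt(-abs(stat[c0]), df = N - k)
    }
    data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
               rank_mean_diff = dif, t = stat, p = p,
               p_fdr = stats::p.adjust(p, method = "BH"),
               stringsAsFactors = FALSE)
}

#' Age-corrected two-tailed Pearson correlation
#'
#' Residualizes both variables on age (least squares with intercept),
#' correlates the residuals, and tests the correlation two-sided with
#' t = r sqrt((n - 3) / (1 - r^2)) on n - 3 df (one df spent on the
#' covariate). Equivalent to the first-order partial correlation.
#'
#' @param x,y numeric vectors (no missing values; apply listwise deletion
#'   upstream).
#' @param age covariate vector, same length.
#' @return list with \code{r}, \code{p}, \code{n} and \code{df}.
#' @export
pearsonPartialAge <- function(x, y, age) {
    stopifnot(length(x) == length(y), length(x) == length(age))
    if (anyNA(x) || anyNA(y) || anyNA(age))
        stop("missing values: apply listwise deletion before correlating")
    n <- length(x)
    if (n < 4L) stop("age-corrected correlation needs n >= 4")
    rx <- stats::residuals(stats::lm(x ~ age))
    ry <- stats::residuals(stats::lm(y ~ age))
    if (stats::sd(rx) < 1e-300 || stats::sd(ry) < 1e-300)
        stop("zero-variance residuals after age correction")
    r <- stats::cor(rx, ry)
    tt <- r * sqrt((n - 3) / max(1e-300, 1 - r^2))
    list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 3), n = n, df = n - 3L)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise level (default 0.05).
#' @param m number of tests (>= 1); 9 per limb domain in the correlation
#'   analysis, giving 0.05 / 9 which is approximately 0.006.
#' @return \code{alpha / m}.
#' @examples
#' bonferroniAlpha(0.05, 9)
#' @export
bonferroniAlpha <- function(alpha = 0.05, m) {
    if (m < 1) stop("number of tests must be >= 1")
    alpha / m
}

#' Group comparison of one variable (H-test plus conditional post hoc)
#'
#' Runs the Kruskal-Wallis test across groups and, only when the global
#' test is significant at \code{alpha}, the Conover-Iman post hoc with BH
#' FDR correction.
#'
#' @param values numeric vector.
#' @param groups group label per value (NA values dropped pairwise).
#' @param alpha global level (default 0.05).
#' @return list with \code{variable} fields \code{H}, \code{df}, \code{p}
#'   and \code{pairwise} (data.frame or \code{NULL}).
#' @export
compareGroups <- function(values, groups, alpha = 0.05) {
    ok <- !is.na(values) & !is.na(groups)
    values <- values[ok]; groups <- as.character(groups[ok])
    split0 <- split(values, groups)
    kw <- kruskalWallis(split0)
    list(H = kw$H, df = kw$df, p = kw$p,
         n = lengths(split0),
         pairwise = if (kw$p < alpha) conoverPosthoc(split0, alpha) else NULL)
}
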