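# Composite sensorimotor scores: min-max normalization over all
# participants, group-mean imputation for subjects missing strictly fewer
# than half of a domain's tests, unweighted averaging into hand-skill and
# stability sum variables, and Cronbach's alpha for internal consistency.

#' Test definitions for a score domain
#'
#' @param name test/column names.
#' @param domain \code{"hand"} or \code{"stability"} per test.
#' @param higherIsBetter logical per test: \code{TRUE} when a larger raw
#'   score means better performance (e.g. Box-and-Block block count),
#'   \code{FALSE} when smaller is better (e.g. Nine-Hole-Peg time, sway
#'   velocity).
#' @return data.frame of test definitions.
#' @export
testDefinitions <- function(name, domain, higherIsBetter) {
    stopifnot(length(name) == length(domain),
              length(name) == length(higherIsBetter),
              all(domain %in% c("hand", "stability")),
              !anyDuplicated(name))
    data.frame(name = name, domain = domain,
               higherIsBetter = higherIsBetter, stringsAsFactors = FALSE)
}

#' Min-max normalize one test's raw scores
#'
#' Maps the best observed performance in the sample to 1 and the worst to
#' 0, linearly in between; for tests where lower raw values are better the
#' mapping is reversed so 1 is always best. Missing values pass through as
#' missing.
#'
#' @param x raw scores (may contain \code{NA}).
#' @param higherIsBetter orientation flag (see [testDefinitions()]).
#' @return Normalized scores in \eqn{[0, 1]} with \code{NA}s preserved.
#' @export
minmaxNormalize <- function(x, higherIsBetter = TRUE) {
    obs <- x[!is.na(x)]
    if (length(unique(obs)) < 2L)
        stop("degenerate test: fewer than 2 distinct observed values")
    r <- range(obs)
    out <- (x - r[1L]) / (r[2L] - r[1L])
    if (!higherIsBetter) out <- 1 - out
    out
}

#' Group-mean imputation of normalized scores
#'
#' For subjects missing strictly fewer than half of the domain's tests,
#' each missing cell is replaced by the mean of that test's observed
#' normalized values within the subject's group (TD, HP or DP), which
#' leaves every test's group mean unchanged. Subjects missing half or more
#' get no imputation and are marked undefined.
#'
#' @param norm matrix of normalized scores, subjects x tests (row names =
#'   subject ids).
#' @param groups character vector of group labels, one per row of
#'   \code{norm}.
#' @return list with \code{completed} (matrix; cells of undefined subjects
#'   left \code{NA}), \code{defined} (logical per subject), \code{nImputed}
#'   (integer per subject) and \code{log} (data.frame of imputed cells).
#' @export
imputeMissing <- function(norm, groups) {
    stopifnot(is.matrix(norm), length(groups) == nrow(norm))
    k <- ncol(norm)
    nMiss <- rowSums(is.na(norm))
    defined <- nMiss < k / 2
    completed <- norm
    logRows <- list()
    for (i in which(defined & nMiss > 0L)) {
        for (j in which(is.na(norm[i, ]))) {
            sameGroup <- groups == groups[i]
            obs <- norm[sameGroup, j]
            obs <- obs[!is.na(obs)]
            if (length(obs) == 0L)
                stop("cannot impute: no observed values for test '",
                     colnames(norm)[j], "' in group ", groups[i])
            completed[i, j] <- mean(obs)
            logRows[[length(logRows) + 1L]] <-
                data.frame(subject = rownames(norm)[i] %||% i,
                           test = colnames(norm)[j] %||% j,
                           group = groups[i], value = mean(obs))
        }
    }
    list(completed = completed, defined = defined,
         nImputed = ifelse(defined, nMiss, 0L),
         log = if (length(logRows)) do.call(rbind, logRows)
               else data.frame(subject = character(0), test = character(0),
                               group = character(0), value = numeric(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sum variable: per-subject mean of a domain's normalized scores
#'
#' @param completed completed (imputed) normalized score matrix.
#' @param defined logical per subject from [imputeMissing()]; undefined
#'   subjects get \code{NA}.
#' @return Numeric vector of sum-variable values in \eqn{[0, 1]}.
#' @export
sumVariable <- function(completed, defined = rep(TRUE, nrow(completed))) {
    out <- rowMeans(completed)
    out[!defined] <- NA_real_
    out
}

#' Cronbach's alpha of a score matrix
#'
#' alpha = k/(k-1) * (1 - sum(var(item_i)) / var(sum(items))), with sample
#' variances over complete rows only (imputed rows are not used, so
#' imputation cannot inflate the consistency estimate). 0.8 is taken as the
#' limit for good internal consistency.
#'
#' @param m numeric matrix, subjects x items (>= 2 items, >= 3 complete
#'   rows).
#' @param limit pass threshold (default 0.8).
#' @return list with \code{alpha}, \code{pass}, \code{k} and \code{n}.
#' @export
cronbachAlpha <- function(m, limit = 0.8) {
    stopifnot(is.matrix(m), ncol(m) >= 2L)
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) < 3L)
        stop("Cronbach's alpha needs at least 3 complete rows")
    k <- ncol(m)
    total <- stats::var(rowSums(m))
    if (total < 1e-300) stop("zero total score variance")
    alpha <- k / (k - 1) * (1 - sum(apply(m, 2L, stats::var)) / total)
    list(alpha = alpha, pass = alpha >= limit, k = k, n = nrow(m))
}

#' Build hand-skill and stability sum variables for a cohort
#'
#' Runs the full composite-score chain: pooled min-max normalization per
#' test, group-mean imputation per domain, unweighted averaging into the
#' domain sum variable, and Cronbach's alpha on complete rows of the
#' normalized scores.
#'
#' @param subjects subject data.frame (id, group, plus raw score columns).
#' @param defs test definitions ([testDefinitions()]); every \code{name}
#'   must be a column of \code{subjects}.
#' @return list with \code{scores} (data.frame: id, group, hand, stability,
#'   n-imputed counts), \code{normalized} (matrix), \code{alpha} (named
#'   list per domain) and \code{imputationLog}.
#' @export
buildSumVariables <- function(subjects, defs) {
    miss <- setdiff(defs$name, names(subjects))
    if (length(miss))
        stop("score column(s) not in subject table: ",
             paste(miss, collapse = ", "))
    norm <- sapply(seq_len(nrow(defs)), function(j)
        minmaxNormalize(subjects[[defs$name[j]]], defs$higherIsBetter[j]))
    dimnames(norm) <- list(subjects$id, defs$name)
    out <- data.frame(id = subjects$id, group = subjects$group,
                      stringsAsFactors = FALSE)
    alphas <- list()
    logs <- list()
    for (dom in unique(defs$domain)) {
        cols <- defs$name[defs$domain == dom]
        imp <- imputeMissing(norm[, cols, drop = FALSE], subjects$group)
        out[[dom]] <- sumVariable(imp$completed, imp$defined)
        out[[paste0(dom, "_imputed")]] <- imp$nImputed
        alphas[[dom]] <- cronbachAlpha(norm[, cols, drop = FALSE])
        logs[[dom]] <- imp$log
    }
    list(scores = out, normalized = norm, alpha = alphas,
         imputationLog = do.call(rbind, logs))
}
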