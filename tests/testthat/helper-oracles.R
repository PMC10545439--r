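# Independent brute-force oracles. These are deliberately naive loop
# implementations, kept separate from the package's code paths so each
# operation can be checked against an independently coded reference.

# trilinear interpolation as an explicit 8-corner weighted sum
oracleTrilinear <- function(v, p) {
    vox <- drop(solve(affine(v)) %*% c(p, 1))[1:3]
    dm <- dim(voxelData(v))
    vox <- pmin(pmax(vox, 0), dm - 1)
    i0 <- floor(vox)
    w <- vox - i0
    val <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        ix <- min(i0[1] + dx, dm[1] - 1)
        iy <- min(i0[2] + dy, dm[2] - 1)
        iz <- min(i0[3] + dz, dm[3] - 1)
        wt <- (if (dx) w[1] else 1 - w[1]) *
              (if (dy) w[2] else 1 - w[2]) *
              (if (dz) w[3] else 1 - w[3])
        val <- val + wt * voxelData(v)[ix + 1, iy + 1, iz + 1]
    }
    val
}

# mid-ranks by counting
oracleRanks <- function(x) {
    sapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2)
}

# Kruskal-Wallis H with tie correction, from the rank-sum formula
oracleKW <- function(groups) {
    x <- unlist(groups)
    N <- length(x)
    r <- oracleRanks(x)
    idx <- rep(seq_along(groups), lengths(groups))
    H0 <- 0
    for (j in seq_along(groups)) {
        Rj <- sum(r[idx == j])
        H0 <- H0 + Rj^2 / length(groups[[j]])
    }
    H0 <- 12 / (N * (N + 1)) * H0 - 3 * (N + 1)
    tie <- table(x)
    C <- 1 - sum(tie^3 - tie) / (N^3 - N)
    H <- H0 / C
    list(H = H, p = stats::pchisq(H, length(groups) - 1, lower.tail = FALSE))
}

# Conover-Iman pairwise statistics from first principles
oracleConover <- function(groups) {
    x <- unlist(groups)
    idx <- rep(seq_along(groups), lengths(groups))
    N <- length(x)
    k <- length(groups)
    r <- oracleRanks(x)
    H <- oracleKW(groups)$H
    S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
    out <- NULL
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
        ri <- mean(r[idx == i]); rj <- mean(r[idx == j])
        ni <- sum(idx == i); nj <- sum(idx == j)
        tt <- (ri - rj) / sqrt(S2 * ((N - 1 - H) / (N - k)) * (1 / ni + 1 / nj))
        out <- rbind(out, data.frame(i = i, j = j, t = tt,
                                     p = 2 * stats::pt(-abs(tt), N - k)))
    }
    out
}

# first-order partial correlation from the three pairwise Pearson r's
oraclePartialR <- function(x, y, age) {
    rxy <- stats::cor(x, y)
    rxa <- stats::cor(x, age)
    rya <- stats::cor(y, age)
    (rxy - rxa * rya) / sqrt((1 - rxa^2) * (1 - rya^2))
}

# Cronbach's alpha in covariance form: k/(k-1) * (1 - tr(C)/sum(C))
oracleAlpha <- function(m) {
    C <- stats::cov(m)
    k <- ncol(m)
    k / (k - 1) * (1 - sum(diag(C)) / sum(C))
}

# lattice-point enumeration for spherical dilation on an isotropic grid
oracleDilationCount <- function(radius, spacing = 1) {
    reach <- ceiling(radius / spacing)
    cnt <- 0L
    for (i in -reach:reach) for (j in -reach:reach) for (k in -reach:reach)
        if ((i^2 + j^2 + k^2) * spacing^2 <= radius^2 + 1e-9)
            cnt <- cnt + 1L
    cnt
}

# along-tract median by explicit per-index loops over sample vectors
oracleProfileMedian <- function(samples, minSupport = 5) {
    values <- numeric(0)
    support <- integer(0)
    k <- 1
    repeat {
        have <- Filter(function(s) length(s) >= k, samples)
        if (length(have) < minSupport) break
        values <- c(values, stats::median(sapply(have, `[`, k)))
        support <- c(support, length(have))
        k <- k + 1
    }
    list(values = values, support = support)
}

# streamline-mode whole-tract mean as a plain double loop
oracleBundleMean <- function(b, v) {
    tot <- 0
    for (m in streamlines(b)) {
        s <- 0
        for (r in seq_len(nrow(m))) s <- s + oracleTrilinear(v, m[r, ])
        tot <- tot + s / nrow(m)
    }
    tot / length(streamlines(b))
}

# voxel visitation by dense 0.1 mm walking, one count per streamline/voxel
oracleTDI <- function(b, grid) {
    dm <- dim(voxelData(grid))
    inv <- solve(affine(grid))
    counts <- array(0, dm)
    for (m in streamlines(b)) {
        seen <- character(0)
        for (r in seq_len(nrow(m) - 1)) {
            a <- m[r, ]; bpt <- m[r + 1, ]
            L <- sqrt(sum((bpt - a)^2))
            for (s in seq(0, L, by = 0.1)) {
                p <- a + (bpt - a) * (if (L > 0) s / L else 0)
                vox <- round(drop(inv %*% c(p, 1))[1:3])
                if (any(vox < 0) || any(vox >= dm)) next
                key <- paste(vox, collapse = ",")
                if (!key %in% seen) {
                    seen <- c(seen, key)
                    counts[vox[1] + 1, vox[2] + 1, vox[3] + 1] <-
                        counts[vox[1] + 1, vox[2] + 1, vox[3] + 1] + 1
                }
            }
            # include the exact segment endpoint
            vox <- round(drop(inv %*% c(bpt, 1))[1:3])
            if (!(any(vox < 0) || any(vox >= dm))) {
                key <- paste(vox, collapse = ",")
                if (!key %in% seen) {
                    seen <- c(seen, key)
                    counts[vox[1] + 1, vox[2] + 1, vox[3] + 1] <-
                        counts[vox[1] + 1, vox[2] + 1, vox[3] + 1] + 1
                }
            }
        }
    }
    counts
}
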