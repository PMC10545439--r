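# Programmatic fixtures shared across test files.

# volume with value a*x + b*y + c*z + d at world coordinates, identity
# affine (world == voxel index)
linearFieldVolume <- function(dm = c(8, 8, 8), coef = c(2, 3, 1), intercept = 0) {
    idx <- arrayInd(seq_len(prod(dm)), dm) - 1
    vals <- idx %*% coef + intercept
    scalarVolume(array(vals, dm))
}

randomVolume <- function(dm = c(6, 7, 5), affine = NULL) {
    if (is.null(affine)) {
        affine <- diag(4)
        diag(affine)[1:3] <- runif(3, 0.5, 2)
        affine[1:3, 4] <- runif(3, -5, 5)
    }
    scalarVolume(array(rnorm(prod(dm)), dm), affine = affine)
}

# n random smooth streamlines inside the world box spanned by a volume
randomStreamlineSet <- function(v, n = 3, npts = 8) {
    dm <- dim(voxelData(v))
    lo <- voxelToWorld(v, c(0.6, 0.6, 0.6))
    hi <- voxelToWorld(v, dm - 1.6)
    sl <- lapply(seq_len(n), function(i) {
        base <- matrix(runif(3, 0, 1), npts, 3, byrow = TRUE)
        drift <- outer(seq(0, 1, length.out = npts), runif(3, -1, 1))
        m <- sweep(sweep(0.5 + 0.35 * sin(base * 6 + drift), 2, hi - lo, "*"),
                   2, lo, "+")
        m + matrix(rnorm(npts * 3, 0, 0.05), npts, 3)
    })
    streamlineSet(sl)
}

# straight axis-aligned streamline from p along unit direction d, length L,
# with points every `step` mm
straightStreamline <- function(p = c(0, 0, 0), d = c(0, 0, 1), L = 10, step = 1) {
    s <- seq(0, L, by = step)
    sweep(outer(s, d), 2, p, "+")
}

# tiny phantom for fast end-to-end pipeline tests
tinyPhantomSpec <- function(...) {
    phantomSpec(dim = c(32L, 32L, 32L), nStreamlines = 8L, bow = 3,
                thalamusRadius = 2.5, tubeRadius = 1.2, ...)
}

# deterministic per-test RNG scope
withSeed <- function(seed, code) {
    old <- if (exists(".Random.seed", .GlobalEnv)) .Random.seed else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    force(code)
}
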