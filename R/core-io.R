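# I/O for the standard formats the pipeline touches, plus the coordinate
# contract shared by all modules: world frame is the NIfTI affine's output
# (RAS mm), voxel indices are 0-based with the voxel center at the integer
# index. TRK's voxel-corner origin convention is normalized at read time so
# downstream code never branches on dialect.

#' Read a NIfTI volume
#'
#' @param path path to a NIfTI-1 file (.nii or .nii.gz).
#' @param units optional unit tag to attach (e.g. \code{"mm^2/s"} for MD).
#' @return A [ScalarVolume-class].
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(scalarVolume(array(1, c(3, 3, 3))), f)
#' v <- readVolume(f)
#' @export
readVolume <- function(path, units = "") {
    if (!file.exists(path))
        stop("volume file not found: ", path)
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e)
                        stop("cannot read NIfTI volume '", path, "': ",
                             conditionMessage(e), call. = FALSE))
    dm <- dim(img)
    if (length(dm) > 3L) {
        if (prod(dm[-(1:3)]) != 1L)
            stop("volume '", path, "' has more than 3 non-singleton dimensions")
        dm <- dm[1:3]
    }
    dat <- array(as.numeric(img), dim = dm)
    scalarVolume(dat, affine = unclass(RNifti::xform(img)), units = units)
}

#' Write a NIfTI volume
#'
#' @param v a [ScalarVolume-class].
#' @param path output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(v, path) {
    stopifnot(is(v, "ScalarVolume"))
    img <- RNifti::asNifti(v@data)
    # pixdim must be set before the sform; the qform is left unset because
    # its quaternion form cannot represent shears exactly
    RNifti::pixdim(img) <- .voxelSpacing(v@affine)
    RNifti::sform(img) <- structure(v@affine, code = 2L)
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Map world-mm points to continuous voxel indices
#'
#' Applies the inverse affine. Indices are 0-based and continuous;
#' out-of-grid indices are legal outputs (consumers decide what to do).
#'
#' @param v a [ScalarVolume-class] supplying the affine.
#' @param p a world-mm point (length-3 vector) or an n x 3 matrix.
#' @return Continuous 0-based voxel coordinates, same shape as \code{p}.
#' @examples
#' v <- scalarVolume(array(0, c(5, 5, 5)))
#' worldToVoxel(v, c(1.5, 2, 0))
#' @export
worldToVoxel <- function(v, p) {
    vec <- !is.matrix(p)
    out <- .applyAffine(.affineInverse(v@affine), p)
    if (vec) drop(out) else out
}

#' Map voxel indices to world mm
#'
#' @param v a [ScalarVolume-class].
#' @param idx 0-based voxel indices (vector or n x 3 matrix), possibly
#'   continuous.
#' @return World-mm coordinates.
#' @export
voxelToWorld <- function(v, idx) {
    vec <- !is.matrix(idx)
    out <- .applyAffine(v@affine, idx)
    if (vec) drop(out) else out
}

## ---- TCK (MRtrix) ----------------------------------------------------------

.writeTCK <- function(s, path) {
    sl <- s@streamlines
    fixed <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ",
                    length(sl), "\nfile: . ")
    # the offset figure is part of the header, so settle its width iteratively
    offset <- nchar(fixed, type = "bytes") + nchar("END\n") + 1L
    repeat {
        new <- nchar(fixed, type = "bytes") + nchar(as.character(offset)) +
            nchar("\nEND\n")
        if (new == offset) break
        offset <- new
    }
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0(fixed, offset, "\nEND\n"), con, eos = NULL)
    for (m in sl) {
        writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
        writeBin(rep(NaN, 3L), con, size = 4L, endian = "little")
    }
    writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
    invisible(path)
}

.readTCK <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    header <- character()
    nbytes <- 0L
    repeat {
        line <- readLines(con, n = 1L, warn = FALSE)
        if (length(line) == 0L)
            stop("truncated TCK header in '", path, "'")
        nbytes <- nbytes + nchar(line, type = "bytes") + 1L
        if (identical(line, "END")) break
        header <- c(header, line)
        if (length(header) > 1000L)
            stop("unterminated TCK header in '", path, "'")
    }
    if (!length(header) || header[1L] != "mrtrix tracks")
        stop("'", path, "' is not a TCK file (bad magic line)")
    kv <- header[grepl(":", header, fixed = TRUE)]
    keys <- sub(":.*$", "", kv)
    vals <- trimws(sub("^[^:]*:", "", kv))
    datatype <- vals[match("datatype", keys)]
    if (is.na(datatype)) datatype <- "Float32LE"
    endian <- if (grepl("BE$", datatype)) "big" else "little"
    size <- if (grepl("^Float64", datatype)) 8L else 4L
    if (!grepl("^Float(32|64)(LE|BE)$", datatype))
        stop("unsupported TCK datatype '", datatype, "'")
    offset <- suppressWarnings(as.numeric(sub("^\\.\\s*", "",
                                              vals[match("file", keys)])))
    if (is.na(offset)) offset <- nbytes
    count <- suppressWarnings(as.integer(vals[match("count", keys)]))
    seek(con, where = offset, origin = "start")
    raw <- readBin(con, what = "numeric", n = file.size(path), size = size,
                   endian = endian)
    if (length(raw) %% 3L != 0L)
        stop("TCK body length is not a multiple of 3 in '", path, "'")
    pts <- matrix(raw, ncol = 3L, byrow = TRUE)
    isEnd <- apply(pts, 1L, function(r) all(is.infinite(r)))
    if (!any(isEnd))
        stop("TCK body missing end-of-file marker in '", path, "'")
    pts <- pts[seq_len(which(isEnd)[1L] - 1L), , drop = FALSE]
    sep <- c(0L, which(apply(pts, 1L, function(r) all(is.nan(r)))),
             nrow(pts) + 1L)
    sl <- list()
    for (i in seq_len(length(sep) - 1L)) {
        if (sep[i] + 1L > sep[i + 1L] - 1L) next
        sl[[length(sl) + 1L]] <- pts[seq(sep[i] + 1L, sep[i + 1L] - 1L), ,
                                     drop = FALSE]
    }
    if (!is.na(count) && count != length(sl))
        stop("TCK header count (", count, ") does not match body (",
             length(sl), ") in '", path, "'")
    streamlineSet(sl)
}

## ---- TRK (TrackVis) --------------------------------------------------------

# TRK stores points in "voxmm": voxel index scaled by voxel size, with the
# origin at the corner of voxel (0,0,0) (voxel center i sits at
# (i + 0.5) * voxel_size). world = A %*% (voxmm / voxel_size - 0.5).

.writeTRK <- function(s, path, affine = diag(4)) {
    vs <- .voxelSpacing(affine)
    inv <- .affineInverse(affine)
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar("TRACK", con, nchars = 5L, eos = NULL)
    writeBin(raw(1L), con)                                   # id_string pad
    writeBin(as.integer(c(0L, 0L, 0L)), con, size = 2L, endian = "little")
    writeBin(as.numeric(vs), con, size = 4L, endian = "little")
    writeBin(numeric(3L), con, size = 4L, endian = "little") # origin (unused)
    writeBin(0L, con, size = 2L, endian = "little")          # n_scalars
    writeBin(raw(200L), con)                                 # scalar names
    writeBin(0L, con, size = 2L, endian = "little")          # n_properties
    writeBin(raw(200L), con)                                 # property names
    writeBin(as.numeric(t(affine)), con, size = 4L, endian = "little")
    writeBin(raw(444L), con)                                 # reserved
    writeChar("RAS", con, nchars = 3L, eos = NULL)
    writeBin(raw(1L), con)
    writeBin(raw(4L), con)                                   # pad2
    writeBin(numeric(6L), con, size = 4L, endian = "little") # image orientation
    writeBin(raw(2L), con)                                   # pad1
    writeBin(raw(6L), con)                                   # invert/swap flags
    writeBin(length(s@streamlines), con, size = 4L, endian = "little")
    writeBin(2L, con, size = 4L, endian = "little")          # version
    writeBin(1000L, con, size = 4L, endian = "little")       # hdr_size
    for (m in s@streamlines) {
        vox <- .applyAffine(inv, m)                          # voxel indices
        voxmm <- sweep(vox + 0.5, 2L, vs, "*")
        writeBin(nrow(m), con, size = 4L, endian = "little")
        writeBin(as.numeric(t(voxmm)), con, size = 4L, endian = "little")
    }
    invisible(path)
}

.readTRK <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readChar(con, nchars = 5L, useBytes = TRUE)
    if (!identical(magic, "TRACK"))
        stop("'", path, "' is not a TRK file (bad magic)")
    readBin(con, "raw", n = 1L)
    invisible(readBin(con, "integer", n = 3L, size = 2L, endian = "little"))
    vs <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
    invisible(readBin(con, "numeric", n = 3L, size = 4L, endian = "little"))
    nScalars <- readBin(con, "integer", n = 1L, size = 2L, endian = "little")
    readBin(con, "raw", n = 200L)
    nProps <- readBin(con, "integer", n = 1L, size = 2L, endian = "little")
    readBin(con, "raw", n = 200L)
    A <- matrix(readBin(con, "numeric", n = 16L, size = 4L, endian = "little"),
                nrow = 4L, byrow = TRUE)
    readBin(con, "raw", n = 444L + 4L + 4L + 24L + 2L + 6L)
    nCount <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    version <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    hdrSize <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (!identical(hdrSize, 1000L))
        stop("TRK header size field is ", hdrSize, ", expected 1000, in '",
             path, "'")
    if (version < 2L || all(A == 0)) A <- diag(4)           # unfilled matrix
    if (any(vs <= 0)) vs <- rep(1, 3L)
    sl <- list()
    repeat {
        n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
        if (length(n) == 0L) break
        vals <- readBin(con, "numeric", n = n * (3L + nScalars) + nProps,
                        size = 4L, endian = "little")
        if (length(vals) < n * (3L + nScalars) + nProps)
            stop("truncated TRK body in '", path, "'")
        m <- matrix(vals[seq_len(n * (3L + nScalars))],
                    ncol = 3L + nScalars, byrow = TRUE)[, 1:3, drop = FALSE]
        vox <- sweep(m, 2L, vs, "/") - 0.5
        sl[[length(sl) + 1L]] <- .applyAffine(A, vox)
    }
    if (nCount > 0L && nCount != length(sl))
        stop("TRK header count (", nCount, ") does not match body (",
             length(sl), ") in '", path, "'")
    streamlineSet(sl)
}

#' Read streamlines (TCK or TRK)
#'
#' The dialect is chosen by file extension. All polylines are returned in
#' world mm per each format's own header transform; TRK's voxel-corner
#' origin convention is converted to the shared world frame.
#'
#' @param path path ending in \code{.tck} or \code{.trk}.
#' @return A [StreamlineSet-class].
#' @export
readStreamlines <- function(path) {
    if (!file.exists(path))
        stop("streamline file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    switch(ext,
           tck = .readTCK(path),
           trk = .readTRK(path),
           stop("unknown streamline format '.", ext, "' for '", path,
                "' (expected .tck or .trk)"))
}

#' Write streamlines (TCK or TRK)
#'
#' @param s a [StreamlineSet-class] (world mm).
#' @param path output path ending in \code{.tck} or \code{.trk}.
#' @param affine voxel-to-world affine recorded in TRK headers (ignored for
#'   TCK, which stores world coordinates directly).
#' @return \code{path}, invisibly.
#' @export
writeStreamlines <- function(s, path, affine = diag(4)) {
    stopifnot(is(s, "StreamlineSet"))
    ext <- tolower(tools::file_ext(path))
    switch(ext,
           tck = .writeTCK(s, path),
           trk = .writeTRK(s, path, affine = affine),
           stop("unknown streamline format '.", ext, "'"))
}

## ---- subject tables --------------------------------------------------------

#' Read a per-subject table of scores and covariates
#'
#' Expects a header row with at least \code{id}, \code{group} (TD/HP/DP),
#' \code{dominance} (left/right) and \code{age} columns; remaining columns
#' are treated as test scores. Empty cells and \code{"NA"} both parse to
#' missing.
#'
#' @param path CSV path.
#' @return A validated \code{data.frame}.
#' @export
readSubjectTable <- function(path) {
    df <- utils::read.csv(path, na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
    validateSubjectTable(df)
    df
}

#' Validate a subject table against the shared vocabulary
#'
#' @param df data.frame with id, group, dominance and age columns.
#' @return \code{df}, invisibly; stops on violation.
#' @export
validateSubjectTable <- function(df) {
    need <- c("id", "group", "dominance", "age")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("subject table is missing column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(df$id))
        stop("subject ids must be unique")
    if (!all(df$group %in% c("TD", "HP", "DP")))
        stop("group must be one of TD, HP, DP")
    if (!all(df$dominance %in% c("left", "right")))
        stop("dominance must be 'left' or 'right'")
    if (!all(is.finite(df$age)) || any(df$age <= 0))
        stop("age must be positive")
    invisible(df)
}

#' Write a subject table
#' @param df subject data.frame.
#' @param path CSV output path.
#' @return \code{path}, invisibly.
#' @export
writeSubjectTable <- function(df, path) {
    utils::write.csv(df, path, row.names = FALSE, na = "")
    invisible(path)
}
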