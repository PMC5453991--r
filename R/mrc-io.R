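# MRC2014/CCP4 volume I/O.
#
# The 1024-byte header is parsed field by field; data are returned with the
# file axis permutation (MAPC/MAPR/MAPS) resolved, so the in-memory array is
# always in canonical x,y,z order.

.parseMRCHeader <- function(raw1024, endian) {
    int <- function(off, n = 1L)
        readBin(raw1024[(off * 4L + 1L):(off * 4L + 4L * n)], integer(),
                n = n, size = 4L, endian = endian)
    flt <- function(off, n = 1L)
        readBin(raw1024[(off * 4L + 1L):(off * 4L + 4L * n)], numeric(),
                n = n, size = 4L, endian = endian)
    list(
        nc = int(0L, 3L),          # grid counts along columns/rows/sections
        mode = int(3L),
        nstart = int(4L, 3L),      # start indices (crs order)
        m = int(7L, 3L),           # sampling along cell X, Y, Z
        cella = flt(10L, 3L),      # cell dimensions (Angstrom)
        cellb = flt(13L, 3L),
        mapcrs = int(16L, 3L),     # axis ids of columns/rows/sections
        dstats = flt(19L, 3L),
        ispg = int(22L),
        nsymbt = int(23L),
        origin = flt(49L, 3L),     # Angstrom, x,y,z
        mapstamp = rawToChar(raw1024[209:212]),
        rms = flt(54L),
        endian = endian
    )
}

#' Read an MRC2014/CCP4 density map
#'
#' Reads the volume, resolves the header axis permutation so the returned
#' array is in x,y,z order, and derives the voxel size from the cell
#' dimensions and sampling counts. When both the origin fields and the start
#' indices are set and disagree, the origin fields take precedence (with a
#' warning).
#'
#' @param path path to an MRC/CCP4 file.
#' @param resolutionHint optional nominal resolution (Angstrom) to attach.
#' @return A \linkS4class{GridMap}.
#' @export
readMap <- function(path, resolutionHint = NA_real_) {
    con <- file(path, "rb")
    on.exit(close(con))
    raw1024 <- readBin(con, raw(), 1024L)
    if (length(raw1024) < 1024L)
        stop("malformed MRC header: file shorter than 1024 bytes")
    h <- .parseMRCHeader(raw1024, "little")
    sane <- function(h) all(h$nc > 0L) && all(h$nc < 1e6) &&
        h$mode %in% c(0L, 1L, 2L, 6L)
    if (!sane(h)) {
        h <- .parseMRCHeader(raw1024, "big")
        if (!sane(h))
            stop("malformed MRC header: implausible NX/NY/NZ or unsupported MODE field")
    }
    if (!setequal(h$mapcrs, 1:3))
        stop("malformed MRC header: MAPC/MAPR/MAPS is not a permutation of 1,2,3")
    if (any(h$m <= 0L))
        stop("malformed MRC header: MX/MY/MZ must be positive")
    if (any(h$cella <= 0))
        stop("malformed MRC header: CELLA must be positive")

    nvox <- prod(h$nc)
    if (h$nsymbt > 0L) readBin(con, raw(), h$nsymbt)
    data <- switch(as.character(h$mode),
        "0" = as.numeric(readBin(con, integer(), nvox, size = 1L,
                                 signed = TRUE, endian = h$endian)),
        "1" = as.numeric(readBin(con, integer(), nvox, size = 2L,
                                 signed = TRUE, endian = h$endian)),
        "2" = readBin(con, numeric(), nvox, size = 4L, endian = h$endian),
        "6" = as.numeric(readBin(con, integer(), nvox, size = 2L,
                                 signed = FALSE, endian = h$endian)))
    if (length(data) != nvox)
        stop("malformed MRC file: data section shorter than NX*NY*NZ")
    arr <- array(data, dim = h$nc)

    # canonicalise axis order: file dim i carries axis mapcrs[i]
    perm <- match(1:3, h$mapcrs)
    if (any(perm != 1:3)) arr <- aperm(arr, perm)
    nstartXYZ <- h$nstart[perm]

    voxel <- h$cella / h$m
    if (max(voxel) - min(voxel) > 1e-4 * mean(voxel))
        warning(sprintf("non-cubic voxels: %.4f %.4f %.4f Angstrom",
                        voxel[1], voxel[2], voxel[3]))

    originField <- h$origin
    originStart <- nstartXYZ * voxel
    if (any(abs(originField) > 1e-6)) {
        origin <- originField
        if (any(abs(nstartXYZ) > 0L) &&
            any(abs(originField - originStart) > 1e-3))
            warning("origin fields and start indices disagree; using origin fields")
    } else {
        origin <- originStart
    }

    GridMap(arr, voxelSize = voxel, origin = origin,
            resolutionHint = resolutionHint, axisOrder = h$mapcrs)
}

#' Write a GridMap as an MRC2014 file
#'
#' Writes mode-2 (float32) data in canonical x,y,z axis order with the voxel
#' size encoded as cell length / sampling and the origin stored in the
#' MRC2014 origin fields.
#'
#' @param map a \linkS4class{GridMap}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeMap <- function(map, path) {
    stopifnot(is(map, "GridMap"))
    con <- tryCatch(file(path, "wb"),
                    error = function(e) stop("cannot open for writing: ", path))
    on.exit(close(con))
    d <- dim(map@data)
    wInt <- function(x) writeBin(as.integer(x), con, size = 4L,
                                 endian = "little")
    wFlt <- function(x) writeBin(as.numeric(x), con, size = 4L,
                                 endian = "little")
    wInt(d)                              # NX NY NZ
    wInt(2L)                             # MODE float32
    wInt(c(0L, 0L, 0L))                  # NXSTART..
    wInt(d)                              # MX MY MZ
    wFlt(d * map@voxelSize)              # CELLA
    wFlt(c(90, 90, 90))                  # CELLB
    wInt(1:3)                            # MAPC MAPR MAPS
    wFlt(c(min(map@data), max(map@data), mean(map@data)))
    wInt(c(1L, 0L))                      # ISPG, NSYMBT
    wInt(rep(0L, 2L))                    # EXTRA words 25-26
    writeChar("MRCO", con, nchars = 4L, eos = NULL)  # EXTTYP
    wInt(20140L)                         # NVERSION
    wInt(rep(0L, 21L))                   # remaining EXTRA
    wFlt(map@origin)                     # ORIGIN x y z
    writeChar("MAP ", con, nchars = 4L, eos = NULL)
    writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
    wFlt(stats::sd(map@data))            # RMS
    wInt(1L)                             # NLABL
    lab <- sprintf("%-80s", "Written by cryobuild")
    writeChar(lab, con, nchars = 80L, eos = NULL)
    writeChar(paste(rep(" ", 80L * 9L), collapse = ""), con,
              nchars = 80L * 9L, eos = NULL)
    writeBin(as.numeric(map@data), con, size = 4L, endian = "little")
    invisible(path)
}
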