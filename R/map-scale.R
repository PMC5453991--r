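# "Map simulation": put a reference map on the working map's amplitude
# scale by interpolating the reference ln(F) radial profile onto the
# working one (Guinier-style lnF vs d^-2 analysis), clamping the
# low-resolution region at d = 10 Angstrom, then low-pass filtering to the
# working resolution.

.LOWRES_CLAMP <- 10  # Angstrom

# Radial shell index and shell centre frequencies for a map's FFT.
.shellIndex <- function(dims, voxel) {
    f <- .freqGrid(dims, voxel)
    df <- 1 / max(dims * voxel)  # one Fourier pixel
    idx <- pmax(1L, as.integer(round(f / df)) + 1L)
    list(f = f, idx = idx, df = df, nShell = max(idx))
}

#' Guinier curve of a map
#'
#' Radially averaged Fourier amplitudes: for each shell (one Fourier pixel
#' wide), \code{lnF = ln(mean |F|)} plotted against \code{d^-2 = f^2}. The
#' map is mean-subtracted first (the DC term is excluded).
#'
#' @param map a \linkS4class{GridMap}.
#' @param nShells optionally merge to at most this many shells.
#' @return data.frame with columns \code{f} (shell centre spatial frequency,
#'   1/Angstrom), \code{d2inv} (= f^2, 1/Angstrom^2), \code{lnF}, and
#'   \code{n} (Fourier voxels in the shell), ordered by increasing d2inv.
#' @export
guinierCurve <- function(map, nShells = NULL) {
    stopifnot(is(map, "GridMap"))
    d <- dim(map@data)
    sh <- .shellIndex(d, map@voxelSize)
    F <- fft(map@data - mean(map@data))
    amp <- as.vector(Mod(F))
    idx <- as.vector(sh$idx)
    # exclude the (zeroed) DC voxel from shell 1
    dc <- 1L
    amp <- amp[-dc]; idx <- idx[-dc]
    sums <- tapply(amp, idx, sum)
    ns <- tapply(amp, idx, length)
    shells <- as.integer(names(sums))
    fc <- (shells - 1L) * sh$df
    keep <- ns > 0
    out <- data.frame(f = fc[keep], d2inv = fc[keep]^2,
                      lnF = log(pmax(sums[keep] / ns[keep], 1e-300)),
                      n = as.integer(ns[keep]))
    out <- out[order(out$d2inv), ]
    rownames(out) <- NULL
    if (!is.null(nShells) && nrow(out) > nShells) {
        grp <- ceiling(seq_len(nrow(out)) / (nrow(out) / nShells))
        out <- do.call(rbind, lapply(split(out, grp), function(s) {
            data.frame(f = stats::weighted.mean(s$f, s$n),
                       d2inv = stats::weighted.mean(s$d2inv, s$n),
                       lnF = log(stats::weighted.mean(exp(s$lnF), s$n)),
                       n = sum(s$n))
        }))
        rownames(out) <- NULL
    }
    out
}

#' Scale a reference map onto the working map's amplitude profile
#'
#' Applies a per-shell multiplicative correction
#' \code{exp(lnF_work - lnF_ref)} to the reference Fourier amplitudes
#' (phases untouched), linearly interpolating the correction between shell
#' centres for off-centre Fourier voxels. Below the resolution of the
#' low-resolution clamp (d >= 10 Angstrom) the correction is held at its
#' value at the shell nearest 10 Angstrom, preventing the strong
#' low-resolution terms from being overweighted. The scaled map is then
#' low-pass filtered to the working resolution.
#'
#' @param reference the reference \linkS4class{GridMap}.
#' @param working the working \linkS4class{GridMap}.
#' @param workingResolution resolution of the working map in Angstrom
#'   (defaults to the working map's resolution hint).
#' @return The scaled, filtered reference \linkS4class{GridMap}.
#' @export
scaleReference <- function(reference, working,
                           workingResolution = resolutionHint(working)) {
    stopifnot(is(reference, "GridMap"), is(working, "GridMap"))
    if (is.na(workingResolution))
        stop("workingResolution is required (no resolution hint on the working map)")
    gw <- guinierCurve(working)
    gr <- guinierCurve(reference)

    # correction (log scale) on the working shell grid, interpolated onto
    # arbitrary frequencies; outside either curve's range, extend flat
    lnFw <- stats::approxfun(gw$f, gw$lnF, rule = 2)
    lnFr <- stats::approxfun(gr$f, gr$lnF, rule = 2)
    fClamp <- 1 / .LOWRES_CLAMP
    corrAt <- function(f) {
        fEff <- pmax(f, fClamp)  # d >= 10 A: use the correction near 10 A
        exp(lnFw(fEff) - lnFr(fEff))
    }

    d <- dim(reference@data)
    sh <- .shellIndex(d, reference@voxelSize)
    mu <- mean(reference@data)
    F <- fft(reference@data - mu)
    corr <- corrAt(as.vector(sh$f))
    corr[1L] <- 1  # DC handled via the mean
    F <- F * array(corr, dim = d)
    out <- Re(fft(F, inverse = TRUE)) / prod(d)
    # restore the mean on the working scale: DC correction = near-DC shell
    out <- out + mu * corrAt(sh$df)
    scaled <- GridMap(array(out, dim = d), voxelSize = reference@voxelSize,
                      origin = reference@origin,
                      resolutionHint = workingResolution)
    lowpassFilter(scaled, workingResolution)
}

#' Write a Guinier table
#'
#' Two-column plain-text table (d^-2, lnF) of a map's Guinier curve.
#'
#' @param map a \linkS4class{GridMap}.
#' @param path output path.
#' @return invisibly, the curve data.frame.
#' @export
writeGuinierTable <- function(map, path) {
    g <- guinierCurve(map)
    utils::write.table(g[, c("d2inv", "lnF")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(g)
}
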