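# Fourier-space helpers shared by the low-pass filter and Guinier analysis.

# |frequency| (1/Angstrom) for every voxel of the FFT of a map.
.freqGrid <- function(dims, voxel) {
    f1 <- function(n, v) {
        k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
        k / (n * v)
    }
    fx <- f1(dims[1], voxel[1])
    fy <- f1(dims[2], voxel[2])
    fz <- f1(dims[3], voxel[3])
    sqrt(outer(outer(fx^2, fy^2, "+"), fz^2, "+"))
}

#' Low-pass filter a map
#'
#' Attenuates Fourier amplitudes beyond 1/resolution with a raised-cosine
#' edge (width of two Fourier pixels) to avoid real-space ringing; the DC
#' term (map mean) is untouched.
#'
#' @param map a \linkS4class{GridMap}.
#' @param resolution cutoff resolution in Angstrom; must exceed twice the
#'   voxel size (Nyquist).
#' @return A low-passed \linkS4class{GridMap} carrying \code{resolution} as
#'   its resolution hint.
#' @export
lowpassFilter <- function(map, resolution) {
    stopifnot(is(map, "GridMap"))
    if (resolution <= 2 * max(map@voxelSize))
        stop(sprintf("resolution (%.2f A) is at/below Nyquist (%.2f A)",
                     resolution, 2 * max(map@voxelSize)))
    d <- dim(map@data)
    f <- .freqGrid(d, map@voxelSize)
    fc <- 1 / resolution
    w <- 2 / (max(d * map@voxelSize))  # two Fourier pixels
    filt <- ifelse(f <= fc, 1,
                   ifelse(f >= fc + w, 0,
                          0.5 * (1 + cos(pi * (f - fc) / w))))
    F <- fft(map@data)
    out <- Re(fft(F * filt, inverse = TRUE)) / prod(d)
    GridMap(array(out, dim = d), voxelSize = map@voxelSize,
            origin = map@origin, resolutionHint = resolution,
            axisOrder = map@axisOrder)
}
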