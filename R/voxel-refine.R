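# Global voxel-size (magnification) calibration: scan a multiplicative
# factor over the refined SSE placements, re-refining each pose per factor,
# and take the factor that maximises the accumulated weighted CC; helix- and
# strand-derived estimates are combined by good-SSE-count weighting.

.FACTOR_GRID <- function() seq(0.9, 1.1, by = 0.001)

#' Scan the voxel-size factor for one template kind
#'
#' For every factor m in the 201-point grid 0.9..1.1 (step 0.001), the map's
#' voxel size is provisionally multiplied by m (which rescales every
#' physical coordinate about the coordinate origin), each placement's
#' translation is compensated by the same factor, and the per-placement
#' weighted CC is accumulated. The peak of the accumulated CC (parabolic
#' sub-grid interpolation around the argmax), divided by the template's
#' scale calibration (see \code{\link{calibrateTemplate}}), gives the
#' voxel-size correction.
#'
#' @param map the working \linkS4class{GridMap} (original voxel size).
#' @param placements refined \linkS4class{Placement}s of one kind
#'   (\code{selectTop} output).
#' @param template the corresponding \linkS4class{DensityTemplate}.
#' @param factors the scan grid (default 201 factors, 0.9..1.1 step 0.001).
#' @param maxit per-factor simplex evaluation budget; the default 0 keeps
#'   the scan a deterministic evaluation of the compensated poses (the
#'   compensation tracks a magnification change exactly, and optimiser
#'   jitter at maxit > 0 only blurs the shallow peak).
#' @param wMin,maxPoints template-support trimming for the scan (speed
#'   knobs; see vignette).
#' @param calibrated divide the peak by the template's stored scale
#'   calibration (set FALSE when measuring the calibration itself).
#' @return list with \code{factors}, \code{ccMatrix} (factor x placement),
#'   \code{ccSum}, \code{rawBestFactor} (grid argmax), \code{peakFactor}
#'   (sub-grid peak), \code{bestFactor} (= peakFactor / calibration),
#'   \code{vOri}, \code{vNew}, \code{goodCount} (placements with CC > 0.3
#'   at the peak), \code{calibration} and \code{flags} ("boundary" when the
#'   argmax hits the scan edge).
#' @export
scanVoxelFactor <- function(map, placements, template,
                            factors = .FACTOR_GRID(), maxit = 0L,
                            wMin = 0.02, maxPoints = 6000L,
                            calibrated = TRUE) {
    if (!length(placements)) stop("no placements to scan")
    vOri <- mean(map@voxelSize)
    support <- .templateSupport(template, wMin = wMin,
                                maxPoints = maxPoints)
    nF <- length(factors); nP <- length(placements)
    ccMat <- matrix(NA_real_, nF, nP)
    rotScale <- 0.15; trScale <- 0.5  # per-factor residual moves are small

    # Every factor starts from the same base pose (the input refinement),
    # offset-compensated by m. The compensation tracks a pure magnification
    # change exactly, so the default is a deterministic CC evaluation per
    # factor: re-running a simplex at every factor (maxit > 0) adds
    # optimiser jitter of the same order as the shallow CC curvature near
    # the optimum and only blurs the argmax.
    for (fi in seq_len(nF)) {
        m <- factors[fi]
        trial <- GridMap(map@data, voxelSize = map@voxelSize * m,
                         origin = map@origin * m,
                         resolutionHint = map@resolutionHint)
        trial@cache <- map@cache  # spline coefficients depend on data only
        interp <- .mapInterpolant(trial)
        for (pi in seq_len(nP)) {
            RStart <- placements[[pi]]@rotation
            tStart <- placements[[pi]]@translation * m
            cc0 <- .poseCC(interp, support, RStart, tStart)
            if (maxit > 0L) {
                fn <- function(p) {
                    Rp <- rotvecToMatrix(p[1:3] * rotScale) %*% RStart
                    -.poseCC(interp, support, Rp, tStart + p[4:6] * trScale)
                }
                opt <- stats::optim(rep(0, 6L), fn, method = "Nelder-Mead",
                                    control = list(maxit = maxit,
                                                   reltol = 1e-6))
                cc0 <- max(cc0, -opt$value)
            }
            ccMat[fi, pi] <- cc0
        }
    }
    ccSum <- rowSums(ccMat)
    best <- which.max(ccSum)
    flags <- character()
    if (best == 1L || best == nF) {
        flags <- "boundary"
        warning("accumulated CC peaks at the scan boundary; result unreliable")
    }
    # sub-grid peak: parabola through the argmax and its neighbours
    peak <- factors[best]
    if (best > 1L && best < nF) {
        y <- ccSum[(best - 1L):(best + 1L)]
        den <- y[1L] - 2 * y[2L] + y[3L]
        if (den < 0)
            peak <- factors[best] +
                0.5 * (y[1L] - y[3L]) / den * (factors[2L] - factors[1L])
    }
    if (calibrated) {
        # invert the calibrated response: y = slope * x around the
        # zero-point bias, sides measured separately
        y <- log(peak / template@scaleCalibration)
        slope <- if (y >= 0) template@scaleResponse[1L]
                 else template@scaleResponse[2L]
        bestFactor <- exp(y / slope)
    } else {
        bestFactor <- peak
    }
    list(factors = factors, ccMatrix = ccMat, ccSum = ccSum,
         rawBestFactor = factors[best], peakFactor = peak,
         bestFactor = bestFactor, vOri = vOri,
         vNew = vOri * bestFactor,
         goodCount = sum(ccMat[best, ] > 0.3),
         calibration = template@scaleCalibration,
         kind = template@kind, flags = flags)
}

#' Combine helix- and strand-derived voxel sizes
#'
#' Weighted average of the per-kind voxel estimates, weights proportional to
#' the number of "good" SSEs (CC > 0.3) of each kind.
#'
#' @param helixResult,strandResult \code{scanVoxelFactor} results (either
#'   may be \code{NULL} when that kind produced no placements).
#' @return the combined voxel size in Angstrom.
#' @export
combineVoxelEstimates <- function(helixResult, strandResult) {
    nH <- if (is.null(helixResult)) 0 else helixResult$goodCount
    nS <- if (is.null(strandResult)) 0 else strandResult$goodCount
    if (nH + nS == 0)
        stop("no good (CC > 0.3) SSEs in either kind; voxel size unchanged")
    vH <- if (nH > 0) helixResult$vNew else 0
    vS <- if (nS > 0) strandResult$vNew else 0
    (nH * vH + nS * vS) / (nH + nS)
}

#' Apply a corrected voxel size to a map
#'
#' Sets the header voxel size uniformly to \code{vNew} and rescales the
#' origin by the same ratio (the origin is a physical distance); the data
#' are untouched.
#'
#' @param map a \linkS4class{GridMap}.
#' @param vNew new voxel size in Angstrom.
#' @return The corrected \linkS4class{GridMap}.
#' @export
applyVoxelSize <- function(map, vNew) {
    stopifnot(is(map, "GridMap"), vNew > 0)
    ratio <- vNew / mean(map@voxelSize)
    out <- GridMap(map@data, voxelSize = rep(vNew, 3L),
                   origin = map@origin * ratio,
                   resolutionHint = map@resolutionHint,
                   axisOrder = map@axisOrder)
    out@cache <- map@cache
    out
}

#' Full voxel-size refinement stage
#'
#' Convenience wrapper running, per template kind: fast search, simplex
#' refinement, top selection, and the factor scan; then combining the two
#' estimates into a corrected map. A second iteration re-refines the
#' (rescaled) placements on the corrected map and re-scans, which removes
#' most of the residual shrinkage of the first-pass correction (poses
#' refined under a badly wrong header are slightly biased).
#'
#' @param map the working \linkS4class{GridMap}.
#' @param helixTemplate,strandTemplate \linkS4class{DensityTemplate}s
#'   (either may be \code{NULL} to skip that kind).
#' @param nKeep,candCCMin search breadth and the candidate CC floor below
#'   which candidates are not refined.
#' @param scanMaxit per-factor simplex budget passed to
#'   \code{scanVoxelFactor}.
#' @param iterations scan passes (>= 1; later passes re-refine poses on
#'   the corrected map, which is cheap).
#' @param verbose print stage progress.
#' @return list with \code{map} (corrected), \code{vOri}, \code{vNew},
#'   per-kind scan results (\code{helix}, \code{strand}, from the final
#'   pass, each carrying its \code{placements}).
#' @export
refineVoxelSize <- function(map, helixTemplate = NULL, strandTemplate = NULL,
                            nKeep = 25L, candCCMin = 0.2, scanMaxit = 0L,
                            iterations = 1L, verbose = FALSE) {
    templates <- list(helix = helixTemplate, strand = strandTemplate)
    vOri <- mean(map@voxelSize)

    searchKind <- function(template) {
        if (is.null(template)) return(NULL)
        if (verbose) message("  searching ", template@kind, " template ...")
        cand <- fastSearch(map, template, nKeep = nKeep)
        cand <- Filter(function(p) !is.na(p@cc) && p@cc > candCCMin, cand)
        if (!length(cand)) return(NULL)
        ref <- lapply(cand, function(p) refinePose(map, template, p))
        top <- selectTop(ref, template)
        if (length(top)) top else NULL
    }
    placements <- lapply(templates, searchKind)

    cur <- map
    results <- list(helix = NULL, strand = NULL)
    for (it in seq_len(max(1L, iterations))) {
        for (kind in c("helix", "strand")) {
            top <- placements[[kind]]
            if (is.null(top)) next
            if (it > 1L) {  # re-refine rescaled poses on the corrected map
                top <- lapply(top, function(p)
                    refinePose(cur, templates[[kind]], p,
                               maxit = 300L, maxPoints = 1500L,
                               restarts = 1L))
                placements[[kind]] <- top
            }
            if (verbose) message("  scanning ", length(top), " ", kind,
                                 " placements (pass ", it, ") ...")
            scan <- withCallingHandlers(
                scanVoxelFactor(cur, top, templates[[kind]],
                                maxit = scanMaxit),
                warning = function(w) {
                    if (grepl("boundary", conditionMessage(w)))
                        invokeRestart("muffleWarning")
                })
            scan$placements <- top
            results[[kind]] <- scan
        }
        vStep <- tryCatch(
            combineVoxelEstimates(results$helix, results$strand),
            error = function(e) { warning(conditionMessage(e)); NULL })
        if (is.null(vStep)) break
        ratio <- vStep / mean(cur@voxelSize)
        cur <- applyVoxelSize(cur, vStep)
        placements <- lapply(placements, function(top) {
            if (is.null(top)) return(NULL)
            lapply(top, function(p) {
                p@translation <- p@translation * ratio
                p
            })
        })
    }
    list(map = cur, vOri = vOri, vNew = mean(cur@voxelSize),
         helix = results$helix, strand = results$strand)
}
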