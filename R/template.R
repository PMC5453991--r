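# Construction of helix/strand density templates from a training map/model
# pair: collect secondary-structure windows, superpose them onto a standard
# segment, sample the map on a standard grid, and reduce to a mean map plus
# a distance-binned correlation (reliability) map.

.SEGMENT_LENGTH <- c(helix = 6L, strand = 4L)
.MAINCHAIN <- c("N", "CA", "C", "O")
.TEMPLATE_RADIUS <- 15
.RMSD_GATE <- 0.5
.N_DIST_GROUPS <- 30L

#' Standard template segment
#'
#' The standard segment a template is built around: a 6-residue ideal helix
#' or a 4-residue ideal strand, centred on the centre of mass of its
#' main-chain atoms.
#'
#' @param kind "helix" or "strand".
#' @return An \linkS4class{AtomModel} centred on its main-chain COM.
#' @export
standardSegment <- function(kind = c("helix", "strand")) {
    kind <- match.arg(kind)
    m <- if (kind == "helix") makeIdealHelix(6L) else makeIdealStrand(4L)
    a <- m@atoms
    mc <- a[a$atom %in% .MAINCHAIN, c("x", "y", "z")]
    com <- colMeans(as.matrix(mc))
    a$x <- a$x - com[1]; a$y <- a$y - com[2]; a$z <- a$z - com[3]
    new("AtomModel", atoms = a)
}

# Standard grid: COM-centred lattice within .TEMPLATE_RADIUS.
.templateGrid <- function(spacing = 0.5) {
    ax <- seq(-.TEMPLATE_RADIUS, .TEMPLATE_RADIUS, by = spacing)
    g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
    dimnames(g) <- NULL
    g[sqrt(rowSums(g^2)) <= .TEMPLATE_RADIUS, , drop = FALSE]
}

# Main-chain coordinates of a residue window, in fixed atom order; NULL if
# any main-chain atom is absent.
.windowCoords <- function(atoms, chain, resnos) {
    rows <- list()
    for (rn in resnos) {
        for (at in .MAINCHAIN) {
            r <- which(atoms$chain == chain & atoms$resno == rn &
                       atoms$atom == at)
            if (length(r) != 1L) return(NULL)
            rows[[length(rows) + 1L]] <- r
        }
    }
    as.matrix(atoms[unlist(rows), c("x", "y", "z")])
}

#' Collect training segments for a template
#'
#' Slides a window of the template length (6 residues for helices, 4 for
#' strands) over every annotated SSE of the model, superposes each window's
#' main-chain atoms onto the standard segment, and keeps windows with RMSD
#' below 0.5 Angstrom together with their standard-frame -> map-frame
#' transforms.
#'
#' @param model an \linkS4class{AtomModel} with secondary-structure labels.
#' @param kind "helix" or "strand".
#' @param standard the standard segment (defaults to
#'   \code{standardSegment(kind)}).
#' @return list with \code{standard} and \code{segments}, a list of
#'   \code{list(rotation, translation, rmsd, chain, start)} entries.
#' @export
collectSegments <- function(model, kind = c("helix", "strand"),
                            standard = standardSegment(kind)) {
    kind <- match.arg(kind)
    lab <- if (kind == "helix") "H" else "E"
    len <- .SEGMENT_LENGTH[[kind]]
    a <- model@atoms
    sa <- standard@atoms
    stdCoords <- as.matrix(sa[sa$atom %in% .MAINCHAIN, c("x", "y", "z")])

    segments <- list()
    ca <- a[a$atom == "CA", , drop = FALSE]
    for (ch in unique(ca$chain)) {
        c1 <- ca[ca$chain == ch, , drop = FALSE]
        r <- rle(c1$ss == lab)
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
        for (k in which(r$values)) {
            resnos <- c1$resno[starts[k]:ends[k]]
            if (length(resnos) < len) next
            for (s in 1:(length(resnos) - len + 1L)) {
                win <- resnos[s:(s + len - 1L)]
                wc <- .windowCoords(a, ch, win)
                if (is.null(wc) || nrow(wc) != nrow(stdCoords)) next
                sp <- suppressWarnings(superpose(stdCoords, wc))
                if (sp$rmsd < .RMSD_GATE)
                    segments[[length(segments) + 1L]] <- list(
                        rotation = sp$rotation,
                        translation = sp$translation,
                        rmsd = sp$rmsd, chain = ch, start = win[1])
            }
        }
    }
    if (!length(segments))
        warning("no labelled SSE windows matched the standard segment")
    list(kind = kind, standard = standard, segments = segments)
}

#' Sample map density on the standard grid for one segment
#'
#' Transforms the standard-grid points into the map frame and interpolates
#' the density there with cubic (third-order) interpolation. Points outside
#' the map count as "no density" (zero); if more than half of the support
#' falls outside, the segment is unusable and \code{NULL} is returned.
#'
#' @param map a \linkS4class{GridMap}.
#' @param rotation,translation standard-frame -> map-frame transform.
#' @param gridPoints n x 3 standard-grid points (Angstrom, COM-centred).
#' @return numeric(n) of sampled densities, or \code{NULL}.
#' @export
sampleSegmentDensity <- function(map, rotation, translation, gridPoints) {
    pts <- gridPoints %*% t(rotation)
    pts <- sweep(pts, 2, translation, "+")
    v <- interpolateMap(map, pts, "cubic")
    bad <- is.na(v)
    if (mean(bad) > 0.5) {
        warning("more than half of the template support lies outside the map; segment dropped")
        return(NULL)
    }
    v[bad] <- 0
    v
}

#' Mean template map
#'
#' Per-grid-point average of the sampled training densities:
#' \code{mean_k = (1/n) sum_n S_nk}.
#'
#' @param samples n_segments x n_gridpoints matrix of sampled densities.
#' @return numeric vector of per-point means.
#' @export
computeMeanMap <- function(samples) {
    samples <- as.matrix(samples)
    if (nrow(samples) == 0L) stop("no training segments")
    colMeans(samples)
}

#' Distance-bin index for template grid points
#'
#' Distances to the nearest standard-segment atom are binned into 30 groups
#' of 0.5 Angstrom; distances of 15 Angstrom or more are excluded
#' (\code{NA}).
#'
#' @param L numeric vector of distances in Angstrom (>= 0).
#' @return integer vector of group indices in 1..30, \code{NA} beyond 15.
#' @export
assignDistanceGroup <- function(L) {
    if (any(L < 0)) stop("distances must be non-negative")
    i <- as.integer(floor(L / 0.5)) + 1L
    i[L >= .TEMPLATE_RADIUS] <- NA_integer_
    i
}

#' Correlation map from training samples
#'
#' For each distance group, computes the Pearson correlation between each
#' segment's samples and the mean map over the group's grid points, averages
#' the per-segment correlations, and broadcasts the group value back to the
#' grid. Groups with fewer than 2 grid points (or without density variation)
#' get a correlation of 0.
#'
#' @param samples n_segments x n_gridpoints matrix.
#' @param meanMap numeric vector from \code{computeMeanMap}.
#' @param groups integer vector of distance-group indices (NA = excluded).
#' @return list with \code{groupCC} (numeric(30)) and \code{corrMap}
#'   (numeric per grid point; 0 on excluded points).
#' @export
computeCorrelationMap <- function(samples, meanMap, groups) {
    samples <- as.matrix(samples)
    if (nrow(samples) < 2L)
        stop("correlation map needs at least 2 training segments")
    groupCC <- numeric(.N_DIST_GROUPS)
    for (i in seq_len(.N_DIST_GROUPS)) {
        k <- which(!is.na(groups) & groups == i)
        if (length(k) < 2L) {
            if (length(k))
                warning(sprintf("distance group %d has < 2 grid points; CC set to 0", i))
            groupCC[i] <- 0
            next
        }
        mu <- meanMap[k]
        if (stats::sd(mu) == 0) { groupCC[i] <- 0; next }
        rho <- apply(samples[, k, drop = FALSE], 1L, function(s) {
            if (stats::sd(s) == 0) NA_real_ else stats::cor(s, mu)
        })
        groupCC[i] <- if (all(is.na(rho))) 0 else mean(rho, na.rm = TRUE)
    }
    corrMap <- numeric(length(groups))
    ok <- !is.na(groups)
    corrMap[ok] <- groupCC[groups[ok]]
    list(groupCC = pmin(1, pmax(-1, groupCC)),
         corrMap = pmin(1, pmax(-1, corrMap)))
}

#' Build a secondary-structure density template
#'
#' Full template pipeline: low-pass filter the training map, collect
#' SSE windows superposed onto the standard segment, sample each on the
#' standard grid, and reduce to the mean map and distance-binned correlation
#' map. 2.5 Angstrom filtering is the shipped default.
#'
#' @param map training \linkS4class{GridMap}, aligned with \code{model}.
#' @param model training \linkS4class{AtomModel} with SSE labels.
#' @param kind "helix" or "strand".
#' @param filterResolution low-pass resolution in Angstrom (default 2.5).
#' @param spacing standard-grid spacing in Angstrom (default 0.5).
#' @return A \linkS4class{DensityTemplate}.
#' @export
buildTemplate <- function(map, model, kind = c("helix", "strand"),
                          filterResolution = 2.5, spacing = 0.5) {
    kind <- match.arg(kind)
    mapF <- lowpassFilter(map, filterResolution)
    coll <- collectSegments(model, kind)
    grid <- .templateGrid(spacing)
    keep <- list(); samples <- list()
    for (seg in coll$segments) {
        v <- withCallingHandlers(
            sampleSegmentDensity(mapF, seg$rotation, seg$translation, grid),
            warning = function(w) invokeRestart("muffleWarning"))
        if (!is.null(v)) {
            keep[[length(keep) + 1L]] <- seg
            samples[[length(samples) + 1L]] <- v
        }
    }
    if (length(keep) < 3L)
        stop(sprintf("only %d usable training segment(s); template would be unreliable",
                     length(keep)))
    S <- do.call(rbind, samples)
    meanMap <- computeMeanMap(S)
    sa <- coll$standard@atoms
    stdXYZ <- as.matrix(sa[, c("x", "y", "z")])
    # nearest-atom distance per grid point
    L <- sqrt(.rowMinDist2(grid, stdXYZ))
    groups <- assignDistanceGroup(L)
    cm <- suppressWarnings(computeCorrelationMap(S, meanMap, groups))
    new("DensityTemplate",
        kind = kind, standardCoords = coll$standard,
        gridPoints = grid, meanMap = meanMap, corrMap = cm$corrMap,
        groupCC = cm$groupCC,
        distGroup = ifelse(is.na(groups), 0L, groups),
        nSegments = length(keep), sourceResolution = filterResolution,
        spacing = spacing, scaleCalibration = 1)
}

#' Calibrate a template's magnification response
#'
#' An ensemble-mean template is slightly blurrier than any single map
#' window, which biases correlation-maximising magnification estimates
#' towards expansion (for matched Gaussian profiles the optimum sits at
#' \code{sqrt(1 + sigma_blur^2 / sigma_feature^2)}, not at 1); in addition,
#' poses refined under a mis-set voxel size absorb part of the scale error,
#' shrinking the measured correction. The training map/model pair has known
#' scale, so both effects can be measured directly, as in any two-point
#' instrument calibration: the full placement pipeline (fast search, pose
#' refinement, top selection, factor scan) is run on (i) the training map
#' itself, giving the zero-point bias, and (ii) the training map with its
#' voxel size mis-set by the edges of the stated +-5 percent
#' magnification-error regime, giving the response slope on each side.
#' Voxel-size scans invert this response.
#'
#' @param template a \linkS4class{DensityTemplate}.
#' @param trainingMap the map the template was built from.
#' @param anchors perturbation factors probing the response (shrink and
#'   expand side).
#' @param nKeep,candCCMin search breadth and candidate CC floor.
#' @param verbose print progress.
#' @return the template with \code{scaleCalibration} and
#'   \code{scaleResponse} set.
#' @export
calibrateTemplate <- function(template, trainingMap,
                              anchors = c(0.95, 1.05), nKeep = 25L,
                              candCCMin = 0.2, verbose = FALSE) {
    # the training map plays the "working map of known scale": use it as-is
    # so the calibration pipeline matches production exactly
    if (verbose) message("calibrating ", template@kind, " template ...")
    runScan <- function(map) {
        cand <- fastSearch(map, template, nKeep = nKeep)
        cand <- Filter(function(p) !is.na(p@cc) && p@cc > candCCMin, cand)
        if (!length(cand)) return(NULL)
        ref <- lapply(cand, function(p) refinePose(map, template, p))
        top <- selectTop(ref, template)
        if (!length(top)) return(NULL)
        scanVoxelFactor(map, top, template, calibrated = FALSE)$peakFactor
    }
    base <- runScan(trainingMap)
    if (is.null(base)) {
        warning("calibration search found no placements; calibration left at 1")
        return(template)
    }
    template@scaleCalibration <- base
    slopes <- c(1, 1)
    for (i in 1:2) {
        f0 <- anchors[i]
        pk <- runScan(perturbVoxelSize(trainingMap, f0))
        if (is.null(pk)) next
        # measured log-correction vs true log-correction log(1/f0)
        slopes[i] <- log(pk / base) / log(1 / f0)
    }
    if (any(slopes <= 0)) {
        warning("degenerate calibration response; slopes left at 1")
        slopes <- c(1, 1)
    }
    # slot order: expansion side (peak > bias), shrinkage side
    template@scaleResponse <- c(slopes[1L], slopes[2L])
    if (verbose)
        message(sprintf("  %s calibration: %.4f, response %.3f/%.3f",
                        template@kind, base, slopes[1L], slopes[2L]))
    template
}

# squared distance from each row of A to its nearest row of B, blockwise.
.rowMinDist2 <- function(A, B) {
    nb <- nrow(B)
    out <- rep(Inf, nrow(A))
    a2 <- rowSums(A^2)
    for (j in seq_len(nb)) {
        d2 <- a2 - 2 * (A %*% B[j, ]) + sum(B[j, ]^2)
        out <- pmin(out, as.vector(d2))
    }
    pmax(out, 0)
}

#' Save / load a template archive
#'
#' Templates are serialised as a small versioned RDS archive (standard
#' coordinates, the two grids and metadata).
#'
#' @param template a \linkS4class{DensityTemplate}.
#' @param path file path.
#' @return \code{loadTemplate} returns the \linkS4class{DensityTemplate};
#'   \code{saveTemplate} returns \code{path} invisibly.
#' @export
saveTemplate <- function(template, path) {
    stopifnot(is(template, "DensityTemplate"))
    obj <- list(format = "cryobuild-template", version = 1L,
                kind = template@kind,
                standardAtoms = template@standardCoords@atoms,
                gridPoints = template@gridPoints,
                meanMap = template@meanMap, corrMap = template@corrMap,
                groupCC = template@groupCC, distGroup = template@distGroup,
                nSegments = template@nSegments,
                sourceResolution = template@sourceResolution,
                spacing = template@spacing,
                scaleCalibration = template@scaleCalibration,
                scaleResponse = template@scaleResponse)
    saveRDS(obj, path, version = 2L)
    invisible(path)
}

#' @rdname saveTemplate
#' @export
loadTemplate <- function(path) {
    obj <- readRDS(path)
    if (!identical(obj$format, "cryobuild-template"))
        stop("not a cryobuild template archive: ", path)
    new("DensityTemplate",
        kind = obj$kind,
        standardCoords = new("AtomModel", atoms = obj$standardAtoms),
        gridPoints = obj$gridPoints, meanMap = obj$meanMap,
        corrMap = obj$corrMap, groupCC = obj$groupCC,
        distGroup = obj$distGroup, nSegments = obj$nSegments,
        sourceResolution = obj$sourceResolution, spacing = obj$spacing,
        scaleCalibration = if (is.null(obj$scaleCalibration)) 1
                           else obj$scaleCalibration,
        scaleResponse = if (is.null(obj$scaleResponse)) c(1, 1)
                        else obj$scaleResponse)
}
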