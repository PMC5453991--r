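# Template search in the working map: a coarse probe-point pre-screen over
# positions x orientations, correlation-map-weighted CC scoring, and
# six-dimensional Nelder-Mead rigid-body refinement of each candidate pose.

# Scoring support of a template: grid points with positive reliability
# weight. `wMin` trims near-zero-weight points (they contribute almost
# nothing to the weighted CC) and `maxPoints` deterministically subsamples
# the rest -- both are speed knobs for the inner refinement loops; the
# user-facing weightedCC() uses the full support.
.templateSupport <- function(template, wMin = 0, maxPoints = Inf) {
    w <- pmax(template@corrMap, 0)
    keep <- which(w > wMin)
    if (!length(keep)) keep <- which(w > 0)
    if (!length(keep))
        stop("template correlation map has no positive weights")
    if (length(keep) > maxPoints) {
        idx <- seq(1L, length(keep), length.out = maxPoints)
        keep <- keep[as.integer(idx)]
    }
    list(points = template@gridPoints[keep, , drop = FALSE],
         mean = template@meanMap[keep], w = w[keep])
}

# Weighted Pearson correlation; x may contain NA (outside-map points),
# scored as zero density.
.weightedPearson <- function(x, y, w) {
    x[is.na(x)] <- 0
    sw <- sum(w)
    mx <- sum(w * x) / sw
    my <- sum(w * y) / sw
    vx <- sum(w * (x - mx)^2) / sw
    vy <- sum(w * (y - my)^2) / sw
    if (vx <= 0 || vy <= 0) return(0)
    sum(w * (x - mx) * (y - my)) / sw / sqrt(vx * vy)
}

# Weighted CC of every orientation at a fixed centre: returns the index of
# the best orientation and its cc.
.bestOrientation <- function(interp, support, orientations, com) {
    cc <- vapply(orientations, function(R)
        .poseCC(interp, support, R, com), numeric(1))
    list(index = which.max(cc), cc = max(cc))
}

# CC at a pose given a prepared interpolant and support (hot path).
.poseCC <- function(interp, support, rotation, translation) {
    pose_cc_cpp(interp$coef, interp$origin, interp$voxel,
                support$points, support$mean, support$w,
                as.numeric(rotation), as.numeric(translation))
}

#' Correlation-map-weighted CC of a template pose
#'
#' Pearson correlation between the working-map density (cubic-interpolated
#' at the pose-transformed standard-grid points) and the template mean map,
#' weighted per point by \code{max(corrMap, 0)} using weighted means and
#' variances. Out-of-map points count as zero density.
#'
#' @param map a \linkS4class{GridMap}.
#' @param template a \linkS4class{DensityTemplate}.
#' @param rotation 3x3 proper rotation (standard frame -> map frame).
#' @param translation numeric(3), Angstrom.
#' @return weighted correlation in [-1, 1].
#' @export
weightedCC <- function(map, template, rotation, translation) {
    interp <- .mapInterpolant(map)
    support <- .templateSupport(template)
    .poseCC(interp, support, rotation, translation)
}

# Probe points for the fast pre-screen: CA and CB positions of the standard
# segment (the "several grid-point values" scorer).
.templateProbes <- function(template) {
    a <- template@standardCoords@atoms
    as.matrix(a[a$atom %in% c("CA", "CB"), c("x", "y", "z")])
}

#' Fast template search
#'
#' Coarse pre-screen of template poses: a quasi-uniform grid of orientations
#' (about 600) crossed with a decimated translation grid restricted to dense
#' map regions, scored only by the map values at the template's CA/CB
#' positions. Fast and imprecise by design -- precision comes from
#' \code{refinePose}.
#'
#' @param map a \linkS4class{GridMap}.
#' @param template a \linkS4class{DensityTemplate}.
#' @param nKeep number of non-redundant candidates to return.
#' @param step translation decimation in voxels (default 2: every other
#'   voxel).
#' @param nDir,nRoll orientation-grid resolution (axis directions x rolls).
#' @param densityQuantile only map positions above this density quantile are
#'   tried as template centres.
#' @return list of candidate \linkS4class{Placement}s (unrefined; \code{cc}
#'   holds the probe score, low-confidence candidates are flagged).
#' @export
fastSearch <- function(map, template, nKeep = 40L, step = 2L,
                       nDir = 72L, nRoll = 8L, densityQuantile = 0.8) {
    d <- dim(map@data)
    ext <- (d - 1L) * map@voxelSize
    if (any(2 * .TEMPLATE_RADIUS > ext + 1e-9))
        warning("map is smaller than the template support; placements may be truncated")
    probes <- .templateProbes(template)
    if (max(sqrt(rowSums(probes^2))) > min(ext) / 2 + 5)
        stop("map too small to hold the template")

    orientations <- .orientationGrid(nDir, nRoll)
    # probe offsets per orientation, in voxel units
    probeList <- lapply(orientations, function(R) {
        p <- probes %*% t(R)
        sweep(p, 2, map@voxelSize, "/")
    })

    idx <- lapply(d, function(n) seq(1L, n, by = step))
    centersVox <- as.matrix(expand.grid(idx[[1]], idx[[2]], idx[[3]])) - 1L
    vals <- map@data[centersVox + 1L]
    thr <- stats::quantile(map@data, densityQuantile)
    centersVox <- centersVox[vals >= thr, , drop = FALSE]
    lowConfidence <- FALSE
    if (nrow(centersVox) == 0L || stats::sd(map@data) == 0) {
        centersVox <- as.matrix(expand.grid(idx[[1]], idx[[2]], idx[[3]])) - 1L
        lowConfidence <- TRUE
    }

    sc <- fast_search_cpp(map@data, probeList, centersVox)
    ord <- order(sc[, 1L], decreasing = TRUE)
    minSep <- 3.0  # Angstrom between accepted candidate centres
    interp <- .mapInterpolant(map)
    # small support for the per-candidate orientation rescoring; reported
    # candidate CCs use the refinement support for comparability
    support <- .templateSupport(template, wMin = 0.05, maxPoints = 500L)
    supportRefine <- .templateSupport(template, wMin = 0.02,
                                      maxPoints = 1800L)
    axis <- .templateAxis(template)
    rolls <- seq(-24, 24, by = 4) * pi / 180
    kept <- list(); keptCOM <- NULL
    for (i in ord) {
        com <- map@origin + centersVox[i, ] * map@voxelSize
        if (!is.null(keptCOM) &&
            min(sqrt(rowSums(sweep(keptCOM, 2, com)^2))) < minSep) next
        # probe scores rank centres well but orientations poorly; rescore
        # every grid orientation at this centre by weighted CC
        bo <- .bestOrientation(interp, support, orientations, com)
        R <- orientations[[bo$index]]
        # polish the grid's two coarsest dimensions: the segment-axis
        # direction (~25 degree spacing) by a two-round cone scan ...
        for (tilt in c(12, 6) * pi / 180) {
            axisMap <- as.vector(R %*% axis)
            perp1 <- if (abs(axisMap[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
            perp1 <- perp1 - sum(perp1 * axisMap) * axisMap
            perp1 <- perp1 / sqrt(sum(perp1^2))
            perp2 <- c(axisMap[2] * perp1[3] - axisMap[3] * perp1[2],
                       axisMap[3] * perp1[1] - axisMap[1] * perp1[3],
                       axisMap[1] * perp1[2] - axisMap[2] * perp1[1])
            cand <- list(R)
            for (az in seq(0, 2 * pi, length.out = 9L)[1:8]) {
                v <- (cos(az) * perp1 + sin(az) * perp2) * tilt
                cand[[length(cand) + 1L]] <- rotvecToMatrix(v) %*% R
            }
            tcc <- vapply(cand, function(Rc)
                .poseCC(interp, support, Rc, com), numeric(1))
            R <- cand[[which.max(tcc)]]
        }
        # ... and the roll about the axis (45 degree steps)
        axisMap <- as.vector(R %*% axis)
        rollcc <- vapply(rolls, function(a)
            .poseCC(interp, support, rotvecToMatrix(axisMap * a) %*% R, com),
            numeric(1))
        R <- rotvecToMatrix(axisMap * rolls[which.max(rollcc)]) %*% R
        # pull the centre onto the best neighbouring voxel (the translation
        # grid is decimated, so starts can be > 1 voxel off)
        shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) *
            rep(map@voxelSize, each = 27L)
        ccs <- vapply(seq_len(27L), function(s)
            .poseCC(interp, support, R, com + shifts[s, ]), numeric(1))
        sBest <- which.max(ccs)
        com <- com + shifts[sBest, ]
        # report the candidate CC on the same support refinePose uses, so
        # scores stay comparable across the search/refine boundary
        ccFull <- .poseCC(interp, supportRefine, R, com)
        pl <- Placement(kind = template@kind,
                        rotation = R,
                        translation = com,
                        cc = min(1, max(-1, ccFull)),
                        refined = FALSE,
                        flags = if (lowConfidence || sc[i, 1L] <= 0)
                            "low-confidence" else character())
        kept[[length(kept) + 1L]] <- pl
        keptCOM <- rbind(keptCOM, com)
        if (length(kept) >= nKeep) break
    }
    kept
}

#' Six-dimensional simplex pose refinement
#'
#' Nelder-Mead maximisation of the weighted CC over 3 rotation + 3
#' translation parameters, with the rotation parameterised as a rotation
#' vector applied about the starting pose (no gimbal issues near the
#' optimum). The returned CC is never below the starting CC.
#'
#' @param map a \linkS4class{GridMap}.
#' @param template a \linkS4class{DensityTemplate}.
#' @param placement starting \linkS4class{Placement} (e.g. from
#'   \code{fastSearch}).
#' @param maxit Nelder-Mead evaluation budget.
#' @param wMin,maxPoints template-support trimming used during refinement
#'   (see details in the package vignette); the final reported CC is always
#'   recomputed on the same support used during optimisation.
#' @return refined \linkS4class{Placement}; flagged "not-converged" when the
#'   iteration cap was hit.
#' @export
refinePose <- function(map, template, placement, maxit = 500L,
                       wMin = 0.02, maxPoints = 1800L, restarts = 3L) {
    interp <- .mapInterpolant(map)
    support <- .templateSupport(template, wMin = wMin, maxPoints = maxPoints)
    R0 <- placement@rotation
    t0 <- placement@translation
    cc0 <- .poseCC(interp, support, R0, t0)
    # one scaled unit = rotScale radians of rotation / trScale Angstrom of
    # shift, so Nelder-Mead's default initial simplex explores a sensible
    # neighbourhood of the starting pose
    rotScale <- 0.25; trScale <- 1.0
    flags <- placement@flags
    R <- R0; tt <- t0; cc <- cc0
    for (r in seq_len(max(1L, restarts))) {
        Rs <- R; ts_ <- tt
        fn <- function(p) {
            Rp <- rotvecToMatrix(p[1:3] * rotScale) %*% Rs
            -.poseCC(interp, support, Rp, ts_ + p[4:6] * trScale)
        }
        opt <- stats::optim(rep(0, 6L), fn, method = "Nelder-Mead",
                            control = list(maxit = maxit, reltol = 1e-6))
        if (opt$convergence != 0L) flags <- union(flags, "not-converged")
        else flags <- setdiff(flags, "not-converged")
        gain <- (-opt$value) - cc
        if (-opt$value >= cc) {  # never accept a pose worse than the start
            R <- rotvecToMatrix(opt$par[1:3] * rotScale) %*% Rs
            tt <- ts_ + opt$par[4:6] * trScale
            cc <- -opt$value
        }
        if (gain < 1e-4) break  # converged; further restarts cannot help
    }
    Placement(kind = placement@kind, rotation = R, translation = tt,
              cc = min(1, max(-1, cc)), refined = TRUE, flags = flags)
}

# Angle (degrees) between the segment axes of two placements, treating
# antiparallel axes as equivalent.
.axisAngle <- function(axis, p1, p2) {
    a1 <- as.vector(p1@rotation %*% axis)
    a2 <- as.vector(p2@rotation %*% axis)
    c_ <- abs(sum(a1 * a2)) / sqrt(sum(a1^2) * sum(a2^2))
    acos(min(1, c_)) * 180 / pi
}

# Principal axis of the standard segment CAs (template frame).
.templateAxis <- function(template) {
    ca <- caCoords(template@standardCoords)
    cc <- sweep(ca, 2, colMeans(ca))
    svd(cc)$v[, 1]
}

#' Select the top non-redundant placements
#'
#' Collapses duplicate poses (COM within \code{comTol} Angstrom and segment
#' axis within \code{axisTol} degrees) keeping the better CC, drops
#' placements with CC at or below \code{ccMin}, and returns at most
#' \code{nTop}, sorted by CC.
#'
#' @param placements list of refined \linkS4class{Placement}s.
#' @param template the \linkS4class{DensityTemplate} they place (for the
#'   segment axis used in redundancy pruning).
#' @param ccMin CC acceptance threshold (default 0.3).
#' @param nTop maximum number kept (default 20).
#' @param comTol,axisTol redundancy thresholds (2 Angstrom, 15 degrees).
#' @return list of \linkS4class{Placement}s (possibly empty).
#' @export
selectTop <- function(placements, template, ccMin = 0.3, nTop = 20L,
                      comTol = 2.0, axisTol = 15) {
    if (!length(placements)) return(list())
    ord <- order(vapply(placements, function(p) p@cc, numeric(1)),
                 decreasing = TRUE)
    axis <- .templateAxis(template)
    kept <- list()
    for (i in ord) {
        p <- placements[[i]]
        if (is.na(p@cc) || p@cc <= ccMin) next
        dup <- FALSE
        for (q in kept) {
            if (sqrt(sum((p@translation - q@translation)^2)) < comTol &&
                .axisAngle(axis, p, q) < axisTol) { dup <- TRUE; break }
        }
        if (dup) next
        kept[[length(kept) + 1L]] <- p
        if (length(kept) >= nTop) break
    }
    kept
}

#' Write placements as a diagnostic PDB + table
#'
#' Emits the placed standard segments as one PDB (chains in placement order)
#' and a tab-separated table of pose parameters and scores for inspection.
#'
#' @param placements list of \linkS4class{Placement}s.
#' @param template the placed \linkS4class{DensityTemplate}.
#' @param pdbPath,tablePath output paths (NULL skips the file).
#' @return invisibly, the placement table as a data.frame.
#' @export
writePlacements <- function(placements, template, pdbPath = NULL,
                            tablePath = NULL) {
    rows <- list(); allAtoms <- list()
    chains <- c(LETTERS, letters, as.character(0:9))
    for (i in seq_along(placements)) {
        p <- placements[[i]]
        m <- .transformModel(template@standardCoords, p@rotation,
                             p@translation)
        a <- m@atoms
        a$chain <- chains[((i - 1L) %% length(chains)) + 1L]
        allAtoms[[i]] <- a
        rv <- p@translation
        rows[[i]] <- data.frame(
            index = i, kind = p@kind, x = rv[1], y = rv[2], z = rv[3],
            cc = p@cc, refined = p@refined,
            flags = paste(p@flags, collapse = ";"),
            stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    if (!is.null(pdbPath) && length(allAtoms))
        writeModel(new("AtomModel", atoms = do.call(rbind, allAtoms)),
                   pdbPath)
    if (!is.null(tablePath))
        utils::write.table(tab, tablePath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    invisible(tab)
}
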