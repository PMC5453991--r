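# Synthetic fixtures: ideal secondary-structure geometry, toy folds with
# known ground truth, and Gaussian-atom density simulation. These stand in
# for experimental depositions so every pipeline stage can be exercised
# self-consistently (the forward model used for training and testing is the
# same simulator).

.ELEMENT_Z <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)

# One-letter <-> three-letter codes for the residue types the fixtures use.
.AA13 <- c(G = "GLY", A = "ALA", S = "SER", V = "VAL", L = "LEU",
           F = "PHE", W = "TRP", R = "ARG", K = "LYS")

# Single-centroid side-chain stand-ins: distance (Angstrom) from CA along
# the CA->CB direction, total scattering weight (sum of heavy-atom Z beyond
# CB), and an elevated B factor so the centroid is smeared over roughly the
# spatial footprint of the real side chain rather than concentrated in a
# point. Crude, but self-consistent across simulation and training.
.SIDECHAINS <- data.frame(
    resname = c("SER", "VAL", "LEU", "PHE", "TRP", "ARG", "LYS"),
    dist = c(2.4, 2.9, 3.3, 4.2, 4.5, 5.0, 4.5),
    weight = c(8, 12, 18, 36, 54, 40, 26),
    b = c(60, 80, 100, 120, 140, 160, 140),
    stringsAsFactors = FALSE)

# Assemble an AtomModel chain from a backbone table, adding side-chain
# centroid pseudo-atoms (atom "SC1", element "X") for bulky residue types.
.chainModel <- function(bb, chain, ss) {
    bb$chain <- chain
    bb$b <- 20
    bb$weight <- NA_real_
    bb$ss <- ss
    extra <- list()
    for (rn in unique(bb$resno)) {
        res <- bb[bb$resno == rn, , drop = FALSE]
        sc <- .SIDECHAINS[.SIDECHAINS$resname == res$resname[1], ]
        if (nrow(sc) == 1L && any(res$atom == "CB")) {
            ca <- unlist(res[res$atom == "CA", c("x", "y", "z")])
            cb <- unlist(res[res$atom == "CB", c("x", "y", "z")])
            u <- (cb - ca) / sqrt(sum((cb - ca)^2))
            p <- ca + sc$dist * u
            extra[[length(extra) + 1L]] <- data.frame(
                chain = chain, resno = rn, resname = res$resname[1],
                atom = "SC1", element = "X", x = p[1], y = p[2], z = p[3],
                b = sc$b, weight = sc$weight, ss = ss,
                stringsAsFactors = FALSE)
        }
    }
    at <- rbind(bb[, .ATOM_COLS], do.call(rbind, extra))
    at <- at[order(at$resno), ]
    AtomModel(at)
}

.expandSeq <- function(sequence, n) {
    if (is.null(sequence)) return(rep("ALA", n))
    if (length(sequence) == 1L && nchar(sequence[1]) > 1L)
        sequence <- strsplit(sequence, "")[[1]]
    if (length(sequence) != n)
        stop("sequence length does not match residue count")
    if (all(sequence %in% names(.AA13))) sequence <- .AA13[sequence]
    unname(sequence)
}

#' Ideal poly-alanine alpha-helix
#'
#' Builds an ideal alpha-helix (rise about 1.5 Angstrom per residue, about
#' 100 degrees of twist per residue, CA radius about 2.3 Angstrom) from
#' standard covalent geometry with fixed (phi, psi) = (-57.8, -47.0).
#' Atoms: N, CA, C, O and CB (CB omitted for GLY).
#'
#' @param n number of residues (>= 4).
#' @param chain chain identifier.
#' @param sequence optional residue types (one- or three-letter), length n.
#' @return An \linkS4class{AtomModel} labelled helix ("H") throughout.
#' @export
makeIdealHelix <- function(n, chain = "A", sequence = NULL) {
    if (n < 4) stop("a helix fixture needs at least 4 residues")
    rn <- .expandSeq(sequence, n)
    bb <- .buildBackbone(n, phi = -57.8, psi = -47.0, resnames = rn)
    .chainModel(bb, chain, "H")
}

#' Ideal beta-strand
#'
#' Extended-chain geometry with fixed (phi, psi) = (-130, 125): rise about
#' 3.3-3.4 Angstrom per residue and a near-collinear CA trace.
#'
#' @inheritParams makeIdealHelix
#' @return An \linkS4class{AtomModel} labelled strand ("E") throughout.
#' @export
makeIdealStrand <- function(n, chain = "A", sequence = NULL) {
    if (n < 4) stop("a strand fixture needs at least 4 residues")
    rn <- .expandSeq(sequence, n)
    bb <- .buildBackbone(n, phi = -130, psi = 125, resnames = rn)
    .chainModel(bb, chain, "E")
}

# Rotation/translation placing a segment so its CA principal axis runs along
# `dir` (N->C sense) and its CA centroid sits at `at`.
.placeSegment <- function(model, dir, at) {
    ca <- caCoords(model)
    com <- colMeans(ca)
    cc <- sweep(ca, 2, com)
    ax <- svd(cc)$v[, 1]
    if (sum(ax * (ca[nrow(ca), ] - ca[1, ])) < 0) ax <- -ax
    # rotate ax onto dir
    Raxis <- .rotationFromZ(dir) %*% t(.rotationFromZ(ax))
    m <- .transformModel(model, Raxis, at - as.vector(Raxis %*% com))
    m
}

.renumber <- function(model, chain) {
    a <- model@atoms
    a$chain <- chain
    new("AtomModel", atoms = a)
}

#' Toy test fold: three-helix bundle plus four-strand sheet
#'
#' A compact synthetic fold of about 77 residues -- three 15-residue helices
#' in an (up, down, up) bundle and a four-strand antiparallel sheet -- built
#' entirely from ideal geometry. Each SSE is its own chain (A..G), so the
#' ground-truth CA positions and secondary-structure labels are exact.
#'
#' @param sequences optional named list/vector of per-chain sequences
#'   (chains A..G; one-letter strings). Defaults use a mix of residue types
#'   so side-chain density is informative.
#' @return An \linkS4class{AtomModel}.
#' @export
makeToyProtein <- function(sequences = NULL) {
    def <- c(A = "AAWLASAFVALSAWA", B = "ALAFAWVALLASAFA",
             C = "AWALSAFALVAWALA", D = "ALWAFVAS", E = "AFALWAVL",
             F = "AWAVLFAS", G = "ALAFAWVS")
    if (!is.null(sequences)) def[names(sequences)] <- unlist(sequences)
    sq <- function(ch) def[[ch]]
    parts <- list(
        .placeSegment(makeIdealHelix(15, "A", sq("A")), c(0, 0, 1),
                      c(0, 0, 0)),
        .placeSegment(makeIdealHelix(15, "B", sq("B")), c(0, 0, -1),
                      c(10, 0, 0)),
        .placeSegment(makeIdealHelix(15, "C", sq("C")), c(0, 0, 1),
                      c(5, 9, 0)),
        .placeSegment(makeIdealStrand(8, "D", sq("D")), c(1, 0, 0),
                      c(5, 22, 0)),
        .placeSegment(makeIdealStrand(8, "E", sq("E")), c(-1, 0, 0),
                      c(5, 26.8, 0)),
        .placeSegment(makeIdealStrand(8, "F", sq("F")), c(1, 0, 0),
                      c(5, 31.6, 0)),
        .placeSegment(makeIdealStrand(8, "G", sq("G")), c(-1, 0, 0),
                      c(5, 36.4, 0)))
    AtomModel(do.call(rbind, lapply(parts, atoms)))
}

#' Reference test fold for likelihood-target training
#'
#' An independent synthetic fold (about 138 residues: five 18-residue
#' helices on a pentagon plus a four-strand sheet of 12-residue strands)
#' used as the "reference map + known model" pair when training
#' log-likelihood targets, so training and evaluation never share a
#' structure.
#'
#' @return An \linkS4class{AtomModel}.
#' @export
makeReferenceProtein <- function() {
    seqs <- c("AWALSAFVALSAWALFAS", "ALAFAWVALLASAFALWA",
              "ASALWAFVALSAWALAFA", "AWALFASVALLASAWALF",
              "ALASAFWALVASAWALFA",
              "AWALFVASALWA", "ALAFAWVSALFA",
              "ASWALFAVALSA", "AFALWAVLASWA")
    parts <- list()
    for (i in 1:5) {
        ang <- 2 * pi * (i - 1) / 5
        at <- c(12 * cos(ang), 12 * sin(ang), 0)
        dir <- c(0, 0, 1) * (if (i %% 2 == 0) -1 else 1)
        parts[[i]] <- .placeSegment(
            makeIdealHelix(18, LETTERS[i], seqs[i]), dir, at)
    }
    for (j in 1:4) {
        dir <- c(if (j %% 2 == 0) -1 else 1, 0, 0)
        at <- c(0, 26 + 4.8 * (j - 1), 0)
        parts[[5 + j]] <- .placeSegment(
            makeIdealStrand(12, LETTERS[5 + j], seqs[5 + j]), dir, at)
    }
    AtomModel(do.call(rbind, lapply(parts, atoms)))
}

#' Simulate a density map from an atomic model
#'
#' Each atom contributes an isotropic 3D Gaussian whose width follows the
#' global B factor (sigma^2 = B / (8 pi^2)) and whose mass equals the atom's
#' scattering weight (element Z, or the explicit \code{weight} column for
#' pseudo-atoms); each atom's grid footprint is normalised so the integrated
#' density is exactly proportional to the summed weights. The map is then
#' low-pass filtered to \code{resolution} and optionally degraded with
#' additive Gaussian noise. Deterministic under a fixed seed.
#'
#' @param model an \linkS4class{AtomModel}.
#' @param voxelSize voxel edge in Angstrom.
#' @param resolution target low-pass resolution in Angstrom
#'   (>= 2 * voxelSize); \code{NA} skips filtering.
#' @param bFactor global Gaussian B factor in Angstrom^2.
#' @param noiseSigma additive Gaussian noise, as a fraction of the peak
#'   noise-free signal.
#' @param seed integer seed for the noise.
#' @param box optional grid dimensions (3 integers); default sizes the box
#'   to the model plus \code{margin}.
#' @param origin optional map origin (Angstrom); default from the auto box.
#' @param margin Angstrom of padding used for the automatic box.
#' @return A \linkS4class{GridMap}.
#' @export
simulateMap <- function(model, voxelSize = 1.0, resolution = 2.5,
                        bFactor = 40, noiseSigma = 0, seed = 1,
                        box = NULL, origin = NULL, margin = 6) {
    stopifnot(is(model, "AtomModel"))
    if (!is.na(resolution) && resolution < 2 * voxelSize)
        stop("resolution must be at least twice the voxel size")
    a <- model@atoms
    xyz <- as.matrix(a[, c("x", "y", "z")])
    w <- ifelse(is.na(a$weight),
                unname(.ELEMENT_Z[a$element]), a$weight)
    if (any(is.na(w)))
        stop("unknown element(s): ",
             paste(unique(a$element[is.na(w)]), collapse = ", "))

    if (is.null(box)) {
        lo <- floor(apply(xyz, 2, min) - margin)
        hi <- ceiling(apply(xyz, 2, max) + margin)
        origin <- lo
        box <- as.integer(ceiling((hi - lo) / voxelSize)) + 1L
    } else {
        box <- as.integer(rep(box, length.out = 3L))
        if (is.null(origin)) origin <- c(0, 0, 0)
    }
    upper <- origin + (box - 1L) * voxelSize
    if (any(xyz < matrix(origin, nrow(xyz), 3, byrow = TRUE)) ||
        any(xyz > matrix(upper, nrow(xyz), 3, byrow = TRUE)))
        stop("model does not fit inside the simulation box")
    edge <- min(c(apply(xyz, 2, min) - origin, upper - apply(xyz, 2, max)))
    if (edge < 5)
        warning(sprintf("model-to-box margin %.1f A is below 5 A", edge))

    # per-atom width: the global B plus any excess of the atom's own B over
    # the baseline 20 (smeared pseudo-atoms carry their spread here)
    bAtom <- bFactor + pmax(0, a$b - 20)
    sigmaAtom <- sqrt(bAtom / (8 * pi^2))
    data <- array(0, dim = box)
    for (i in seq_len(nrow(xyz))) {
        sigma <- sigmaAtom[i]
        half <- ceiling(6 * sigma / voxelSize)
        ax1 <- seq_len(2L * half + 1L) - half - 1L
        gv <- (xyz[i, ] - origin) / voxelSize  # 0-based fractional voxel
        g0 <- round(gv)
        ix <- g0[1] + ax1; iy <- g0[2] + ax1; iz <- g0[3] + ax1
        kx <- exp(-((ix - gv[1])^2) * voxelSize^2 / (2 * sigma^2))
        ky <- exp(-((iy - gv[2])^2) * voxelSize^2 / (2 * sigma^2))
        kz <- exp(-((iz - gv[3])^2) * voxelSize^2 / (2 * sigma^2))
        okx <- ix >= 0 & ix < box[1]
        oky <- iy >= 0 & iy < box[2]
        okz <- iz >= 0 & iz < box[3]
        kern <- outer(outer(kx[okx], ky[oky]), kz[okz])
        # mass-preserving splat: grid sum * voxel^3 == atom weight
        kern <- kern * (w[i] / (sum(kx) * sum(ky) * sum(kz) * voxelSize^3))
        data[ix[okx] + 1L, iy[oky] + 1L, iz[okz] + 1L] <-
            data[ix[okx] + 1L, iy[oky] + 1L, iz[okz] + 1L] + kern
    }
    map <- GridMap(data, voxelSize = voxelSize, origin = origin,
                   resolutionHint = resolution)
    if (!is.na(resolution)) map <- lowpassFilter(map, resolution)
    if (noiseSigma > 0) {
        set.seed(as.integer(seed))
        peak <- max(abs(map@data))
        noisy <- map@data + stats::rnorm(length(map@data),
                                         sd = noiseSigma * peak)
        map <- GridMap(array(noisy, dim = box), voxelSize = voxelSize,
                       origin = origin, resolutionHint = resolution)
    }
    map
}

#' Introduce a magnification (voxel-size) error
#'
#' Multiplies the header voxel size (and origin, which is a physical
#' distance) by \code{factor}, leaving the data untouched: the map's
#' coordinates now mis-state physical distances, exactly as a microscope
#' magnification error would.
#'
#' @param map a \linkS4class{GridMap}.
#' @param factor multiplicative error; values outside [0.9, 1.1] warn but
#'   are still applied.
#' @return The perturbed \linkS4class{GridMap}.
#' @export
perturbVoxelSize <- function(map, factor) {
    stopifnot(is(map, "GridMap"), factor > 0)
    if (factor < 0.9 || factor > 1.1)
        warning(sprintf("factor %.3f outside the expected [0.9, 1.1] range",
                        factor))
    GridMap(map@data, voxelSize = map@voxelSize * factor,
            origin = map@origin * factor,
            resolutionHint = map@resolutionHint, axisOrder = map@axisOrder)
}
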