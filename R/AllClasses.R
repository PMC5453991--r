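#' @import methods
NULL

#' GridMap: a 3D density grid with physical metadata
#'
#' Container for a cryo-EM density map. Data are always held in canonical
#' x,y,z axis order (any file axis permutation is resolved at read time), so
#' conversion between grid indices and Angstrom positions never involves a
#' permutation. Position of voxel (i,j,k) (1-based) is
#' \code{origin + (c(i,j,k) - 1) * voxelSize}.
#'
#' @slot data 3D numeric array of density values, canonical x,y,z order.
#' @slot voxelSize numeric(3), Angstrom per grid step along x, y, z (> 0).
#' @slot origin numeric(3), position of grid index (1,1,1) in Angstrom.
#' @slot axisOrder integer(3), the axis permutation found in the source file
#'   (informational; data are already canonicalised).
#' @slot resolutionHint numeric(1), nominal resolution in Angstrom
#'   (\code{NA_real_} when unknown).
#' @slot cache environment used to memoise the spline-coefficient array;
#'   treated as immutable together with \code{data}.
#'
#' @exportClass GridMap
setClass("GridMap",
    representation(
        data = "array",
        voxelSize = "numeric",
        origin = "numeric",
        axisOrder = "integer",
        resolutionHint = "numeric",
        cache = "environment"
    ),
    prototype(
        voxelSize = c(1, 1, 1),
        origin = c(0, 0, 0),
        axisOrder = 1:3,
        resolutionHint = NA_real_
    )
)

setValidity("GridMap", function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
        msg <- c(msg, "data must be a 3D array")
    else if (any(dim(object@data) < 2L))
        msg <- c(msg, "data dimensions must all be >= 2")
    if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
        any(object@voxelSize <= 0))
        msg <- c(msg, "voxelSize must be 3 positive finite values")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
        msg <- c(msg, "origin must be 3 finite values")
    if (length(object@axisOrder) != 3L ||
        !setequal(object@axisOrder, 1:3))
        msg <- c(msg, "axisOrder must be a permutation of 1:3")
    if (length(msg)) msg else TRUE
})

#' Construct a GridMap
#'
#' @param data 3D numeric array (canonical x,y,z order).
#' @param voxelSize voxel edge length(s) in Angstrom; recycled to length 3.
#' @param origin position of the first voxel in Angstrom; length 3.
#' @param resolutionHint nominal resolution in Angstrom, or NA.
#' @param axisOrder axis permutation of the source file (default 1:3).
#' @return A \linkS4class{GridMap}.
#' @export
GridMap <- function(data, voxelSize = 1, origin = c(0, 0, 0),
                    resolutionHint = NA_real_, axisOrder = 1:3) {
    new("GridMap",
        data = data,
        voxelSize = rep(as.numeric(voxelSize), length.out = 3L),
        origin = as.numeric(origin),
        axisOrder = as.integer(axisOrder),
        resolutionHint = as.numeric(resolutionHint),
        cache = new.env(parent = emptyenv())
    )
}

#' AtomModel: chains, residues and atoms with coordinates
#'
#' Flat atom table (one row per atom) ordered by chain then residue number,
#' plus an optional per-residue secondary-structure label. Column
#' \code{weight} carries an explicit scattering weight for pseudo-atoms;
#' \code{NA} means "look up the element".
#'
#' @slot atoms data.frame with columns chain, resno, resname, atom, element,
#'   x, y, z, b, weight, ss (one of "H", "E", "-").
#'
#' @exportClass AtomModel
setClass("AtomModel", representation(atoms = "data.frame"))

.ATOM_COLS <- c("chain", "resno", "resname", "atom", "element",
                "x", "y", "z", "b", "weight", "ss")

setValidity("AtomModel", function(object) {
    a <- object@atoms
    msg <- character()
    if (!all(.ATOM_COLS %in% names(a)))
        msg <- c(msg, paste("atoms must have columns:",
                            paste(.ATOM_COLS, collapse = ", ")))
    else {
        if (nrow(a) && any(!is.finite(a$x) | !is.finite(a$y) |
                           !is.finite(a$z)))
            msg <- c(msg, "atom coordinates must be finite")
        if (nrow(a)) {
            bad <- vapply(split(a$resno, a$chain),
                          function(r) is.unsorted(r, strictly = FALSE),
                          logical(1))
            if (any(bad))
                msg <- c(msg, "residues within a chain must be ordered by resno")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct an AtomModel
#'
#' @param atoms data.frame of atoms; missing optional columns (\code{b},
#'   \code{weight}, \code{ss}, \code{element}) are filled with defaults.
#' @return An \linkS4class{AtomModel}.
#' @export
AtomModel <- function(atoms) {
    if (is.null(atoms$b)) atoms$b <- 20
    if (is.null(atoms$weight)) atoms$weight <- NA_real_
    if (is.null(atoms$ss)) atoms$ss <- "-"
    if (is.null(atoms$element))
        atoms$element <- substr(trimws(atoms$atom), 1L, 1L)
    atoms <- atoms[, .ATOM_COLS]
    rownames(atoms) <- NULL
    new("AtomModel", atoms = atoms)
}

#' DensityTemplate: a secondary-structure density template
#'
#' A standard helix or strand segment together with its mean density map and
#' correlation (reliability-weight) map sampled on a standard grid centred on
#' the segment's centre of mass.
#'
#' @slot kind "helix" or "strand".
#' @slot standardCoords \linkS4class{AtomModel} of the standard segment,
#'   centred on its main-chain centre of mass.
#' @slot gridPoints n x 3 matrix of standard-grid positions (Angstrom,
#'   COM-centred, within 15 Angstrom of the COM).
#' @slot meanMap numeric(n), per-point mean training density.
#' @slot corrMap numeric(n), per-point averaged correlation (in [-1, 1]).
#' @slot groupCC numeric(30), mean correlation per 0.5-Angstrom distance bin.
#' @slot distGroup integer(n), distance-bin index of each grid point.
#' @slot nSegments number of training segments used.
#' @slot sourceResolution low-pass resolution of the training map (Angstrom).
#' @slot spacing standard-grid spacing (Angstrom).
#' @slot scaleCalibration systematic magnification-bias factor of this
#'   template, measured on the known-scale training pair at build time;
#'   voxel-size scans divide their peak by it (1 = uncalibrated).
#' @slot scaleResponse length-2 response slopes (expansion side, shrinkage
#'   side) of the factor scan, measured by perturbing the training map by
#'   the edges of the +-5 percent magnification-error regime; scans invert
#'   this response (c(1, 1) = uncalibrated).
#'
#' @exportClass DensityTemplate
setClass("DensityTemplate",
    representation(
        kind = "character",
        standardCoords = "AtomModel",
        gridPoints = "matrix",
        meanMap = "numeric",
        corrMap = "numeric",
        groupCC = "numeric",
        distGroup = "integer",
        nSegments = "numeric",
        sourceResolution = "numeric",
        spacing = "numeric",
        scaleCalibration = "numeric",
        scaleResponse = "numeric"
    ),
    prototype(scaleCalibration = 1, scaleResponse = c(1, 1))
)

setValidity("DensityTemplate", function(object) {
    msg <- character()
    if (!object@kind %in% c("helix", "strand"))
        msg <- c(msg, "kind must be 'helix' or 'strand'")
    n <- nrow(object@gridPoints)
    if (length(object@meanMap) != n || length(object@corrMap) != n ||
        length(object@distGroup) != n)
        msg <- c(msg, "meanMap/corrMap/distGroup must match gridPoints rows")
    if (length(object@corrMap) &&
        any(object@corrMap < -1 - 1e-9 | object@corrMap > 1 + 1e-9))
        msg <- c(msg, "corrMap values must lie in [-1, 1]")
    if (n && any(sqrt(rowSums(object@gridPoints^2)) > 15 + 1e-6))
        msg <- c(msg, "grid points must lie within 15 Angstrom of the COM")
    if (length(msg)) msg else TRUE
})

#' Placement: a rigid pose of a template in a map
#'
#' @slot kind "helix" or "strand".
#' @slot rotation proper 3x3 rotation (standard frame -> map frame).
#' @slot translation numeric(3), Angstrom; the placed template COM.
#' @slot cc weighted correlation score at this pose.
#' @slot refined logical, TRUE after simplex refinement.
#' @slot flags character vector of diagnostic flags.
#'
#' @exportClass Placement
setClass("Placement",
    representation(
        kind = "character",
        rotation = "matrix",
        translation = "numeric",
        cc = "numeric",
        refined = "logical",
        flags = "character"
    ),
    prototype(cc = NA_real_, refined = FALSE, flags = character())
)

setValidity("Placement", function(object) {
    msg <- character()
    R <- object@rotation
    if (!all(dim(R) == c(3L, 3L)))
        msg <- c(msg, "rotation must be 3x3")
    else {
        if (max(abs(crossprod(R) - diag(3))) > 1e-6)
            msg <- c(msg, "rotation must be orthonormal")
        if (abs(det(R) - 1) > 1e-6)
            msg <- c(msg, "rotation must be proper (det = +1)")
    }
    if (length(object@translation) != 3L)
        msg <- c(msg, "translation must be length 3")
    if (!is.na(object@cc) && (object@cc < -1 - 1e-9 || object@cc > 1 + 1e-9))
        msg <- c(msg, "cc must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
})

#' Construct a Placement
#'
#' @param kind "helix" or "strand".
#' @param rotation 3x3 proper rotation.
#' @param translation numeric(3), Angstrom.
#' @param cc weighted correlation score.
#' @param refined logical.
#' @param flags character vector of diagnostic flags.
#' @return A \linkS4class{Placement}.
#' @export
Placement <- function(kind, rotation, translation, cc = NA_real_,
                      refined = FALSE, flags = character()) {
    new("Placement", kind = kind, rotation = rotation,
        translation = as.numeric(translation), cc = as.numeric(cc),
        refined = refined, flags = flags)
}

#' LLKTarget: per-offset density statistics in a local C-alpha frame
#'
#' Learned mean/variance profile of density at a fixed set of offsets around
#' a C-alpha, expressed in the canonical frame built from the
#' Ca(i-1), Ca(i), Ca(i+1) triplet. Used as a log-likelihood scoring target.
#'
#' @slot offsets m x 3 matrix of sample offsets (Angstrom) in the local frame.
#' @slot mu numeric(m), per-offset mean density.
#' @slot sigma2 numeric(m), per-offset density variance (floored > 0).
#' @slot kind "ca" for the generic target, or a residue type (e.g. "TRP").
#' @slot nTrain number of training triplets accumulated.
#'
#' @exportClass LLKTarget
setClass("LLKTarget",
    representation(
        offsets = "matrix",
        mu = "numeric",
        sigma2 = "numeric",
        kind = "character",
        nTrain = "numeric"
    )
)

setValidity("LLKTarget", function(object) {
    msg <- character()
    m <- nrow(object@offsets)
    if (length(object@mu) != m || length(object@sigma2) != m)
        msg <- c(msg, "mu/sigma2 must match the offset count")
    if (length(object@sigma2) && any(object@sigma2 <= 0))
        msg <- c(msg, "sigma2 must be strictly positive (floored)")
    if (length(msg)) msg else TRUE
})

#' ChainFragment: an ordered C-alpha trace
#'
#' @slot ca n x 3 matrix of ordered C-alpha positions (Angstrom).
#' @slot llk numeric(n), per-C-alpha log-likelihood score (NA where unscored).
#' @slot source identifier of the seeding placement.
#' @slot types character(n), residue-type assignment or NA.
#'
#' @exportClass ChainFragment
setClass("ChainFragment",
    representation(
        ca = "matrix",
        llk = "numeric",
        source = "character",
        types = "character"
    )
)

setValidity("ChainFragment", function(object) {
    msg <- character()
    n <- nrow(object@ca)
    if (ncol(object@ca) != 3L) msg <- c(msg, "ca must be n x 3")
    if (length(object@llk) != n) msg <- c(msg, "llk must match ca rows")
    if (length(object@types) != n) msg <- c(msg, "types must match ca rows")
    if (n >= 2) {
        d <- sqrt(rowSums((object@ca[-1, , drop = FALSE] -
                           object@ca[-n, , drop = FALSE])^2))
        if (any(d < 3.0 - 1e-6 | d > 4.2 + 1e-6))
            msg <- c(msg, "consecutive Ca-Ca distances must lie in [3.0, 4.2]")
    }
    if (n >= 3) {
        D <- as.matrix(dist(object@ca))
        off <- abs(row(D) - col(D)) >= 2
        if (any(D[off] < 3.0 - 1e-6))
            msg <- c(msg, "non-consecutive Ca pairs must be >= 3.0 apart")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ChainFragment
#'
#' @param ca n x 3 matrix of ordered C-alpha positions (Angstrom).
#' @param llk numeric(n) per-position scores.
#' @param source fragment source label.
#' @param types character(n) residue types or NA.
#' @return A \linkS4class{ChainFragment} (validity enforces the chain
#'   geometry invariants).
#' @export
ChainFragment <- function(ca, llk = rep(NA_real_, nrow(ca)),
                          source = "seed", types = rep(NA_character_, nrow(ca))) {
    new("ChainFragment", ca = ca, llk = as.numeric(llk),
        source = source, types = as.character(types))
}
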