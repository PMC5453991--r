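#' @rdname GridMap-class
#' @param object,x a GridMap
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname GridMap-class
#' @export
setGeneric("gridData", function(x) standardGeneric("gridData"))

#' @rdname GridMap-class
#' @export
setGeneric("mapOrigin", function(x) standardGeneric("mapOrigin"))

#' @rdname GridMap-class
#' @export
setGeneric("resolutionHint", function(x) standardGeneric("resolutionHint"))

#' @rdname AtomModel-class
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname AtomModel-class
#' @export
setGeneric("caCoords", function(x, ...) standardGeneric("caCoords"))

setMethod("voxelSize", "GridMap", function(x) x@voxelSize)
setMethod("gridData", "GridMap", function(x) x@data)
setMethod("mapOrigin", "GridMap", function(x) x@origin)
setMethod("resolutionHint", "GridMap", function(x) x@resolutionHint)

setMethod("show", "GridMap", function(object) {
    d <- dim(object@data)
    cat(sprintf("GridMap: %d x %d x %d voxels\n", d[1], d[2], d[3]))
    cat(sprintf("  voxel size (A): %.4f %.4f %.4f\n",
                object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
    cat(sprintf("  origin (A):     %.3f %.3f %.3f\n",
                object@origin[1], object@origin[2], object@origin[3]))
    cat(sprintf("  density: min %.4g  mean %.4g  max %.4g\n",
                min(object@data), mean(object@data), max(object@data)))
    if (!is.na(object@resolutionHint))
        cat(sprintf("  resolution hint: %.2f A\n", object@resolutionHint))
})

setMethod("atoms", "AtomModel", function(x) x@atoms)

#' Extract C-alpha coordinates
#'
#' @param x an AtomModel
#' @param chain optional chain identifier(s) to restrict to
#' @param ... unused
#' @return n x 3 matrix of CA coordinates in model order.
#' @export
setMethod("caCoords", "AtomModel", function(x, chain = NULL, ...) {
    a <- x@atoms
    keep <- trimws(a$atom) == "CA"
    if (!is.null(chain)) keep <- keep & a$chain %in% chain
    as.matrix(a[keep, c("x", "y", "z")])
})

setMethod("show", "AtomModel", function(object) {
    a <- object@atoms
    nres <- nrow(unique(a[, c("chain", "resno")]))
    cat(sprintf("AtomModel: %d atoms, %d residues, %d chain(s)\n",
                nrow(a), nres, length(unique(a$chain))))
    ss <- a$ss[trimws(a$atom) == "CA"]
    if (length(ss))
        cat(sprintf("  secondary structure: %d helix, %d strand, %d other\n",
                    sum(ss == "H"), sum(ss == "E"), sum(ss == "-")))
})

setMethod("show", "DensityTemplate", function(object) {
    cat(sprintf("DensityTemplate (%s): %d grid points, %d training segments\n",
                object@kind, nrow(object@gridPoints), object@nSegments))
    cat(sprintf("  spacing %.2f A, source resolution %.2f A\n",
                object@spacing, object@sourceResolution))
    cat(sprintf("  corrMap range: %.3f .. %.3f\n",
                min(object@corrMap), max(object@corrMap)))
})

setMethod("show", "Placement", function(object) {
    cat(sprintf("Placement (%s): COM (%.2f, %.2f, %.2f) A, cc = %.3f%s\n",
                object@kind, object@translation[1], object@translation[2],
                object@translation[3], object@cc,
                if (object@refined) " [refined]" else ""))
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "LLKTarget", function(object) {
    cat(sprintf("LLKTarget (%s): %d offsets, trained on %d triplets\n",
                object@kind, nrow(object@offsets), object@nTrain))
})

setMethod("show", "ChainFragment", function(object) {
    cat(sprintf("ChainFragment: %d C-alphas (source %s)%s\n",
                nrow(object@ca), object@source,
                if (all(is.na(object@types))) "" else ", typed"))
})
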