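# Two-stage pipeline orchestration: secondary-structure stage (template
# search + voxel-size refinement) followed by the C-alpha stage (reference
# scaling, LLK training, extension, optional sequence assignment).

#' Default pipeline configuration
#'
#' Every tunable of the pipeline with its documented default. Fields may be
#' overridden via \code{runPipeline(config = list(...))} or a YAML file.
#'
#' @return named list of defaults.
#' @export
defaultConfig <- function() {
    list(
        workingMap = NULL,        # path to MRC, or a GridMap
        resolution = NULL,        # working map resolution (Angstrom), required
        referenceMap = NULL,      # path to MRC, or a GridMap
        referenceModel = NULL,    # path to PDB, or an AtomModel
        sequence = NULL,          # FASTA path or sequence string (optional)
        templates = NULL,         # list(helix=, strand=) archives (optional)
        outDir = NULL,            # output directory (optional)
        nResidues = NULL,         # residues to build (or use mass)
        mass = NULL,              # Daltons; nResidues = mass / 110
        seed = 1L,
        refineVoxel = TRUE,       # voxel-refinement stage toggle
        sidechains = TRUE,        # sequence/side-chain assignment toggle
        templateResolution = 2.5, # template low-pass (Angstrom)
        templateSpacing = 0.5,    # standard-grid spacing (Angstrom)
        nKeep = 25L,              # fast-search candidates per kind
        candCCMin = 0.15,         # candidate CC floor before refinement
        ccMin = 0.3,              # selection threshold (top-20 gate)
        nTop = 20L,               # placements kept per kind
        densityWeight = 2,        # extension density-bonus weight
        seqMargin = 0.05          # sequence-assignment acceptance margin
    )
}

#' Read a pipeline configuration file
#'
#' Flat YAML key-value file; unknown keys are rejected, missing keys take
#' the documented defaults.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
readConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    def <- defaultConfig()
    unknown <- setdiff(names(cfg), names(def))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    utils::modifyList(def, cfg)
}

.asMap <- function(x, resolution = NA_real_) {
    if (is(x, "GridMap")) return(x)
    readMap(x, resolutionHint = resolution)
}

.asModel <- function(x) {
    if (is(x, "AtomModel")) return(x)
    readModel(x)
}

.stageMsg <- function(verbose, ...) if (verbose) message("[cryobuild] ", ...)

#' Run the full model-building pipeline
#'
#' Executes: template preparation, secondary-structure search, voxel-size
#' refinement, reference-map scaling, LLK-target training, C-alpha
#' extension, fragment merging, optional sequence assignment, and output.
#' Identical configuration and seed give identical outputs.
#'
#' @param config list of configuration values (see
#'   \code{\link{defaultConfig}}); missing entries take defaults.
#' @param verbose print stage progress to stderr.
#' @return list with the built \code{model} (\linkS4class{AtomModel}),
#'   \code{fragments}, \code{placements}, \code{voxel} (refinement result),
#'   \code{scaledReference}, \code{llk}, and \code{config}.
#' @export
runPipeline <- function(config = list(), verbose = TRUE) {
    cfg <- utils::modifyList(defaultConfig(), config)
    if (is.null(cfg$workingMap)) stop("config: workingMap is required")
    if (is.null(cfg$resolution)) stop("config: resolution is required")
    set.seed(as.integer(cfg$seed))
    outDir <- cfg$outDir
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    emit <- function(name, fn) {
        if (!is.null(outDir)) fn(file.path(outDir, name))
    }

    working <- .asMap(cfg$workingMap, cfg$resolution)
    if (is.na(working@resolutionHint))
        working@resolutionHint <- cfg$resolution

    ## --- templates ---------------------------------------------------
    .stageMsg(verbose, "stage: templates")
    if (!is.null(cfg$templates)) {
        th <- loadTemplate(cfg$templates$helix)
        ts <- loadTemplate(cfg$templates$strand)
    } else {
        if (is.null(cfg$referenceMap) || is.null(cfg$referenceModel))
            stop("stage templates: need template archives or a reference map/model pair")
        refMap <- .asMap(cfg$referenceMap)
        refModel <- .asModel(cfg$referenceModel)
        th <- calibrateTemplate(
            buildTemplate(refMap, refModel, "helix",
                          filterResolution = cfg$templateResolution,
                          spacing = cfg$templateSpacing), refMap)
        ts <- calibrateTemplate(
            buildTemplate(refMap, refModel, "strand",
                          filterResolution = cfg$templateResolution,
                          spacing = cfg$templateSpacing), refMap)
    }

    ## --- secondary-structure stage ------------------------------------
    .stageMsg(verbose, "stage: secondary-structure search + voxel refinement")
    if (cfg$refineVoxel) {
        vox <- refineVoxelSize(working, th, ts, nKeep = cfg$nKeep,
                               candCCMin = cfg$candCCMin,
                               verbose = verbose)
        corrected <- vox$map
        ratio <- vox$vNew / vox$vOri
        rescalePl <- function(p) {
            p@translation <- p@translation * ratio
            p
        }
        placements <- c(
            if (!is.null(vox$helix)) lapply(vox$helix$placements, rescalePl),
            if (!is.null(vox$strand)) lapply(vox$strand$placements, rescalePl))
        emit("scan_profile.tsv", function(f) {
            tabs <- list()
            for (kind in c("helix", "strand")) {
                r <- vox[[kind]]
                if (!is.null(r))
                    tabs[[kind]] <- data.frame(kind = kind, m = r$factors,
                                               ccSum = r$ccSum)
            }
            utils::write.table(do.call(rbind, tabs), f, sep = "\t",
                               quote = FALSE, row.names = FALSE)
        })
        emit("corrected.mrc", function(f) writeMap(corrected, f))
    } else {
        runKind <- function(template) {
            cand <- fastSearch(working, template, nKeep = cfg$nKeep)
            cand <- Filter(function(p) !is.na(p@cc) && p@cc > cfg$candCCMin,
                           cand)
            ref <- lapply(cand, function(p) refinePose(working, template, p))
            selectTop(ref, template, ccMin = cfg$ccMin, nTop = cfg$nTop)
        }
        vox <- list(vOri = mean(working@voxelSize),
                    vNew = mean(working@voxelSize))
        corrected <- working
        placements <- c(runKind(th), runKind(ts))
    }
    emit("placements.tsv", function(f)
        writePlacements(placements, th, tablePath = f))
    for (kind in c("helix", "strand")) {
        pk <- Filter(function(p) p@kind == kind, placements)
        tmplK <- if (kind == "helix") th else ts
        if (length(pk))
            emit(paste0("placements_", kind, ".pdb"),
                 function(f) writePlacements(pk, tmplK, pdbPath = f))
    }

    ## --- C-alpha stage ------------------------------------------------
    model <- NULL; fragments <- list(); llk <- NULL; scaledRef <- NULL
    if (!is.null(cfg$referenceMap) && !is.null(cfg$referenceModel)) {
        .stageMsg(verbose, "stage: reference scaling + LLK training")
        refMap <- .asMap(cfg$referenceMap)
        refModel <- .asModel(cfg$referenceModel)
        scaledRef <- scaleReference(refMap, corrected, cfg$resolution)
        emit("scaled_reference.mrc", function(f) writeMap(scaledRef, f))
        emit("guinier_working.tsv",
             function(f) writeGuinierTable(corrected, f))
        emit("guinier_reference.tsv",
             function(f) writeGuinierTable(scaledRef, f))
        llk <- trainLLKTarget(scaledRef, refModel,
                              withTypes = isTRUE(cfg$sidechains))

        .stageMsg(verbose, "stage: C-alpha extension")
        nResidues <- cfg$nResidues
        if (is.null(nResidues) && !is.null(cfg$mass))
            nResidues <- round(cfg$mass / 110)
        stdCA <- lapply(list(helix = th, strand = ts), function(t)
            caCoords(t@standardCoords))
        # shared acceptance threshold from all seed interiors
        seeds <- lapply(seq_along(placements), function(i) {
            p <- placements[[i]]
            ca <- stdCA[[p@kind]] %*% t(p@rotation)
            sweep(ca, 2, p@translation, "+")
        })
        fragments <- list()
        total <- 0L
        for (i in seq_along(seeds)) {
            if (!is.null(nResidues) && total >= nResidues) break
            fr <- extendChain(corrected, llk$ca, seeds[[i]],
                              densityWeight = cfg$densityWeight,
                              source = sprintf("sse%02d", i))
            fragments[[length(fragments) + 1L]] <- fr
            total <- total + nrow(fr@ca)
        }
        fragments <- mergeFragments(fragments)

        if (isTRUE(cfg$sidechains) && !is.null(cfg$sequence) &&
            length(llk$types)) {
            .stageMsg(verbose, "stage: sequence assignment")
            sq <- cfg$sequence
            if (length(sq) == 1L && file.exists(sq))
                sq <- paste(readFasta(sq), collapse = "")
            fragments <- assignSequence(corrected, fragments, sq,
                                        llk$types, margin = cfg$seqMargin)
        }
        model <- fragmentsToModel(fragments)
        emit("model.pdb", function(f) writeModel(model, f))
    }

    .stageMsg(verbose, "pipeline complete")
    list(model = model, fragments = fragments, placements = placements,
         voxel = vox, scaledReference = scaledRef, llk = llk,
         templates = list(helix = th, strand = ts), config = cfg)
}
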