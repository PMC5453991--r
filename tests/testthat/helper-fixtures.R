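# Shared, lazily built fixtures. Everything is generated in code (no stored
# data); expensive objects are memoised for the duration of the test run.

.fx <- new.env(parent = emptyenv())

.memo <- function(name, builder) {
    if (is.null(.fx[[name]])) .fx[[name]] <- builder()
    .fx[[name]]
}

fxToyModel <- function() .memo("toyModel", makeToyProtein)

fxToyMap <- function() .memo("toyMap", function()
    simulateMap(fxToyModel(), voxelSize = 1.0, resolution = 2.5))

fxRefModel <- function() .memo("refModel", makeReferenceProtein)

fxRefMap <- function() .memo("refMap", function()
    simulateMap(fxRefModel(), voxelSize = 1.0, resolution = 2.5))

# uncalibrated templates (fast; enough for most unit tests)
fxHelixTemplate <- function() .memo("helixTemplate", function()
    buildTemplate(fxToyMap(), fxToyModel(), "helix"))

fxStrandTemplate <- function() .memo("strandTemplate", function()
    buildTemplate(fxToyMap(), fxToyModel(), "strand"))

# calibrated templates (expensive; used by the acceptance suite)
fxCalTemplates <- function() .memo("calTemplates", function() list(
    helix = calibrateTemplate(fxHelixTemplate(), fxToyMap()),
    strand = calibrateTemplate(fxStrandTemplate(), fxToyMap())))

# search + refine + select on the toy map with the calibrated templates
fxToyPlacements <- function() .memo("toyPlacements", function() {
    tm <- fxCalTemplates()
    runKind <- function(template) {
        cand <- fastSearch(fxToyMap(), template)
        cand <- Filter(function(p) !is.na(p@cc) && p@cc > 0.15, cand)
        ref <- lapply(cand, function(p) refinePose(fxToyMap(), template, p))
        selectTop(ref, template)
    }
    list(helix = runKind(tm$helix), strand = runKind(tm$strand))
})

# LLK targets trained on the independent reference fixture, scaled onto the
# toy working map
fxLLK <- function() .memo("llk", function() {
    scaled <- scaleReference(fxRefMap(), fxToyMap(), 2.5)
    suppressWarnings(trainLLKTarget(scaled, fxRefModel()))
})

# main-chain COM of every template-length window of a toy-protein SSE chain
fxWindowCOMs <- function(chain, len) {
    a <- atoms(fxToyModel())
    mc <- c("N", "CA", "C", "O")
    resnos <- sort(unique(a$resno[a$chain == chain]))
    t(vapply(seq_len(length(resnos) - len + 1L), function(s) {
        sel <- a$chain == chain & a$resno %in% resnos[s:(s + len - 1L)] &
            a$atom %in% mc
        colMeans(as.matrix(a[sel, c("x", "y", "z")]))
    }, numeric(3)))
}

# smallest distance from any placement COM to any window COM of a chain
fxBestCOMError <- function(placements, chain, len) {
    wc <- fxWindowCOMs(chain, len)
    min(vapply(placements, function(p)
        min(sqrt(rowSums(sweep(wc, 2, p@translation)^2))), numeric(1)))
}

# rotation angle (degrees) between two rotation matrices
rotationAngle <- function(R1, R2) {
    tr <- sum(diag(t(R1) %*% R2))
    acos(min(1, max(-1, (tr - 1) / 2))) * 180 / pi
}

# random proper rotation
randomRotation <- function() {
    v <- stats::rnorm(3)
    cryobuild:::rotvecToMatrix(v / sqrt(sum(v^2)) * stats::runif(1, 0, pi))
}
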