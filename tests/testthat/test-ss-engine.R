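# Template search and pose scoring.

# small template-like object over arbitrary points
miniTemplate <- function(pts, meanMap, corrMap, kind = "helix") {
    new("DensityTemplate", kind = kind,
        standardCoords = standardSegment(kind),
        gridPoints = pts, meanMap = meanMap, corrMap = corrMap,
        groupCC = rep(0.5, 30),
        distGroup = rep(1L, nrow(pts)), nSegments = 5,
        sourceResolution = 2.5, spacing = 1, scaleCalibration = 1,
        scaleResponse = c(1, 1))
}

test_that("weighted CC matches a direct-sum weighted-Pearson oracle", {
    set.seed(10)
    for (k in 1:5) {
        map <- GridMap(array(rnorm(6^3), dim = c(6, 6, 6)), voxelSize = 1)
        pts <- matrix(runif(3 * 40, 0.5, 4.5), 40, 3) -
            matrix(c(2.5, 2.5, 2.5), 40, 3, byrow = TRUE)
        mn <- rnorm(40)
        w0 <- runif(40)
        tm <- miniTemplate(pts, mn, w0)
        R <- randomRotation() * 0 + diag(3)  # identity pose, centre of grid
        tr <- c(2.5, 2.5, 2.5)
        got <- weightedCC(map, tm, R, tr)
        # oracle: interpolate, then the weighted-Pearson sums written out
        x <- interpolateMap(map, sweep(pts %*% t(R), 2, tr, "+"))
        x[is.na(x)] <- 0
        w <- pmax(w0, 0); sw <- sum(w)
        mx <- sum(w * x) / sw; my <- sum(w * mn) / sw
        oracle <- sum(w * (x - mx) * (mn - my)) /
            (sw * sqrt(sum(w * (x - mx)^2) / sw) *
                  sqrt(sum(w * (mn - my)^2) / sw))
        expect_equal(got, oracle, tolerance = 1e-10)
    }
})

test_that("weighted CC is affine-invariant in the density and antisymmetric", {
    set.seed(11)
    map <- GridMap(array(rnorm(6^3), dim = c(6, 6, 6)), voxelSize = 1)
    pts <- matrix(runif(3 * 30, 0.5, 4.5), 30, 3) -
        matrix(c(2.5, 2.5, 2.5), 30, 3, byrow = TRUE)
    tm <- miniTemplate(pts, rnorm(30), runif(30))
    tr <- c(2.5, 2.5, 2.5)
    cc0 <- weightedCC(map, tm, diag(3), tr)
    mapA <- GridMap(3.7 * gridData(map) + 11, voxelSize = 1)
    expect_equal(weightedCC(mapA, tm, diag(3), tr), cc0, tolerance = 1e-10)
    mapN <- GridMap(-gridData(map), voxelSize = 1)
    expect_equal(weightedCC(mapN, tm, diag(3), tr), -cc0, tolerance = 1e-10)
})

test_that("a template matches its own simulated density nearly perfectly", {
    std <- standardSegment("helix")
    map <- simulateMap(std, voxelSize = 1, resolution = 2.5, margin = 8)
    pts <- cryobuild:::.templateGrid(1.0)
    keep <- sqrt(rowSums(pts^2)) <= 8
    pts <- pts[keep, , drop = FALSE]
    mn <- interpolateMap(map, pts)
    mn[is.na(mn)] <- 0
    tm <- miniTemplate(pts, mn, rep(1, nrow(pts)))  # uniform weights
    expect_gt(weightedCC(map, tm, diag(3), c(0, 0, 0)), 0.95)
})

test_that("fast search finds an isolated helix near its true pose", {
    h <- cryobuild:::.placeSegment(makeIdealHelix(8), c(0, 0, 1), c(0, 0, 0))
    map <- simulateMap(h, voxelSize = 1, resolution = 2.5, margin = 9)
    tm <- fxHelixTemplate()
    cand <- suppressWarnings(fastSearch(map, tm, nKeep = 10))
    expect_gt(length(cand), 0L)
    coll <- collectSegments(h, "helix")
    trueCOM <- t(vapply(coll$segments, `[[`, numeric(3), "translation"))
    errs <- vapply(cand, function(p)
        min(sqrt(rowSums(sweep(trueCOM, 2, p@translation)^2))), numeric(1))
    expect_lt(min(errs), 2)
    # axis within 20 degrees (antiparallel counts)
    axis <- cryobuild:::.templateAxis(tm)
    best <- cand[[which.min(errs)]]
    aTrue <- as.vector(coll$segments[[1]]$rotation %*% axis)
    aGot <- as.vector(best@rotation %*% axis)
    ang <- acos(min(1, abs(sum(aTrue * aGot))))
    expect_lt(ang * 180 / pi, 20)
})

test_that("an empty map yields only low-confidence candidates", {
    empty <- GridMap(array(0, dim = c(30, 30, 30)), voxelSize = 1)
    cand <- suppressWarnings(fastSearch(empty, fxHelixTemplate(),
                                        nKeep = 5))
    expect_true(all(vapply(cand, function(p)
        "low-confidence" %in% p@flags, logical(1))))
    expect_true(all(vapply(cand, function(p) p@cc == 0, logical(1))))
})

test_that("two identical well-separated helices are both found", {
    h1 <- cryobuild:::.placeSegment(makeIdealHelix(8, "A"), c(0, 0, 1),
                                    c(0, 0, 0))
    h2 <- cryobuild:::.placeSegment(makeIdealHelix(8, "B"), c(0, 0, 1),
                                    c(16, 0, 0))
    both <- AtomModel(rbind(atoms(h1), atoms(h2)))
    map <- simulateMap(both, voxelSize = 1, resolution = 2.5, margin = 8)
    cand <- suppressWarnings(fastSearch(map, fxHelixTemplate(), nKeep = 20))
    com <- t(vapply(cand, function(p) p@translation, numeric(3)))
    near1 <- min(sqrt(rowSums(sweep(com, 2, c(0, 0, 0))^2)))
    near2 <- min(sqrt(rowSums(sweep(com, 2, c(16, 0, 0))^2)))
    expect_lt(near1, 3.5)
    expect_lt(near2, 3.5)
})

test_that("simplex refinement never lowers the CC and recovers from offsets", {
    # self-match fixture: the template's mean map is the map's own density,
    # so the CC optimum coincides with the true pose
    std <- standardSegment("helix")
    map <- simulateMap(std, voxelSize = 1, resolution = 2.5, margin = 9)
    pts <- cryobuild:::.templateGrid(0.8)
    pts <- pts[sqrt(rowSums(pts^2)) <= 9, , drop = FALSE]
    mn <- interpolateMap(map, pts)
    mn[is.na(mn)] <- 0
    tm <- miniTemplate(pts, mn, rep(1, nrow(pts)))
    truePose <- Placement("helix", diag(3), c(0, 0, 0))

    r0 <- refinePose(map, tm, truePose)
    expect_lt(sqrt(sum(r0@translation^2)), 0.2 + 1e-9)
    expect_lt(rotationAngle(r0@rotation, diag(3)), 2)

    set.seed(12)
    for (k in 1:3) {
        ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
        Rp <- cryobuild:::rotvecToMatrix(ax * 15 * pi / 180)
        dt <- rnorm(3); dt <- dt / sqrt(sum(dt^2)) * 1.5
        start <- Placement("helix", Rp, dt)
        cc0 <- weightedCC(map, tm, Rp, dt)
        rr <- refinePose(map, tm, start)
        expect_gte(rr@cc, cc0 - 1e-12)  # monotone contract
        expect_lt(sqrt(sum(rr@translation^2)), 0.3)
        expect_lt(rotationAngle(rr@rotation, diag(3)), 3)
    }
    # the contract also holds on a realistic map with the real template
    cand <- suppressWarnings(fastSearch(fxToyMap(), fxHelixTemplate(),
                                        nKeep = 3))
    for (p in cand) {
        r <- refinePose(fxToyMap(), fxHelixTemplate(), p)
        expect_gte(r@cc, p@cc - 1e-12)
    }
})

test_that("top selection enforces the CC gate, the cap and redundancy pruning", {
    tm <- fxHelixTemplate()
    set.seed(13)
    mk <- function(cc, tr, R = diag(3))
        Placement("helix", R, tr, cc = cc, refined = TRUE)
    # 25 distinct placements all above the gate -> exactly 20 kept
    pls <- lapply(1:25, function(i)
        mk(0.31 + i / 100, c(5 * i, 0, 0)))
    top <- selectTop(pls, tm)
    expect_equal(length(top), 20L)
    expect_equal(top[[1]]@cc, max(vapply(pls, function(p) p@cc, numeric(1))))
    # all at/below the gate -> empty
    expect_equal(length(selectTop(lapply(1:5, function(i)
        mk(0.3, c(5 * i, 0, 0))), tm)), 0L)
    # duplicates (same pose, jittered) collapse to the best one
    dup <- c(lapply(1:5, function(i) mk(0.4 + i / 100,
                                        c(0.1 * i, 0, 0))),
             list(mk(0.9, c(30, 0, 0))))
    topd <- selectTop(dup, tm)
    expect_equal(length(topd), 2L)
    expect_equal(sort(vapply(topd, function(p) p@cc, numeric(1))),
                 c(0.45, 0.9))
})
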