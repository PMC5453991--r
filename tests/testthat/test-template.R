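# Template construction: segment collection, mean map, distance groups,
# correlation map.

test_that("segment collection keeps matching geometry and rejects mismatches", {
    std <- standardSegment("helix")
    coll <- collectSegments(std, "helix")
    expect_equal(length(coll$segments), 1L)
    expect_lt(coll$segments[[1]]$rmsd, 1e-9)

    h <- makeIdealHelix(10)
    collH <- collectSegments(h, "helix")
    expect_equal(length(collH$segments), 5L)  # 10 - 6 + 1 sliding windows
    expect_true(all(vapply(collH$segments, `[[`, numeric(1), "rmsd") < 0.05))

    # a strand window tested against the helix standard is rejected
    s <- makeIdealStrand(6)
    a <- atoms(s); a$ss <- "H"  # mislabel so windows are offered
    expect_warning(collMis <- collectSegments(new("AtomModel", atoms = a),
                                              "helix"),
                   "no labelled SSE")
    expect_equal(length(collMis$segments), 0L)
})

test_that("distance groups follow floor(L/0.5)+1 with the 15 A cut", {
    expect_equal(assignDistanceGroup(0.2), 1L)
    expect_equal(assignDistanceGroup(0.5), 2L)
    expect_equal(assignDistanceGroup(14.99), 30L)
    expect_true(is.na(assignDistanceGroup(15.0)))
    expect_true(is.na(assignDistanceGroup(20)))
    expect_error(assignDistanceGroup(-0.1), "non-negative")
    L <- seq(0, 16, by = 0.01)
    g <- assignDistanceGroup(L)
    expect_equal(g[L < 15], as.integer(floor(L[L < 15] / 0.5)) + 1L)
})

test_that("mean map matches a direct-summation oracle", {
    set.seed(7)
    S <- matrix(rnorm(10 * 200), 10, 200)
    expect_equal(computeMeanMap(S[1, , drop = FALSE]), S[1, ])
    expect_equal(computeMeanMap(rbind(S[1, ], -S[1, ])), rep(0, 200))
    oracle <- vapply(seq_len(200), function(k) sum(S[, k]) / 10, numeric(1))
    expect_equal(computeMeanMap(S), oracle, tolerance = 1e-12)
    expect_error(computeMeanMap(S[0, , drop = FALSE]), "no training")
})

test_that("correlation map matches a per-group Pearson oracle", {
    set.seed(8)
    n <- 5; K <- 300
    S <- matrix(rnorm(n * K), n, K)
    groups <- sample(1:6, K, replace = TRUE)  # only groups 1..6 populated
    mn <- computeMeanMap(S)
    got <- suppressWarnings(computeCorrelationMap(S, mn, groups))
    for (i in 1:6) {
        k <- which(groups == i)
        rhos <- vapply(seq_len(n), function(s) cor(S[s, k], mn[k]),
                       numeric(1))
        expect_equal(got$groupCC[i], mean(rhos), tolerance = 1e-10)
        expect_true(all(abs(got$corrMap[k] - got$groupCC[i]) < 1e-12))
    }
    expect_true(all(got$groupCC[7:30] == 0))

    # identical segments correlate perfectly in every populated group
    Sid <- matrix(rep(rnorm(K), 4), 4, K, byrow = TRUE)
    gid <- suppressWarnings(computeCorrelationMap(Sid, computeMeanMap(Sid),
                                                  groups))
    expect_true(all(abs(gid$groupCC[1:6] - 1) < 1e-9))

    # independent noise: group correlations are small. Each segment's own
    # contribution to the mean leaves E[rho] ~ 1/sqrt(n_segments), so with
    # 100 noise segments the group correlation sits near 0.1.
    set.seed(9)
    Sn <- matrix(rnorm(100 * 400), 100, 400)
    gn <- rep(1L, 400)
    cn <- suppressWarnings(computeCorrelationMap(Sn, computeMeanMap(Sn), gn))
    expect_lt(abs(cn$groupCC[1]), 0.15)
})

test_that("built templates are deterministic, order-invariant and scale-covariant", {
    t1 <- fxHelixTemplate()
    expect_gte(t1@nSegments, 3)
    expect_true(all(t1@corrMap >= -1 & t1@corrMap <= 1))
    t2 <- buildTemplate(fxToyMap(), fxToyModel(), "helix")
    expect_identical(t1@meanMap, t2@meanMap)
    expect_identical(t1@corrMap, t2@corrMap)

    # global density rescale: mean x c, correlation map unchanged
    mapC <- GridMap(gridData(fxToyMap()) * 2.5,
                    voxelSize = voxelSize(fxToyMap()),
                    origin = mapOrigin(fxToyMap()))
    t3 <- buildTemplate(mapC, fxToyModel(), "helix")
    expect_equal(t3@meanMap, 2.5 * t1@meanMap, tolerance = 1e-9)
    expect_equal(t3@corrMap, t1@corrMap, tolerance = 1e-9)

    # correlation is strongest near the backbone on the fixture ensemble
    expect_gt(mean(t1@groupCC[1:4]), mean(t1@groupCC[20:30]))
})

test_that("sampling respects the 15 A support and drops truncated segments", {
    tm <- fxHelixTemplate()
    expect_lte(max(sqrt(rowSums(tm@gridPoints^2))), 15 + 1e-9)
    # a transform placing the segment far outside the map is dropped
    expect_warning(
        v <- sampleSegmentDensity(fxToyMap(), diag(3), c(500, 500, 500),
                                  tm@gridPoints),
        "outside")
    expect_null(v)
    # identity sampling on a node-aligned grid returns stored values
    m <- GridMap(array(rnorm(20^3), dim = c(20, 20, 20)), voxelSize = 1,
                 origin = c(-10, -10, -10))
    pts <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
    v2 <- sampleSegmentDensity(m, diag(3), c(0, 0, 0), pts)
    idx <- sweep(pts, 2, c(-10, -10, -10)) + 1
    expect_equal(v2, gridData(m)[idx], tolerance = 1e-9)
})

test_that("template archives round-trip", {
    tm <- fxHelixTemplate()
    p <- withr::local_tempfile(fileext = ".rds")
    saveTemplate(tm, p)
    t2 <- loadTemplate(p)
    expect_identical(t2@meanMap, tm@meanMap)
    expect_identical(t2@corrMap, tm@corrMap)
    expect_identical(t2@scaleCalibration, tm@scaleCalibration)
    expect_error(suppressWarnings(
        loadTemplate(withr::local_tempfile(fileext = ".rds"))))
})
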