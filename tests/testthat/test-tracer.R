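# LLK targets, chain extension, fragment merging, sequence assignment,
# evaluation.

test_that("training on a constant map gives flat mu and floored variance", {
    const <- GridMap(array(3, dim = c(40, 40, 40)), voxelSize = 1,
                     origin = c(-20, -20, -20))
    h <- makeIdealHelix(12)
    tgt <- suppressWarnings(trainLLKTarget(const, h, withTypes = FALSE))
    expect_true(all(abs(tgt$ca@mu - 3) < 1e-9))
    expect_lt(max(tgt$ca@sigma2), 1e-9)  # at the (tiny) variance floor
    expect_gt(min(tgt$ca@sigma2), 0)
})

test_that("mu is higher near the backbone than in the normal direction", {
    llk <- fxLLK()
    off <- llk$ca@offsets
    near <- sqrt(rowSums(off^2)) < 1.5
    farNormal <- abs(off[, 3]) > 3.2  # e3: normal to the chain plane
    expect_gt(mean(llk$ca@mu[near]), mean(llk$ca@mu[farNormal]))
})

test_that("targets trained on disjoint halves of the reference agree", {
    scaled <- scaleReference(fxRefMap(), fxToyMap(), 2.5)
    a <- atoms(fxRefModel())
    chains <- sort(unique(a$chain))
    half1 <- new("AtomModel",
                 atoms = a[a$chain %in% chains[c(1, 3, 6, 8)], ])
    half2 <- new("AtomModel",
                 atoms = a[a$chain %in% chains[c(2, 4, 5, 7, 9)], ])
    t1 <- suppressWarnings(trainLLKTarget(scaled, half1, withTypes = FALSE))
    t2 <- suppressWarnings(trainLLKTarget(scaled, half2, withTypes = FALSE))
    expect_gt(cor(t1$ca@mu, t2$ca@mu), 0.9)
})

test_that("the LLK score discriminates true C-alpha poses from solvent", {
    llk <- fxLLK()
    map <- fxToyMap()
    frames <- cryobuild:::.modelFrames(fxToyModel())
    sTrue <- vapply(frames, function(fr)
        llkScore(map, llk$ca, fr$pos, fr$rot), numeric(1))
    set.seed(15)
    d <- dim(gridData(map)); o <- mapOrigin(map)
    rnd <- cbind(runif(3000, o[1] + 5, o[1] + d[1] - 6),
                 runif(3000, o[2] + 5, o[2] + d[2] - 6),
                 runif(3000, o[3] + 5, o[3] + d[3] - 6))
    vals <- interpolateMap(map, rnd)
    solv <- rnd[vals < stats::quantile(gridData(map), 0.5), , drop = FALSE]
    solv <- solv[seq_len(min(1000, nrow(solv))), , drop = FALSE]
    sSolv <- apply(solv, 1, function(p) llkScore(map, llk$ca, p))
    expect_gt(mean(sTrue), stats::median(sSolv))
    pooled <- sqrt((stats::var(sTrue) * (length(sTrue) - 1) +
                    stats::var(sSolv) * (length(sSolv) - 1)) /
                   (length(sTrue) + length(sSolv) - 2))
    expect_gt((mean(sTrue) - mean(sSolv)) / pooled, 3)
})

test_that("a single-offset target reduces to negative squared error ranking", {
    tgt <- new("LLKTarget", offsets = matrix(0, 1, 3), mu = 2, sigma2 = 1,
               kind = "ca", nTrain = 10)
    m <- GridMap(array(seq(0, 7, length.out = 8^3), dim = c(8, 8, 8)),
                 voxelSize = 1)
    pos <- rbind(c(2, 2, 2), c(4, 4, 4), c(6, 6, 6))
    sc <- apply(pos, 1, function(p) llkScore(m, tgt, p))
    rho <- interpolateMap(m, pos)
    expect_equal(order(sc), order(-(rho - 2)^2))
    expect_equal(sc, -(rho - 2)^2 / 2 - 0.5 * log(1), tolerance = 1e-9)
})

test_that("the LLK score is equivariant under joint map/pose shifts", {
    llk <- fxLLK()
    map <- fxToyMap()
    shifted <- GridMap(gridData(map), voxelSize = voxelSize(map),
                       origin = mapOrigin(map) + c(7, -3, 2))
    frames <- cryobuild:::.modelFrames(fxToyModel())[1:10]
    for (fr in frames) {
        s1 <- llkScore(map, llk$ca, fr$pos, fr$rot)
        s2 <- llkScore(shifted, llk$ca, fr$pos + c(7, -3, 2), fr$rot)
        expect_equal(s1, s2, tolerance = 1e-9)
    }
})

test_that("extension stops at the ends of an isolated helix", {
    h <- cryobuild:::.placeSegment(makeIdealHelix(6), c(0, 0, 1), c(0, 0, 0))
    map <- simulateMap(h, voxelSize = 1, resolution = 2.5, margin = 10)
    llk <- fxLLK()
    ca <- caCoords(h)
    fr <- extendChain(map, llk$ca, ca)
    expect_lte(nrow(fr@ca), 6L + 2L)  # at most 1 extra residue per end
    validObject(fr)
})

test_that("extension from SSE seeds recovers most of the toy protein", {
    llk <- fxLLK()
    pls <- fxToyPlacements()
    tm <- fxCalTemplates()
    stdCA <- list(helix = caCoords(tm$helix@standardCoords),
                  strand = caCoords(tm$strand@standardCoords))
    all <- c(pls$helix, pls$strand)
    frs <- lapply(seq_along(all), function(i) {
        p <- all[[i]]
        seed <- sweep(stdCA[[p@kind]] %*% t(p@rotation), 2,
                      p@translation, "+")
        extendChain(fxToyMap(), llk$ca, seed, source = sprintf("s%02d", i))
    })
    for (f in frs) validObject(f)  # all geometry invariants hold
    merged <- mergeFragments(frs)
    for (f in merged) validObject(f)
    ev <- evaluateModel(fragmentsToModel(merged), fxToyModel())
    expect_gte(ev$coverage2, 70)
    .fx$tracedFragments <- merged  # reused by the acceptance suite
})

test_that("fragment merging joins split chains and removes duplicates", {
    ca <- caCoords(makeIdealHelix(10))
    f1 <- ChainFragment(ca[1:5, ], llk = rep(-1, 5), source = "a")
    f2 <- ChainFragment(ca[6:10, ], llk = rep(-2, 5), source = "b")
    m <- mergeFragments(list(f1, f2))
    expect_equal(length(m), 1L)
    expect_equal(nrow(m[[1]]@ca), 10L)
    # identical duplicates: one survivor
    m2 <- mergeFragments(list(f1, ChainFragment(ca[1:5, ],
                                                llk = rep(-3, 5))))
    expect_equal(length(m2), 1L)
    expect_equal(m2[[1]]@llk, rep(-1, 5))  # the better mean LLK wins
    # random fragment soup: output is pairwise non-overlapping
    set.seed(16)
    soup <- list()
    for (k in 1:6) {
        n <- sample(4:8, 1)
        start <- runif(3, -20, 20)
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        pts <- t(sapply(0:(n - 1), function(i) start + i * 3.8 * dir))
        soup[[k]] <- ChainFragment(pts, llk = rnorm(n))
    }
    out <- mergeFragments(soup)
    allCA <- do.call(rbind, lapply(out, function(f) f@ca))
    tags <- rep(seq_along(out), vapply(out, function(f) nrow(f@ca),
                                       integer(1)))
    D <- as.matrix(dist(allCA))
    cross <- outer(tags, tags, "!=")
    if (any(cross)) expect_gte(min(D[cross]), 3.0 - 1e-9)
})

test_that("sequence assignment recovers the register and refuses ambiguity", {
    llk <- fxLLK()
    map <- fxToyMap()
    # fragment = the true CA trace of toy helix A (sequence AAWLASAFVALSAWA)
    caA <- caCoords(fxToyModel(), chain = "A")
    frag <- ChainFragment(caA, llk = rep(-1, nrow(caA)), source = "A")
    out <- assignSequence(map, list(frag), "AAWLASAFVALSAWA", llk$types,
                          margin = 0.02)
    expect_false(all(is.na(out[[1]]@types)))
    expect_equal(out[[1]]@types, unname(cryobuild:::.AA13[
        strsplit("AAWLASAFVALSAWA", "")[[1]]]))
    # a two-fold ambiguous poly-ALA sequence yields no assignment
    amb <- assignSequence(map, list(frag), strrep("A", 20), llk$types)
    expect_true(all(is.na(amb[[1]]@types)))
    # reversing the sequence reverses the recovered direction
    rev1 <- assignSequence(map, list(frag),
                           paste(rev(strsplit("AAWLASAFVALSAWA", "")[[1]]),
                                 collapse = ""), llk$types, margin = 0.02)
    expect_equal(rev1[[1]]@types, out[[1]]@types)
    # a fragment longer than the sequence is flagged, not assigned
    long <- assignSequence(map, list(frag), "AAW", llk$types)
    expect_true(grepl("seq-too-short", long[[1]]@source))
})

test_that("model evaluation matches a brute-force nearest-neighbour oracle", {
    tp <- fxToyModel()
    ev <- evaluateModel(tp, tp)
    expect_equal(ev$within1, 100)
    expect_equal(ev$within2, 100)
    expect_lt(ev$rmsd, 1e-6)

    evs <- evaluateModel(cryobuild:::.transformModel(tp, diag(3),
                                                     c(1.5, 0, 0)), tp)
    expect_equal(evs$within1, 0)
    expect_equal(evs$within2, 100)
    expect_equal(evs$rmsd, 1.5, tolerance = 1e-9)

    set.seed(17)
    fake <- fxToyModel()
    af <- atoms(fake)
    af$x <- af$x + rnorm(nrow(af), sd = 2)
    af$y <- af$y + rnorm(nrow(af), sd = 2)
    af$z <- af$z + rnorm(nrow(af), sd = 2)
    fake <- new("AtomModel", atoms = af)
    ev2 <- evaluateModel(fake, tp)
    cb <- caCoords(fake); ct <- caCoords(tp)
    dOracle <- apply(cb, 1, function(p)
        min(sqrt(colSums((t(ct) - p)^2))))
    expect_equal(ev2$within1, 100 * mean(dOracle < 1))
    expect_equal(ev2$within2, 100 * mean(dOracle < 2))
    expect_equal(ev2$rmsd, sqrt(mean(dOracle^2)), tolerance = 1e-12)
})
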